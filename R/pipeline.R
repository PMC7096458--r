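#' Run the two-stage semi-supervised deconvolution pipeline
#'
#' Applies optional gene filtering (low expression, then coefficient of
#' variation), then Stage I (marker-anchored clustering of row-normalized
#' gene vectors, exhaustive vertex search, novel-marker extraction) and
#' Stage II (marker-constrained KL-NMF on the filtered expression matrix
#' using the Stage-I marker catalog). An empty `known_markers` list yields
#' the fully unsupervised CAM-mode pipeline (`L = 0`).
#'
#' @param Y expression matrix (genes x samples).
#' @param known_markers marker catalog for `L <= K` cell types, or `list()`.
#' @param K number of cell types in the mixture.
#' @param C number of k-means clusters (`K <= C <= m`).
#' @param seed integer seed covering clustering and NMF initialization.
#' @param drop_low fraction of low-mean genes to drop first (0 disables).
#' @param keep_cv fraction of top-CV genes kept after the first filter
#'   (1 disables).
#' @param normalize row-normalize gene vectors before Stage I geometry.
#' @param kmeans_restarts k-means restarts in Stage I.
#' @param candidate_budget cap on the number of vertex-search subsets.
#' @param stage2 a [stage2_config()]; its `seed` is overridden by `seed`.
#' @return object of class `semicam_result`: list with `proportions`,
#'   `signature`, `identified_markers`, `selection`, `cluster_model`,
#'   `trace`, `config_snapshot`, `seed`.
#' @export
run_semicam <- function(Y, known_markers = list(), K, C = 50L, seed = 1L,
                        drop_low = 0, keep_cv = 1, normalize = TRUE,
                        kmeans_restarts = 10L, candidate_budget = 1e6,
                        stage2 = stage2_config()) {
  validate_expression(Y)
  L <- length(known_markers)
  if (L > K) stop("more marker cell types than cell types K", call. = FALSE)
  if (K > C) stop("need K <= C clusters", call. = FALSE)

  if (drop_low > 0) Y <- filter_low_expression(Y, drop_low)
  if (keep_cv < 1) Y <- filter_top_cv(Y, keep_cv)
  zero_rows <- rowSums(Y) <= 0
  if (any(zero_rows)) {
    warning(sum(zero_rows), " all-zero gene row(s) removed before deconvolution",
            call. = FALSE)
    Y <- Y[!zero_rows, , drop = FALSE]
  }
  if (L > 0L) known_markers <- align_markers(known_markers, Y)

  Ygeom <- if (normalize) normalize_rows(Y) else Y
  model <- withCallingHandlers(
    cluster_anchored(Ygeom, known_markers, C, seed = seed,
                     restarts = kmeans_restarts, normalized = normalize),
    error = function(e) stop("stage I (clustering): ", conditionMessage(e),
                             call. = FALSE))
  selection <- tryCatch(
    find_vertices(model, K, L, candidate_budget = candidate_budget),
    error = function(e) stop("stage I (vertex search): ",
                             conditionMessage(e), call. = FALSE))
  identified <- extract_novel_markers(model, selection, known_markers)

  stage2$seed <- as.integer(seed)
  fit <- tryCatch(
    seminmf_fit(Y, identified, config = stage2),
    error = function(e) stop("stage II (semi-NMF): ", conditionMessage(e),
                             call. = FALSE))

  structure(list(proportions = fit$P, signature = fit$X,
                 identified_markers = identified, selection = selection,
                 cluster_model = model, trace = fit$trace,
                 config_snapshot = list(K = K, C = C, L = L,
                                        drop_low = drop_low, keep_cv = keep_cv,
                                        normalize = normalize,
                                        kmeans_restarts = kmeans_restarts,
                                        candidate_budget = candidate_budget,
                                        stage2 = unclass(stage2)),
                 seed = as.integer(seed)),
            class = "semicam_result")
}

#' @export
print.semicam_result <- function(x, ...) {
  cs <- x$config_snapshot
  cat("semi-CAM deconvolution: K =", cs$K, "cell types, L =", cs$L,
      "anchored, C =", cs$C, "clusters\n")
  cat("vertex clusters:",
      paste(x$selection$vertex_cluster_indices, collapse = " "),
      "| total margin", format(x$selection$total_margin, digits = 5), "\n")
  cat("stage II:", x$trace$iterations_run, "iterations",
      if (x$trace$converged) "(converged)\n" else "(not converged)\n")
  cat("estimated proportions (first samples):\n")
  print(round(x$proportions[, seq_len(min(5L, ncol(x$proportions))),
                            drop = FALSE], 4))
  invisible(x)
}

#' Multi-seed ensemble deconvolution
#'
#' Runs [run_semicam()] with seeds `base_seed .. base_seed + n_runs - 1`,
#' matches every run's components to the first successful run's components
#' (via [match_cell_types()] on the proportion matrices), averages the
#' matched proportion matrices element-wise, and renormalizes columns to sum
#' to one. Averaging over seeds smooths out the randomness of the clustering
#' and NMF initializations.
#'
#' @param Y expression matrix.
#' @param known_markers marker catalog or `list()`.
#' @param K number of cell types.
#' @param C number of clusters.
#' @param n_runs ensemble size.
#' @param base_seed first seed.
#' @param ... further arguments passed to [run_semicam()].
#' @return a `semicam_result` whose `proportions` is the ensemble average;
#'   `runs` holds the per-run results and `n_runs_used` the number of
#'   successful runs.
#' @export
run_ensemble <- function(Y, known_markers = list(), K, C = 50L,
                         n_runs = 100L, base_seed = 1L, ...) {
  stopifnot(n_runs >= 1L)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    runs[[r]] <- tryCatch(
      run_semicam(Y, known_markers, K = K, C = C,
                  seed = base_seed + r - 1L, ...),
      error = function(e) {
        warning("ensemble run ", r, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) stop("all ensemble runs failed", call. = FALSE)
  runs <- runs[ok]
  ref <- runs[[1L]]$proportions
  acc <- matrix(0, nrow(ref), ncol(ref))
  for (res in runs) {
    perm <- match_cell_types(res$proportions, ref)
    acc <- acc + align_to_truth(res$proportions, perm)
  }
  P <- acc / length(runs)
  P <- sweep(P, 2L, colSums(P), "/")
  dimnames(P) <- dimnames(ref)
  out <- runs[[1L]]
  out$proportions <- P
  out$runs <- runs
  out$n_runs_used <- length(runs)
  out
}
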