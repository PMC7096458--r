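#' Simulation configuration
#'
#' Governs the heteroscedastic noise added to simulated mixtures. The noise
#' for a mixture entry with expected signal `s` is Gaussian with standard
#' deviation `sigma = 2^(alpha * log2 s) = s^alpha`, so `alpha` ties the
#' noise magnitude to the signal: for signals above 1, larger `alpha` means
#' stronger noise (`alpha = 0.85` plays the weak-noise setting and
#' `alpha = 0.9` the strong one).
#'
#' @param alpha noise exponent (>= 0).
#' @param n_samples number of mixture samples (>= 2).
#' @param seed integer seed.
#' @param clip_negative set negative post-noise values to 0 (default TRUE).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(alpha = 0.85, n_samples = 10L, seed = 1L,
                              clip_negative = TRUE) {
  stopifnot(alpha >= 0, n_samples >= 2L)
  structure(list(alpha = alpha, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), clip_negative = clip_negative),
            class = "simulation_config")
}

#' Generate a block-marker signature matrix and its true marker catalog
#'
#' Emulates pure cell-line profiles: every gene gets a baseline expression
#' drawn log-uniformly over `[2^4, 2^12]` (the working range of
#' linear-scale microarray intensities), shared across cell types; for each
#' cell type, `markers_per_type` exclusive genes have their expression
#' multiplied by `fold` in that cell type's column only.
#'
#' @param m number of genes (>= `K * markers_per_type`).
#' @param K number of cell types.
#' @param markers_per_type exclusive marker genes per cell type.
#' @param fold marker over-expression factor (> 1).
#' @param seed integer seed.
#' @return list with `X` (m x K signature matrix, gene ids `gene_1..gene_m`,
#'   cell types `celltype_1..celltype_K`) and `markers` (the true catalog;
#'   empty list when `markers_per_type = 0`).
#' @export
make_signature <- function(m, K, markers_per_type = 20L, fold = 10,
                           seed = 1L) {
  stopifnot(K >= 1L, markers_per_type >= 0L, fold > 1)
  if (m < K * markers_per_type)
    stop("m must be at least K * markers_per_type", call. = FALSE)
  gene_ids <- sprintf("gene_%d", seq_len(m))
  types <- sprintf("celltype_%d", seq_len(K))
  baseline <- with_seed(seed, 2^runif(m, 4, 12))
  X <- matrix(baseline, m, K, dimnames = list(gene_ids, types))
  markers <- list()
  if (markers_per_type > 0L) {
    for (k in seq_len(K)) {
      idx <- ((k - 1L) * markers_per_type + 1L):(k * markers_per_type)
      X[idx, k] <- X[idx, k] * fold
      markers[[types[k]]] <- gene_ids[idx]
    }
    markers <- marker_catalog(markers)
  }
  list(X = X, markers = markers)
}

#' Simulate mixing proportions
#'
#' Draws `K * n_samples` independent Uniform(0,1) values and scales each
#' sample's column to sum to one.
#'
#' @param K number of cell types.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return a K x n_samples proportion matrix with rownames
#'   `celltype_1..celltype_K` and colnames `sample_1..sample_n`.
#' @export
simulate_proportions <- function(K, n_samples, seed = 1L) {
  stopifnot(K >= 1L, n_samples >= 1L)
  P <- with_seed(seed, matrix(runif(K * n_samples), K, n_samples))
  P <- sweep(P, 2L, colSums(P), "/")
  dimnames(P) <- list(sprintf("celltype_%d", seq_len(K)),
                      sprintf("sample_%d", seq_len(n_samples)))
  validate_proportions(P)
  P
}

#' Simulate a noisy bulk mixture from known factors
#'
#' The expected signal is `S = X P`; each observed value is
#' `y_ij = s_ij + e_ij` with `e_ij ~ N(0, s_ij^(2 alpha))`, i.e. noise
#' standard deviation `sigma_ij = 2^(alpha * log2 s_ij) = s_ij^alpha`.
#' Entries with zero signal stay noiseless. Negative values are clipped to
#' zero when `config$clip_negative` is set. The noise stream is seeded from
#' `config$seed`, independent of the proportion stream.
#'
#' @param X signature matrix (genes x cell types).
#' @param P proportion matrix (cell types x samples).
#' @param config a [simulation_config()].
#' @return the simulated bulk data: a validated expression matrix when
#'   `clip_negative` is on; otherwise a plain numeric matrix that may
#'   contain negative entries.
#' @export
simulate_mixture <- function(X, P, config = simulation_config()) {
  validate_signature(X)
  validate_proportions(P)
  if (ncol(X) != nrow(P))
    stop("X and P do not conform (cell-type dimension)", call. = FALSE)
  S <- X %*% P
  sigma <- S^config$alpha
  sigma[S == 0] <- 0
  E <- with_seed(config$seed + 500000L,
                 matrix(rnorm(length(S), sd = sigma), nrow(S), ncol(S)))
  Y <- S + E
  colnames(Y) <- if (!is.null(colnames(P))) colnames(P) else
    sprintf("sample_%d", seq_len(ncol(P)))
  rownames(Y) <- rownames(X)
  if (!config$clip_negative) return(Y)  # may hold negatives: plain matrix
  Y[Y < 0] <- 0
  expression_matrix(Y, gene_ids = rownames(X), sample_ids = colnames(Y))
}

#' Simulate a complete benchmark-style dataset
#'
#' Convenience wrapper tying together [make_signature()],
#' [simulate_proportions()] and [simulate_mixture()] with independently
#' seeded sub-streams derived from one seed.
#'
#' @param m number of genes.
#' @param K number of cell types.
#' @param markers_per_type exclusive markers per cell type.
#' @param fold marker over-expression factor.
#' @param alpha noise exponent.
#' @param n_samples number of mixture samples.
#' @param seed integer master seed.
#' @return list with `Y` (bulk mixture), `X` (true signature), `P` (true
#'   proportions), `markers` (true marker catalog).
#' @export
simulate_dataset <- function(m = 1000L, K = 4L, markers_per_type = 20L,
                             fold = 10, alpha = 0.85, n_samples = 10L,
                             seed = 1L) {
  sig <- make_signature(m, K, markers_per_type, fold, seed = seed)
  P <- simulate_proportions(K, n_samples, seed = seed + 100000L)
  cfg <- simulation_config(alpha = alpha, n_samples = n_samples, seed = seed)
  Y <- simulate_mixture(sig$X, P, cfg)
  list(Y = Y, X = sig$X, P = P, markers = sig$markers)
}
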