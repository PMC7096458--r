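# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Row-sum normalize an expression matrix
#'
#' Divides every gene vector by its row sum so that gene vectors live on the
#' perspective-projected simplex used by convex analysis of mixtures: after
#' normalization, mixture gene vectors are convex combinations of the
#' cell-type vertices.
#'
#' @param Y expression matrix with strictly positive row sums.
#' @return the normalized matrix (rows sum to 1).
#' @export
normalize_rows <- function(Y) {
  validate_expression(Y)
  rs <- rowSums(Y)
  if (any(rs <= 0))
    stop("gene(s) with zero row sum cannot be normalized: ",
         paste(rownames(Y)[rs <= 0][seq_len(min(5L, sum(rs <= 0)))],
               collapse = ", "), call. = FALSE)
  Y / rs
}

#' Initial cluster centers for marker-anchored k-means
#'
#' The first L centers are the per-cell-type means of the known marker genes;
#' the remaining `C - L` centers are distinct non-marker gene rows sampled
#' uniformly without replacement.
#'
#' @param Y expression matrix (typically row-normalized).
#' @param markers marker catalog (L cell types).
#' @param C total number of clusters, `C >= L`.
#' @param seed integer seed for the random center draw.
#' @return list with `centers` (C x n matrix), `anchored_types` (cell type
#'   names of the first L centers) and `random_gene_ids`.
#' @export
init_centers <- function(Y, markers, C, seed = 1L) {
  validate_expression(Y)
  if (length(markers) > 0L) markers <- align_markers(markers, Y)
  L <- length(markers)
  if (C < L) stop("C must be at least the number of anchored cell types",
                  call. = FALSE)
  marker_genes <- unlist(markers, use.names = FALSE)
  free <- setdiff(rownames(Y), marker_genes)
  if (C - L > length(free))
    stop("C - L exceeds the number of non-marker genes", call. = FALSE)
  anchored <- if (L > 0L)
    t(vapply(markers, function(g)
      colMeans(Y[g, , drop = FALSE]), numeric(ncol(Y))))
  else matrix(numeric(0), 0L, ncol(Y))
  picked <- if (C - L > 0L) with_seed(seed, sample(free, C - L)) else character(0)
  centers <- rbind(anchored, Y[picked, , drop = FALSE])
  rownames(centers) <- NULL
  list(centers = centers, anchored_types = names(markers),
       random_gene_ids = picked)
}

# Lloyd k-means with deterministic tie-breaking (lowest cluster index) and
# an explicit empty-cluster policy: an emptied center is re-seeded at the
# point farthest from its nearest center and the iteration continues. The
# policy, and ties resolving to the anchored (first) clusters, are what the
# anchored clustering needs on degenerate inputs where stats::kmeans stops.
lloyd_kmeans <- function(X, centers, iter.max = 200L) {
  m <- nrow(X); C <- nrow(centers)
  xsq <- rowSums(X^2)
  assign_pts <- function(centers) {
    d2 <- xsq - 2 * X %*% t(centers) +
      matrix(rowSums(centers^2), m, C, byrow = TRUE)
    list(cl = max.col(-d2, ties.method = "first"), d2 = d2)
  }
  cl_old <- integer(m)
  reseeded <- 0L
  for (it in seq_len(iter.max)) {
    a <- assign_pts(centers)
    cl <- a$cl
    repeat {
      sizes <- tabulate(cl, C)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      dmin <- a$d2[cbind(seq_len(m), cl)]
      far <- which.max(dmin)
      centers[empty[1L], ] <- X[far, ]
      a$d2[, empty[1L]] <-
        xsq - 2 * as.numeric(X %*% centers[empty[1L], ]) +
        sum(centers[empty[1L], ]^2)
      cl <- max.col(-a$d2, ties.method = "first")
      reseeded <- reseeded + 1L
      if (reseeded > 10L * C) break  # fewer distinct points than centers
    }
    sizes <- tabulate(cl, C)
    forced <- FALSE
    while (any(sizes == 0L)) {
      # duplicated points cannot be separated by distance; split the largest
      # cluster by fiat and keep that partition (no further Lloyd steps,
      # which would undo the split)
      empty1 <- which(sizes == 0L)[1L]
      donor <- which.max(sizes)
      mv <- tail(which(cl == donor), 1L)
      cl[mv] <- empty1
      sizes <- tabulate(cl, C)
      forced <- TRUE
    }
    centers <- rowsum(X, cl) / sizes
    if (forced || identical(cl, cl_old)) break
    cl_old <- cl
  }
  d2 <- xsq - 2 * X %*% t(centers) +
    matrix(rowSums(centers^2), m, C, byrow = TRUE)
  tot_withinss <- sum(pmax(d2[cbind(seq_len(m), cl)], 0))
  if (reseeded > 0L)
    message("k-means re-seeded ", reseeded, " empty cluster(s)")
  list(cluster = setNames(cl, rownames(X)), centers = centers,
       tot.withinss = tot_withinss)
}

# Replace each cell type's marker rows by their average so that k-means
# necessarily keeps them together (identical points share a cluster).
collapse_marker_rows <- function(Y, markers) {
  for (g in markers) {
    avg <- colMeans(Y[g, , drop = FALSE])
    Y[g, ] <- matrix(avg, length(g), ncol(Y), byrow = TRUE)
  }
  Y
}

#' Marker-anchored k-means clustering of genes
#'
#' Each cell type's known marker rows are replaced by their average (forcing
#' co-clustering), k-means is run from [init_centers()] with Euclidean
#' distance, and the clusters are relabelled so that clusters `1..L` are the
#' anchored clusters containing the markers of cell types `1..L`. The
#' non-anchored initial centers are redrawn across `restarts` restarts
#' (anchored centers stay fixed) and the solution with the lowest total
#' within-cluster sum of squares that keeps the L anchored clusters distinct
#' wins.
#'
#' @param Y expression matrix (row-normalize first for CAM geometry).
#' @param markers marker catalog; may be empty (`list()`) for the fully
#'   unsupervised mode.
#' @param C number of clusters.
#' @param seed integer seed.
#' @param restarts number of k-means restarts.
#' @param normalized flag recorded on the model stating whether `Y` was
#'   row-normalized by the caller.
#' @return an object of class `cluster_model`: list with `assignments`
#'   (named integer vector over genes), `centers` (C x n), `anchored`
#'   (indices `1..L`), `C`, `L`, `sizes`, `tot_withinss`, `normalized`.
#' @export
cluster_anchored <- function(Y, markers, C, seed = 1L, restarts = 10L,
                             normalized = FALSE) {
  validate_expression(Y)
  if (length(markers) > 0L) markers <- align_markers(markers, Y)
  L <- length(markers)
  if (C < 1L || C > nrow(Y)) stop("C must lie in [1, m]", call. = FALSE)
  Ywork <- if (L > 0L) collapse_marker_rows(Y, markers) else Y

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 0:4) {
      init <- init_centers(Ywork, markers, C, seed = seed + 1000L * r + attempt)
      if (anyDuplicated(init$centers)) next
      fit <- tryCatch(
        suppressMessages(lloyd_kmeans(Ywork, init$centers, iter.max = 200L)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (L > 0L) {
      anchor_cl <- vapply(markers, function(g) {
        cl <- unique(fit$cluster[g])
        # identical rows can only split on exact distance ties; unify
        if (length(cl) > 1L) cl <- as.integer(names(which.max(table(fit$cluster[g]))))
        cl[1L]
      }, integer(1))
      if (anyDuplicated(anchor_cl)) next  # two marker groups merged
    }
    if (is.null(best) || fit$tot.withinss < best$fit$tot.withinss)
      best <- list(fit = fit,
                   anchor_cl = if (L > 0L) anchor_cl else integer(0))
  }
  if (is.null(best))
    stop("k-means failed to produce ", C,
         " clusters with distinct anchored clusters; lower C or restarts",
         call. = FALSE)

  fit <- best$fit
  cluster <- fit$cluster
  if (L > 0L) for (l in seq_len(L)) cluster[markers[[l]]] <- best$anchor_cl[l]
  # relabel: anchored clusters first, remaining clusters in index order
  new_order <- c(best$anchor_cl, setdiff(seq_len(C), best$anchor_cl))
  relabel <- integer(C); relabel[new_order] <- seq_len(C)
  assignments <- setNames(relabel[cluster], rownames(Y))
  centers <- fit$centers[new_order, , drop = FALSE]
  rownames(centers) <- NULL
  colnames(centers) <- colnames(Y)
  # recompute centers from the clustering input to reflect any tie unification
  for (cl in seq_len(C))
    centers[cl, ] <- colMeans(Ywork[assignments == cl, , drop = FALSE])
  structure(list(assignments = assignments, centers = centers,
                 anchored = seq_len(L), C = as.integer(C), L = as.integer(L),
                 anchored_types = names(markers),
                 sizes = tabulate(assignments, C),
                 tot_withinss = fit$tot.withinss, normalized = normalized),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Marker-anchored k-means model: C =", x$C, "clusters,",
      x$L, "anchored,", length(x$assignments), "genes\n")
  cat("cluster sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

# Euclidean projection of v onto the probability simplex (sort-based).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  pmax(v - (css[rho] - 1) / rho, 0)
}

#' Margin-of-error: distance from a point to the convex hull of vertices
#'
#' Computes `delta = min_alpha || g - V' alpha ||_2` subject to
#' `alpha >= 0, sum(alpha) = 1` — the Euclidean distance from a cluster
#' center to the simplex spanned by a candidate vertex set — together with
#' the minimizing convex weights. Solved by non-negative least squares on a
#' sum-to-one-augmented system, refined by projected gradient descent.
#'
#' @param g numeric vector of length n (a cluster center).
#' @param vertices K x n matrix whose rows are the candidate vertices.
#' @return list of class `margin_result` with `delta` and `weights`.
#' @export
margin_of_error <- function(g, vertices) {
  V <- as.matrix(vertices)
  if (ncol(V) != length(g))
    stop("vertex dimension does not match center dimension", call. = FALSE)
  K <- nrow(V)
  if (K == 1L) {
    return(structure(list(delta = sqrt(sum((g - V[1L, ])^2)), weights = 1),
                     class = "margin_result"))
  }
  if (K <= 10L) {
    sol <- simplex_lsq_exact(matrix(g, 1L), V)
    alpha <- sol$weights[, 1L]
    delta <- sol$deltas[1L]
  } else {
    alpha <- simplex_lsq_iterative(g, V)
    delta <- sqrt(max(sum((g - as.numeric(t(V) %*% alpha))^2), 0))
  }
  structure(list(delta = delta, weights = alpha), class = "margin_result")
}

# Exact simplex-constrained least squares for small K, vectorized over many
# target points at once; the compiled support-enumeration solver does the
# work (see src/simplex.cpp).
# `Gm`: M x n matrix of target points (rows); `V`: K x n vertex matrix.
simplex_lsq_exact <- function(Gm, V) {
  cpp_simplex_lsq(V %*% t(V), V %*% t(Gm), rowSums(Gm^2))
}

# Projected-gradient solver used when K is too large for support
# enumeration.
simplex_lsq_iterative <- function(g, V) {
  K <- nrow(V)
  G <- V %*% t(V)
  h <- as.numeric(V %*% g)
  alpha <- rep(1 / K, K)
  step <- 1 / max(sum(abs(G)), 1e-12)
  f <- function(a) 0.5 * sum((g - as.numeric(t(V) %*% a))^2)
  fa <- f(alpha)
  for (it in seq_len(5000L)) {
    grad <- as.numeric(G %*% alpha) - h
    newa <- project_simplex(alpha - step * grad)
    fn <- f(newa)
    if (fn > fa) break
    conv <- fa - fn <= 1e-13 * max(fa, 1e-30)
    alpha <- newa
    fa <- fn
    if (conv) break
  }
  alpha
}

#' Exhaustive simplex-vertex search over cluster centers
#'
#' Enumerates every subset of `K - L` non-anchored cluster centers, combines
#' it with the L anchored centers, sums the margins-of-error of all remaining
#' (non-vertex) centers to that candidate simplex, and returns the candidate
#' minimizing the total margin. Ties are broken by the lexicographically
#' smallest index tuple.
#'
#' @param model a `cluster_model`.
#' @param K number of cell types (vertices to select), `L <= K <= C`.
#' @param L number of anchored clusters (defaults to the model's).
#' @param candidate_budget maximum number of subsets to enumerate.
#' @return object of class `vertex_selection`: list with
#'   `vertex_cluster_indices` (length K, first L anchored), `total_margin`,
#'   and `n_candidates_evaluated`.
#' @export
find_vertices <- function(model, K, L = model$L, candidate_budget = 1e6) {
  stopifnot(inherits(model, "cluster_model"))
  C <- model$C
  if (L > K || K > C)
    stop("need L <= K <= C (got L=", L, ", K=", K, ", C=", C, ")",
         call. = FALSE)
  n_cand <- choose(C - L, K - L)
  if (n_cand > candidate_budget)
    stop("vertex search would enumerate ", n_cand,
         " candidate subsets (budget ", candidate_budget,
         "); lower the number of clusters C", call. = FALSE)
  anchored <- seq_len(L)
  free <- setdiff(seq_len(C), anchored)
  subsets <- if (K - L > 0L) combn(free, K - L) else matrix(integer(0), 0L, 1L)
  if (K <= 10L) {
    res <- cpp_vertex_search(tcrossprod(model$centers),
                             matrix(as.integer(subsets),
                                    nrow = nrow(subsets),
                                    ncol = ncol(subsets)),
                             as.integer(anchored))
    return(structure(list(
      vertex_cluster_indices = res$vertex_cluster_indices,
      total_margin = res$total_margin,
      n_candidates_evaluated = as.integer(res$n_candidates_evaluated)),
      class = "vertex_selection"))
  }
  best_total <- Inf
  best_idx <- NULL
  for (j in seq_len(ncol(subsets))) {
    vidx <- c(anchored, subsets[, j])
    others <- setdiff(seq_len(C), vidx)
    Vm <- model$centers[vidx, , drop = FALSE]
    total <- 0
    for (cc in others) {
      total <- total + margin_of_error(model$centers[cc, ], Vm)$delta
      if (total >= best_total) break
    }
    if (total < best_total) {
      best_total <- total
      best_idx <- vidx
    }
  }
  structure(list(vertex_cluster_indices = best_idx, total_margin = best_total,
                 n_candidates_evaluated = ncol(subsets)),
            class = "vertex_selection")
}

#' @export
print.vertex_selection <- function(x, ...) {
  cat("Vertex selection:", paste(x$vertex_cluster_indices, collapse = " "),
      "| total margin", format(x$total_margin, digits = 6),
      "|", x$n_candidates_evaluated, "candidates\n")
  invisible(x)
}

#' Extract the marker catalog implied by the selected vertex clusters
#'
#' Every gene belonging to a selected vertex cluster becomes a marker of the
#' corresponding cell type. Anchored vertices keep their input cell-type
#' names (and thus retain the known markers in their lists); newly selected
#' vertices receive synthetic names `"celltype_<k>*"`.
#'
#' @param model a `cluster_model`.
#' @param selection a `vertex_selection` from [find_vertices()].
#' @param known the input marker catalog (may be empty list).
#' @return a marker catalog over all K cell types.
#' @export
extract_novel_markers <- function(model, selection, known = list()) {
  stopifnot(inherits(model, "cluster_model"),
            inherits(selection, "vertex_selection"))
  idx <- selection$vertex_cluster_indices
  L <- model$L
  genes_by_cluster <- split(names(model$assignments), model$assignments)
  entries <- list()
  for (k in seq_along(idx)) {
    nm <- if (k <= L) model$anchored_types[k] else paste0("celltype_", k, "*")
    entries[[nm]] <- genes_by_cluster[[as.character(idx[k])]]
  }
  marker_catalog(entries)
}
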