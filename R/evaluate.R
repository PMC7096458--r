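# Row-wise Pearson correlations between two K x n matrices; a constant row
# (zero variance) correlates 0 by convention for matching purposes.
rowwise_cor <- function(A, B) {
  K <- nrow(A)
  M <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (sd(A[i, ]) == 0 || sd(B[j, ]) == 0) next
    M[i, j] <- cor(A[i, ], B[j, ])
  }
  M
}

# Hungarian algorithm (Jonker-style shortest augmenting path with dual
# potentials) minimizing the total cost of a square assignment.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L              # columns indexed 1..n as 2..n+1; slot 1 is virtual
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)              # assignment[row] = column
  for (j in 2L:(n + 1L)) assignment[p[j]] <- j - 1L
  assignment
}

#' Match estimated components to true cell types
#'
#' Finds the bijection between the rows of the estimated and true proportion
#' matrices that maximizes the sum of row-wise Pearson correlations, by
#' optimal assignment (Hungarian algorithm) on the K x K correlation matrix.
#' Rows with zero variance are given correlation 0 for matching purposes.
#'
#' @param P_est estimated proportion matrix (K x n).
#' @param P_true true proportion matrix (K x n).
#' @return integer vector `perm` of length K: `perm[i] = j` means estimated
#'   row `i` corresponds to true row `j`. Named by the estimated rownames
#'   when present.
#' @export
match_cell_types <- function(P_est, P_true) {
  if (!all(dim(P_est) == dim(P_true)))
    stop("P_est and P_true must have the same shape", call. = FALSE)
  M <- rowwise_cor(P_est, P_true)
  perm <- solve_assignment(-M)
  names(perm) <- rownames(P_est)
  perm
}

# Reorder estimated rows so row j of the result corresponds to true row j.
align_to_truth <- function(P_est, perm) {
  aligned <- P_est
  aligned[perm, ] <- P_est
  rn <- rownames(P_est)
  if (!is.null(rn)) rownames(aligned)[perm] <- rn
  aligned
}

#' Pooled Pearson correlation between matched proportion matrices
#'
#' Correlation over all `K * n` paired entries after applying the row
#' matching — the single-number accuracy summary quoted for a deconvolution
#' run.
#'
#' @param P_est estimated proportion matrix.
#' @param P_true true proportion matrix.
#' @param perm matching from [match_cell_types()]; computed when `NULL`.
#' @return scalar correlation in `[-1, 1]`.
#' @export
pooled_pearson <- function(P_est, P_true, perm = NULL) {
  if (is.null(perm)) perm <- match_cell_types(P_est, P_true)
  aligned <- align_to_truth(P_est, perm)
  if (sd(aligned) == 0 || sd(P_true) == 0)
    stop("degenerate evaluation: zero variance in pooled proportions",
         call. = FALSE)
  cor(as.vector(aligned), as.vector(P_true))
}

#' Per-sample root-mean-square error of matched proportions
#'
#' For each sample j, `sqrt(mean_k (phat_kj - p_kj)^2)` after row matching.
#'
#' @param P_est estimated proportion matrix.
#' @param P_true true proportion matrix.
#' @param perm matching from [match_cell_types()]; computed when `NULL`.
#' @return numeric vector of length n (named by sample ids when present).
#' @export
rmse_per_sample <- function(P_est, P_true, perm = NULL) {
  if (is.null(perm)) perm <- match_cell_types(P_est, P_true)
  aligned <- align_to_truth(P_est, perm)
  out <- sqrt(colMeans((aligned - P_true)^2))
  names(out) <- colnames(P_true)
  out
}

#' Full accuracy report for an estimated proportion matrix
#'
#' @param P_est estimated proportion matrix.
#' @param P_true true proportion matrix.
#' @return object of class `evaluation_report`: list with `permutation`,
#'   `pooled_pearson`, `per_type_pearson` (one correlation per true cell
#'   type) and `rmse_per_sample`.
#' @export
evaluate_proportions <- function(P_est, P_true) {
  perm <- match_cell_types(P_est, P_true)
  aligned <- align_to_truth(P_est, perm)
  per_type <- vapply(seq_len(nrow(P_true)), function(k) {
    if (sd(aligned[k, ]) == 0 || sd(P_true[k, ]) == 0) return(0)
    cor(aligned[k, ], P_true[k, ])
  }, numeric(1))
  names(per_type) <- rownames(P_true)
  structure(list(permutation = perm,
                 pooled_pearson = pooled_pearson(P_est, P_true, perm),
                 per_type_pearson = per_type,
                 rmse_per_sample = rmse_per_sample(P_est, P_true, perm)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Deconvolution accuracy report\n")
  cat("  pooled Pearson r:", format(x$pooled_pearson, digits = 4), "\n")
  cat("  per-type r:", paste(format(x$per_type_pearson, digits = 3),
                             collapse = " "), "\n")
  cat("  mean per-sample RMSE:",
      format(mean(x$rmse_per_sample), digits = 4), "\n")
  invisible(x)
}
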