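#' Configuration for the marker-constrained NMF stage
#'
#' @param max_iter maximum number of alternating update iterations.
#' @param tol convergence threshold on the relative change of the objective.
#' @param epsilon positive guard added inside divisions and logarithms.
#' @param seed integer seed for the random initialization.
#' @param divergence `"KL"` (generalized Kullback-Leibler, default) or
#'   `"Euclidean"` (squared Frobenius).
#' @param n_restarts number of random restarts; the fit with the lowest final
#'   objective is returned.
#' @return a list of class `stage2_config`.
#' @export
stage2_config <- function(max_iter = 2000L, tol = 1e-6, epsilon = 1e-12,
                          seed = 1L, divergence = c("KL", "Euclidean"),
                          n_restarts = 1L) {
  divergence <- match.arg(divergence)
  stopifnot(max_iter >= 1L, tol > 0, epsilon > 0, n_restarts >= 1L)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 epsilon = epsilon, seed = as.integer(seed),
                 divergence = divergence, n_restarts = as.integer(n_restarts)),
            class = "stage2_config")
}

#' Generalized Kullback-Leibler divergence between two matrices
#'
#' `D(Y, Yhat) = sum_ij [ y log(y / yhat) - y + yhat ]` with the convention
#' `0 * log 0 = 0`.
#'
#' @param Y non-negative matrix of observations.
#' @param Yhat positive matrix of fitted values, same shape.
#' @return the divergence (a non-negative scalar when `Y`, `Yhat` >= 0).
#' @export
kl_divergence <- function(Y, Yhat) {
  if (!all(dim(Y) == dim(Yhat)))
    stop("Y and Yhat must have the same shape", call. = FALSE)
  if (any(Y < 0)) stop("Y must be non-negative", call. = FALSE)
  if (any(Yhat <= 0)) stop("Yhat must be strictly positive", call. = FALSE)
  pos <- Y > 0
  sum(Y[pos] * log(Y[pos] / Yhat[pos])) - sum(Y) + sum(Yhat)
}

#' Force marker-gene rows of a signature matrix to a single cell type
#'
#' For every marker gene, all entries of its row except the one in its own
#' cell type's column are set to exactly zero. Marker genes absent from the
#' matrix are dropped with a warning (error if a cell type loses all its
#' markers); an empty catalog leaves `X` untouched.
#'
#' @param X signature matrix (genes x cell types, dimnames set).
#' @param markers marker catalog whose cell types name columns of `X`.
#' @return the masked signature matrix.
#' @export
apply_marker_constraints <- function(X, markers) {
  if (length(markers) == 0L) return(X)
  markers <- align_markers(markers, X)
  missing_ct <- setdiff(names(markers), colnames(X))
  if (length(missing_ct))
    stop("marker cell type(s) not among signature columns: ",
         paste(missing_ct, collapse = ", "), call. = FALSE)
  for (ct in names(markers)) {
    cols <- colnames(X) != ct
    X[markers[[ct]], cols] <- 0
  }
  X
}

# Vectorized bisection for the per-column Lagrange multiplier lambda_j
# solving colSums(num_fun(lambda)) = 1. `fsum(lam)` returns the column sums
# for a vector of lambdas; it must be strictly decreasing in each lambda.
# lo/hi bracket the root per column: fsum(lo) >= 1 >= fsum(hi).
bisect_lambda <- function(fsum, lo, hi, iters = 80L) {
  for (it in seq_len(iters)) {
    mid <- (lo + hi) / 2
    high <- fsum(mid) > 1
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
  }
  (lo + hi) / 2
}

# One sum-to-one-constrained multiplicative update of P for the generalized
# KL objective. Derived from the standard majorization with a per-sample
# Lagrange multiplier, so each update cannot increase the objective while
# keeping every column of P exactly on the simplex.
update_P_kl <- function(Y, X, P, eps) {
  Yhat <- pmax(X %*% P, eps)
  B <- P * crossprod(X, Y / Yhat)        # K x n
  a <- colSums(X)                        # K
  n <- ncol(P); K <- nrow(P)
  csB <- colSums(B)
  dead <- csB <= 0                       # zero data column: keep previous p
  lo_base <- apply(ifelse(B > 0, a, Inf), 2L, min)  # need a_k + lam > 0
  lo <- -lo_base + 1e-12 * pmax(lo_base, 1)
  hi <- csB - lo_base                    # f(hi) <= 1 (equality iff a constant)
  hi <- pmax(hi, lo + 1e-9)
  zero <- B == 0
  fsum <- function(lam) {
    den <- a + matrix(lam, K, n, byrow = TRUE)
    term <- B / den
    term[zero] <- 0
    colSums(term)
  }
  # expand hi until fsum(hi) <= 1 (it is by construction, but guard numerics)
  for (t in 1:60) {
    bad <- fsum(hi) > 1
    if (!any(bad)) break
    hi[bad] <- hi[bad] + 2^t * pmax(abs(hi[bad]), 1)
  }
  # Newton on the convex decreasing f(lam) = sum_k b_k/(a_k+lam): one step
  # from the f <= 1 side lands on the f >= 1 side, after which convergence
  # is monotone; lo remains a hard lower bound.
  lam <- hi
  ok <- FALSE
  for (it in 1:40) {
    den <- a + matrix(lam, K, n, byrow = TRUE)
    term <- B / den
    term[zero] <- 0
    f <- colSums(term)
    if (all(abs(f - 1) < 1e-12 | dead)) { ok <- TRUE; break }
    fp <- -colSums(term / den)
    lam <- pmax(lam - (f - 1) / pmin(fp, -1e-300), lo)
  }
  if (!ok) lam <- bisect_lambda(fsum, lo, pmax(hi, lam))
  Pn <- B / (a + matrix(lam, K, n, byrow = TRUE))
  Pn[B == 0] <- 0
  Pn[, dead] <- P[, dead]
  sweep(Pn, 2L, colSums(Pn), "/")
}

# Constrained P update for the squared-Frobenius objective, from the
# diagonal quadratic majorization with simplex KKT conditions.
update_P_euc <- function(Y, X, P, eps) {
  G <- crossprod(X, Y)                   # K x n
  Dm <- pmax(crossprod(X, X %*% P), eps) # K x n
  n <- ncol(P); K <- nrow(P)
  pfun <- function(lam) {
    pmax(P * (G - matrix(lam, K, n, byrow = TRUE)) / Dm, 0)
  }
  fsum <- function(lam) colSums(pfun(lam))
  hi <- apply(G, 2L, max)                # all terms clamp to 0
  lo <- apply(G, 2L, min) - 1
  for (t in 1:60) {
    bad <- fsum(lo) < 1
    if (!any(bad)) break
    lo[bad] <- lo[bad] - 2^t
  }
  Pn <- pfun(bisect_lambda(fsum, lo, hi))
  dead <- colSums(Pn) <= 0
  Pn[, dead] <- P[, dead]
  sweep(Pn, 2L, colSums(Pn), "/")
}

seminmf_objective <- function(Y, X, P, divergence, eps) {
  Yhat <- pmax(X %*% P, eps)
  if (divergence == "KL") kl_divergence(Y, Yhat) else 0.5 * sum((Y - Yhat)^2)
}

seminmf_init <- function(Y, markers, seed) {
  m <- nrow(Y); K <- length(markers)
  scale <- mean(Y)
  with_seed(seed, {
    X <- matrix(runif(m * K) * scale, m, K,
                dimnames = list(rownames(Y), names(markers)))
    for (ct in names(markers)) {
      g <- markers[[ct]]
      X[g, ] <- 0
      X[g, ct] <- rowMeans(Y[g, , drop = FALSE])
    }
    P <- matrix(runif(K * ncol(Y)), K, ncol(Y),
                dimnames = list(names(markers), colnames(Y)))
    P <- sweep(P, 2L, colSums(P), "/")
    list(X = X, P = P)
  })
}

#' Marker-constrained NMF deconvolution (semi-NMF)
#'
#' Factorizes the bulk matrix `Y ~ X P` by alternating multiplicative
#' updates under the generalized Kullback-Leibler divergence (or the squared
#' Frobenius norm), subject to: all factors non-negative; every column of
#' `P` summing to one; and every marker-gene row of `X` zero outside its own
#' cell type's column. The sum-to-one constraint is enforced inside the `P`
#' update through a per-sample Lagrange multiplier on the majorizing
#' surrogate, so each iteration is monotone non-increasing in the objective
#' while keeping `P` exactly on the simplex. Marker zeros are created at
#' initialization and preserved automatically by the multiplicative updates;
#' [apply_marker_constraints()] is re-applied after every `X` update as a
#' safety net.
#'
#' @param Y expression matrix (genes x samples).
#' @param markers marker catalog covering all K cell types; every cell type
#'   needs at least one marker present in `Y`.
#' @param config a [stage2_config()].
#' @param init optional list with matrices `X` (m x K) and `P` (K x n) to
#'   start from instead of the seeded random initialization.
#' @return object of class `seminmf_fit`: list with `X` (signature matrix),
#'   `P` (proportion matrix), and `trace` (list with
#'   `objective_per_iteration`, `iterations_run`, `converged`).
#' @export
seminmf_fit <- function(Y, markers, config = stage2_config(), init = NULL) {
  validate_expression(Y)
  markers <- align_markers(markers, Y)
  K <- length(markers)
  if (K < 1L) stop("markers must cover at least one cell type", call. = FALSE)
  eps <- config$epsilon

  # marker mask precomputed once; equivalent to apply_marker_constraints
  mask <- matrix(FALSE, nrow(Y), K,
                 dimnames = list(rownames(Y), names(markers)))
  for (ct in names(markers)) mask[markers[[ct]], colnames(mask) != ct] <- TRUE

  run_one <- function(seed) {
    start <- if (is.null(init)) seminmf_init(Y, markers, seed) else init
    X <- apply_marker_constraints(start$X, markers)
    P <- sweep(start$P, 2L, colSums(start$P), "/")
    obj <- seminmf_objective(Y, X, P, config$divergence, eps)
    trace <- numeric(config$max_iter + 1L)
    trace[1L] <- obj
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(config$max_iter)) {
      if (config$divergence == "KL") {
        Yhat <- pmax(X %*% P, eps)
        X <- X * (((Y / Yhat) %*% t(P)) /
                    matrix(rowSums(P) + eps, nrow(X), K, byrow = TRUE))
        X[mask] <- 0
        P <- update_P_kl(Y, X, P, eps)
      } else {
        X <- X * ((Y %*% t(P)) / pmax((X %*% P) %*% t(P), eps))
        X[mask] <- 0
        P <- update_P_euc(Y, X, P, eps)
      }
      new_obj <- seminmf_objective(Y, X, P, config$divergence, eps)
      trace[it + 1L] <- new_obj
      iters <- it
      if (abs(obj - new_obj) <= config$tol * max(abs(obj), eps)) {
        converged <- TRUE
        obj <- new_obj
        break
      }
      obj <- new_obj
    }
    list(X = X, P = P, obj = obj,
         trace = list(objective_per_iteration = trace[seq_len(iters + 1L)],
                      iterations_run = iters, converged = converged))
  }

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    res <- run_one(config$seed + r - 1L)
    if (is.null(best) || res$obj < best$obj) best <- res
    if (!is.null(init)) break  # explicit start: restarts are identical
  }
  if (!best$trace$converged)
    warning("semi-NMF did not converge within ", config$max_iter,
            " iterations (relative tol ", config$tol, ")", call. = FALSE)
  validate_proportions(best$P)
  structure(list(X = best$X, P = best$P, trace = best$trace,
                 divergence = config$divergence),
            class = "seminmf_fit")
}

#' @export
print.seminmf_fit <- function(x, ...) {
  tr <- x$trace
  cat("Marker-constrained NMF fit (", x$divergence, " divergence): ",
      nrow(x$X), " genes, ", ncol(x$X), " cell types, ", ncol(x$P),
      " samples\n", sep = "")
  cat("iterations:", tr$iterations_run,
      if (tr$converged) "(converged)" else "(not converged)",
      "| final objective:",
      format(tail(tr$objective_per_iteration, 1L), digits = 8), "\n")
  invisible(x)
}
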