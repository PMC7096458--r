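#' Marker selection parameters
#'
#' Thresholds used when calling marker genes from pure-cell replicate
#' profiles: the t-test p-value cutoff, the minimum log2 fold change between
#' the highest and second-highest expressing cell types, a cap on the
#' second-highest cell type's maximum linear-scale expression, and the number
#' of top-ranked genes kept per cell type.
#'
#' @param p_threshold p-value cutoff, in (0, 1].
#' @param log2fc_threshold minimum log2 fold change (>= 0).
#' @param second_highest_cap maximum allowed linear expression among the
#'   second-highest cell type's replicates (default 128 = 2^7).
#' @param top_n markers kept per cell type, ranked by p-value.
#' @return a list of class `marker_selection_params`.
#' @export
marker_selection_params <- function(p_threshold = 0.05, log2fc_threshold = 1.5,
                                    second_highest_cap = 128, top_n = 100L) {
  stopifnot(p_threshold > 0, p_threshold <= 1, log2fc_threshold >= 0,
            top_n >= 1L, second_highest_cap > 0)
  structure(list(p_threshold = p_threshold,
                 log2fc_threshold = log2fc_threshold,
                 second_highest_cap = second_highest_cap,
                 top_n = as.integer(top_n)),
            class = "marker_selection_params")
}

#' Remove low-expression genes
#'
#' Genes are ranked by mean expression across samples and the
#' `floor(drop_fraction * m)` lowest-mean genes are removed. The relative
#' order of the surviving genes is preserved. Ties in the mean are broken by
#' original row order.
#'
#' @param Y expression matrix.
#' @param drop_fraction fraction of genes to drop, in `[0, 1)`.
#' @return the filtered expression matrix.
#' @export
filter_low_expression <- function(Y, drop_fraction = 0.5) {
  validate_expression(Y)
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)", call. = FALSE)
  n_drop <- floor(drop_fraction * nrow(Y))
  if (n_drop == 0L) return(Y)
  if (nrow(Y) < 2L)
    stop("need at least 2 genes to filter by expression", call. = FALSE)
  means <- rowMeans(Y)
  drop_idx <- order(means)[seq_len(n_drop)]
  Y[-drop_idx, , drop = FALSE]
}

#' Keep the most variable genes by coefficient of variation
#'
#' Genes are ranked by CV = sample standard deviation / mean (a gene with
#' mean 0 is assigned CV 0) and the top `ceil(keep_fraction * m)` genes are
#' retained, preserving their original order.
#'
#' @param Y expression matrix with at least 2 samples.
#' @param keep_fraction fraction of genes to keep, in `(0, 1]`.
#' @return the filtered expression matrix.
#' @export
filter_top_cv <- function(Y, keep_fraction = 0.5) {
  validate_expression(Y)
  if (ncol(Y) < 2L)
    stop("coefficient of variation needs at least 2 samples", call. = FALSE)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]", call. = FALSE)
  n_keep <- ceiling(keep_fraction * nrow(Y))
  if (n_keep >= nrow(Y)) return(Y)
  mu <- rowMeans(Y)
  s <- apply(Y, 1L, sd)
  cv <- ifelse(mu > 0, s / mu, 0)
  keep_idx <- sort(order(cv, decreasing = TRUE)[seq_len(n_keep)])
  Y[keep_idx, , drop = FALSE]
}

# log2 transform with a +1 guard only when values below 1 are present
# (MAS5-scale intensities are >> 1; synthetic or clipped data may not be).
log2_guarded <- function(Y) {
  if (any(Y < 1)) log2(Y + 1) else log2(Y)
}

# Pooled-variance two-sided t-test on two small replicate vectors.
# A pooled variance of exactly 0 is the degenerate limit: p = 0 when the
# means differ, p = 1 when they are equal.
pooled_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2L)
  d <- mean(x) - mean(y)
  if (sp2 == 0) return(if (d == 0) 1 else 0)
  tval <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tval), df = nx + ny - 2L)
}

#' Select marker genes from pure-cell replicate profiles
#'
#' For each gene the cell types are ranked by mean log2 expression; the gene
#' is a candidate marker of the highest-expressing type. A two-sided
#' equal-variance t-test compares the replicate groups of the highest and
#' second-highest types on the log2 scale. The gene qualifies when
#' p < `p_threshold`, the log2 fold change (difference of group means on the
#' log2 scale) exceeds `log2fc_threshold`, and the maximum linear expression
#' among the second-highest type's replicates is below `second_highest_cap`.
#' Per cell type the `top_n` qualifying genes with the smallest p-values are
#' kept (ties broken by larger fold change, then gene id).
#'
#' @param pure expression matrix of pure-cell samples (replicates as columns).
#' @param group_labels cell type label per column of `pure`.
#' @param params a [marker_selection_params()] object.
#' @return a marker catalog; cell types with no qualifying gene are omitted
#'   with a warning. Attribute `stats` holds a data frame of the per-gene
#'   test results (candidate type, p-value, log2 fold change, second-highest
#'   max, selection flag, and Benjamini-Hochberg adjusted p-value among the
#'   candidate type's tested genes).
#' @export
select_markers_from_pure <- function(pure, group_labels,
                                     params = marker_selection_params()) {
  validate_expression(pure, "pure profile matrix")
  group_labels <- as.character(group_labels)
  if (length(group_labels) != ncol(pure))
    stop("group_labels must have one label per sample", call. = FALSE)
  types <- unique(group_labels)
  if (length(types) < 2L)
    stop("need at least 2 cell types to select markers", call. = FALSE)
  reps <- split(seq_along(group_labels),
                factor(group_labels, levels = types))
  few <- names(reps)[lengths(reps) < 2L]
  if (length(few))
    stop("cell type(s) with fewer than 2 replicates: ",
         paste(few, collapse = ", "), call. = FALSE)

  L2 <- log2_guarded(pure)
  group_mean <- sapply(reps, function(i) rowMeans(L2[, i, drop = FALSE]))

  m <- nrow(pure)
  cand <- character(m); pval <- numeric(m); lfc <- numeric(m)
  second_max <- numeric(m)
  for (i in seq_len(m)) {
    ord <- order(group_mean[i, ], decreasing = TRUE)
    hi <- types[ord[1L]]; lo <- types[ord[2L]]
    cand[i] <- hi
    lfc[i] <- group_mean[i, ord[1L]] - group_mean[i, ord[2L]]
    pval[i] <- pooled_t_pvalue(L2[i, reps[[hi]]], L2[i, reps[[lo]]])
    second_max[i] <- max(pure[i, reps[[lo]]])
  }
  qualifies <- pval < params$p_threshold &
    lfc > params$log2fc_threshold &
    second_max < params$second_highest_cap

  stats_df <- data.frame(gene_id = rownames(pure), cell_type = cand,
                         p_value = pval, log2_fold_change = lfc,
                         second_highest_max = second_max,
                         selected = FALSE, fdr = NA_real_,
                         stringsAsFactors = FALSE)
  for (ct in types)
    stats_df$fdr[cand == ct] <- p.adjust(pval[cand == ct], method = "BH")

  entries <- list()
  for (ct in types) {
    idx <- which(qualifies & cand == ct)
    if (length(idx) == 0L) {
      warning("no qualifying marker genes for cell type ", ct, call. = FALSE)
      next
    }
    ord <- idx[order(pval[idx], -lfc[idx], rownames(pure)[idx])]
    keep <- ord[seq_len(min(params$top_n, length(ord)))]
    stats_df$selected[keep] <- TRUE
    entries[[ct]] <- rownames(pure)[keep]
  }
  if (length(entries) == 0L)
    stop("no marker genes qualified for any cell type", call. = FALSE)
  out <- marker_catalog(entries)
  attr(out, "stats") <- stats_df
  out
}

#' Benjamini-Hochberg FDR summary for selected markers
#'
#' Summarizes, per cell type, the largest BH-adjusted p-value among the
#' selected markers — a descriptive false-discovery-rate report for a marker
#' list.
#'
#' @param markers catalog returned by [select_markers_from_pure()] (must
#'   carry its `stats` attribute).
#' @return data frame with columns `cell_type`, `n_markers`, `max_fdr`.
#' @export
marker_fdr_report <- function(markers) {
  st <- attr(markers, "stats")
  if (is.null(st))
    stop("markers must come from select_markers_from_pure()", call. = FALSE)
  sel <- st[st$selected, , drop = FALSE]
  out <- do.call(rbind, lapply(names(markers), function(ct) {
    s <- sel[sel$cell_type == ct, , drop = FALSE]
    data.frame(cell_type = ct, n_markers = nrow(s), max_fdr = max(s$fdr))
  }))
  rownames(out) <- NULL
  out
}
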