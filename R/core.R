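#' @importFrom stats rnorm runif sd cor kmeans setNames pt p.adjust
#' @importFrom utils combn read.table write.table tail
NULL

#' Construct a validated expression matrix
#'
#' An expression matrix is an ordinary numeric matrix of non-negative,
#' linear-scale expression values with genes as rows and samples as columns.
#' Gene and sample identifiers are carried as `rownames`/`colnames` and are
#' treated as opaque strings (probe ids and gene symbols are equally valid).
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   existing rownames).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to existing colnames).
#' @return the validated matrix with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  validate_expression(values)
  values
}

#' Validate an expression matrix
#'
#' Checks non-negativity, finiteness, presence and uniqueness of gene and
#' sample identifiers.
#'
#' @param Y numeric matrix with gene rownames and sample colnames.
#' @param what label used in error messages.
#' @return `Y`, invisibly.
#' @export
validate_expression <- function(Y, what = "expression matrix") {
  if (!is.matrix(Y) || !is.numeric(Y))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(Y) < 1L || ncol(Y) < 1L)
    stop(what, " must have at least one gene and one sample", call. = FALSE)
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop(what, " must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(Y)))
    stop(what, ": duplicated gene id(s): ",
         paste(unique(rownames(Y)[duplicated(rownames(Y))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(Y)))
    stop(what, ": duplicated sample id(s): ",
         paste(unique(colnames(Y)[duplicated(colnames(Y))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(Y)))
    stop(what, " contains non-finite entries", call. = FALSE)
  if (any(Y < 0))
    stop(what, " contains negative entries", call. = FALSE)
  invisible(Y)
}

#' Construct a validated marker catalog
#'
#' A marker catalog maps each of L cell types to a non-empty list of marker
#' gene identifiers. No gene may be listed under two cell types. Order of
#' cell types is preserved (insertion order).
#'
#' @param entries named list, cell type name -> character vector of gene ids.
#' @return the validated named list, with attribute `L` (number of cell types).
#' @export
marker_catalog <- function(entries) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == ""))
    stop("marker catalog must be a named list of gene-id vectors", call. = FALSE)
  if (anyDuplicated(names(entries)))
    stop("marker catalog: duplicated cell type name", call. = FALSE)
  entries <- lapply(entries, as.character)
  if (any(lengths(entries) == 0L))
    stop("marker catalog: cell type with an empty marker list: ",
         paste(names(entries)[lengths(entries) == 0L], collapse = ", "),
         call. = FALSE)
  all_genes <- unlist(entries, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("marker catalog: gene(s) listed under more than one cell type: ",
         paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "),
         call. = FALSE)
  attr(entries, "L") <- length(entries)
  entries
}

#' Number of cell types with known markers
#' @param markers a marker catalog.
#' @return integer L.
#' @export
n_marker_types <- function(markers) length(markers)

#' Validate a proportion matrix
#'
#' Cell types x samples matrix of mixing fractions; every column must sum to
#' one (tolerance 1e-8) and all entries must lie in `[0, 1]`.
#'
#' @param P numeric matrix, cell types x samples.
#' @param what label used in error messages.
#' @return `P`, invisibly.
#' @export
validate_proportions <- function(P, what = "proportion matrix") {
  if (!is.matrix(P) || !is.numeric(P))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1 + 1e-12))
    stop(what, " entries must be finite fractions in [0, 1]", call. = FALSE)
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-8))
    stop(what, ": column(s) do not sum to 1: ",
         paste(which(abs(cs - 1) > 1e-8), collapse = ", "), call. = FALSE)
  invisible(P)
}

#' Validate a signature matrix against marker constraints
#'
#' @param X numeric matrix, genes x cell types, non-negative.
#' @param markers optional marker catalog; when given, every marker gene row
#'   must be zero outside its own cell type's column.
#' @return `X`, invisibly.
#' @export
validate_signature <- function(X, markers = NULL) {
  if (!is.matrix(X) || !is.numeric(X) || any(!is.finite(X)) || any(X < 0))
    stop("signature matrix must be a non-negative finite numeric matrix",
         call. = FALSE)
  if (!is.null(markers)) {
    for (ct in names(markers)) {
      g <- intersect(markers[[ct]], rownames(X))
      off <- X[g, setdiff(colnames(X), ct), drop = FALSE]
      if (length(off) && any(off != 0))
        stop("signature matrix violates marker constraint for cell type ", ct,
             call. = FALSE)
    }
  }
  invisible(X)
}

delimiter_for <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and gene ids in the first column. The
#' delimiter is auto-detected from the file extension (`.csv` -> comma,
#' anything else -> tab) unless given explicitly.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` to auto-detect.
#' @return a validated expression matrix.
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delimiter_for(path, delimiter)
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   colClasses = "character", check.names = FALSE,
                   comment.char = "", quote = "\"")
  if (ncol(df) < 2L)
    stop("expression file must have a gene-id column and >= 1 sample column",
         call. = FALSE)
  gene_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at data row %d (gene %s), column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 gene_ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]),
         call. = FALSE)
  if (anyNA(num))
    stop("missing value at data row ", which(is.na(num), arr.ind = TRUE)[1L, 1L],
         call. = FALSE)
  expression_matrix(num, gene_ids = gene_ids, sample_ids = colnames(vals))
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 12 significant digits so that a write/read cycle
#' round-trips to that precision.
#'
#' @param Y expression matrix.
#' @param path output file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @param digits significant digits to keep.
#' @return `path`, invisibly.
#' @export
write_expression <- function(Y, path, delimiter = NULL, digits = 12L) {
  validate_expression(Y)
  sep <- delimiter_for(path, delimiter)
  out <- cbind(gene_id = rownames(Y),
               matrix(formatC(Y, digits = digits, format = "g"),
                      nrow(Y), ncol(Y), dimnames = dimnames(Y)))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a marker catalog from two-column delimited text
#'
#' Columns are (cell_type, gene_id); a header row is skipped when its first
#' field looks like a column name (`cell_type`, `celltype`, `type`,
#' case-insensitive). Cell types appear in the catalog in order of first
#' appearance.
#'
#' @param path file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @return a validated marker catalog.
#' @export
read_markers <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- delimiter_for(path, delimiter)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = sep, colClasses = "character",
               comment.char = "", quote = "\""),
    error = function(e) stop("marker file is empty or unreadable: ", path,
                             call. = FALSE))
  if (ncol(df) < 2L)
    stop("marker file must have two columns (cell_type, gene_id)",
         call. = FALSE)
  if (tolower(df[1L, 1L]) %in% c("cell_type", "celltype", "cell.type", "type"))
    df <- df[-1L, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("marker file contains no marker entries", call. = FALSE)
  split_idx <- split(seq_len(nrow(df)), factor(df[[1L]], levels = unique(df[[1L]])))
  marker_catalog(lapply(split_idx, function(i) df[[2L]][i]))
}

#' Write a marker catalog as two-column delimited text
#' @param markers marker catalog.
#' @param path output file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, delimiter = NULL) {
  markers <- marker_catalog(markers)
  sep <- delimiter_for(path, delimiter)
  df <- data.frame(cell_type = rep(names(markers), lengths(markers)),
                   gene_id = unlist(markers, use.names = FALSE))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a proportion matrix as delimited text
#'
#' Rows are cell types, columns are samples; values printed to 6 decimals.
#'
#' @param P proportion matrix (cell types x samples).
#' @param path output file path.
#' @param delimiter field separator; `NULL` to auto-detect from extension.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(P, path, delimiter = NULL) {
  sep <- delimiter_for(path, delimiter)
  out <- cbind(cell_type = rownames(P),
               matrix(sprintf("%.6f", P), nrow(P), ncol(P),
                      dimnames = dimnames(P)))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Restrict a marker catalog to genes present in an expression matrix
#'
#' Markers absent from the matrix (e.g. removed by filtering) are dropped
#' with a warning; an error is raised only when a cell type loses all of its
#' markers.
#'
#' @param markers marker catalog.
#' @param Y expression matrix.
#' @return marker catalog containing only genes found in `rownames(Y)`.
#' @export
align_markers <- function(markers, Y) {
  markers <- marker_catalog(markers)
  present <- lapply(markers, intersect, rownames(Y))
  dropped <- sum(lengths(markers)) - sum(lengths(present))
  if (dropped > 0L)
    warning(dropped, " marker gene(s) absent from the expression matrix were dropped",
            call. = FALSE)
  lost <- names(present)[lengths(present) == 0L]
  if (length(lost))
    stop("cell type(s) lost all markers after alignment: ",
         paste(lost, collapse = ", "), call. = FALSE)
  marker_catalog(present)
}
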