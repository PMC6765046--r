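# Expression container and transforms: log2(FPKM + 1), per-tissue slices,
# median profiles and tissue-similarity matrix.

#' Construct an expression set
#'
#' @param values Numeric matrix, isoforms x samples, FPKM-scale
#'   (nonnegative).
#' @param tissue_map data.frame with columns `sample_id`, `tissue` covering
#'   every column of `values`.
#' @return Object of class `expression_set` with elements `values`,
#'   `tissue_map`, `tissues` (tissue order of first appearance).
#' @export
expression_set <- function(values, tissue_map) {
  stopifnot(is.matrix(values))
  stopifnot(all(c("sample_id", "tissue") %in% names(tissue_map)))
  tissue_map <- data.frame(sample_id = as.character(tissue_map$sample_id),
                           tissue = as.character(tissue_map$tissue),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tissue_map$sample_id)) {
    stop("duplicate sample ids in tissue map")
  }
  unmapped <- setdiff(colnames(values), tissue_map$sample_id)
  if (length(unmapped) > 0) {
    stop("sample(s) absent from tissue map: ",
         paste(unmapped, collapse = ", "))
  }
  if (any(values < 0)) stop("expression values must be nonnegative")
  tissue_map <- tissue_map[match(colnames(values), tissue_map$sample_id), ]
  structure(list(values = values, tissue_map = tissue_map,
                 tissues = unique(tissue_map$tissue)),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("<expression_set> ", nrow(x$values), " isoforms x ", ncol(x$values),
      " samples, ", length(x$tissues), " tissues\n", sep = "")
  invisible(x)
}

#' Log-transform expression values
#'
#' Applies `log2(x + 1)` cell-wise; zeros map to zero and the transform is
#' monotone and invertible.
#'
#' @param values Nonnegative numeric matrix (or an [expression_set()], whose
#'   values slot is transformed).
#' @return Object of the same shape, transformed.
#' @export
log_transform <- function(values) {
  if (inherits(values, "expression_set")) {
    values$values <- log_transform(values$values)
    return(values)
  }
  if (any(values < 0)) stop("log transform requires nonnegative input")
  log2(values + 1)
}

#' Split an expression matrix into per-tissue slices plus a pooled slice
#'
#' @param expr An [expression_set()].
#' @param log Apply [log_transform()] first (default TRUE).
#' @return Named list: one matrix per tissue (columns = that tissue's
#'   samples) and `"organism"` with all samples. Tissue slices partition
#'   the columns.
#' @export
tissue_slices <- function(expr, log = TRUE) {
  values <- if (log) log_transform(expr$values) else expr$values
  out <- lapply(stats::setNames(expr$tissues, expr$tissues), function(t) {
    values[, expr$tissue_map$sample_id[expr$tissue_map$tissue == t],
           drop = FALSE]
  })
  out$organism <- values
  out
}

#' Per-tissue median log-expression profiles
#'
#' @param expr An [expression_set()].
#' @return Matrix tissue x isoform of per-tissue medians of
#'   `log2(FPKM + 1)`.
#' @export
median_profiles <- function(expr) {
  slices <- tissue_slices(expr, log = TRUE)
  slices$organism <- NULL
  t(vapply(slices, function(m) apply(m, 1, stats::median),
           numeric(nrow(expr$values))))
}

#' Tissue-by-tissue Pearson similarity of median expression profiles
#'
#' @param profiles Matrix tissue x isoform as returned by
#'   [median_profiles()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
tissue_similarity <- function(profiles) {
  s <- stats::cor(t(profiles))
  diag(s) <- 1
  s
}
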