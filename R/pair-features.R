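# Per-pair feature rows: Fisher z-transformed Pearson correlations over the
# expression slices (one per tissue plus organism-wide) and the nine
# sequence feature groups. With 17 tissues configured this is the
# 27-dimensional pair feature row (18 expression + 9 sequence).

#' Fisher z-transform of a Pearson correlation (as used by the pipeline)
#'
#' Computes `z = 1/2 * log2((1 - rho) / (1 + rho))`: note the base-2
#' logarithm and the sign inversion relative to the classical Fisher
#' transform. Correlations of exactly +1 and -1 (within 1e-12) are replaced
#' by the extreme values -100 and +100; undefined correlations (`NA`, e.g.
#' from a constant vector) map to 0; all other values are clipped to
#' [-100, 100]. A `classical` flag switches to
#' `1/2 * ln((1 + rho)/(1 - rho))` with +1 -> +100 and -1 -> -100.
#'
#' @param rho Numeric vector of correlations in [-1, 1]; `NA` marks an
#'   undefined correlation.
#' @param classical Use the textbook transform instead (default FALSE).
#' @return Numeric vector of z values in [-100, 100].
#' @export
fisher_z <- function(rho, classical = FALSE) {
  out <- numeric(length(rho))
  ok <- !is.na(rho)
  r <- rho[ok]
  if (any(abs(r) > 1 + 1e-8)) {
    stop("correlation outside [-1, 1]: ", max(abs(r)))
  }
  r <- pmin(1, pmax(-1, r))
  at_pos <- abs(r - 1) < 1e-12
  at_neg <- abs(r + 1) < 1e-12
  z <- numeric(length(r))
  mid <- !at_pos & !at_neg
  if (classical) {
    z[mid] <- 0.5 * log((1 + r[mid]) / (1 - r[mid]))
    z[at_pos] <- 100
    z[at_neg] <- -100
  } else {
    z[mid] <- 0.5 * log2((1 - r[mid]) / (1 + r[mid]))
    z[at_pos] <- -100
    z[at_neg] <- 100
  }
  out[ok] <- pmin(100, pmax(-100, z))
  out
}

#' Names of the pair feature columns
#'
#' Tissues in configured order, then the organism-wide slice, then the nine
#' sequence groups.
#'
#' @param tissues Character vector of tissue names.
#' @return Character vector of length `length(tissues) + 1 + 9`, each
#'   prefixed with `"z_"`.
#' @export
pair_feature_names <- function(tissues) {
  paste0("z_", c(tissues, "organism", sequence_group_names()))
}

#' Enumerate all unordered isoform pairs of a catalog
#'
#' Yields each of the `C(n, 2)` pairs exactly once in canonical order
#' (lexicographically smaller id first), with no self-pairs. Same-gene
#' isoform pairs are included.
#'
#' @param catalog A [gene_catalog()] or a character vector of isoform ids.
#' @return data.frame with columns `isoform_a`, `isoform_b`.
#' @export
enumerate_pairs <- function(catalog) {
  ids <- if (inherits(catalog, "gene_catalog")) catalog$records$isoform_id
         else as.character(catalog)
  ids <- sort(unique(ids))
  n <- length(ids)
  if (n < 2) {
    return(data.frame(isoform_a = character(0), isoform_b = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2)
  data.frame(isoform_a = ids[idx[1, ]], isoform_b = ids[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Number of unordered pairs among n isoforms
#'
#' `C(n, 2)`, computed without materializing the pairs; for the 75,826
#' isoforms of a genome-scale catalog this is 2,874,753,225.
#'
#' @param n Number of isoforms.
#' @return Exact pair count as a double.
#' @export
pair_count <- function(n) {
  choose(n, 2)
}

#' Put isoform pairs in canonical order
#'
#' @param pairs data.frame with `isoform_a`, `isoform_b`.
#' @return Same frame with each pair ordered so `isoform_a < isoform_b`.
#' @export
canonical_pairs <- function(pairs) {
  swap <- pairs$isoform_a > pairs$isoform_b
  tmp <- pairs$isoform_a[swap]
  pairs$isoform_a[swap] <- pairs$isoform_b[swap]
  pairs$isoform_b[swap] <- tmp
  pairs
}

# Precompute row-centered values and row sums of squares for row-pair
# Pearson correlations.
.cor_prep <- function(m) {
  centered <- m - rowMeans(m)
  list(centered = centered, ss = sqrt(rowSums(centered^2)),
       ids = rownames(m))
}

# Row-wise Pearson correlation between rows a_idx and b_idx of a prepared
# matrix; rows with zero variance give NA (undefined). Works in chunks so
# large pair sets never materialize huge index expansions.
.rowpair_cor <- function(prep, a_idx, b_idx, chunk_size = 2000L) {
  n <- length(a_idx)
  rho <- numeric(n)
  for (start in seq(1, n, by = chunk_size)) {
    i <- start:min(start + chunk_size - 1, n)
    num <- rowSums(prep$centered[a_idx[i], , drop = FALSE] *
                   prep$centered[b_idx[i], , drop = FALSE])
    denom <- prep$ss[a_idx[i]] * prep$ss[b_idx[i]]
    rho[i] <- ifelse(denom == 0, NA_real_, num / denom)
  }
  # guard against rounding pushing |rho| past 1
  pmin(1, pmax(-1, rho))
}

#' Build pair feature rows for a set of isoform pairs
#'
#' For every expression slice the feature is the Fisher z-transform of the
#' Pearson correlation between the two isoforms' log expression over that
#' slice's samples; for every sequence group it is the transform of the
#' correlation between the two isoforms' descriptor vectors over the
#' group's frozen key order.
#'
#' @param pairs data.frame with columns `isoform_a`, `isoform_b`.
#' @param groups Named list of 9 descriptor matrices from
#'   [catalog_feature_groups()].
#' @param expr An [expression_set()] covering all isoforms in `pairs`.
#' @param classical Passed to [fisher_z()].
#' @return data.frame: `isoform_a`, `isoform_b`, then one `z_*` column per
#'   feature in [pair_feature_names()] order.
#' @export
pair_feature_matrix <- function(pairs, groups, expr, classical = FALSE) {
  pairs <- canonical_pairs(pairs)
  slices <- tissue_slices(expr, log = TRUE)
  ids <- rownames(expr$values)
  missing <- setdiff(unique(c(pairs$isoform_a, pairs$isoform_b)), ids)
  if (length(missing) > 0) {
    stop("isoform(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  out <- pairs[, c("isoform_a", "isoform_b")]
  for (s in names(slices)) {
    prep <- .cor_prep(slices[[s]])
    rho <- .rowpair_cor(prep, match(pairs$isoform_a, prep$ids),
                        match(pairs$isoform_b, prep$ids))
    out[[paste0("z_", s)]] <- fisher_z(rho, classical = classical)
  }
  for (g in sequence_group_names()) {
    m <- groups[[g]]
    if (is.null(m)) stop("missing sequence feature group: ", g)
    gm <- setdiff(unique(c(pairs$isoform_a, pairs$isoform_b)), rownames(m))
    if (length(gm) > 0) {
      stop("isoform(s) missing from group ", g, ": ",
           paste(gm, collapse = ", "))
    }
    prep <- .cor_prep(m)
    rho <- .rowpair_cor(prep, match(pairs$isoform_a, prep$ids),
                        match(pairs$isoform_b, prep$ids))
    out[[paste0("z_", g)]] <- fisher_z(rho, classical = classical)
  }
  rownames(out) <- NULL
  out
}

#' Feature row for a single isoform pair
#'
#' Convenience wrapper over [pair_feature_matrix()]; symmetric in its two
#' arguments.
#'
#' @param isoform_a,isoform_b Isoform ids.
#' @inheritParams pair_feature_matrix
#' @return One-row data.frame.
#' @export
pair_row <- function(isoform_a, isoform_b, groups, expr, classical = FALSE) {
  pair_feature_matrix(data.frame(isoform_a = isoform_a,
                                 isoform_b = isoform_b,
                                 stringsAsFactors = FALSE),
                      groups, expr, classical = classical)
}
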