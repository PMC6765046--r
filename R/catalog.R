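# Gene catalog: isoform identity, parent gene, mRNA and protein sequences.

#' Construct a gene catalog
#'
#' @param records data.frame with columns `isoform_id`, `gene_id`.
#' @param mrna Named character vector (or list) of mRNA sequences over
#'   A/C/G/T, one per isoform.
#' @param protein Named character vector (or list) of protein sequences over
#'   the 20 standard amino acids, one per isoform.
#' @return An object of class `gene_catalog` with elements `records`,
#'   `mrna`, `protein`.
#' @export
gene_catalog <- function(records, mrna, protein) {
  stopifnot(is.data.frame(records),
            all(c("isoform_id", "gene_id") %in% names(records)))
  records <- records[, c("isoform_id", "gene_id")]
  records[] <- lapply(records, as.character)
  rownames(records) <- NULL
  if (anyDuplicated(records$isoform_id)) {
    stop("duplicate isoform ids in catalog: ",
         paste(unique(records$isoform_id[duplicated(records$isoform_id)]),
               collapse = ", "))
  }
  mrna <- as.list(mrna)
  protein <- as.list(protein)
  missing_m <- setdiff(records$isoform_id, names(mrna))
  missing_p <- setdiff(records$isoform_id, names(protein))
  if (length(missing_m) > 0 || length(missing_p) > 0) {
    stop("sequences missing for isoforms: ",
         paste(union(missing_m, missing_p), collapse = ", "))
  }
  structure(list(records = records,
                 mrna = mrna[records$isoform_id],
                 protein = protein[records$isoform_id]),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", nrow(x$records), " isoforms, ",
      length(unique(x$records$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' Genes producing exactly one isoform
#'
#' @param catalog A [gene_catalog()].
#' @return Character vector of single-isoform gene ids.
#' @export
single_isoform_genes <- function(catalog) {
  tab <- table(catalog$records$gene_id)
  names(tab)[tab == 1]
}

#' Map genes to their isoform ids
#'
#' @param catalog A [gene_catalog()].
#' @return Named list, gene id -> character vector of isoform ids.
#' @export
gene_isoforms <- function(catalog) {
  split(catalog$records$isoform_id, catalog$records$gene_id)
}

#' Assemble and filter a catalog from raw sequence maps
#'
#' Applies the load-time filters: isoforms are dropped when the protein is
#' shorter than 30 residues, when either sequence contains non-standard
#' characters, or when the mRNA sequence, protein sequence or (optionally)
#' expression row is missing. Dropped isoforms and their reasons are
#' recorded in the `"filtered"` attribute and reported via `message()`.
#'
#' @param mapping data.frame with columns `isoform_id`, `gene_id`.
#' @param mrna Named character vector of mRNA sequences.
#' @param protein Named character vector of protein sequences.
#' @param expression_ids Optional character vector of isoform ids with
#'   expression data; isoforms absent from it are dropped.
#' @param min_protein_length Minimum retained protein length (default 30).
#' @return A [gene_catalog()] of the retained isoforms.
#' @export
load_catalog <- function(mapping, mrna, protein, expression_ids = NULL,
                         min_protein_length = 30) {
  stopifnot(all(c("isoform_id", "gene_id") %in% names(mapping)))
  ids <- as.character(mapping$isoform_id)
  reasons <- character(0)
  drop <- function(id, why) reasons[id] <<- why
  for (id in ids) {
    m <- mrna[[id]]
    p <- protein[[id]]
    if (is.null(m) || is.na(m) || !nzchar(m)) { drop(id, "missing mRNA sequence"); next }
    if (is.null(p) || is.na(p) || !nzchar(p)) { drop(id, "missing protein sequence"); next }
    if (!is.null(expression_ids) && !(id %in% expression_ids)) {
      drop(id, "missing expression profile"); next
    }
    if (nchar(p) < min_protein_length) { drop(id, "protein shorter than minimum length"); next }
    if (length(setdiff(unique(.seq_chars(m)), DNA_ALPHABET)) > 0) {
      drop(id, "non-standard mRNA characters"); next
    }
    if (length(setdiff(unique(.seq_chars(p)), AA_ALPHABET)) > 0) {
      drop(id, "non-standard protein characters"); next
    }
  }
  keep <- setdiff(ids, names(reasons))
  if (length(reasons) > 0) {
    message(length(reasons), " isoform(s) filtered at load time")
  }
  out <- gene_catalog(mapping[match(keep, ids), , drop = FALSE],
                      mrna[keep], protein[keep])
  attr(out, "filtered") <- data.frame(isoform_id = names(reasons),
                                      reason = unname(reasons),
                                      stringsAsFactors = FALSE)
  out
}
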