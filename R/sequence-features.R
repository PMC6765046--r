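# Per-isoform sequence descriptor groups: nucleotide and amino-acid k-mer
# composition, conjoint-triad descriptors, pseudo-amino-acid composition and
# Moran autocorrelation. Every frequency-type descriptor is a probability
# vector over a fixed, lexicographically ordered key set; pair-level
# correlations downstream rely on that frozen ordering.

#' Names of the nine sequence feature groups, in canonical order
#'
#' Order: mRNA 3- to 6-mers, then protein 1-mer and 2-mer composition,
#' conjoint triads, pseudo-amino-acid composition, Moran autocorrelation.
#'
#' @return Character vector of length 9.
#' @export
sequence_group_names <- function() {
  c("mrna_3mer", "mrna_4mer", "mrna_5mer", "mrna_6mer",
    "prot_1mer", "prot_2mer", "conjoint_triad", "pseudo_aac", "moran")
}

#' Enumerate all k-mers over an alphabet in lexicographic order
#'
#' @param k Word length.
#' @param alphabet Character vector of single characters.
#' @return Character vector of length `length(alphabet)^k`, sorted.
#' @export
kmer_keys <- function(k, alphabet) {
  stopifnot(k >= 1, length(alphabet) >= 1)
  alphabet <- sort(alphabet)
  keys <- alphabet
  for (i in seq_len(k - 1)) {
    keys <- as.vector(t(outer(keys, alphabet, paste0)))
  }
  sort(keys)
}

.seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' k-mer composition of a sequence
#'
#' Frequency of every k-length word over the given alphabet: the count of
#' word i divided by the number of k-windows, `l - (k - 1)` for a sequence
#' of length `l`. The result is a probability vector over the full
#' lexicographically ordered k-mer key set.
#'
#' @param sequence Single string over `alphabet`.
#' @param k Word length; the sequence must be at least this long.
#' @param alphabet Character vector of allowed characters (default DNA).
#' @return Named numeric vector of length `length(alphabet)^k` summing to 1.
#' @export
kmer_composition <- function(sequence, k, alphabet = DNA_ALPHABET) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  l <- nchar(sequence)
  if (l < k) {
    stop("sequence length ", l, " is shorter than k = ", k)
  }
  chars <- .seq_chars(sequence)
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0) {
    stop("sequence contains characters outside the alphabet: ",
         paste(bad, collapse = ", "))
  }
  keys <- kmer_keys(k, alphabet)
  subs <- substring(sequence, 1:(l - k + 1), k:l)
  counts <- tabulate(match(subs, keys), nbins = length(keys))
  out <- counts / (l - k + 1)
  names(out) <- keys
  out
}

# Canonical dipole / side-chain-volume partition of the 20 amino acids into
# 7 classes used by the conjoint-triad descriptor.
CT_CLASSES <- list(
  c("A", "G", "V"),
  c("I", "L", "F", "P"),
  c("Y", "M", "T", "S"),
  c("H", "N", "Q", "W"),
  c("R", "K"),
  c("D", "E"),
  c("C"))

.ct_class_map <- local({
  map <- character(0)
  for (i in seq_along(CT_CLASSES)) map[CT_CLASSES[[i]]] <- as.character(i)
  function() map
})

#' Conjoint-triad descriptor of a protein sequence
#'
#' The 20 amino acids are grouped into 7 classes by side-chain volume and
#' dipole; the sequence is rewritten over the class alphabet and 3-mer
#' frequencies are computed, giving 7^3 = 343 values summing to 1.
#'
#' @param protein_sequence Single string over the 20 standard amino acids,
#'   length at least 3.
#' @return Named numeric vector of length 343.
#' @export
conjoint_triad <- function(protein_sequence) {
  if (nchar(protein_sequence) < 3) {
    stop("conjoint triads need a protein of length >= 3")
  }
  chars <- .seq_chars(protein_sequence)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-standard amino acids in sequence: ", paste(bad, collapse = ", "))
  }
  reduced <- paste(.ct_class_map()[chars], collapse = "")
  kmer_composition(reduced, 3, alphabet = as.character(1:7))
}

.standardize_scale <- function(scale) {
  scale <- scale[AA_ALPHABET]
  if (anyNA(scale)) stop("property scale must cover all 20 standard residues")
  (scale - mean(scale)) / sqrt(mean((scale - mean(scale))^2))
}

#' Pseudo-amino-acid composition (Chou type 1)
#'
#' The 20 amino-acid frequencies extended with `lambda` sequence-order
#' correlation factors. Correlation factor j averages, over all residue
#' pairs at distance j, the mean squared difference of the standardized
#' property values across the supplied scales. The full vector is
#' normalized so that it sums to 1:
#' entry u <= 20 is `f_u / (sum f + w sum theta)` and entry 20 + j is
#' `w theta_j / (sum f + w sum theta)`.
#'
#' @param protein_sequence String over the 20 standard amino acids, strictly
#'   longer than `lambda`.
#' @param lambda Number of sequence-order correlation factors (default 25;
#'   must be below the shortest retained protein length, 30).
#' @param weight Weighting factor `w` for the correlation part (default 0.05).
#' @param scales Named list of residue property tables
#'   (default [paac_default_scales()]).
#' @return Named numeric vector of length `20 + lambda` summing to 1.
#' @export
pseudo_aac <- function(protein_sequence, lambda = 25, weight = 0.05,
                       scales = paac_default_scales()) {
  n <- nchar(protein_sequence)
  if (n <= lambda) {
    stop("protein length ", n, " must exceed lambda = ", lambda)
  }
  if (weight < 0) stop("weight must be nonnegative")
  chars <- .seq_chars(protein_sequence)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-standard amino acids in sequence: ", paste(bad, collapse = ", "))
  }
  comp <- tabulate(match(chars, AA_ALPHABET), nbins = 20) / n
  names(comp) <- AA_ALPHABET

  theta <- numeric(0)
  if (lambda > 0) {
    H <- vapply(scales, .standardize_scale, numeric(20))  # 20 x nscale
    rownames(H) <- AA_ALPHABET
    idx <- match(chars, AA_ALPHABET)
    theta <- vapply(seq_len(lambda), function(j) {
      a <- idx[1:(n - j)]
      b <- idx[(1 + j):n]
      mean(rowMeans((H[b, , drop = FALSE] - H[a, , drop = FALSE])^2))
    }, numeric(1))
    names(theta) <- paste0("lambda", sprintf("%02d", seq_len(lambda)))
  }
  denom <- sum(comp) + weight * sum(theta)
  out <- c(comp, weight * theta) / denom
  out
}

#' Moran autocorrelation descriptors of a protein sequence
#'
#' For each property scale P (standardized over the 20 residues) and each
#' lag d, the spatial autocorrelation
#' `I(d) = [mean over i of (P_i - Pbar)(P_{i+d} - Pbar)] / [mean of (P_i - Pbar)^2]`
#' with Pbar the sequence mean of the property. By contract, `I(d)` is 0
#' when fewer than one residue pair exists at lag d (`N - d < 1`) or when
#' the denominator vanishes (constant property along the sequence).
#'
#' @param protein_sequence String over the 20 standard amino acids,
#'   length >= 2.
#' @param scales Named list of residue property tables
#'   (default [moran_default_scales()]).
#' @param nlag Maximum lag (default 30).
#' @return Named numeric vector of length `length(scales) * nlag`, keys
#'   `<scale>_d<lag>` in lexicographic order.
#' @export
moran_autocorrelation <- function(protein_sequence,
                                  scales = moran_default_scales(),
                                  nlag = 30) {
  stopifnot(nlag >= 1)
  n <- nchar(protein_sequence)
  if (n < 2) stop("Moran autocorrelation needs a protein of length >= 2")
  chars <- .seq_chars(protein_sequence)
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-standard amino acids in sequence: ", paste(bad, collapse = ", "))
  }
  out <- numeric(0)
  for (s in sort(names(scales))) {
    P <- .standardize_scale(scales[[s]])[chars]
    vals <- moran_lags(P, nlag)
    names(vals) <- paste0(s, "_d", sprintf("%02d", seq_len(nlag)))
    out <- c(out, vals)
  }
  out[order(names(out))]
}

#' Moran autocorrelation of a numeric property track
#'
#' Core computation behind [moran_autocorrelation()], exposed so arbitrary
#' property tracks can be autocorrelated directly.
#'
#' @param P Numeric vector of per-position property values.
#' @param nlag Maximum lag.
#' @return Numeric vector of length `nlag`; degenerate lags are 0.
#' @export
moran_lags <- function(P, nlag) {
  n <- length(P)
  dev <- P - mean(P)
  denom <- mean(dev^2)
  vapply(seq_len(nlag), function(d) {
    if (n - d < 1 || denom == 0) return(0)
    num <- sum(dev[1:(n - d)] * dev[(1 + d):n]) / (n - d)
    num / denom
  }, numeric(1))
}

#' Compute all nine sequence feature groups for one isoform
#'
#' @param mrna_sequence mRNA sequence over A/C/G/T.
#' @param protein_sequence Protein sequence over the 20 standard residues.
#' @param paac_lambda,paac_weight Pseudo-amino-acid composition parameters.
#' @param moran_nlag Maximum Moran lag.
#' @return Named list of 9 numeric vectors, names and order as
#'   [sequence_group_names()].
#' @export
compute_all_sequence_groups <- function(mrna_sequence, protein_sequence,
                                        paac_lambda = 25, paac_weight = 0.05,
                                        moran_nlag = 30) {
  list(
    mrna_3mer = kmer_composition(mrna_sequence, 3),
    mrna_4mer = kmer_composition(mrna_sequence, 4),
    mrna_5mer = kmer_composition(mrna_sequence, 5),
    mrna_6mer = kmer_composition(mrna_sequence, 6),
    prot_1mer = kmer_composition(protein_sequence, 1, alphabet = AA_ALPHABET),
    prot_2mer = kmer_composition(protein_sequence, 2, alphabet = AA_ALPHABET),
    conjoint_triad = conjoint_triad(protein_sequence),
    pseudo_aac = pseudo_aac(protein_sequence, lambda = paac_lambda,
                            weight = paac_weight),
    moran = moran_autocorrelation(protein_sequence, nlag = moran_nlag))
}

#' Compute sequence feature groups for every isoform in a catalog
#'
#' @param catalog A [gene_catalog()].
#' @inheritParams compute_all_sequence_groups
#' @return Named list of 9 matrices (isoform x key), rows in catalog order.
#' @export
catalog_feature_groups <- function(catalog, paac_lambda = 25,
                                   paac_weight = 0.05, moran_nlag = 30) {
  ids <- catalog$records$isoform_id
  per_iso <- lapply(ids, function(id) {
    compute_all_sequence_groups(catalog$mrna[[id]], catalog$protein[[id]],
                                paac_lambda = paac_lambda,
                                paac_weight = paac_weight,
                                moran_nlag = moran_nlag)
  })
  groups <- sequence_group_names()
  out <- lapply(groups, function(g) {
    m <- do.call(rbind, lapply(per_iso, `[[`, g))
    rownames(m) <- ids
    m
  })
  names(out) <- groups
  out
}
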