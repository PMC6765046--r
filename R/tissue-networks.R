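# Leave-one-tissue-out (LOTO) ablation: train one full model plus one model
# per tissue with that tissue's expression feature removed, then classify
# every scored pair by whether its prediction flips under the ablation at
# the stated confidence bands (full >= 0.6 and ablated <= 0.4 for
# tissue-specific functional pairs, and the reverse for tissue-specific
# non-functional pairs).

#' Train the full + per-tissue-ablated forest ensemble
#'
#' All `1 + length(tissues)` models are trained on the identical pair set
#' with the same seed, so prediction flips reflect feature removal rather
#' than sampling noise. The organism-wide expression feature is always
#' retained.
#'
#' @param train Labeled pair feature frame (the training split).
#' @param tissues Tissue names; each must have a `z_<tissue>` feature
#'   column.
#' @param n_trees,seed Forest parameters.
#' @return List of class `loto_ensemble`: `full`, `ablated` (named list,
#'   one model per tissue), `tissues`.
#' @export
train_loto_ensemble <- function(train, tissues, n_trees = 100, seed = 1) {
  feature_cols <- .feature_cols(train)
  missing <- setdiff(paste0("z_", tissues), feature_cols)
  if (length(missing) > 0) {
    stop("no feature column for tissue(s): ",
         paste(sub("^z_", "", missing), collapse = ", "))
  }
  full <- train_forest(train, n_trees = n_trees, seed = seed)
  ablated <- lapply(stats::setNames(tissues, tissues), function(t) {
    train_forest(train, n_trees = n_trees, seed = seed,
                 drop_features = paste0("z_", t))
  })
  structure(list(full = full, ablated = ablated, tissues = tissues),
            class = "loto_ensemble")
}

#' @export
print.loto_ensemble <- function(x, ...) {
  cat("<loto_ensemble> full model + ", length(x$ablated),
      " tissue-ablated models\n", sep = "")
  invisible(x)
}

#' Classify a pair under one tissue's ablation
#'
#' Confidence-banded flip logic: full probability >= 0.6 with ablated
#' probability <= 0.4 is `tissue_functional`; full <= 0.4 with ablated
#' >= 0.6 is `tissue_nonfunctional`; an unchanged predicted label (both
#' probabilities on the same side of 0.5) is `reference`; a label flip
#' that misses the confidence bands is `low_confidence` and excluded from
#' the networks.
#'
#' @param prob_full,prob_ablated Probability vectors in [0, 1].
#' @return Character vector over
#'   {tissue_functional, tissue_nonfunctional, reference, low_confidence}.
#' @export
classify_pair_loto <- function(prob_full, prob_ablated) {
  stopifnot(length(prob_full) == length(prob_ablated),
            all(prob_full >= 0 & prob_full <= 1),
            all(prob_ablated >= 0 & prob_ablated <= 1))
  out <- rep("low_confidence", length(prob_full))
  out[(prob_full >= 0.5) == (prob_ablated >= 0.5)] <- "reference"
  out[prob_full >= 0.6 & prob_ablated <= 0.4] <- "tissue_functional"
  out[prob_full <= 0.4 & prob_ablated >= 0.6] <- "tissue_nonfunctional"
  out
}

#' Build per-tissue functional and non-functional networks
#'
#' Scores every pair once with the full model and once with each ablated
#' model, applies [classify_pair_loto()] per tissue, and assembles the
#' edge sets. Tissue-specific edges carry the ablated-model probability as
#' weight (lower weight, stronger tissue-specific functional pair);
#' reference edges carry the full-model probability. Pairs that qualify
#' under more than one tissue's ablation are emitted to each such tissue
#' and flagged `multi_tissue`.
#'
#' @param pairs Pair feature frame (ids + `z_*` columns) for the pairs to
#'   score.
#' @param ensemble A [train_loto_ensemble()].
#' @return List of class `tissue_networks`: `tissue` (named list; per
#'   tissue a list with `functional` and `nonfunctional` edge frames),
#'   `reference` (pairs label-stable under every ablation), `scores`
#'   (per-pair full and ablated probabilities and classes).
#' @export
build_tissue_networks <- function(pairs, ensemble) {
  stopifnot(inherits(ensemble, "loto_ensemble"))
  ids <- pairs[, c("isoform_a", "isoform_b")]
  prob_full <- predict(ensemble$full, pairs)
  classes <- list()
  probs <- list()
  for (t in ensemble$tissues) {
    probs[[t]] <- predict(ensemble$ablated[[t]], pairs)
    classes[[t]] <- classify_pair_loto(prob_full, probs[[t]])
  }
  class_m <- do.call(cbind, classes)
  n_specific <- rowSums(class_m == "tissue_functional" |
                        class_m == "tissue_nonfunctional")
  tissue_sets <- lapply(stats::setNames(ensemble$tissues, ensemble$tissues),
                        function(t) {
    mk <- function(cls) {
      sel <- which(classes[[t]] == cls)
      out <- data.frame(ids[sel, , drop = FALSE],
                        prob_full = prob_full[sel],
                        prob_ablated = probs[[t]][sel],
                        weight = probs[[t]][sel],
                        tissue = rep(t, length(sel)),
                        loto_class = rep(cls, length(sel)),
                        multi_tissue = n_specific[sel] > 1,
                        stringsAsFactors = FALSE)
      rownames(out) <- NULL
      out
    }
    list(functional = mk("tissue_functional"),
         nonfunctional = mk("tissue_nonfunctional"))
  })
  ref_sel <- rowSums(class_m == "reference") == length(ensemble$tissues)
  reference <- ids[ref_sel, , drop = FALSE]
  reference$prob_full <- prob_full[ref_sel]
  reference$weight <- reference$prob_full
  reference$loto_class <- "reference"
  rownames(reference) <- NULL
  scores <- cbind(ids, prob_full = prob_full,
                  as.data.frame(probs, check.names = FALSE))
  structure(list(tissue = tissue_sets, reference = reference,
                 scores = scores),
            class = "tissue_networks")
}

#' @export
print.tissue_networks <- function(x, ...) {
  nf <- vapply(x$tissue, function(t) nrow(t$functional), integer(1))
  nn <- vapply(x$tissue, function(t) nrow(t$nonfunctional), integer(1))
  cat("<tissue_networks> ", length(x$tissue), " tissues; ",
      sum(nf), " functional, ", sum(nn), " non-functional edges; ",
      nrow(x$reference), " reference pairs\n", sep = "")
  invisible(x)
}
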