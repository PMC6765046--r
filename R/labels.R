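# Gold-standard construction: functional (positive) and non-functional
# (negative) isoform pairs from ontology annotations (with evidence and
# term-size filters, true-path and inverse-NOT propagation), pathway
# memberships and filtered protein-protein interactions.
#
# Positives come from pairs of single-isoform genes co-annotated to a
# retained term or pathway, or linked by a retained PPI. Negatives pair
# every isoform of a NOT-annotated gene with every isoform of each
# positively annotated gene of the same retained term; multi-isoform genes
# participate on both sides. Pairs in both sets resolve to positive.

#' Remove ontology annotations with excluded evidence codes
#'
#' Drops annotation records whose evidence code is in the excluded set
#' (default IEA, NAS, ND). The rule is scoped to ontology annotations;
#' pathway and PPI tables carry no evidence codes and are untouched.
#'
#' @param annotations data.frame with columns `gene_id`, `term_id`,
#'   `qualifier`, `evidence_code`.
#' @param excluded Evidence codes to remove.
#' @return Filtered data.frame.
#' @export
filter_evidence <- function(annotations, excluded = c("IEA", "NAS", "ND")) {
  annotations[!(annotations$evidence_code %in% excluded), , drop = FALSE]
}

.propagate <- function(dag, annotations, closure) {
  if (nrow(annotations) == 0) return(annotations)
  extra <- lapply(seq_len(nrow(annotations)), function(i) {
    targets <- closure[[annotations$term_id[i]]]
    if (length(targets) == 0) return(NULL)
    out <- annotations[rep(i, length(targets)), , drop = FALSE]
    out$term_id <- targets
    out
  })
  out <- rbind(annotations, do.call(rbind, extra))
  out[!duplicated(out[, c("gene_id", "term_id", "qualifier")]), ,
      drop = FALSE]
}

#' Propagate positive annotations up the ontology (true path rule)
#'
#' A gene annotated to term T becomes annotated to every ancestor of T.
#' Monotone (never removes records) and idempotent.
#'
#' @param dag An [ontology_dag()].
#' @param annotations Positive annotation records.
#' @return Propagated, de-duplicated records.
#' @export
propagate_true_path <- function(dag, annotations) {
  unknown <- setdiff(unique(annotations$term_id), dag$terms)
  if (length(unknown) > 0) {
    stop("annotation to unknown term(s): ", paste(unknown, collapse = ", "))
  }
  out <- .propagate(dag, annotations, dag$ancestors)
  rownames(out) <- NULL
  out
}

#' Propagate NOT annotations down the ontology (inverse true path rule)
#'
#' A gene NOT-annotated to term T becomes NOT-annotated to every descendant
#' of T. Monotone and idempotent.
#'
#' @param dag An [ontology_dag()].
#' @param annotations NOT annotation records.
#' @return Propagated, de-duplicated records.
#' @export
propagate_not_inverse <- function(dag, annotations) {
  unknown <- setdiff(unique(annotations$term_id), dag$terms)
  if (length(unknown) > 0) {
    stop("annotation to unknown term(s): ", paste(unknown, collapse = ", "))
  }
  descendants <- lapply(stats::setNames(dag$terms, dag$terms),
                        function(t) dag_descendants(dag, t))
  out <- .propagate(dag, annotations, descendants)
  rownames(out) <- NULL
  out
}

#' Gene sets per term
#'
#' @param annotations Annotation records.
#' @return Named list, term id -> character vector of unique gene ids.
#' @export
term_gene_sets <- function(annotations) {
  lapply(split(annotations$gene_id, annotations$term_id), unique)
}

#' Filter term gene sets by size
#'
#' Keeps terms whose annotated gene count lies in
#' `[min_genes, max_genes]` (defaults 10 and 1000): terms annotated to
#' fewer genes are too specific, terms with more are too broad. Applied
#' after propagation.
#'
#' @param sets Named list of gene sets from [term_gene_sets()].
#' @param min_genes,max_genes Inclusive size bounds.
#' @return Filtered named list.
#' @export
filter_terms <- function(sets, min_genes = 10, max_genes = 1000) {
  sizes <- lengths(sets)
  sets[sizes >= min_genes & sizes <= max_genes]
}

#' Filter protein-protein interaction records by source-specific quality
#'
#' APID records are kept only with at least 2 experimental evidences; IID
#' records with only orthologous evidence are dropped; Mentha records need
#' a score of at least 0.2; and every source requires both interactors to
#' be from the target organism.
#'
#' @param ppi data.frame with the PPI columns (see [read_ppi()]). Known
#'   sources: IntAct, BioGRID, APID, IID, Mentha.
#' @param target_taxon Taxon id both interactors must carry
#'   (default `"10090"`, mouse).
#' @return data.frame of retained gene pairs (`gene_a`, `gene_b`),
#'   canonically ordered and de-duplicated.
#' @export
filter_ppi <- function(ppi, target_taxon = "10090") {
  known <- c("IntAct", "BioGRID", "APID", "IID", "Mentha")
  unknown <- setdiff(unique(ppi$source), known)
  if (length(unknown) > 0) {
    stop("unknown PPI source(s): ", paste(unknown, collapse = ", "))
  }
  keep <- ppi$taxon_a == target_taxon & ppi$taxon_b == target_taxon
  keep <- keep & !(ppi$source == "APID" & ppi$evidence_count < 2)
  keep <- keep & !(ppi$source == "IID" & ppi$orthology_flag)
  keep <- keep & !(ppi$source == "Mentha" & ppi$score < 0.2)
  out <- ppi[keep, c("gene_a", "gene_b"), drop = FALSE]
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]
  out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  out <- out[out$gene_a != out$gene_b, , drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.pair_key <- function(a, b) paste(a, b, sep = "\r")

.gene_pairs_to_isoform_pairs <- function(gene_a, gene_b, iso_of, provenance) {
  rows <- lapply(seq_along(gene_a), function(i) {
    expand.grid(isoform_a = iso_of[[gene_a[i]]],
                isoform_b = iso_of[[gene_b[i]]],
                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) return(NULL)
  out$provenance <- provenance
  canonical_pairs(out)
}

.collapse_pairs <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(isoform_a = character(0), isoform_b = character(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  key <- .pair_key(df$isoform_a, df$isoform_b)
  prov <- vapply(split(df$provenance, key),
                 function(p) paste(sort(unique(p)), collapse = ";"),
                 character(1))
  first <- !duplicated(key)
  out <- df[first, c("isoform_a", "isoform_b"), drop = FALSE]
  out$provenance <- prov[.pair_key(out$isoform_a, out$isoform_b)]
  out <- out[order(out$isoform_a, out$isoform_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build functional (positive) isoform pairs
#'
#' A pair is positive iff both genes produce a single isoform and the genes
#' are co-annotated to a retained term or pathway, or are linked by a
#' retained PPI. Only pairs of different genes are emitted.
#'
#' @param catalog A [gene_catalog()].
#' @param term_sets Retained term gene sets (after propagation and size
#'   filtering).
#' @param pathway_sets Optional named list of pathway gene sets (flat
#'   memberships, no propagation or size filter).
#' @param ppi_pairs Optional data.frame of retained PPI gene pairs from
#'   [filter_ppi()].
#' @return data.frame `isoform_a`, `isoform_b`, `provenance`.
#' @export
build_positive_pairs <- function(catalog, term_sets, pathway_sets = NULL,
                                 ppi_pairs = NULL) {
  singles <- single_isoform_genes(catalog)
  iso_of <- gene_isoforms(catalog)
  chunks <- list()
  add_coannotation <- function(sets, source) {
    for (nm in names(sets)) {
      g <- sort(intersect(sets[[nm]], singles))
      if (length(g) < 2) next
      idx <- utils::combn(length(g), 2)
      chunks[[length(chunks) + 1]] <<- data.frame(
        isoform_a = unlist(iso_of[g[idx[1, ]]], use.names = FALSE),
        isoform_b = unlist(iso_of[g[idx[2, ]]], use.names = FALSE),
        provenance = paste0(source, ":", nm),
        stringsAsFactors = FALSE)
    }
  }
  add_coannotation(term_sets, "term")
  if (!is.null(pathway_sets)) add_coannotation(pathway_sets, "pathway")
  if (!is.null(ppi_pairs) && nrow(ppi_pairs) > 0) {
    both_single <- ppi_pairs$gene_a %in% singles &
      ppi_pairs$gene_b %in% singles &
      ppi_pairs$gene_a %in% names(iso_of) &
      ppi_pairs$gene_b %in% names(iso_of)
    pp <- ppi_pairs[both_single, , drop = FALSE]
    if (nrow(pp) > 0) {
      chunks[[length(chunks) + 1]] <- data.frame(
        isoform_a = unlist(iso_of[pp$gene_a], use.names = FALSE),
        isoform_b = unlist(iso_of[pp$gene_b], use.names = FALSE),
        provenance = "ppi",
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(chunks) > 0) canonical_pairs(do.call(rbind, chunks)) else NULL
  .collapse_pairs(df)
}

#' Build non-functional (negative) isoform pairs
#'
#' For each retained term, every isoform of each NOT-annotated gene is
#' paired with every isoform of each positively annotated gene of that
#' term. Both sides may be multi-isoform genes; same-gene pairs are never
#' emitted.
#'
#' @param catalog A [gene_catalog()].
#' @param not_sets Named list, term -> NOT-annotated genes (after inverse
#'   propagation), restricted to retained terms.
#' @param pos_sets Named list, term -> positively annotated genes (after
#'   propagation and size filtering).
#' @return data.frame `isoform_a`, `isoform_b`, `provenance`.
#' @export
build_negative_pairs <- function(catalog, not_sets, pos_sets) {
  iso_of <- gene_isoforms(catalog)
  chunks <- list()
  for (term in intersect(names(not_sets), names(pos_sets))) {
    ng <- intersect(not_sets[[term]], names(iso_of))
    pg <- intersect(setdiff(pos_sets[[term]], ng), names(iso_of))
    if (length(ng) == 0 || length(pg) == 0) next
    grid <- expand.grid(gene_a = ng, gene_b = pg, stringsAsFactors = FALSE)
    grid <- grid[grid$gene_a != grid$gene_b, , drop = FALSE]
    if (nrow(grid) == 0) next
    chunks[[length(chunks) + 1]] <-
      .gene_pairs_to_isoform_pairs(grid$gene_a, grid$gene_b, iso_of,
                                   paste0("not:", term))
  }
  df <- if (length(chunks) > 0) do.call(rbind, chunks) else NULL
  .collapse_pairs(df)
}

#' Resolve positive/negative conflicts
#'
#' A pair found in both sets (positive for one term, negative for another)
#' is kept positive only, because the two genes share at least one
#' biological process. The returned sets are disjoint; all other pairs
#' remain unknown.
#'
#' @param positives,negatives Pair frames from [build_positive_pairs()] and
#'   [build_negative_pairs()].
#' @return List with elements `positive` and `negative` (disjoint).
#' @export
resolve_conflicts <- function(positives, negatives) {
  pk <- .pair_key(positives$isoform_a, positives$isoform_b)
  nk <- .pair_key(negatives$isoform_a, negatives$isoform_b)
  list(positive = positives,
       negative = negatives[!(nk %in% pk), , drop = FALSE])
}

#' Build the full labeled gold standard from raw inputs
#'
#' Runs the whole labeling pipeline: evidence filtering, true-path and
#' inverse-NOT propagation, term-size filtering (applied uniformly to the
#' term set used for both positives and negatives), PPI quality filtering,
#' positive and negative pair construction, and conflict resolution.
#'
#' @param catalog A [gene_catalog()].
#' @param dag An [ontology_dag()].
#' @param annotations Ontology annotation records (`gene_id`, `term_id`,
#'   `qualifier`, `evidence_code`).
#' @param pathways Optional data.frame `pathway_id`, `gene_id`.
#' @param ppi Optional PPI data.frame (see [read_ppi()]).
#' @param min_term_size,max_term_size Term-size bounds (defaults 10, 1000).
#' @param excluded_evidence Evidence codes removed before propagation.
#' @param target_taxon PPI taxon filter.
#' @return List: `positive`, `negative` (disjoint pair frames with
#'   provenance), `term_sets` (retained positive term gene sets),
#'   `not_sets` (NOT gene sets on retained terms).
#' @export
build_gold_standard <- function(catalog, dag, annotations, pathways = NULL,
                                ppi = NULL, min_term_size = 10,
                                max_term_size = 1000,
                                excluded_evidence = c("IEA", "NAS", "ND"),
                                target_taxon = "10090") {
  ann <- filter_evidence(annotations, excluded_evidence)
  pos_ann <- propagate_true_path(dag, ann[ann$qualifier == "positive", ,
                                          drop = FALSE])
  not_ann <- propagate_not_inverse(dag, ann[ann$qualifier == "NOT", ,
                                            drop = FALSE])
  pos_sets <- filter_terms(term_gene_sets(pos_ann), min_term_size,
                           max_term_size)
  not_sets <- term_gene_sets(not_ann)
  not_sets <- not_sets[intersect(names(not_sets), names(pos_sets))]
  pathway_sets <- NULL
  if (!is.null(pathways) && nrow(pathways) > 0) {
    pathway_sets <- lapply(split(pathways$gene_id, pathways$pathway_id),
                           unique)
  }
  ppi_pairs <- if (!is.null(ppi) && nrow(ppi) > 0) {
    filter_ppi(ppi, target_taxon)
  } else NULL
  positives <- build_positive_pairs(catalog, pos_sets, pathway_sets,
                                    ppi_pairs)
  negatives <- build_negative_pairs(catalog, not_sets, pos_sets)
  res <- resolve_conflicts(positives, negatives)
  list(positive = res$positive, negative = res$negative,
       term_sets = pos_sets, not_sets = not_sets)
}
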