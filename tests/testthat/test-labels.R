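# Gold-standard construction: evidence filters, propagation, term-size and
# PPI filters, pair building and conflict resolution.

chain_dag <- function() {
  ontology_dag(c("root", "mid", "leaf"),
               list(mid = "root", leaf = "mid"))
}

ann_row <- function(gene, term, qualifier = "positive", ev = "EXP") {
  data.frame(gene_id = gene, term_id = term, qualifier = qualifier,
             evidence_code = ev, stringsAsFactors = FALSE)
}

test_that("evidence filter removes exactly the excluded codes", {
  ann <- do.call(rbind, Map(ann_row, paste0("G", 1:5), "T1",
                            ev = c("EXP", "IEA", "NAS", "ND", "IDA")))
  kept <- filter_evidence(ann)
  expect_setequal(kept$evidence_code, c("EXP", "IDA"))
  expect_equal(nrow(filter_evidence(ann[0, ])), 0)
})

test_that("true-path propagation annotates every ancestor and is idempotent", {
  dag <- chain_dag()
  ann <- ann_row("G1", "leaf")
  prop <- propagate_true_path(dag, ann)
  expect_setequal(prop$term_id, c("leaf", "mid", "root"))
  # a root annotation is unchanged
  expect_equal(propagate_true_path(dag, ann_row("G2", "root"))$term_id,
               "root")
  # idempotent and monotone
  expect_equal(propagate_true_path(dag, prop), prop)
  expect_true(all(paste(ann$gene_id, ann$term_id) %in%
                    paste(prop$gene_id, prop$term_id)))
})

test_that("NOT propagation runs down the DAG and is idempotent", {
  dag <- chain_dag()
  ann <- ann_row("G1", "mid", qualifier = "NOT")
  prop <- propagate_not_inverse(dag, ann)
  expect_setequal(prop$term_id, c("mid", "leaf"))
  expect_false("root" %in% prop$term_id)
  expect_equal(propagate_not_inverse(dag,
                                     ann_row("G1", "leaf", "NOT"))$term_id,
               "leaf")
  expect_equal(propagate_not_inverse(dag, prop), prop)
})

test_that("propagation operators are monotone and idempotent on fixtures", {
  st <- fx_small_study()
  ann <- filter_evidence(st$annotations)
  pos <- ann[ann$qualifier == "positive", ]
  nt <- ann[ann$qualifier == "NOT", ]
  p1 <- propagate_true_path(st$ontology, pos)
  expect_gte(nrow(p1), nrow(pos))
  expect_equal(propagate_true_path(st$ontology, p1), p1)
  n1 <- propagate_not_inverse(st$ontology, nt)
  expect_gte(nrow(n1), nrow(nt))
  expect_equal(propagate_not_inverse(st$ontology, n1), n1)
})

test_that("term-size filter keeps the inclusive [10, 1000] band", {
  sets <- list(a = paste0("g", 1:9), b = paste0("g", 1:10),
               c = paste0("g", 1:1000), d = paste0("g", 1:1001))
  kept <- filter_terms(sets)
  expect_setequal(names(kept), c("b", "c"))
  expect_length(filter_terms(list()), 0)
})

test_that("PPI quality filters follow the per-source rules", {
  base <- data.frame(gene_a = "G1", gene_b = "G2", source = "IntAct",
                     evidence_count = 5, score = 0.9,
                     orthology_flag = FALSE, taxon_a = "10090",
                     taxon_b = "10090", stringsAsFactors = FALSE)
  make <- function(...) {
    out <- base
    args <- list(...)
    out[names(args)] <- args
    out
  }
  ppi <- rbind(make(source = "APID", evidence_count = 1),
               make(source = "APID", evidence_count = 2, gene_b = "G3"),
               make(source = "Mentha", score = 0.19, gene_b = "G4"),
               make(source = "Mentha", score = 0.2, gene_b = "G5"),
               make(source = "IID", orthology_flag = TRUE, gene_b = "G6"),
               make(source = "IID", orthology_flag = FALSE, gene_b = "G7"),
               make(taxon_b = "9606", gene_b = "G8"),
               make(gene_b = "G9"))
  kept <- filter_ppi(ppi)
  expect_setequal(kept$gene_b, c("G3", "G5", "G7", "G9"))
  expect_error(filter_ppi(make(source = "StringDB")), "unknown PPI source")
})

fig1_catalog <- function() {
  # G1, G2 single-isoform; G3 two isoforms; G4 three isoforms
  recs <- data.frame(
    isoform_id = c("M1", "M2", "M31", "M32", "M41", "M42", "M43"),
    gene_id = c("G1", "G2", "G3", "G3", "G4", "G4", "G4"),
    stringsAsFactors = FALSE)
  seqs <- function(n) stats::setNames(rep(strrep("ACGT", 10), n),
                                      recs$isoform_id)
  prot <- stats::setNames(rep(strrep("ACDEFGHIKLMNPQRSTVWY", 2), 7),
                          recs$isoform_id)
  gene_catalog(recs, seqs(7), prot)
}

test_that("positives require two single-isoform genes sharing a source", {
  cat1 <- fig1_catalog()
  pos <- build_positive_pairs(cat1,
                              term_sets = list(T1 = c("G1", "G2", "G4")))
  # G4 is multi-isoform: only the single-isoform pair G1-G2 remains
  expect_equal(nrow(pos), 1)
  expect_equal(pos$isoform_a, "M1")
  expect_equal(pos$isoform_b, "M2")
  # 4 single-isoform genes co-annotated -> C(4,2) = 6 pairs
  cat2 <- gene_catalog(data.frame(isoform_id = paste0("M", 1:4),
                                  gene_id = paste0("G", 1:4)),
                       stats::setNames(rep("ACGT", 4), paste0("M", 1:4)),
                       stats::setNames(rep(strrep("A", 30), 4),
                                       paste0("M", 1:4)))
  pos2 <- build_positive_pairs(cat2,
                               term_sets = list(T1 = paste0("G", 1:4)))
  expect_equal(nrow(pos2), 6)
})

test_that("PPI positives are an independent source beside co-annotation", {
  cat1 <- fig1_catalog()
  pos <- build_positive_pairs(cat1, term_sets = list(),
                              ppi_pairs = data.frame(gene_a = "G1",
                                                     gene_b = "G2"))
  expect_equal(nrow(pos), 1)
  expect_equal(pos$provenance, "ppi")
  # PPI between single- and multi-isoform genes contributes nothing
  pos2 <- build_positive_pairs(cat1, term_sets = list(),
                               ppi_pairs = data.frame(gene_a = "G1",
                                                      gene_b = "G4"))
  expect_equal(nrow(pos2), 0)
})

test_that("the worked NOT example yields its ten negative pairs", {
  cat1 <- fig1_catalog()
  neg <- build_negative_pairs(
    cat1,
    not_sets = list(T1 = "G3"),
    pos_sets = list(T1 = c("G1", "G2", "G3", "G4")))
  expect_equal(nrow(neg), 10)  # {M31, M32} x {M1, M2, M41, M42, M43}
  expect_true(all(neg$isoform_a %in% c("M1", "M2", "M31", "M32") |
                    neg$isoform_b %in% c("M31", "M32")))
  # never pairs a NOT gene's isoforms with each other
  both_g3 <- grepl("^M3", neg$isoform_a) & grepl("^M3", neg$isoform_b)
  expect_false(any(both_g3))
})

test_that("conflicting pairs resolve to positive and the sets are disjoint", {
  pos <- data.frame(isoform_a = "M1", isoform_b = "M2",
                    provenance = "term:T1", stringsAsFactors = FALSE)
  neg <- data.frame(isoform_a = c("M1", "M1"), isoform_b = c("M2", "M3"),
                    provenance = "not:T2", stringsAsFactors = FALSE)
  res <- resolve_conflicts(pos, neg)
  expect_equal(nrow(res$positive), 1)
  expect_equal(res$negative$isoform_b, "M3")
  key <- function(df) paste(df$isoform_a, df$isoform_b)
  expect_length(intersect(key(res$positive), key(res$negative)), 0)
})

test_that("gold standard matches a brute-force pair enumerator", {
  st <- fx_small_study()
  gold <- fx_small_dataset()$gold

  # independent re-derivation: scan all pairs against the stated rules
  ann <- st$annotations[!(st$annotations$evidence_code %in%
                            c("IEA", "NAS", "ND")), ]
  anc <- st$ontology$ancestors
  pos_ann <- ann[ann$qualifier == "positive", ]
  gene_terms <- list()
  for (i in seq_len(nrow(pos_ann))) {
    g <- pos_ann$gene_id[i]; t <- pos_ann$term_id[i]
    gene_terms[[g]] <- union(gene_terms[[g]], c(t, anc[[t]]))
  }
  term_genes <- list()
  for (g in names(gene_terms)) {
    for (t in gene_terms[[g]]) term_genes[[t]] <- union(term_genes[[t]], g)
  }
  retained <- names(term_genes)[lengths(term_genes) >= 2 &
                                  lengths(term_genes) <= 1000]
  not_ann <- ann[ann$qualifier == "NOT", ]
  not_terms <- list()
  for (i in seq_len(nrow(not_ann))) {
    g <- not_ann$gene_id[i]; t <- not_ann$term_id[i]
    desc <- setdiff(names(anc)[vapply(anc, function(a) t %in% a,
                                      logical(1))], t)
    for (tt in intersect(c(t, desc), retained)) {
      not_terms[[tt]] <- union(not_terms[[tt]], g)
    }
  }
  pw <- split(st$pathways$gene_id, st$pathways$pathway_id)
  ppi_ok <- filter_ppi(st$ppi)
  singles <- single_isoform_genes(st$catalog)
  iso_of <- gene_isoforms(st$catalog)
  gene_of <- stats::setNames(st$catalog$records$gene_id,
                             st$catalog$records$isoform_id)

  pairs <- enumerate_pairs(st$catalog)
  is_pos <- logical(nrow(pairs))
  is_neg <- logical(nrow(pairs))
  ppi_key <- paste(ppi_ok$gene_a, ppi_ok$gene_b)
  for (i in seq_len(nrow(pairs))) {
    ga <- gene_of[[pairs$isoform_a[i]]]
    gb <- gene_of[[pairs$isoform_b[i]]]
    if (ga == gb) next
    if (ga %in% singles && gb %in% singles) {
      shared_term <- any(vapply(retained, function(t)
        ga %in% term_genes[[t]] && gb %in% term_genes[[t]], logical(1)))
      shared_pw <- any(vapply(pw, function(s)
        ga %in% s && gb %in% s, logical(1)))
      in_ppi <- paste(min(ga, gb), max(ga, gb)) %in% ppi_key
      is_pos[i] <- shared_term || shared_pw || in_ppi
    }
    if (!is_pos[i]) {
      for (t in names(not_terms)) {
        hit <- (ga %in% not_terms[[t]] && gb %in% term_genes[[t]] &&
                  !(gb %in% not_terms[[t]])) ||
               (gb %in% not_terms[[t]] && ga %in% term_genes[[t]] &&
                  !(ga %in% not_terms[[t]]))
        if (hit) { is_neg[i] <- TRUE; break }
      }
    }
  }
  key <- function(a, b) paste(a, b)
  expect_setequal(key(gold$positive$isoform_a, gold$positive$isoform_b),
                  key(pairs$isoform_a[is_pos], pairs$isoform_b[is_pos]))
  expect_setequal(key(gold$negative$isoform_a, gold$negative$isoform_b),
                  key(pairs$isoform_a[is_neg], pairs$isoform_b[is_neg]))
})

test_that("final label sets are disjoint with no same-gene pairs", {
  gold <- fx_default_dataset()$gold
  st <- fx_default_study()
  key <- function(df) paste(df$isoform_a, df$isoform_b)
  expect_length(intersect(key(gold$positive), key(gold$negative)), 0)
  gene_of <- stats::setNames(st$catalog$records$gene_id,
                             st$catalog$records$isoform_id)
  for (df in list(gold$positive, gold$negative)) {
    expect_false(any(gene_of[df$isoform_a] == gene_of[df$isoform_b]))
    expect_true(all(df$isoform_a < df$isoform_b))
  }
})
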