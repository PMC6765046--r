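# Synthetic-data generator: determinism, planted structure, annotations.

test_that("config validation names the offending field", {
  expect_error(sim_config(samples_per_tissue = 1), "samples_per_tissue")
  expect_error(sim_config(n_genes = 4, single_isoform_fraction = 0.5,
                          planted_module_count = 0),
               "single_isoform_fraction")
  expect_error(sim_config(module_coexpression_rho = 0),
               "module_coexpression_rho")
  expect_error(sim_config(n_terms = 2), "n_terms")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("identical config and seed give identical studies", {
  cfg <- fx_small_config()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$catalog, s2$catalog)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$ppi, s2$ppi)
  # a different seed changes the sequences
  s3 <- simulate_catalog(fx_small_config(seed = 43))
  expect_false(identical(s1$catalog$mrna, s3$mrna))
})

test_that("single-isoform fraction controls isoform counts exactly", {
  cfg <- sim_config(n_genes = 50, single_isoform_fraction = 1.0,
                    planted_module_count = 2, module_size = 4,
                    n_terms = 10, dag_depth = 2, seed = 1)
  cat1 <- simulate_catalog(cfg)
  expect_true(all(table(cat1$records$gene_id) == 1))

  cfg2 <- sim_config(n_genes = 50, single_isoform_fraction = 0.5,
                     planted_module_count = 2, module_size = 4,
                     n_terms = 10, dag_depth = 2, seed = 1)
  cat2 <- simulate_catalog(cfg2)
  expect_length(single_isoform_genes(cat2), 25)
})

test_that("catalog sequences satisfy the load-time contracts", {
  cat1 <- fx_small_study()$catalog
  dna <- strsplit("ACGT", "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (id in cat1$records$isoform_id) {
    expect_gte(nchar(cat1$protein[[id]]), 30)
    expect_true(all(strsplit(cat1$mrna[[id]], "")[[1]] %in% dna))
    expect_true(all(strsplit(cat1$protein[[id]], "")[[1]] %in% aa))
  }
})

test_that("expression table has the configured shape and no negatives", {
  st <- fx_small_study()
  cfg <- st$config
  expect_equal(dim(st$expression$values),
               c(nrow(st$catalog$records),
                 length(cfg$tissues) * cfg$samples_per_tissue))
  expect_true(all(st$expression$values >= 0))
})

test_that("noiseless planted modules are perfectly co-expressed in tissue", {
  cfg <- sim_config(n_genes = 40, single_isoform_fraction = 0.6,
                    tissues = c("heart", "liver"), samples_per_tissue = 4,
                    n_terms = 8, dag_depth = 2, planted_module_count = 2,
                    module_size = 4, noise_sd = 0, seed = 9)
  st <- simulate_study(cfg)
  lk <- fx_planted_lookup(st)
  slices <- tissue_slices(st$expression)
  m1 <- st$modules$gene_id[st$modules$module == 1]
  iso <- unlist(gene_isoforms(st$catalog)[m1])
  cors <- stats::cor(t(slices$heart[iso, ]))
  expect_equal(unname(cors[upper.tri(cors)]),
               rep(1, sum(upper.tri(cors))), tolerance = 1e-12)
})

test_that("within-module correlation beats random pairs", {
  st <- fx_small_study()
  lk <- fx_planted_lookup(st)
  slices <- tissue_slices(st$expression)
  pairs <- enumerate_pairs(st$catalog)
  planted <- fx_same_module(lk, pairs$isoform_a, pairs$isoform_b)
  m <- slices$heart
  rho <- sapply(seq_len(nrow(pairs)), function(i) {
    suppressWarnings(stats::cor(m[pairs$isoform_a[i], ],
                                m[pairs$isoform_b[i], ]))
  })
  expect_gt(mean(rho[planted], na.rm = TRUE),
            mean(rho[!planted], na.rm = TRUE) + 0.5)
})

test_that("cross-module pairs decorrelate under heavy noise", {
  # Monte-Carlo over 100 seeds: mean |rho| of a cross-module pair stays
  # near zero while same-module pairs stay strongly correlated
  rhos <- numeric(100)
  for (s in seq_len(100)) {
    cfg <- sim_config(n_genes = 20, single_isoform_fraction = 0.8,
                      tissues = c("a", "b"), samples_per_tissue = 4,
                      n_terms = 4, dag_depth = 1, planted_module_count = 2,
                      module_size = 4, noise_sd = 2, seed = 1000 + s)
    st <- simulate_catalog(cfg)
    ex <- simulate_expression(st, cfg)
    m <- log_transform(ex$values)
    i1 <- "G0001.1"; i2 <- "G0005.1"  # modules 1 and 2
    rhos[s] <- suppressWarnings(stats::cor(m[i1, ], m[i2, ]))
  }
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.1)
})

test_that("annotation generator plants the promised structure", {
  st <- fx_small_study()
  cfg <- st$config
  # acyclic and rooted: construction validates acyclicity; roots exist
  expect_true(sum(lengths(st$ontology$parents) == 0) >= 1)
  expect_equal(sum(st$annotations$qualifier == "NOT"),
               cfg$not_annotation_count)
  # excluded evidence codes are present to exercise filtering
  expect_true(any(st$annotations$evidence_code %in% c("IEA", "NAS", "ND")))
  # module genes are co-annotated to their module term
  for (m in seq_len(cfg$planted_module_count)) {
    members <- st$modules$gene_id[st$modules$module == m]
    term <- st$module_terms[[as.character(m)]]
    ann <- st$annotations
    got <- ann$gene_id[ann$term_id == term & ann$qualifier == "positive" &
                         !(ann$evidence_code %in% c("IEA", "NAS", "ND"))]
    expect_true(all(members %in% got))
  }
})

test_that("no NOT records yields an empty negative set", {
  cfg <- sim_config(n_genes = 40, single_isoform_fraction = 0.6,
                    tissues = c("a", "b"), samples_per_tissue = 2,
                    n_terms = 8, dag_depth = 2, planted_module_count = 3,
                    module_size = 4, not_annotation_count = 0, seed = 2)
  st <- simulate_study(cfg)
  gold <- build_gold_standard(st$catalog, st$ontology, st$annotations,
                              st$pathways, st$ppi, min_term_size = 2)
  expect_equal(nrow(gold$negative), 0)
  expect_gt(nrow(gold$positive), 0)
})

test_that("a planted module of 4 single-isoform genes yields C(4,2) term positives", {
  cfg <- sim_config(n_genes = 30, single_isoform_fraction = 0.8,
                    tissues = c("a", "b"), samples_per_tissue = 2,
                    n_terms = 4, dag_depth = 2, planted_module_count = 1,
                    module_size = 4, not_annotation_count = 0, seed = 3)
  st <- simulate_study(cfg)
  term <- st$module_terms[["1"]]
  gold <- build_gold_standard(st$catalog, st$ontology, st$annotations,
                              pathways = NULL, ppi = NULL,
                              min_term_size = 2)
  from_term <- gold$positive[grepl(paste0("term:", term),
                                   gold$positive$provenance), ]
  expect_equal(nrow(from_term), choose(4, 2))
})

test_that("dag_depth 1 makes every term a root so propagation is identity", {
  cfg <- sim_config(n_genes = 20, single_isoform_fraction = 0.8,
                    tissues = c("a", "b"), samples_per_tissue = 2,
                    n_terms = 4, dag_depth = 1, planted_module_count = 2,
                    module_size = 4, seed = 4)
  st <- simulate_study(cfg)
  expect_true(all(lengths(st$ontology$parents) == 0))
  pos <- st$annotations[st$annotations$qualifier == "positive", ]
  expect_equal(propagate_true_path(st$ontology, pos), pos)
})
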