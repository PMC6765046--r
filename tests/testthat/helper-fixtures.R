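# Shared fixtures, built once per test session. All are generated in code
# from seeded configurations; nothing is read from disk.

.fx_cache <- new.env(parent = emptyenv())

.fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, build(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

# Small catalog/study for structural tests (fast to regenerate).
fx_small_config <- function(seed = 42) {
  sim_config(n_genes = 40, max_isoforms_per_gene = 3,
             single_isoform_fraction = 0.6,
             tissues = c("heart", "liver", "kidney"),
             samples_per_tissue = 3, n_terms = 10, dag_depth = 2,
             not_annotation_count = 4, planted_module_count = 3,
             module_size = 4, module_coexpression_rho = 0.9,
             noise_sd = 0.4, seed = seed)
}

fx_small_study <- function() .fx("small_study", function() {
  simulate_study(fx_small_config())
})

fx_small_dataset <- function() .fx("small_dataset", function() {
  pair_dataset(fx_small_study(), min_term_size = 2)
})

# Default study conditions (the generator's defaults), seed 7.
fx_default_study <- function() .fx("default_study", function() {
  simulate_study(sim_config(seed = 7))
})

fx_default_dataset <- function() .fx("default_dataset", function() {
  pair_dataset(fx_default_study())
})

# Strong planted signal: default conditions with small noise.
fx_strong_dataset <- function() .fx("strong_dataset", function() {
  pair_dataset(simulate_study(sim_config(noise_sd = 0.3, seed = 11)))
})

# Tissue-ablation fixture: modules co-expressed only in their home tissue,
# sequences uninformative, so the signal for a planted pair lives in one
# tissue's expression feature. Eight samples per tissue keep per-tissue
# sample correlations informative (three-sample correlations of unrelated
# isoforms are regularly extreme by chance).
fx_loto_config <- function() {
  sim_config(tissue_specific_modules = TRUE,
             module_sequence_similarity = FALSE, noise_sd = 0.3,
             samples_per_tissue = 8, seed = 3)
}

fx_loto_study <- function() .fx("loto_study", function() {
  simulate_study(fx_loto_config())
})

fx_loto_dataset <- function() .fx("loto_dataset", function() {
  pair_dataset(fx_loto_study())
})

# Scored pair universe for the LOTO fixture: every labeled pair plus a
# seeded random sample of unknown pairs, mirroring prediction over all
# pairs at fixture scale.
fx_loto_universe <- function() .fx("loto_universe", function() {
  st <- fx_loto_study()
  pd <- fx_loto_dataset()
  all_pairs <- enumerate_pairs(st$catalog)
  set.seed(99)
  extra <- all_pairs[sample(nrow(all_pairs), 4000), ]
  universe <- unique(rbind(pd$dataset[, c("isoform_a", "isoform_b")],
                           extra))
  pair_feature_matrix(universe, pd$groups, st$expression)
})

fx_loto_networks <- function() .fx("loto_networks", function() {
  pd <- fx_loto_dataset()
  split <- sample_balanced_split(pd$dataset, 150, 50, seed = 1)
  ens <- train_loto_ensemble(split$train, fx_loto_config()$tissues,
                             seed = 1)
  list(split = split, ensemble = ens,
       networks = build_tissue_networks(fx_loto_universe(), ens))
})

# Truth oracle for planted pairs: both genes in the same module.
fx_planted_lookup <- function(study) {
  ma <- study$modules
  list(gene_of = stats::setNames(study$catalog$records$gene_id,
                                 study$catalog$records$isoform_id),
       mod_of = stats::setNames(ma$module, ma$gene_id),
       home_of = stats::setNames(ma$home_tissue, ma$gene_id))
}

fx_same_module <- function(lk, a, b) {
  ga <- lk$gene_of[a]; gb <- lk$gene_of[b]
  !is.na(lk$mod_of[ga]) & !is.na(lk$mod_of[gb]) &
    lk$mod_of[ga] == lk$mod_of[gb]
}
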