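# Seeded synthetic-data generator. Emulates the statistical structure the
# pipeline assumes: a gene catalog with 1..k isoforms per gene, planted
# co-functional modules whose members are both co-annotated (shared
# ontology terms, pathways, PPIs) and co-expressed (tissue-structured
# latent factors), an ontology forest with positive and NOT annotations,
# and toy PPI tables with the quality fields the filters act on. Module
# membership drives BOTH the labels and the features, so the planted
# signal is genuinely learnable.

#' Simulation configuration
#'
#' Defaults define the package's desk-scale study conditions: 200 genes
#' (70% single-isoform), 4 tissues x 3 samples, 6 planted modules of 10
#' single-isoform genes (so module terms survive the default
#' 10..1000-gene term-size filter), within-module target correlation 0.9
#' and noise SD 0.5.
#'
#' @param n_genes Number of genes.
#' @param max_isoforms_per_gene Maximum isoforms for multi-isoform genes.
#' @param single_isoform_fraction Fraction of genes producing exactly one
#'   isoform; `round(fraction * n_genes)` genes are single-isoform.
#' @param tissues Tissue names.
#' @param samples_per_tissue Samples per tissue (at least 2; a Pearson
#'   correlation needs two samples).
#' @param n_terms Ontology terms; at least
#'   `planted_module_count * dag_depth`.
#' @param dag_depth Depth of each module's term chain (1 = all roots).
#' @param not_annotation_count Number of planted NOT annotation records.
#' @param planted_module_count Number of co-functional modules.
#' @param module_size Single-isoform genes per module.
#' @param module_coexpression_rho Target within-module correlation in
#'   (0, 1].
#' @param noise_sd Nonnegative expression noise SD (log2 scale).
#' @param tissue_specific_modules If TRUE each module is co-expressed only
#'   in its home tissue (round-robin over `tissues`); otherwise in all.
#' @param module_sequence_similarity If TRUE (default) module members
#'   derive their sequences from a shared ancestor, so sequence
#'   descriptors also separate the classes; set FALSE to confine the
#'   planted signal to co-expression (used when studying tissue
#'   ablation, where a tissue-independent sequence signal would mask the
#'   tissue-specific one).
#' @param tissue_groups Optional named list grouping tissues that should
#'   share similar expression profiles (e.g. a brain-like trio).
#' @param seed Integer seed; all three generators derive their streams
#'   from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, max_isoforms_per_gene = 3,
                       single_isoform_fraction = 0.7,
                       tissues = c("heart", "liver", "kidney", "lung"),
                       samples_per_tissue = 3, n_terms = 30, dag_depth = 3,
                       not_annotation_count = 10, planted_module_count = 6,
                       module_size = 10, module_coexpression_rho = 0.9,
                       noise_sd = 0.5, tissue_specific_modules = FALSE,
                       module_sequence_similarity = TRUE,
                       tissue_groups = NULL, seed = 1) {
  config <- list(n_genes = n_genes,
                 max_isoforms_per_gene = max_isoforms_per_gene,
                 single_isoform_fraction = single_isoform_fraction,
                 tissues = as.character(tissues),
                 samples_per_tissue = samples_per_tissue,
                 n_terms = n_terms, dag_depth = dag_depth,
                 not_annotation_count = not_annotation_count,
                 planted_module_count = planted_module_count,
                 module_size = module_size,
                 module_coexpression_rho = module_coexpression_rho,
                 noise_sd = noise_sd,
                 tissue_specific_modules = tissue_specific_modules,
                 module_sequence_similarity = module_sequence_similarity,
                 tissue_groups = tissue_groups, seed = seed)
  fail <- function(field, why) {
    stop("invalid simulation config: field '", field, "' ", why)
  }
  if (n_genes < 1) fail("n_genes", "must be positive")
  if (max_isoforms_per_gene < 1) fail("max_isoforms_per_gene",
                                      "must be positive")
  if (single_isoform_fraction < 0 || single_isoform_fraction > 1) {
    fail("single_isoform_fraction", "must lie in [0, 1]")
  }
  if (round(single_isoform_fraction * n_genes) < 4) {
    fail("single_isoform_fraction",
         "must give at least 4 single-isoform genes")
  }
  if (length(tissues) < 1 || anyDuplicated(tissues)) {
    fail("tissues", "must be a nonempty set of distinct names")
  }
  if (samples_per_tissue < 2) fail("samples_per_tissue", "must be >= 2")
  if (dag_depth < 1) fail("dag_depth", "must be >= 1")
  if (n_terms < dag_depth) fail("n_terms", "must be >= dag_depth")
  if (n_terms < planted_module_count * dag_depth) {
    fail("n_terms", "must cover one term chain per planted module")
  }
  if (not_annotation_count < 0) fail("not_annotation_count",
                                     "must be nonnegative")
  if (planted_module_count < 0) fail("planted_module_count",
                                     "must be nonnegative")
  if (module_size < 2) fail("module_size", "must be >= 2")
  if (planted_module_count * module_size >
      round(single_isoform_fraction * n_genes)) {
    fail("module_size",
         "modules must fit inside the single-isoform genes")
  }
  if (module_coexpression_rho <= 0 || module_coexpression_rho > 1) {
    fail("module_coexpression_rho", "must lie in (0, 1]")
  }
  if (noise_sd < 0) fail("noise_sd", "must be nonnegative")
  if (!is.numeric(seed) || abs(seed) >= 2^31 - 10) {
    fail("seed", "must be a 32-bit integer")
  }
  if (!is.null(tissue_groups)) {
    unknown <- setdiff(unlist(tissue_groups), tissues)
    if (length(unknown) > 0) {
      fail("tissue_groups", paste0("names unknown tissue(s): ",
                                   paste(unknown, collapse = ", ")))
    }
  }
  structure(config, class = "sim_config")
}

.gene_ids <- function(config) sprintf("G%04d", seq_len(config$n_genes))

.n_single <- function(config) {
  round(config$single_isoform_fraction * config$n_genes)
}

#' Planted module membership implied by a configuration
#'
#' Deterministic given the config: module m occupies single-isoform genes
#' `(m-1)*module_size + 1 .. m*module_size`, and its home tissue cycles
#' through the tissue list.
#'
#' @param config A [sim_config()].
#' @return data.frame `gene_id`, `module`, `home_tissue`.
#' @export
module_assignments <- function(config) {
  genes <- .gene_ids(config)
  m <- config$planted_module_count
  if (m == 0) {
    return(data.frame(gene_id = character(0), module = integer(0),
                      home_tissue = character(0), stringsAsFactors = FALSE))
  }
  idx <- seq_len(m * config$module_size)
  data.frame(
    gene_id = genes[idx],
    module = rep(seq_len(m), each = config$module_size),
    home_tissue = rep(config$tissues[(seq_len(m) - 1) %%
                                       length(config$tissues) + 1],
                      each = config$module_size),
    stringsAsFactors = FALSE)
}

.resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

.random_seq <- function(len, alphabet) {
  paste(.resample(alphabet, len), collapse = "")
}

.mutate_seq <- function(sequence, rate, alphabet) {
  chars <- .seq_chars(sequence)
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- .resample(alphabet, sum(hit))
  paste(chars, collapse = "")
}

#' Simulate a gene catalog with mRNA and protein sequences
#'
#' Single-isoform genes come first; planted-module genes derive their
#' sequences from a per-module ancestor (5% per-site mutation), and the
#' isoforms of one gene derive from a per-gene base sequence (2%
#' mutation), so module membership is visible to the sequence descriptors.
#' Protein sequences are generated independently of the mRNA (no
#' translation consistency): the pipeline treats them as separate feature
#' sources.
#'
#' @param config A [sim_config()].
#' @return A [gene_catalog()]; byte-identical across runs for a fixed
#'   seed.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  genes <- .gene_ids(config)
  n_single <- .n_single(config)
  n_iso <- rep(1L, config$n_genes)
  if (config$n_genes > n_single && config$max_isoforms_per_gene >= 2) {
    n_iso[(n_single + 1):config$n_genes] <-
      .resample(2:config$max_isoforms_per_gene, config$n_genes - n_single)
  }
  ma <- module_assignments(config)

  ancestors <- lapply(seq_len(max(0, config$planted_module_count)),
                      function(m) {
    list(mrna = .random_seq(sample(300:600, 1), DNA_ALPHABET),
         protein = .random_seq(sample(60:150, 1), AA_ALPHABET))
  })

  records <- list()
  mrna <- list()
  protein <- list()
  for (i in seq_len(config$n_genes)) {
    g <- genes[i]
    mod <- ma$module[match(g, ma$gene_id)]
    if (!is.na(mod) && config$module_sequence_similarity) {
      base_m <- .mutate_seq(ancestors[[mod]]$mrna, 0.05, DNA_ALPHABET)
      base_p <- .mutate_seq(ancestors[[mod]]$protein, 0.05, AA_ALPHABET)
    } else {
      base_m <- .random_seq(sample(300:600, 1), DNA_ALPHABET)
      base_p <- .random_seq(sample(60:150, 1), AA_ALPHABET)
    }
    for (j in seq_len(n_iso[i])) {
      id <- paste0(g, ".", j)
      records[[id]] <- data.frame(isoform_id = id, gene_id = g,
                                  stringsAsFactors = FALSE)
      if (n_iso[i] == 1) {
        mrna[[id]] <- base_m
        protein[[id]] <- base_p
      } else {
        mrna[[id]] <- .mutate_seq(base_m, 0.02, DNA_ALPHABET)
        protein[[id]] <- .mutate_seq(base_p, 0.02, AA_ALPHABET)
      }
    }
  }
  gene_catalog(do.call(rbind, records), mrna, protein)
}

#' Simulate tissue-structured expression with planted co-expression
#'
#' Log-scale model per isoform and sample: a gene baseline, a gene x
#' tissue effect (tissues in the same configured group share most of it),
#' and for planted-module members a shared per-module latent factor with
#' weight `sqrt(rho)` plus independent noise with SD
#' `noise_sd * sqrt(1 - rho)`; other isoforms get independent noise with
#' SD `noise_sd`. With `noise_sd = 0`, within-module within-tissue
#' correlations are exactly 1. FPKM values are `max(2^x - 1, 0)`.
#'
#' @param catalog The catalog from [simulate_catalog()] (same config).
#' @param config A [sim_config()].
#' @return An [expression_set()] (isoform x sample FPKM).
#' @export
simulate_expression <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(catalog$records) == 0) stop("catalog is empty")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)

  tissues <- config$tissues
  spt <- config$samples_per_tissue
  samples <- paste0(rep(tissues, each = spt), "_s", seq_len(spt))
  tissue_of_sample <- rep(tissues, each = spt)
  genes <- .gene_ids(config)
  ma <- module_assignments(config)
  rho <- config$module_coexpression_rho

  group_of <- stats::setNames(tissues, tissues)
  if (!is.null(config$tissue_groups)) {
    for (gname in names(config$tissue_groups)) {
      group_of[config$tissue_groups[[gname]]] <- gname
    }
  }
  groups <- unique(unname(group_of))

  baseline <- stats::setNames(stats::rnorm(length(genes), mean = 4, sd = 1),
                              genes)
  group_comp <- matrix(stats::rnorm(length(genes) * length(groups)),
                       length(genes), length(groups),
                       dimnames = list(genes, groups))
  idio <- matrix(stats::rnorm(length(genes) * length(tissues), sd = 0.2),
                 length(genes), length(tissues),
                 dimnames = list(genes, tissues))
  tissue_effect <- group_comp[, group_of[tissues], drop = FALSE] + idio
  colnames(tissue_effect) <- tissues

  n_mod <- config$planted_module_count
  latent <- array(stats::rnorm(max(1, n_mod) * length(samples)),
                  dim = c(max(1, n_mod), length(samples)))

  ids <- catalog$records$isoform_id
  gene_of <- catalog$records$gene_id
  mod_of <- ma$module[match(gene_of, ma$gene_id)]
  home_of <- ma$home_tissue[match(gene_of, ma$gene_id)]

  x <- matrix(0, length(ids), length(samples),
              dimnames = list(ids, samples))
  eps <- matrix(stats::rnorm(length(ids) * length(samples)),
                length(ids), length(samples))
  for (s in seq_along(samples)) {
    t <- tissue_of_sample[s]
    base <- baseline[gene_of] + tissue_effect[gene_of, t]
    in_mod <- !is.na(mod_of)
    amp <- ifelse(in_mod & (!config$tissue_specific_modules |
                              home_of == t), 1, 0)
    amp[is.na(amp)] <- 0
    shared <- ifelse(in_mod, latent[pmax(mod_of, 1), s], 0) * sqrt(rho) * amp
    noise <- config$noise_sd * ifelse(in_mod, sqrt(1 - rho), 1) * eps[, s]
    x[, s] <- base + shared + noise
  }
  fpkm <- pmax(2^x - 1, 0)
  expression_set(fpkm, data.frame(sample_id = samples,
                                  tissue = tissue_of_sample,
                                  stringsAsFactors = FALSE))
}

#' Simulate ontology, annotations, pathways and PPIs
#'
#' Builds an acyclic, rooted ontology forest (one depth-`dag_depth` chain
#' per planted module plus randomly attached background terms, some with
#' two parents), annotates each module's genes -- and two multi-isoform
#' "extra" genes -- to the module's deepest term with experimental
#' evidence codes, scatters background annotations including excluded
#' evidence codes (IEA/NAS/ND) to exercise filtering, plants exactly
#' `not_annotation_count` NOT records on internal terms of the module
#' chains, and emits pathway memberships (mirroring the first two
#' modules) and within-module PPI records together with records each PPI
#' quality filter must reject.
#'
#' @param catalog The catalog from [simulate_catalog()] (same config).
#' @param config A [sim_config()].
#' @return List: `ontology` ([ontology_dag()]), `annotations`,
#'   `pathways`, `ppi`, `module_terms` (named chr, module -> deepest
#'   term).
#' @export
simulate_annotations <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)

  n_mod <- config$planted_module_count
  depth <- config$dag_depth
  terms <- sprintf("T%03d", seq_len(config$n_terms))
  parents <- list()
  level <- stats::setNames(integer(config$n_terms), terms)

  module_terms <- character(0)
  for (m in seq_len(n_mod)) {
    chain <- terms[((m - 1) * depth + 1):(m * depth)]
    for (d in seq_along(chain)) {
      parents[[chain[d]]] <- if (d == 1) character(0) else chain[d - 1]
      level[chain[d]] <- d
    }
    module_terms[as.character(m)] <- chain[depth]
  }
  bg <- terms[setdiff(seq_len(config$n_terms),
                      seq_len(n_mod * depth))]
  for (i in seq_along(bg)) {
    t <- bg[i]
    candidates <- bg[seq_len(i - 1)][level[bg[seq_len(i - 1)]] < depth]
    if (i == 1 || length(candidates) == 0) {
      parents[[t]] <- character(0)
      level[t] <- 1L
    } else {
      p <- .resample(candidates, 1)
      parents[[t]] <- p
      level[t] <- level[p] + 1L
      # occasional second parent keeps multi-parent terms exercised
      extra <- setdiff(candidates[level[candidates] < level[t]], p)
      if (length(extra) > 0 && stats::runif(1) < 0.3) {
        parents[[t]] <- c(p, .resample(extra, 1))
      }
    }
  }
  dag <- ontology_dag(terms, parents)

  genes <- .gene_ids(config)
  n_single <- .n_single(config)
  multi <- setdiff(genes, genes[seq_len(n_single)])
  ma <- module_assignments(config)
  good_ev <- c("EXP", "IDA", "IMP", "IGI")

  ann <- list()
  add <- function(gene, term, qualifier, evidence) {
    ann[[length(ann) + 1]] <<- data.frame(gene_id = gene, term_id = term,
                                          qualifier = qualifier,
                                          evidence_code = evidence,
                                          stringsAsFactors = FALSE)
  }
  extras_of <- list()
  for (m in seq_len(n_mod)) {
    members <- ma$gene_id[ma$module == m]
    term <- module_terms[[as.character(m)]]
    add(members, term, "positive", .resample(good_ev, length(members)))
    if (length(multi) >= 2) {
      extras <- multi[((m - 1) * 2) %% length(multi) + c(1, 2)]
      extras_of[[as.character(m)]] <- extras
      add(extras, term, "positive", .resample(good_ev, length(extras)))
    }
    # annotations that the evidence filter must remove
    spurious <- setdiff(genes, c(members, unlist(extras_of)))
    add(.resample(spurious, 2), term, "positive",
        .resample(c("IEA", "NAS", "ND"), 2))
  }
  if (length(bg) > 0) {
    for (t in bg) {
      add(.resample(genes, 3), t, "positive",
          .resample(c(good_ev, "IEA", "NAS", "ND"), 3))
    }
  }

  # NOT records on internal terms of the module chains (or the deepest
  # term when the chain has depth 1), planted round-robin over modules
  not_pool <- if (length(multi) > 0) multi else genes
  not_pool <- setdiff(not_pool, unlist(extras_of))
  if (length(not_pool) == 0) not_pool <- genes
  k <- 0L
  while (k < config$not_annotation_count && n_mod > 0) {
    m <- (k %% n_mod) + 1L
    chain_start <- (m - 1) * depth + 1
    term <- if (depth >= 2 && (k %% 2L == 0L)) {
      terms[chain_start + depth - 2]  # internal: parent of the deepest
    } else {
      module_terms[[as.character(m)]]
    }
    gene <- not_pool[(k %/% n_mod) %% length(not_pool) + 1L]
    add(gene, term, "NOT", "IDA")
    k <- k + 1L
  }
  if (n_mod == 0 && config$not_annotation_count > 0) {
    for (k in seq_len(config$not_annotation_count)) {
      add(not_pool[(k - 1) %% length(not_pool) + 1],
          terms[(k - 1) %% length(terms) + 1], "NOT", "IDA")
    }
  }
  annotations <- do.call(rbind, ann)
  annotations <-
    annotations[!duplicated(annotations[, c("gene_id", "term_id",
                                            "qualifier")]), , drop = FALSE]
  rownames(annotations) <- NULL

  pathways <- NULL
  if (n_mod >= 1) {
    pw <- lapply(seq_len(min(2, n_mod)), function(m) {
      members <- ma$gene_id[ma$module == m]
      data.frame(pathway_id = sprintf("P%02d", m),
                 gene_id = c(members, extras_of[[as.character(m)]][1]),
                 stringsAsFactors = FALSE)
    })
    pathways <- do.call(rbind, pw)
  } else {
    pathways <- data.frame(pathway_id = character(0),
                           gene_id = character(0), stringsAsFactors = FALSE)
  }

  ppi_rows <- list()
  add_ppi <- function(a, b, source, evidence_count = 3, score = 0.6,
                      orthology_flag = FALSE, taxon_a = "10090",
                      taxon_b = "10090") {
    ppi_rows[[length(ppi_rows) + 1]] <<- data.frame(
      gene_a = a, gene_b = b, source = source,
      evidence_count = evidence_count, score = score,
      orthology_flag = orthology_flag, taxon_a = taxon_a,
      taxon_b = taxon_b, stringsAsFactors = FALSE)
  }
  sources <- c("IntAct", "BioGRID", "APID", "IID", "Mentha")
  for (m in seq_len(n_mod)) {
    members <- ma$gene_id[ma$module == m]
    for (j in seq_len(min(3, length(members) - 1))) {
      add_ppi(members[j], members[j + 1], sources[(m + j) %% 5 + 1])
    }
  }
  if (n_mod >= 1) {
    members <- ma$gene_id[ma$module == 1]
    # records every quality filter must reject
    add_ppi(members[1], members[4], "APID", evidence_count = 1)
    add_ppi(members[1], members[5], "Mentha", score = 0.1)
    add_ppi(members[1], members[6], "IID", orthology_flag = TRUE)
    add_ppi(members[1], members[7], "IntAct", taxon_b = "9606")
  }
  ppi <- if (length(ppi_rows) > 0) do.call(rbind, ppi_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               source = character(0), evidence_count = numeric(0),
               score = numeric(0), orthology_flag = logical(0),
               taxon_a = character(0), taxon_b = character(0),
               stringsAsFactors = FALSE)

  list(ontology = dag, annotations = annotations, pathways = pathways,
       ppi = ppi, module_terms = module_terms)
}

#' Simulate a complete study
#'
#' Runs [simulate_catalog()], [simulate_expression()] and
#' [simulate_annotations()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: `config`, `catalog`, `expression`,
#'   `ontology`, `annotations`, `pathways`, `ppi`, `module_terms`,
#'   `modules` (membership frame).
#' @export
simulate_study <- function(config = sim_config()) {
  catalog <- simulate_catalog(config)
  expr <- simulate_expression(catalog, config)
  ann <- simulate_annotations(catalog, config)
  structure(list(config = config, catalog = catalog, expression = expr,
                 ontology = ann$ontology, annotations = ann$annotations,
                 pathways = ann$pathways, ppi = ann$ppi,
                 module_terms = ann$module_terms,
                 modules = module_assignments(config)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> ", nrow(x$catalog$records), " isoforms, ",
      length(x$config$tissues), " tissues, ",
      x$config$planted_module_count, " planted modules\n", sep = "")
  invisible(x)
}

#' Labeled pair features for a simulated study
#'
#' Convenience pipeline: builds the gold standard, computes the sequence
#' feature groups and assembles the pair feature rows for every labeled
#' pair.
#'
#' @param study A [simulate_study()] result.
#' @param min_term_size,max_term_size Term-size filter bounds.
#' @param paac_lambda Pseudo-amino-acid composition lambda.
#' @return List: `dataset` (ids, `label`, `z_*` columns), `gold`,
#'   `groups`.
#' @export
pair_dataset <- function(study, min_term_size = 10, max_term_size = 1000,
                         paac_lambda = 25) {
  gold <- build_gold_standard(study$catalog, study$ontology,
                              study$annotations, study$pathways, study$ppi,
                              min_term_size = min_term_size,
                              max_term_size = max_term_size)
  groups <- catalog_feature_groups(study$catalog,
                                   paac_lambda = paac_lambda)
  pairs <- rbind(
    cbind(gold$positive[, c("isoform_a", "isoform_b")], label = 1),
    cbind(gold$negative[, c("isoform_a", "isoform_b")], label = 0))
  feats <- pair_feature_matrix(pairs[, c("isoform_a", "isoform_b")],
                               groups, study$expression)
  dataset <- cbind(pairs[, c("isoform_a", "isoform_b")],
                   label = pairs$label,
                   feats[, grep("^z_", names(feats)), drop = FALSE])
  rownames(dataset) <- NULL
  list(dataset = dataset, gold = gold, groups = groups)
}

#' Write a simulated study to disk in the pipeline's file formats
#'
#' Emits FASTA sequences, OBO ontology, GAF annotations and the TSV
#' tables into a directory, so generated fixtures double as format
#' round-trip tests.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mrna = file.path(dir, "mrna.fasta"),
    protein = file.path(dir, "protein.fasta"),
    mapping = file.path(dir, "isoform_gene_map.tsv"),
    expression = file.path(dir, "expression.tsv"),
    tissue_map = file.path(dir, "tissue_map.tsv"),
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.gaf.tsv"),
    pathways = file.path(dir, "pathways.tsv"),
    ppi = file.path(dir, "ppi.tsv"))
  write_fasta(unlist(study$catalog$mrna), paths$mrna)
  write_fasta(unlist(study$catalog$protein), paths$protein)
  utils::write.table(study$catalog$records, paths$mapping, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression(study$expression, paths$expression, paths$tissue_map)
  write_obo(study$ontology, paths$ontology)
  write_annotations(study$annotations, paths$annotations)
  write_pathways(study$pathways, paths$pathways)
  write_ppi(study$ppi, paths$ppi)
  invisible(paths)
}
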