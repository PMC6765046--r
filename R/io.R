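# Readers and writers for every on-disk format the pipeline touches:
# FASTA sequences, an OBO-dialect ontology, GAF-dialect annotations, and the
# TSV tables (expression, tissue map, pathway membership, PPI, edge lists).
# Readers validate strictly; each writer/reader pair is inverse on valid
# data, so synthetic fixtures double as round-trip tests.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; for `seq_type = "dna"`, `U` is
#' normalized to `T` so downstream k-mer counting works over A/T/C/G.
#'
#' @param path FASTA file.
#' @param seq_type `"raw"` (no normalization beyond uppercasing), `"dna"` or
#'   `"protein"` (alphabet validated).
#' @return Named character vector, id -> sequence.
#' @export
read_fasta <- function(path, seq_type = c("raw", "dna", "protein")) {
  seq_type <- match.arg(seq_type)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (seq_type == "dna") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    bad <- vapply(seqs, function(s)
      length(setdiff(unique(.seq_chars(s)), DNA_ALPHABET)) > 0, logical(1))
    if (any(bad)) {
      stop("non-standard nucleotide characters in: ",
           paste(ids[bad], collapse = ", "))
    }
  } else if (seq_type == "protein") {
    bad <- vapply(seqs, function(s)
      length(setdiff(unique(.seq_chars(s)), AA_ALPHABET)) > 0, logical(1))
    if (any(bad)) {
      stop("non-standard amino-acid characters in: ",
           paste(ids[bad], collapse = ", "))
    }
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an OBO-dialect ontology file
#'
#' Parses `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: <type> <id>` lines and builds a rooted directed acyclic
#' graph over term ids (edges child -> parent). Only the configured relation
#' types become edges. Cycles are an input error.
#'
#' @param path OBO file.
#' @param relations Relation types kept as edges
#'   (default `c("is_a", "part_of")`).
#' @return An `ontology_dag` (see [ontology_dag()]).
#' @export
read_ontology <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path)
  terms <- character(0)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && nzchar(cur$id)) {
      terms <<- c(terms, cur$id)
      parents[[cur$id]] <<- unique(cur$parents)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(id = "", parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    if ("is_a" %in% relations && grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    }
    if (grepl("^relationship:", ln)) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", ln)))
      parts <- strsplit(body, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% relations) {
        cur$parents <- c(cur$parents, parts[2])
      }
    }
  }
  flush()
  ontology_dag(terms, parents)
}

#' Write an ontology DAG in the OBO dialect
#'
#' @param dag An [ontology_dag()].
#' @param path Output file.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in dag$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t)), con)
    for (p in dag$parents[[t]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read GAF-dialect annotations
#'
#' Accepts either the minimal dialect (a header line naming at least
#' `gene_id`, `qualifier`, `term_id`, `evidence_code`; extra columns are
#' ignored) or full 17-column header-less GAF (columns 2, 4, 5 and 7).
#' Comment lines starting with `!` are skipped. A qualifier field containing
#' `NOT` (for example `NOT|involved_in`) yields qualifier `"NOT"`; anything
#' else yields `"positive"`.
#'
#' @param path Annotation file.
#' @return data.frame with columns `gene_id`, `term_id`, `qualifier`,
#'   `evidence_code`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(0), term_id = character(0),
                      qualifier = character(0), evidence_code = character(0),
                      stringsAsFactors = FALSE))
  }
  gaf_layout <- !grepl("(^|\t)gene_id(\t|$)", lines[1])
  if (gaf_layout) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 7)) {
      stop("header-less annotation rows must have at least 7 GAF columns")
    }
    m <- do.call(rbind, lapply(fields, function(f) f[c(2, 4, 5, 7)]))
    df <- data.frame(gene_id = m[, 1], qualifier_raw = m[, 2],
                     term_id = m[, 3], evidence_code = m[, 4],
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                            check.names = FALSE)
    need <- c("gene_id", "qualifier", "term_id", "evidence_code")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0) {
      stop("annotation file missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    names(df)[names(df) == "qualifier"] <- "qualifier_raw"
  }
  df$qualifier <- ifelse(grepl("(^|\\|)NOT($|\\|)", df$qualifier_raw),
                         "NOT", "positive")
  df[, c("gene_id", "term_id", "qualifier", "evidence_code")]
}

#' Write annotations in the minimal GAF dialect
#'
#' @param annotations data.frame with `gene_id`, `term_id`, `qualifier`,
#'   `evidence_code`.
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  out <- data.frame(gene_id = annotations$gene_id,
                    qualifier = ifelse(annotations$qualifier == "NOT",
                                       "NOT|involved_in", "involved_in"),
                    term_id = annotations$term_id,
                    evidence_code = annotations$evidence_code)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path, required, what) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " file missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Read an expression table with its sample-to-tissue map
#'
#' @param path TSV with an `isoform_id` column and one column per sample.
#' @param tissue_map_path TSV with columns `sample_id`, `tissue`.
#' @return An [expression_set()].
#' @export
read_expression <- function(path, tissue_map_path) {
  df <- .read_tsv(path, "isoform_id", "expression")
  tissue_map <- .read_tsv(tissue_map_path, c("sample_id", "tissue"),
                          "tissue map")
  values <- as.matrix(df[, setdiff(names(df), "isoform_id"), drop = FALSE])
  rownames(values) <- df$isoform_id
  expression_set(values, tissue_map)
}

#' Write an expression set as a TSV pair
#'
#' @param expr An [expression_set()].
#' @param path Expression TSV path.
#' @param tissue_map_path Tissue map TSV path.
#' @export
write_expression <- function(expr, path, tissue_map_path) {
  df <- data.frame(isoform_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$tissue_map, tissue_map_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pathway membership table
#'
#' @param path TSV with columns `pathway_id`, `gene_id`.
#' @return data.frame.
#' @export
read_pathways <- function(path) {
  .read_tsv(path, c("pathway_id", "gene_id"), "pathway")
}

#' Write a pathway membership table
#' @param pathways data.frame with `pathway_id`, `gene_id`.
#' @param path Output file.
#' @export
write_pathways <- function(pathways, path) {
  utils::write.table(pathways, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

PPI_COLUMNS <- c("gene_a", "gene_b", "source", "evidence_count", "score",
                 "orthology_flag", "taxon_a", "taxon_b")

#' Read a protein-protein interaction table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `source`,
#'   `evidence_count`, `score`, `orthology_flag`, `taxon_a`, `taxon_b`.
#' @return data.frame.
#' @export
read_ppi <- function(path) {
  df <- .read_tsv(path, PPI_COLUMNS, "PPI")
  df$orthology_flag <- as.logical(df$orthology_flag)
  for (col in c("gene_a", "gene_b", "source", "taxon_a", "taxon_b")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$evidence_count <- as.numeric(df$evidence_count)
  df$score <- as.numeric(df$score)
  df
}

#' Write a protein-protein interaction table
#' @param ppi data.frame with the PPI columns.
#' @param path Output file.
#' @export
write_ppi <- function(ppi, path) {
  utils::write.table(ppi[, PPI_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

EDGE_COLUMNS <- c("isoform_a", "isoform_b", "prob_full", "prob_ablated",
                  "tissue", "loto_class")

#' Write a tissue edge list
#'
#' Probabilities are written with 6 decimals, so a write/read round trip
#' preserves them to that precision.
#'
#' @param edges data.frame with columns `isoform_a`, `isoform_b`,
#'   `prob_full`, `prob_ablated`, `tissue`, `loto_class`.
#' @param path Output file.
#' @export
write_edge_list <- function(edges, path) {
  out <- edges[, EDGE_COLUMNS]
  out$prob_full <- sprintf("%.6f", out$prob_full)
  out$prob_ablated <- sprintf("%.6f", out$prob_ablated)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tissue edge list written by [write_edge_list()]
#'
#' @param path Edge list TSV.
#' @return data.frame with the edge-list columns.
#' @export
read_edge_list <- function(path) {
  df <- .read_tsv(path, EDGE_COLUMNS, "edge list")
  df$prob_full <- as.numeric(df$prob_full)
  df$prob_ablated <- as.numeric(df$prob_ablated)
  df
}
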