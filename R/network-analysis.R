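# Gene-level network construction and graph analyses: collapsing isoform
# edges to gene edges, summary statistics, central nodes, shared-pair
# fractions, per-gene tissue ranking and hypergeometric enrichment.

.edges_to_graph <- function(edges, from = "isoform_a", to = "isoform_b") {
  igraph::graph_from_data_frame(
    data.frame(from = edges[[from]], to = edges[[to]],
               stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Collapse an isoform edge list to a gene network
#'
#' Isoform nodes of one gene merge into a single gene node; edges between
#' isoforms of the same gene become self-loops and are dropped; parallel
#' edges are de-duplicated keeping the minimum contributing weight and a
#' multiplicity count.
#'
#' @param edges data.frame with columns `isoform_a`, `isoform_b` and
#'   optionally `weight`.
#' @param catalog A [gene_catalog()] mapping every isoform to its gene.
#' @return data.frame `gene_a`, `gene_b`, `weight`, `multiplicity` in
#'   canonical gene order.
#' @export
collapse_to_genes <- function(edges, catalog) {
  gene_of <- stats::setNames(catalog$records$gene_id,
                             catalog$records$isoform_id)
  unmapped <- setdiff(unique(c(edges$isoform_a, edges$isoform_b)),
                      names(gene_of))
  if (length(unmapped) > 0) {
    stop("isoform(s) without a gene mapping: ",
         paste(unmapped, collapse = ", "))
  }
  ga <- unname(gene_of[edges$isoform_a])
  gb <- unname(gene_of[edges$isoform_b])
  w <- if ("weight" %in% names(edges)) edges$weight else
    rep(NA_real_, nrow(edges))
  keep <- ga != gb
  ga <- ga[keep]; gb <- gb[keep]; w <- w[keep]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  key <- paste(ga, gb, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(gene_a = ga[first], gene_b = gb[first],
                    stringsAsFactors = FALSE)
  out$weight <- as.numeric(tapply(w, key, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))[key[first]])
  out$multiplicity <- as.integer(table(key)[key[first]])
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Density of a simple undirected graph
#'
#' `2 E / (N (N - 1))` for `N >= 2` nodes and `E` edges; 0 for smaller
#' graphs.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return Density in [0, 1].
#' @export
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Summary statistics of an edge list
#'
#' Number of nodes, edges, density, connected components and the size of
#' the largest connected component. Nodes are those touched by at least
#' one edge.
#'
#' @param edges data.frame with two id columns (isoform- or gene-level).
#' @param from,to Names of the id columns (defaults `isoform_a`,
#'   `isoform_b`; gene frames are auto-detected).
#' @return List of class `graph_summary`.
#' @export
summarize_graph <- function(edges, from = NULL, to = NULL) {
  if (is.null(from)) {
    from <- if ("gene_a" %in% names(edges)) "gene_a" else "isoform_a"
    to <- if ("gene_b" %in% names(edges)) "gene_b" else "isoform_b"
  }
  g <- igraph::simplify(.edges_to_graph(edges, from, to))
  comp <- igraph::components(g)
  structure(list(n_nodes = igraph::vcount(g),
                 n_edges = igraph::ecount(g),
                 density = graph_density(igraph::vcount(g),
                                         igraph::ecount(g)),
                 n_components = comp$no,
                 largest_component_size =
                   if (comp$no == 0) 0L else max(comp$csize)),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf(paste0("<graph_summary> %d nodes, %d edges, density %.3g, ",
                     "%d components (largest %d)\n"),
              x$n_nodes, x$n_edges, x$density, x$n_components,
              x$largest_component_size))
  invisible(x)
}

#' Central nodes of a network
#'
#' Computed on the largest connected component only: the intersection of
#' the top-fraction node sets by betweenness centrality and by degree
#' centrality (both unweighted). The top set size is
#' `floor(fraction * component size)` with a minimum of 1; ties are broken
#' by node id for determinism.
#'
#' @param edges Edge frame (see [summarize_graph()]).
#' @param fraction Top fraction per measure (default 0.10).
#' @param from,to Id column names (auto-detected by default).
#' @return Character vector of central node ids.
#' @export
central_nodes <- function(edges, fraction = 0.10, from = NULL, to = NULL) {
  if (is.null(from)) {
    from <- if ("gene_a" %in% names(edges)) "gene_a" else "isoform_a"
    to <- if ("gene_b" %in% names(edges)) "gene_b" else "isoform_b"
  }
  g <- igraph::simplify(.edges_to_graph(edges, from, to))
  if (igraph::vcount(g) == 0) stop("empty graph")
  comp <- igraph::components(g)
  members <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  sub <- igraph::induced_subgraph(g, members)
  ids <- igraph::V(sub)$name
  k <- max(1L, floor(fraction * length(ids)))
  top <- function(score) {
    ids[order(-score, ids)][seq_len(k)]
  }
  between <- igraph::betweenness(sub, weights = NA)
  degree <- igraph::degree(sub)
  sort(intersect(top(between), top(degree)))
}

.edge_keys <- function(edges, from, to) {
  a <- edges[[from]]
  b <- edges[[to]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  unique(paste(a, b, sep = "\r"))
}

#' Fraction of pairs shared between tissue networks
#'
#' Entry (i, j) is the number of edges shared by tissues i and j divided
#' by tissue i's edge count: asymmetric by construction, with unit
#' diagonal.
#'
#' @param networks Named list of edge frames, one per tissue.
#' @param from,to Id column names (auto-detected from the first network).
#' @return Square matrix of fractions, tissues in list order.
#' @export
shared_pair_fractions <- function(networks, from = NULL, to = NULL) {
  stopifnot(length(networks) >= 2)
  if (is.null(from)) {
    nm <- names(networks[[1]])
    from <- if ("gene_a" %in% nm) "gene_a" else "isoform_a"
    to <- if ("gene_b" %in% nm) "gene_b" else "isoform_b"
  }
  keys <- lapply(networks, .edge_keys, from = from, to = to)
  n <- length(keys)
  out <- matrix(NA_real_, n, n, dimnames = list(names(networks),
                                                names(networks)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- if (length(keys[[i]]) == 0) 0 else
        length(intersect(keys[[i]], keys[[j]])) / length(keys[[i]])
    }
    if (length(keys[[i]]) > 0) out[i, i] <- 1
  }
  out
}

#' Rank tissues per gene by functional interaction count
#'
#' For every gene, tissues are ordered by the number of that gene's edges
#' in the tissue's functional gene network, descending, with ties broken
#' by tissue name. Genes absent from every network get an empty ranking.
#'
#' @param networks Named list of gene-level edge frames, one per tissue.
#' @return Named list, gene id -> ordered character vector of tissues with
#'   at least one interaction; `attr(,"counts")` holds the full gene x
#'   tissue count matrix.
#' @export
rank_tissues_per_gene <- function(networks) {
  genes <- sort(unique(unlist(lapply(networks, function(e)
    c(e$gene_a, e$gene_b)))))
  counts <- matrix(0L, length(genes), length(networks),
                   dimnames = list(genes, names(networks)))
  for (t in names(networks)) {
    tab <- table(c(networks[[t]]$gene_a, networks[[t]]$gene_b))
    counts[names(tab), t] <- as.integer(tab)
  }
  ranking <- lapply(stats::setNames(genes, genes), function(g) {
    cnt <- counts[g, ]
    cnt <- cnt[cnt > 0]
    names(cnt)[order(-cnt, names(cnt))]
  })
  attr(ranking, "counts") <- counts
  ranking
}

#' Hypergeometric enrichment of a gene set against term gene sets
#'
#' One-sided hypergeometric test per term of size within
#' `[min_term_size, max_term_size]`, Benjamini-Hochberg adjustment, and a
#' significance flag at the adjusted-p cutoff.
#'
#' @param genes Character vector of hit genes (for example central genes);
#'   must be a subset of `universe`.
#' @param term_sets Named list of term gene sets.
#' @param universe Character vector of all genes in the background.
#' @param min_term_size,max_term_size Term-size bounds (defaults 10, 1000).
#' @param p_cutoff Adjusted-p significance cutoff (default 0.05).
#' @return data.frame: `term`, `term_size`, `overlap`, `p`, `p_adjusted`,
#'   `significant`, ordered by p.
#' @export
enrichment <- function(genes, term_sets, universe, min_term_size = 10,
                       max_term_size = 1000, p_cutoff = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  extra <- setdiff(genes, universe)
  if (length(extra) > 0) {
    stop("hit gene(s) outside the universe: ", paste(extra, collapse = ", "))
  }
  term_sets <- lapply(term_sets, function(s) intersect(unique(s), universe))
  term_sets <- filter_terms(term_sets, min_term_size, max_term_size)
  if (length(term_sets) == 0) {
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0)))
  }
  n_univ <- length(unique(universe))
  n_hit <- length(unique(genes))
  rows <- lapply(names(term_sets), function(term) {
    m <- length(term_sets[[term]])
    q <- length(intersect(genes, term_sets[[term]]))
    p <- stats::phyper(q - 1, m, n_univ - m, n_hit, lower.tail = FALSE)
    data.frame(term = term, term_size = m, overlap = q, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjusted <= p_cutoff
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
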