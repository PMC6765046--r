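# Gene-level collapse, graph summaries, centrality, sharing, ranking and
# enrichment.

test_that("collapse to genes merges isoforms, drops self-loops, keeps min weight", {
  catalog <- gene_catalog(
    data.frame(isoform_id = c("M11", "M12", "M21"),
               gene_id = c("G1", "G1", "G2")),
    stats::setNames(rep("ACGT", 3), c("M11", "M12", "M21")),
    stats::setNames(rep(strrep("A", 30), 3), c("M11", "M12", "M21")))
  edges <- data.frame(isoform_a = c("M11", "M12", "M11"),
                      isoform_b = c("M21", "M21", "M12"),
                      weight = c(0.3, 0.2, 0.9), stringsAsFactors = FALSE)
  gn <- collapse_to_genes(edges, catalog)
  expect_equal(nrow(gn), 1)  # the intra-gene M11-M12 edge is dropped
  expect_equal(gn$gene_a, "G1")
  expect_equal(gn$gene_b, "G2")
  expect_equal(gn$multiplicity, 2L)
  expect_equal(gn$weight, 0.2)
  expect_error(collapse_to_genes(
    data.frame(isoform_a = "X", isoform_b = "M11"), catalog), "X")
})

test_that("gene adjacency is conserved by the collapse", {
  fx <- fx_loto_networks()
  st <- fx_loto_study()
  edges <- do.call(rbind, lapply(fx$networks$tissue, function(t)
    t$functional[, c("isoform_a", "isoform_b", "weight")]))
  gn <- collapse_to_genes(edges, st$catalog)
  gene_of <- stats::setNames(st$catalog$records$gene_id,
                             st$catalog$records$isoform_id)
  want <- unique(paste(pmin(gene_of[edges$isoform_a],
                            gene_of[edges$isoform_b]),
                       pmax(gene_of[edges$isoform_a],
                            gene_of[edges$isoform_b])))
  want <- want[vapply(strsplit(want, " "),
                      function(p) p[1] != p[2], logical(1))]
  expect_setequal(paste(gn$gene_a, gn$gene_b), want)
})

test_that("graph summaries match hand-checked structures", {
  triangle <- data.frame(isoform_a = c("a", "b", "c"),
                         isoform_b = c("b", "c", "a"))
  s <- summarize_graph(triangle)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$density, 1)
  expect_equal(s$n_components, 1)
  expect_equal(s$largest_component_size, 3)

  two <- data.frame(isoform_a = c("a", "c"), isoform_b = c("b", "d"))
  s2 <- summarize_graph(two)
  expect_equal(s2$n_components, 2)
  expect_equal(s2$largest_component_size, 2)
})

test_that("summaries agree with a breadth-first oracle on random graphs", {
  oracle <- function(edges) {
    nodes <- unique(c(edges$isoform_a, edges$isoform_b))
    adj <- lapply(stats::setNames(nodes, nodes), function(n) character(0))
    seen_edge <- character(0)
    for (i in seq_len(nrow(edges))) {
      a <- edges$isoform_a[i]; b <- edges$isoform_b[i]
      if (a == b) next
      k <- paste(min(a, b), max(a, b))
      if (k %in% seen_edge) next
      seen_edge <- c(seen_edge, k)
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    unvisited <- nodes
    sizes <- integer(0)
    while (length(unvisited) > 0) {
      frontier <- unvisited[1]
      comp <- character(0)
      while (length(frontier) > 0) {
        comp <- union(comp, frontier)
        frontier <- setdiff(unique(unlist(adj[frontier])), comp)
      }
      sizes <- c(sizes, length(comp))
      unvisited <- setdiff(unvisited, comp)
    }
    list(n_nodes = length(nodes), n_edges = length(seen_edge),
         n_components = length(sizes), largest = max(sizes))
  }
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    m <- sample(10:300, 1)
    edges <- data.frame(
      isoform_a = paste0("n", sample(n, m, replace = TRUE)),
      isoform_b = paste0("n", sample(n, m, replace = TRUE)),
      stringsAsFactors = FALSE)
    edges <- edges[edges$isoform_a != edges$isoform_b, ]
    s <- summarize_graph(edges)
    o <- oracle(edges)
    expect_equal(s$n_nodes, o$n_nodes)
    expect_equal(s$n_edges, o$n_edges)
    expect_equal(s$n_components, o$n_components)
    expect_equal(s$largest_component_size, o$largest)
    expect_equal(s$density, graph_density(o$n_nodes, o$n_edges))
  }
})

test_that("central nodes come from both measures on the largest component", {
  # star: the hub is central by both betweenness and degree
  star <- data.frame(isoform_a = "hub", isoform_b = paste0("leaf", 1:9))
  expect_equal(central_nodes(star, fraction = 0.1), "hub")

  # path of 11 nodes with the middle named to sort first among interior
  path_nodes <- c(paste0("x", sprintf("%02d", 1:5)), "m",
                  paste0("x", sprintf("%02d", 6:10)))
  path <- data.frame(isoform_a = path_nodes[-11],
                     isoform_b = path_nodes[-1])
  # betweenness oracle for a path: (#left) * (#right), maximal in the middle
  lefts <- seq_along(path_nodes) - 1
  rights <- rev(lefts)
  expect_equal(path_nodes[which.max(lefts * rights)], "m")
  expect_equal(central_nodes(path, fraction = 0.1), "m")

  # result is always inside the largest component
  two_comp <- rbind(star,
                    data.frame(isoform_a = "z1", isoform_b = "z2"))
  expect_true(all(central_nodes(two_comp, 0.2) %in%
                    c("hub", paste0("leaf", 1:9))))
})

test_that("shared-pair fractions follow the row-weighted definition", {
  a <- data.frame(gene_a = paste0("g", 1:10), gene_b = paste0("h", 1:10))
  b <- rbind(a[1:2, ],
             data.frame(gene_a = paste0("p", 1:98),
                        gene_b = paste0("q", 1:98)))
  f <- shared_pair_fractions(list(A = a, B = b))
  expect_equal(f["A", "B"], 0.2)   # 2 of A's 10 edges
  expect_equal(f["B", "A"], 0.02)  # 2 of B's 100 edges
  expect_equal(unname(diag(f)), c(1, 1))
  ident <- shared_pair_fractions(list(A = a, B = a))
  expect_true(all(ident == 1))
  disj <- shared_pair_fractions(list(A = a, B = b[-(1:2), ]))
  expect_equal(disj["A", "B"], 0)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("tissue ranking per gene counts functional interactions", {
  nets <- list(
    heart = data.frame(gene_a = rep("g1", 5), gene_b = paste0("x", 1:5)),
    liver = data.frame(gene_a = rep("g1", 2), gene_b = paste0("x", 1:2)))
  r <- rank_tissues_per_gene(nets)
  expect_equal(r$g1, c("heart", "liver"))
  expect_equal(r$x3, "heart")
  # top-n lists are prefixes of top-(n+1) lists by construction
  expect_equal(r$g1[1], "heart")
  # absent gene gets an empty ranking
  expect_length(r[["nope"]], 0)
  # deterministic tie-break by tissue name
  nets$liver <- nets$heart
  nets$liver$gene_b <- paste0("y", 1:5)
  r2 <- rank_tissues_per_gene(nets)
  expect_equal(r2$g1, c("heart", "liver"))
})

test_that("enrichment matches the closed-form hypergeometric and BH", {
  universe <- paste0("g", 1:100)
  term_sets <- list(hit_term = paste0("g", 1:10),
                    mid_term = paste0("g", c(1:5, 51:60)),
                    null_term = paste0("g", 51:62),
                    tiny = paste0("g", 1:9))
  hits <- paste0("g", 1:10)
  out <- enrichment(hits, term_sets, universe)
  # a size-9 term is excluded by the minimum term size
  expect_false("tiny" %in% out$term)
  # all 10 hits inside a 10-gene term: point mass 1 / C(100, 10)
  expect_equal(out$p[out$term == "hit_term"], 1 / choose(100, 10),
               tolerance = 1e-12)
  # raw p from the closed form for the partial-overlap term
  m <- 15; q <- 5
  p_mid <- sum(choose(m, q:10) * choose(100 - m, 10 - (q:10))) /
    choose(100, 10)
  expect_equal(out$p[out$term == "mid_term"], p_mid, tolerance = 1e-12)
  # BH by hand: sorted p * m / rank, cumulative minimum from the back
  p_sorted <- sort(out$p)
  adj <- rev(cummin(rev(p_sorted * length(p_sorted) / seq_along(p_sorted))))
  expect_equal(sort(out$p_adjusted), pmin(adj, 1), tolerance = 1e-12)
  expect_true(out$significant[out$term == "hit_term"])
  expect_error(enrichment(hits, term_sets, character(0)), "universe")
  expect_error(enrichment("not_in_universe", term_sets, universe),
               "outside the universe")
})
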