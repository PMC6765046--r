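# Ontology DAG container: terms, child -> parent edges, and the
# ancestor/descendant closures used by annotation propagation.

#' Construct an ontology DAG
#'
#' Edges point from child terms to parent terms. Construction validates
#' acyclicity and computes the ancestor closure; a cycle is an input error
#' that names one of its members.
#'
#' @param terms Character vector of term ids.
#' @param parents Named list, term id -> character vector of parent term
#'   ids. Terms absent from the list are roots.
#' @return Object of class `ontology_dag` with elements `terms`, `parents`,
#'   `ancestors` (closure, excluding the term itself) and `children`.
#' @export
ontology_dag <- function(terms, parents = list()) {
  terms <- unique(as.character(terms))
  parents <- parents[intersect(names(parents), terms)]
  for (t in setdiff(terms, names(parents))) parents[[t]] <- character(0)
  unknown <- setdiff(unique(unlist(parents)), terms)
  if (length(unknown) > 0) {
    stop("parent term(s) not declared: ", paste(unknown, collapse = ", "))
  }

  ancestors <- vector("list", length(terms))
  names(ancestors) <- terms
  state <- stats::setNames(rep(0L, length(terms)), terms)  # 0 new, 1 visiting, 2 done
  visit <- function(t) {
    if (state[[t]] == 1L) stop("ontology contains a cycle through term ", t)
    if (state[[t]] == 2L) return(ancestors[[t]])
    state[[t]] <<- 1L
    anc <- character(0)
    for (p in parents[[t]]) anc <- union(anc, c(p, visit(p)))
    ancestors[[t]] <<- anc
    state[[t]] <<- 2L
    anc
  }
  for (t in terms) visit(t)

  children <- lapply(stats::setNames(terms, terms), function(t) character(0))
  for (t in terms) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  structure(list(terms = terms, parents = parents,
                 ancestors = ancestors, children = children),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat("<ontology_dag> ", length(x$terms), " terms, ", n_edges, " edges, ",
      sum(lengths(x$parents) == 0), " root(s)\n", sep = "")
  invisible(x)
}

#' Ancestors of a term (excluding itself)
#' @param dag An [ontology_dag()].
#' @param term Term id.
#' @return Character vector.
#' @export
dag_ancestors <- function(dag, term) {
  if (!(term %in% dag$terms)) stop("unknown term: ", term)
  dag$ancestors[[term]]
}

#' Descendants of a term (excluding itself)
#' @param dag An [ontology_dag()].
#' @param term Term id.
#' @return Character vector.
#' @export
dag_descendants <- function(dag, term) {
  if (!(term %in% dag$terms)) stop("unknown term: ", term)
  out <- character(0)
  frontier <- dag$children[[term]]
  while (length(frontier) > 0) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(dag$children[frontier])), out)
  }
  out
}
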