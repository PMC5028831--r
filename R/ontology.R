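#' Build the GO-tree subgraph of significant terms
#'
#' Nodes are the significant terms plus their full ancestor closure under
#' the child-to-parent hierarchy; edges are the hierarchy edges restricted
#' to that node set. Ancestors pulled in only by closure are flagged
#' non-significant. Multi-parent terms are allowed: the result is a DAG, as
#' the Gene Ontology is, despite the "tree" name.
#'
#' @param significant character vector of significant term ids.
#' @param hierarchy data.frame with `child`, `parent` (and optionally
#'   `namespace`) columns; must be acyclic.
#' @param term_info optional data.frame (`id`, plus e.g. `namespace`,
#'   `name`, `p_value`) merged onto the nodes.
#' @return object of class `term_graph`: `nodes` (id, significant, ...),
#'   `edges` (child, parent), `roots`.
#' @export
build_go_tree <- function(significant, hierarchy, term_info = NULL) {
  assert_acyclic(hierarchy)
  parents_of <- split(hierarchy$parent, hierarchy$child)
  nodes <- unique(significant)
  frontier <- nodes
  while (length(frontier)) {
    up <- unique(unlist(parents_of[frontier], use.names = FALSE))
    frontier <- setdiff(up, nodes)
    nodes <- c(nodes, frontier)
  }
  edges <- hierarchy[hierarchy$child %in% nodes &
                       hierarchy$parent %in% nodes,
                     c("child", "parent"), drop = FALSE]
  rownames(edges) <- NULL
  node_df <- data.frame(id = nodes, significant = nodes %in% significant)
  if (!is.null(term_info))
    node_df <- merge(node_df, term_info, by = "id", all.x = TRUE,
                     sort = FALSE)
  roots <- setdiff(nodes, edges$child)
  structure(list(nodes = node_df, edges = edges, roots = roots),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("term_graph: %d nodes (%d significant), %d edges, %d roots\n",
              nrow(x$nodes), sum(x$nodes$significant), nrow(x$edges),
              length(x$roots)))
  invisible(x)
}

#' Convert a term graph to a [network] (for GraphML/DOT export)
#' @param tree a `term_graph`.
#' @return a directed [network] with child -> parent edges.
#' @export
term_graph_as_network <- function(tree) {
  network(tree$nodes,
          data.frame(src = tree$edges$child, dst = tree$edges$parent,
                     type = rep("is_a", nrow(tree$edges))),
          directed = TRUE)
}

#' Select focus terms by name pattern and collect their DEGs
#'
#' Matches term names against the given patterns (fixed strings or regular
#' expressions, case-insensitive), then returns the union of the DEG
#' memberships of the matched terms, each gene once, with the indices of the
#' matched terms it belongs to.
#'
#' @param annotation an [annotation_set].
#' @param patterns character vector of name patterns (non-empty).
#' @param deg_set DEG ids; memberships are intersected with this set.
#' @param terms optional restriction to a term-id subset (e.g. the
#'   significant terms) before matching.
#' @return list with `terms` (data.frame: index, id, name) and `genes`
#'   (data.frame: gene, term_indices as comma-separated string).
#' @export
select_focus_terms <- function(annotation, patterns, deg_set,
                               terms = NULL) {
  if (!length(patterns)) stop("patterns must be non-empty")
  tinfo <- annotation$terms
  if (!is.null(terms)) tinfo <- tinfo[tinfo$id %in% terms, , drop = FALSE]
  hit_list <- lapply(patterns, function(p)
    tinfo$id[grepl(p, tinfo$name, ignore.case = TRUE)])
  matched <- unique(unlist(hit_list))
  if (!length(matched)) {
    warning("no term name matches any pattern")
    return(list(terms = data.frame(index = integer(), id = character(),
                                   name = character()),
                genes = data.frame(gene = character(),
                                   term_indices = character())))
  }
  sel <- data.frame(index = seq_along(matched), id = matched,
                    name = tinfo$name[match(matched, tinfo$id)])
  members <- lapply(matched, function(id)
    intersect(annotation$genesets[[id]], deg_set))
  genes <- sort(unique(unlist(members)))
  idx <- vapply(genes, function(g) {
    paste(sel$index[vapply(members, function(m) g %in% m, TRUE)],
          collapse = ",")
  }, "")
  list(terms = sel,
       genes = data.frame(gene = genes, term_indices = unname(idx),
                          row.names = NULL))
}
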