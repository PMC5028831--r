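#' Gene-level count matrix with lengths and a two-group design
#'
#' The root input of the pipeline: integer read counts per gene per sample,
#' per-gene transcript lengths (bp) and a sample-to-group assignment. For the
#' differential-expression stage exactly two distinct groups are required.
#'
#' @param counts integer matrix, genes x samples; rownames are gene ids,
#'   colnames sample ids.
#' @param lengths numeric vector of positive gene lengths (bp), one per gene.
#' @param groups named character vector mapping each sample id to its group
#'   label.
#' @return an object of class `count_matrix` with elements `counts`,
#'   `lengths`, `gene_ids`, `sample_ids`, `groups`.
#' @export
count_matrix <- function(counts, lengths, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(lengths) != nrow(counts))
    stop("one length per gene required")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive and finite")
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)))
    stop("every sample needs a group label; missing: ",
         paste(colnames(counts)[is.na(groups)], collapse = ", "))
  structure(list(
    counts = counts,
    lengths = stats::setNames(as.numeric(lengths), rownames(counts)),
    gene_ids = rownames(counts),
    sample_ids = colnames(counts),
    groups = groups
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tb <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Expression value matrix (RPKM or normalized counts)
#'
#' @param values numeric matrix, genes x samples, finite and non-negative.
#' @param kind one of `"RPKM"` or `"UQ-normalized-counts"`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, kind = c("RPKM", "UQ-normalized-counts")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(list(values = values, kind = kind), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Term -> gene annotation collection with namespaces and a hierarchy
#'
#' Substrate for enrichment testing and GO-tree construction. `terms` carries
#' one row per term; memberships are a named list of gene-id vectors. The
#' hierarchy is an edge list (child, parent) restricted to within-namespace
#' is-a style links; it must be acyclic.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace` (one of
#'   biological_process, molecular_function, cellular_component, pathway).
#' @param genesets named list (by term id) of character vectors of gene ids.
#' @param hierarchy data.frame with columns `child`, `parent`, `namespace`
#'   (may have zero rows).
#' @param universe character vector of all annotatable gene ids.
#' @return object of class `annotation_set`.
#' @export
annotation_set <- function(terms, genesets, hierarchy = NULL, universe) {
  ns_ok <- c("biological_process", "molecular_function",
             "cellular_component", "pathway")
  if (!all(terms$namespace %in% ns_ok))
    stop("unknown namespace: ",
         paste(setdiff(unique(terms$namespace), ns_ok), collapse = ", "))
  if (!setequal(names(genesets), terms$id))
    stop("genesets must be named by the term ids")
  extra <- setdiff(unique(unlist(genesets)), universe)
  if (length(extra))
    stop("term members outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  if (is.null(hierarchy))
    hierarchy <- data.frame(child = character(), parent = character(),
                            namespace = character())
  assert_acyclic(hierarchy)
  structure(list(terms = terms, genesets = genesets[terms$id],
                 hierarchy = hierarchy, universe = universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms over %d genes\n",
              nrow(x$terms), length(x$universe)))
  print(table(x$terms$namespace))
  invisible(x)
}

# Closed vocabulary of typed interaction edges (KEGG-style relations).
RELATION_TYPES <- c("activation", "binding/association", "compound",
                    "expression", "indirect effect", "inhibition",
                    "missing interaction", "phosphorylation",
                    "dephosphorylation", "ubiquitination")

#' Typed relation table (gene-gene or pathway-pathway interactions)
#'
#' @param df data.frame with columns `src`, `dst`, `type` and optionally
#'   `directed` (logical, default TRUE). Self-loops are rejected and types
#'   must come from the closed vocabulary in `relation_types()`.
#' @return object of class `relation_table` (a validated data.frame).
#' @export
relation_table <- function(df) {
  if (!all(c("src", "dst", "type") %in% names(df)))
    stop("relation table needs columns src, dst, type")
  if (is.null(df$directed)) df$directed <- TRUE
  bad <- setdiff(unique(df$type), RELATION_TYPES)
  if (length(bad))
    stop("relation types outside the closed vocabulary: ",
         paste(bad, collapse = ", "))
  if (any(df$src == df$dst)) stop("self-loops are not allowed")
  class(df) <- c("relation_table", "data.frame")
  df
}

#' The closed vocabulary of relation types
#' @return character vector of admissible `type` values.
#' @export
relation_types <- function() RELATION_TYPES

#' Node/edge network with typed or signed edges
#'
#' Unifies the pathway-act, gene-act and co-expression outputs: `nodes` is a
#' data.frame with an `id` column plus attributes (direction, p-value, degree,
#' k-core number); `edges` has `src`, `dst` plus attributes (type, or r/q and
#' sign for co-expression edges).
#'
#' @param nodes data.frame with at least an `id` column.
#' @param edges data.frame with at least `src` and `dst` columns (endpoints
#'   must appear in `nodes$id`).
#' @param directed logical flag.
#' @return object of class `network`.
#' @export
network <- function(nodes, edges, directed = FALSE) {
  if (!"id" %in% names(nodes)) stop("nodes need an id column")
  if (nrow(edges) &&
      !all(c(edges$src, edges$dst) %in% nodes$id))
    stop("edge endpoints must be listed in nodes")
  structure(list(nodes = nodes, edges = edges, directed = directed),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges (%s)\n", nrow(x$nodes),
              nrow(x$edges), if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' qPCR plate of Ct values
#'
#' @param records data.frame with columns `gene`, `sample`, `group`,
#'   `replicate`, `ct` (threshold cycles, finite, in (0, 45)).
#' @param reference_gene housekeeping gene id; must be measured in every
#'   sample present on the plate.
#' @param calibrator_group group label used as the calibrator in ddCt.
#' @return object of class `qpcr_plate`.
#' @export
qpcr_plate <- function(records, reference_gene, calibrator_group) {
  need <- c("gene", "sample", "group", "replicate", "ct")
  if (!all(need %in% names(records)))
    stop("plate records need columns ", paste(need, collapse = ", "))
  if (any(!is.finite(records$ct)) ||
      any(records$ct <= 0) || any(records$ct >= 45))
    stop("Ct values must be finite and within (0, 45)")
  samples <- unique(records$sample)
  ref_samples <- unique(records$sample[records$gene == reference_gene])
  missing <- setdiff(samples, ref_samples)
  if (length(missing))
    stop("reference gene ", reference_gene, " missing in sample(s): ",
         paste(missing, collapse = ", "))
  if (!calibrator_group %in% records$group)
    stop("calibrator group ", calibrator_group, " not on the plate")
  structure(list(records = records, reference_gene = reference_gene,
                 calibrator_group = calibrator_group),
            class = "qpcr_plate")
}

#' @export
print.qpcr_plate <- function(x, ...) {
  cat(sprintf("qpcr_plate: %d wells, %d genes, reference %s, calibrator %s\n",
              nrow(x$records), length(unique(x$records$gene)),
              x$reference_gene, x$calibrator_group))
  invisible(x)
}

# Internal: stop with a listed cycle if the child->parent edge list is cyclic.
assert_acyclic <- function(hierarchy) {
  if (!nrow(hierarchy)) return(invisible(TRUE))
  parents <- split(hierarchy$parent, hierarchy$child)
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(node, stack) {
    s <- get0(node, envir = state, ifnotfound = 0L)
    if (s == 2L) return(invisible(NULL))
    if (s == 1L) {
      cyc <- c(stack[which(stack == node)[1]:length(stack)], node)
      stop("cycle detected in hierarchy: ", paste(cyc, collapse = " -> "))
    }
    assign(node, 1L, envir = state)
    for (p in parents[[node]]) visit(p, c(stack, node))
    assign(node, 2L, envir = state)
  }
  for (ch in unique(hierarchy$child)) visit(ch, character())
  invisible(TRUE)
}
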