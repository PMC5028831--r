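#' Read a counts TSV (gene_id, length, then one column per sample)
#'
#' @param counts_path path to the counts TSV.
#' @param design_path path to the design TSV (columns `sample`, `group`).
#' @return a [count_matrix].
#' @export
read_counts_tsv <- function(counts_path, design_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(tab)))
    stop("counts TSV needs gene_id and length columns")
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  samples <- setdiff(names(tab), c("gene_id", "length"))
  mat <- as.matrix(tab[, samples, drop = FALSE])
  rownames(mat) <- tab$gene_id
  groups <- stats::setNames(design$group, design$sample)
  count_matrix(mat, tab$length, groups)
}

#' Write a count_matrix to counts + design TSVs
#' @param cm a [count_matrix].
#' @param counts_path,design_path output paths.
#' @return invisibly, the two paths.
#' @export
write_counts_tsv <- function(cm, counts_path, design_path) {
  tab <- data.frame(gene_id = cm$gene_ids, length = cm$lengths,
                    cm$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = cm$sample_ids, group = unname(cm$groups)),
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_path, design_path))
}

#' Read a GMT annotation file plus an OBO-lite hierarchy
#'
#' GMT lines are `term_id <TAB> name|namespace <TAB> gene...`; the hierarchy
#' TSV has columns `child`, `parent`, `namespace` and may be absent.
#'
#' @param gmt_path path to the GMT file.
#' @param hierarchy_path optional path to the OBO-lite TSV.
#' @param universe gene universe; defaults to the union of all memberships.
#' @return an [annotation_set].
#' @export
read_gmt <- function(gmt_path, hierarchy_path = NULL, universe = NULL) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  desc <- strsplit(vapply(parts, `[[`, "", 2L), "|", fixed = TRUE)
  genesets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(genesets) <- ids
  terms <- data.frame(
    id = ids,
    name = vapply(desc, `[[`, "", 1L),
    namespace = vapply(desc, function(d) d[[min(2L, length(d))]], ""))
  hierarchy <- NULL
  if (!is.null(hierarchy_path) && file.exists(hierarchy_path))
    hierarchy <- utils::read.delim(hierarchy_path, stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- unique(unlist(genesets))
  annotation_set(terms, genesets, hierarchy, universe)
}

#' Write an annotation_set as GMT + OBO-lite TSV
#' @param ann an [annotation_set].
#' @param gmt_path,hierarchy_path output paths.
#' @return invisibly, the paths written.
#' @export
write_gmt <- function(ann, gmt_path, hierarchy_path = NULL) {
  lines <- vapply(seq_len(nrow(ann$terms)), function(i) {
    id <- ann$terms$id[i]
    paste(c(id, paste0(ann$terms$name[i], "|", ann$terms$namespace[i]),
            ann$genesets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  if (!is.null(hierarchy_path))
    utils::write.table(ann$hierarchy, hierarchy_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(gmt_path, hierarchy_path))
}

#' Read/write a typed relation TSV (src, dst, type, directed)
#' @param path file path.
#' @return a [relation_table].
#' @export
read_relations <- function(path) {
  relation_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_relations
#' @param rel a [relation_table].
#' @export
write_relations <- function(rel, path) {
  utils::write.table(as.data.frame(rel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a qPCR plate TSV (gene, sample, group, replicate, ct)
#' @param path file path.
#' @param reference_gene,calibrator_group see [qpcr_plate].
#' @return a [qpcr_plate].
#' @export
read_qpcr_tsv <- function(path, reference_gene, calibrator_group) {
  qpcr_plate(utils::read.delim(path, stringsAsFactors = FALSE),
             reference_gene, calibrator_group)
}

#' @rdname read_qpcr_tsv
#' @param plate a [qpcr_plate].
#' @export
write_qpcr_tsv <- function(plate, path) {
  utils::write.table(plate$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network as SIF (Cytoscape simple interaction format)
#'
#' One line per edge: `src <TAB> type <TAB> dst`; isolated nodes are written
#' as single-column lines so they survive a round trip.
#'
#' @param net a [network].
#' @param path output path.
#' @param type_col edge attribute used as the SIF interaction type; falls
#'   back to `"--"` when absent.
#' @return invisibly, `path`.
#' @export
write_sif <- function(net, path, type_col = "type") {
  e <- net$edges
  lines <- character()
  if (nrow(e)) {
    ty <- if (type_col %in% names(e)) as.character(e[[type_col]]) else
      rep("--", nrow(e))
    lines <- paste(e$src, ty, e$dst, sep = "\t")
  }
  isolated <- setdiff(net$nodes$id, c(e$src, e$dst))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network as GraphML with all node and edge attributes
#' @param net a [network].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_network_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a network to an igraph object (attributes preserved)
#' @param net a [network].
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  vertices <- net$nodes
  edges <- net$edges
  if (!nrow(edges))
    edges <- data.frame(src = character(), dst = character())
  igraph::graph_from_data_frame(edges, directed = net$directed,
                                vertices = vertices)
}

#' Export a network (or term graph) in DOT format
#' @param net a [network].
#' @param path output path.
#' @param name graph name in the DOT header.
#' @return invisibly, `path`.
#' @export
write_dot <- function(net, path, name = "g") {
  arrow <- if (net$directed) "->" else "--"
  kw <- if (net$directed) "digraph" else "graph"
  quote_id <- function(x) paste0('"', gsub('"', "'", x), '"')
  node_lines <- vapply(seq_len(nrow(net$nodes)), function(i) {
    attrs <- net$nodes[i, setdiff(names(net$nodes), "id"), drop = FALSE]
    lab <- paste(sprintf('%s="%s"', names(attrs),
                         vapply(attrs, as.character, "")), collapse = ", ")
    sprintf("  %s [%s];", quote_id(net$nodes$id[i]), lab)
  }, "")
  edge_lines <- if (nrow(net$edges)) {
    vapply(seq_len(nrow(net$edges)), function(i) {
      sprintf("  %s %s %s;", quote_id(net$edges$src[i]), arrow,
              quote_id(net$edges$dst[i]))
    }, "")
  } else character()
  writeLines(c(sprintf("%s %s {", kw, name), node_lines, edge_lines, "}"),
             path)
  invisible(path)
}

#' Checksum manifest of output artifacts
#'
#' @param paths character vector of files (must exist).
#' @param manifest_path where to write the manifest JSON.
#' @return invisibly, the manifest as a data.frame (file, md5, bytes).
#' @export
write_manifest <- function(paths, manifest_path) {
  info <- file.info(paths)
  m <- data.frame(file = basename(paths),
                  md5 = unname(tools::md5sum(paths)),
                  bytes = info$size)
  m <- m[order(m$file), ]
  jsonlite::write_json(m, manifest_path, dataframe = "rows", digits = NA)
  invisible(m)
}
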