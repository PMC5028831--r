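#' Pathway-act network: induced interaction subgraph of significant pathways
#'
#' Nodes are the significant pathways; edges are the relation-table rows
#' whose two endpoints are both significant. Node centrality is plain degree
#' and the top-degree nodes are the "central" pathways.
#'
#' @param significant character vector of significant pathway ids.
#' @param relations a [relation_table] over pathway ids.
#' @param p_values optional named vector of enrichment P attached to nodes.
#' @return a [network]; `attr(, "central")` holds the maximum-degree nodes.
#' @export
pathway_act_network <- function(significant, relations, p_values = NULL) {
  significant <- unique(significant)
  keep <- relations$src %in% significant & relations$dst %in% significant
  edges <- as.data.frame(relations[keep, , drop = FALSE])
  rownames(edges) <- NULL
  deg <- table(factor(c(edges$src, edges$dst), levels = significant))
  nodes <- data.frame(id = significant, degree = as.integer(deg))
  if (!is.null(p_values)) nodes$p_value <- unname(p_values[nodes$id])
  net <- network(nodes, edges, directed = any(edges$directed))
  attr(net, "central") <-
    if (nrow(nodes)) nodes$id[nodes$degree == max(nodes$degree)] else
      character()
  net
}

#' Gene-act network: typed interactions restricted to DEGs
#'
#' Induced subgraph of the relation table on the called DEG set; node
#' attribute is the up/down call. Relations touching ids that are not DEGs
#' are skipped and counted.
#'
#' @param calls named character vector of calls (`"up"`/`"down"`), names are
#'   gene ids; typically `with(de$table, setNames(call, gene))` filtered to
#'   DEGs.
#' @param relations a [relation_table] over gene ids.
#' @return a [network] with node `direction`; `attr(, "n_skipped")` counts
#'   the skipped relations.
#' @export
gene_act_network <- function(calls, relations) {
  degs <- names(calls)[calls %in% c("up", "down")]
  keep <- relations$src %in% degs & relations$dst %in% degs
  n_skipped <- sum(!keep)
  if (n_skipped)
    message(n_skipped, " relation(s) with non-DEG endpoint skipped")
  edges <- as.data.frame(relations[keep, , drop = FALSE])
  rownames(edges) <- NULL
  nodes <- data.frame(id = degs, direction = unname(calls[degs]))
  net <- network(nodes, edges, directed = any(edges$directed))
  attr(net, "n_skipped") <- n_skipped
  net
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure with the usual monotone (running-minimum) enforcement:
#' `q_(i) = min_{j >= i} p_(j) * m / j`.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as the input; elementwise `q >= p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (!m) return(numeric())
  ord <- order(p)
  q <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Per-group Pearson co-expression network with FDR-selected edges
#'
#' All-pairs Pearson correlation across the given samples; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom; BH
#' across all pairs; edges kept where `q < alpha`, signed by the sign of r
#' (positive = solid, negative = dotted, in the usual rendering). Genes with
#' zero variance across the samples are excluded with a log entry. Note the
#' feasibility bound at n = 3: |r| must exceed 0.997 for raw p < 0.05
#' (t critical 12.706 at df = 1), so with three replicates per group an
#' FDR-selected network is typically empty; a loud warning is emitted then.
#'
#' @param expr numeric matrix (genes x samples) of normalized expression for
#'   the selected genes, already subset to one group's samples (or pooled,
#'   if so configured).
#' @param alpha edge FDR threshold (default 0.05).
#' @return a [network] with edge attributes `r`, `p`, `q`, `sign`; excluded
#'   genes in `attr(, "excluded")`.
#' @export
coexpression_network <- function(expr, alpha = 0.05) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (nrow(expr) < 2) stop("need at least 2 genes")
  v <- apply(expr, 1, stats::var)
  excluded <- rownames(expr)[v == 0 | !is.finite(v)]
  if (length(excluded))
    message(length(excluded), " zero-variance gene(s) excluded: ",
            paste(utils::head(excluded, 5), collapse = ", "))
  expr <- expr[!(rownames(expr) %in% excluded), , drop = FALSE]
  genes <- rownames(expr)
  G <- nrow(expr); n <- ncol(expr)
  if (G < 2)
    return(structure(network(data.frame(id = genes),
                             data.frame(src = character(),
                                        dst = character())),
                     excluded = excluded))
  cm <- stats::cor(t(expr))
  iu <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[iu]
  r_t <- pmin(pmax(r, -1), 1)
  tstat <- r_t * sqrt((n - 2) / pmax(1 - r_t^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r_t) >= 1 - 1e-12] <- 0  # perfectly correlated pairs
  q <- bh_fdr(p)
  keep <- q < alpha
  edges <- data.frame(src = genes[iu[keep, 1]], dst = genes[iu[keep, 2]],
                      r = r[keep], p = p[keep], q = q[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      weight = abs(r[keep]))
  if (!nrow(edges))
    warning("no co-expression edge passes FDR < ", alpha,
            " with n = ", n,
            " samples; consider pooled samples or --edge-alpha")
  net <- network(data.frame(id = genes), edges, directed = FALSE)
  attr(net, "excluded") <- excluded
  net
}

#' k-core decomposition by iterative minimum-degree peeling
#'
#' Standard core decomposition of the undirected simple view of the network
#' (edge direction, sign and weight are ignored; parallel edges collapse).
#' A node's core number is the largest k such that it survives in the
#' subgraph where every node keeps at least k neighbours. Hubs are the
#' nodes attaining the maximum core number; ties all returned.
#'
#' @param net a [network] (or a 2-column edge data.frame plus `nodes`).
#' @return list with `core` (named integer per node), `max_core`, and
#'   `hubs` (ids attaining the maximum).
#' @export
kcore_decompose <- function(net) {
  nodes <- net$nodes$id
  e <- unique(data.frame(
    a = pmin(net$edges$src, net$edges$dst),
    b = pmax(net$edges$src, net$edges$dst)))
  e <- e[e$a != e$b, , drop = FALSE]
  core <- stats::setNames(integer(length(nodes)), nodes)
  if (!length(nodes)) return(list(core = core, max_core = 0L,
                                  hubs = character()))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character())
  for (i in seq_len(nrow(e))) {
    adj[[e$a[i]]] <- c(adj[[e$a[i]]], e$b[i])
    adj[[e$b[i]]] <- c(adj[[e$b[i]]], e$a[i])
  }
  deg <- vapply(adj, length, 1L)
  alive <- stats::setNames(rep(TRUE, length(nodes)), nodes)
  k <- 0L
  while (any(alive)) {
    k_min <- min(deg[alive])
    k <- max(k, k_min)
    # peel every node of degree <= current k, cascading
    repeat {
      peel <- names(which(alive & deg <= k))
      if (!length(peel)) break
      for (v in peel) {
        core[v] <- k
        alive[v] <- FALSE
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
  }
  max_core <- max(core)
  list(core = core, max_core = max_core,
       hubs = names(core)[core == max_core])
}

#' Attach core numbers to a network's nodes
#' @param net a [network].
#' @return the network with a `core` node column; hub ids in
#'   `attr(, "hubs")`.
#' @export
with_core_numbers <- function(net) {
  kc <- kcore_decompose(net)
  net$nodes$core <- unname(kc$core[net$nodes$id])
  attr(net, "hubs") <- kc$hubs
  net
}
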