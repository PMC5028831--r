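#' Hypergeometric over-representation test per term
#'
#' One-sided Fisher P for each term: with `N` universe genes, `K` of them in
#' the term, `n` DEGs and `k` DEGs in the term,
#' `P = sum_{i >= k} C(K, i) C(N-K, n-i) / C(N, n)`.
#' Computed for a DEG subset (all, up or down, as labelled). Terms with no
#' universe member (`K = 0`) are skipped with a log entry.
#'
#' @param deg_set character vector of DEG ids (must lie in the universe).
#' @param annotation an [annotation_set].
#' @param subset_label label recorded per row (`"all"`, `"up"`, `"down"`).
#' @return data.frame of class `enrichment_result`: term, name, namespace,
#'   subset, k, K, n, N, p_value, bh_q.
#' @export
fisher_enrich <- function(deg_set, annotation, subset_label = "all") {
  stopifnot(inherits(annotation, "annotation_set"))
  universe <- annotation$universe
  extra <- setdiff(deg_set, universe)
  if (length(extra))
    stop("DEGs outside the universe: ", paste(utils::head(extra, 5),
                                              collapse = ", "))
  deg_set <- unique(deg_set)
  N <- length(universe); n <- length(deg_set)
  K <- vapply(annotation$genesets, length, 1L)
  skip <- K == 0
  if (any(skip))
    message(sum(skip), " term(s) with no universe members skipped")
  terms <- annotation$terms[!skip, , drop = FALSE]
  K <- K[terms$id]
  k <- vapply(annotation$genesets[terms$id],
              function(gs) length(intersect(gs, deg_set)), 1L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms$id, name = terms$name,
                    namespace = terms$namespace, subset = subset_label,
                    k = k, K = unname(K), n = n, N = N,
                    p_value = p, row.names = NULL)
  out$bh_q <- bh_fdr(out$p_value)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Chi-squared cross-check of a 2x2 enrichment table
#'
#' Optional alternative to the Fisher test (with Yates correction), intended
#' only for terms where all expected cell counts are at least 5; the Fisher
#' test remains authoritative for the significance filter.
#'
#' @param k,K,n,N 2x2 margins as in [fisher_enrich].
#' @return list with `p_value` and `applicable` (all expected cells >= 5).
#' @export
chisq_enrich <- function(k, K, n, N) {
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  applicable <- all(expected >= 5)
  p <- tryCatch(
    suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value),
    error = function(e) NA_real_)
  list(p_value = p, applicable = applicable)
}

#' Filter significant terms at a raw-P threshold
#'
#' Strict inequality (`p < p_threshold`); stable sort by p ascending, ties
#' broken by term id. No multiple-testing correction is applied to the
#' filter; the BH column is reported for transparency only.
#'
#' @param res an `enrichment_result`.
#' @param p_threshold significance cut (default 0.05).
#' @return the filtered, sorted `enrichment_result`.
#' @export
significant_terms <- function(res, p_threshold = 0.05) {
  out <- res[res$p_value < p_threshold, , drop = FALSE]
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k most significant terms per namespace and subset
#'
#' @param res an `enrichment_result` (typically already filtered).
#' @param k how many per (namespace, subset) block (default 15).
#' @return ranked data.frame with a `rank` column; fewer than `k` rows per
#'   block when fewer terms exist.
#' @export
top_k_report <- function(res, k = 15) {
  parts <- split(as.data.frame(res),
                 list(res$namespace, res$subset), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$p_value, d$term), , drop = FALSE]
    d <- utils::head(d, k)
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Write an enrichment result TSV
#' @param res an `enrichment_result` (or the top-k report).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_enrichment_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
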