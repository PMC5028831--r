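#' Read-mapping summary with derived rates
#'
#' One row per sample with total, mapped/unmapped and unique/repeat-mapped
#' read counts. Exact bookkeeping is enforced for mapped + unmapped; the
#' unique + repeat decomposition is checked only within a small tolerance
#' because published summaries are known to disagree by a handful of reads.
#'
#' @param df data.frame with columns `sample`, `all_reads`, `mapped`,
#'   `unmapped`, `unique_mapped`, `repeat_mapped` (extra columns kept).
#' @param tolerance allowed |unique + repeat - mapped| discrepancy in reads.
#' @return object of class `mapping_summary`.
#' @export
mapping_summary <- function(df, tolerance = 100) {
  need <- c("sample", "all_reads", "mapped", "unmapped", "unique_mapped",
            "repeat_mapped")
  if (!all(need %in% names(df)))
    stop("mapping summary needs columns ", paste(need, collapse = ", "))
  if (any(df$mapped + df$unmapped != df$all_reads))
    stop("mapped + unmapped must equal all_reads exactly")
  off <- abs(df$unique_mapped + df$repeat_mapped - df$mapped)
  if (any(off > tolerance))
    stop("unique + repeat deviates from mapped by more than ", tolerance,
         " reads in: ", paste(df$sample[off > tolerance], collapse = ", "))
  structure(df, class = c("mapping_summary", "data.frame"))
}

#' Read a mapping-summary TSV
#' @param path TSV with the [mapping_summary] columns.
#' @return a [mapping_summary].
#' @export
read_mapping_summary <- function(path) {
  mapping_summary(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Per-sample mapped and unique-mapped rates
#'
#' `mapped_rate = mapped / all_reads`; `unique_rate = unique_mapped /
#' all_reads`, rounded to 3 decimals for report output.
#'
#' @param summary a [mapping_summary].
#' @param digits rounding for the report (default 3, matching the usual
#'   presentation); use `NULL` for unrounded values.
#' @return data.frame with `sample`, `mapped_rate`, `unique_rate`.
#' @export
mapping_rates <- function(summary, digits = 3) {
  if (any(summary$all_reads <= 0)) stop("all_reads must be positive")
  out <- data.frame(sample = summary$sample,
                    mapped_rate = summary$mapped / summary$all_reads,
                    unique_rate = summary$unique_mapped / summary$all_reads)
  if (!is.null(digits)) {
    out$mapped_rate <- round(out$mapped_rate, digits)
    out$unique_rate <- round(out$unique_rate, digits)
  }
  out
}

#' RPKM expression values
#'
#' `RPKM_gj = 1e9 * C_gj / (N_j * L_g)` with `N_j` the per-sample total
#' mapped reads. By default `N_j` is the within-matrix column sum so the
#' pipeline is self-contained; aligner-reported totals can be supplied as an
#' override.
#'
#' @param cm a [count_matrix].
#' @param totals optional named per-sample totals overriding column sums.
#' @return an [expression_matrix] of kind `"RPKM"`.
#' @export
rpkm <- function(cm, totals = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$lengths <= 0)) stop("zero-length gene(s) present")
  N <- if (is.null(totals)) colSums(cm$counts) else totals[cm$sample_ids]
  if (any(!is.finite(N)) || any(N <= 0))
    stop("per-sample total mapped reads must be positive")
  vals <- 1e9 * sweep(cm$counts / cm$lengths, 2, N, `/`)
  expression_matrix(vals, "RPKM")
}

#' Upper-quartile size factors
#'
#' Per-sample scaling by the 75th percentile of that sample's nonzero gene
#' counts, normalized to geometric mean 1 so neither group serves as the
#' reference: `s_j = Q75_j / geomean(Q75)`.
#'
#' @param cm a [count_matrix].
#' @return named positive numeric vector of size factors.
#' @export
upper_quartile_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  q75 <- vapply(seq_len(ncol(cm$counts)), function(j) {
    x <- cm$counts[, j]
    x <- x[x > 0]
    if (!length(x))
      stop("sample ", cm$sample_ids[j], " has no nonzero counts")
    stats::quantile(x, 0.75, names = FALSE, type = 7)
  }, 1.0)
  s <- q75 / exp(mean(log(q75)))
  stats::setNames(s, cm$sample_ids)
}

#' Normalize counts by size factors
#'
#' `value_gj = C_gj / s_j`; the per-group means of these values are the
#' "normalized counts" reported alongside fold changes.
#'
#' @param cm a [count_matrix].
#' @param factors positive per-sample size factors (e.g. from
#'   [upper_quartile_factors]).
#' @return an [expression_matrix] of kind `"UQ-normalized-counts"`.
#' @export
normalize_counts <- function(cm, factors = upper_quartile_factors(cm)) {
  stopifnot(inherits(cm, "count_matrix"))
  factors <- factors[cm$sample_ids]
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("size factors must be positive and finite")
  expression_matrix(sweep(cm$counts, 2, factors, `/`),
                    "UQ-normalized-counts")
}

#' Write mapping rates / RPKM report TSVs
#' @param summary a [mapping_summary].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_mapping_report <- function(summary, path) {
  out <- cbind(as.data.frame(summary), mapping_rates(summary)[, -1])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mapping_report
#' @param em an [expression_matrix].
#' @export
write_expression_tsv <- function(em, path) {
  tab <- data.frame(gene_id = rownames(em$values), em$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
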