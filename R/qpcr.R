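#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged per (gene, sample); per-animal
#' `dCt_s = Ct_gene,s - Ct_reference,s`; `ddCt` is the mean dCt of the test
#' group minus the mean dCt of the calibrator group; the relative quantity
#' is `rq = 2^-ddCt`. Significance is a Welch t-test on the per-animal dCt
#' values (the biological unit), starred at P < 0.05 (*) and P < 0.01 (**).
#' Amplification efficiency is fixed at 2.
#'
#' @param plate a [qpcr_plate].
#' @param gene target gene (must not be the reference gene).
#' @param test_group group compared against the calibrator; defaults to the
#'   non-calibrator group on the plate.
#' @return object of class `relative_quant`: `gene`, `rq`, `ddct`,
#'   `dct` (per-animal values by group), `p_value`, `stars`.
#' @export
ddct <- function(plate, gene, test_group = NULL) {
  stopifnot(inherits(plate, "qpcr_plate"))
  if (gene == plate$reference_gene)
    stop("target gene must differ from the reference gene")
  rec <- plate$records
  if (!gene %in% rec$gene) stop("gene ", gene, " not on the plate")
  groups <- unique(rec$group)
  if (length(groups) < 2) stop("both groups must be present on the plate")
  if (is.null(test_group))
    test_group <- setdiff(groups, plate$calibrator_group)[1]
  avg <- function(g) {
    d <- rec[rec$gene == g, ]
    tapply(d$ct, d$sample, mean)
  }
  ct_g <- avg(gene); ct_ref <- avg(plate$reference_gene)
  missing <- setdiff(names(ct_g), names(ct_ref))
  if (length(missing))
    stop("reference well missing for sample(s): ",
         paste(missing, collapse = ", "))
  dct <- ct_g - ct_ref[names(ct_g)]
  grp_of <- rec$group[match(names(dct), rec$sample)]
  d_test <- dct[grp_of == test_group]
  d_cal <- dct[grp_of == plate$calibrator_group]
  if (!length(d_test) || !length(d_cal))
    stop("gene ", gene, " not measured in both groups")
  ddct_val <- mean(d_test) - mean(d_cal)
  p <- if (length(d_test) > 1 && length(d_cal) > 1 &&
           (stats::sd(d_test) > 0 || stats::sd(d_cal) > 0))
    stats::t.test(d_test, d_cal)$p.value else 1
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  structure(list(gene = gene, rq = 2^(-ddct_val), ddct = ddct_val,
                 dct = list(test = d_test, calibrator = d_cal),
                 test_group = test_group,
                 calibrator_group = plate$calibrator_group,
                 p_value = p, stars = stars),
            class = "relative_quant")
}

#' @export
print.relative_quant <- function(x, ...) {
  cat(sprintf("%s: rq = %.3f (ddCt %.3f, %s vs %s), P = %.3g %s\n",
              x$gene, x$rq, x$ddct, x$test_group, x$calibrator_group,
              x$p_value, x$stars))
  invisible(x)
}

#' Relative quantification of every target gene on a plate
#'
#' @param plate a [qpcr_plate].
#' @param test_group see [ddct].
#' @return data.frame of class `rq_table`: gene, rq, ddct, p_value, stars.
#' @export
rq_table <- function(plate, test_group = NULL) {
  genes <- setdiff(unique(plate$records$gene), plate$reference_gene)
  rows <- lapply(genes, function(g) {
    q <- ddct(plate, g, test_group)
    data.frame(gene = g, rq = q$rq, ddct = q$ddct, p_value = q$p_value,
               stars = q$stars)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rq_table", "data.frame")
  out
}

#' Sign concordance between qPCR and RNA-seq fold changes
#'
#' A gene agrees when `sign(log2 rq)` equals the sign of the RNA-seq log2
#' fold change (same test-vs-calibrator direction assumed on both sides).
#'
#' @param rq an `rq_table` (or data.frame with `gene` and `rq`).
#' @param de a `de_result` (or data.frame with `gene` and `log2fc`).
#' @return list with `per_gene` (gene, log2_rq, log2fc, agree) and
#'   `fraction` (overall agreement among comparable genes).
#' @export
concordance <- function(rq, de) {
  detab <- if (inherits(de, "de_result")) de$table else de
  common <- intersect(rq$gene, detab$gene)
  if (!length(common)) stop("no genes shared between qPCR and RNA-seq tables")
  lrq <- log2(rq$rq[match(common, rq$gene)])
  lfc <- detab$log2fc[match(common, detab$gene)]
  agree <- sign(lrq) == sign(lfc)
  list(per_gene = data.frame(gene = common, log2_rq = lrq, log2fc = lfc,
                             agree = agree),
       fraction = mean(agree, na.rm = TRUE))
}

#' Write an rq_table TSV
#' @param rq an `rq_table`.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_rq_tsv <- function(rq, path) {
  utils::write.table(as.data.frame(rq), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
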