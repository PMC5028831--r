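#' Method-of-moments NB size parameters
#'
#' Pooled estimator on normalized counts: `r_g = mean^2 / max(var - mean,
#' eps)` with `eps = 1e-8`, capped at `1e8` for (near-)zero-variance genes.
#' The mean pools all samples; the variance is the pooled *within-group*
#' variance, so that a real expression difference between the groups does
#' not masquerade as biological dispersion (using the cross-group variance
#' collapses the mixture onto the equal-expression pattern). Used as the
#' per-gene size of the negative binomial inside the empirical-Bayes
#' mixture.
#'
#' @param norm an [expression_matrix] (or bare matrix) of normalized counts.
#' @param groups named group labels per sample (two groups, each with at
#'   least two samples).
#' @return named numeric vector of per-gene `r`.
#' @export
estimate_size_params <- function(norm, groups) {
  x <- if (inherits(norm, "expression_matrix")) norm$values else norm
  g <- groups[colnames(x)]
  labs <- unique(g)
  if (length(labs) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("each group needs at least two samples")
  m <- rowMeans(x)
  x1 <- x[, g == labs[1], drop = FALSE]
  x2 <- x[, g == labs[2], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  rowvar <- function(z) rowSums((z - rowMeans(z))^2) / (ncol(z) - 1)
  v <- ((n1 - 1) * rowvar(x1) + (n2 - 1) * rowvar(x2)) / (n1 + n2 - 2)
  r <- pmin(m^2 / pmax(v - m, 1e-8), 1e8)
  stats::setNames(r, rownames(x))
}

#' Empirical-Bayes moderated NB size parameters
#'
#' With three replicates per group the per-gene moment estimator of
#' [estimate_size_params] is extremely noisy (4 degrees of freedom), and
#' genes whose within-group variance is underestimated by chance produce
#' overconfident posteriors. This estimator squeezes the per-gene excess
#' dispersion `phi_g = max(var - mean, 0) / mean^2` toward the central
#' dispersion, in the manner of limma's variance squeezing: the prior
#' degrees of freedom `d0` are estimated from the spread of
#' `log(phi_hat)` by trigamma moment matching, and the moderated value is
#' `max(phi_hat, (d0 * phi0 + d * phi_hat) / (d0 + d))` with
#' `d = n1 + n2 - 2`: a one-sided squeeze that pulls underestimated
#' dispersions up without ever assuming a gene less dispersed than
#' observed.
#'
#' @inheritParams estimate_size_params
#' @param min_mean genes below this mean are ignored when estimating the
#'   prior (their moment dispersions are dominated by shot noise).
#' @return named numeric vector of per-gene moderated `r`; the estimated
#'   prior is attached as `attr(, "prior")` (`phi0`, `d0`).
#' @export
moderate_size_params <- function(norm, groups, min_mean = 10) {
  x <- if (inherits(norm, "expression_matrix")) norm$values else norm
  g <- groups[colnames(x)]
  labs <- unique(g)
  if (length(labs) != 2) stop("exactly two groups required")
  x1 <- x[, g == labs[1], drop = FALSE]
  x2 <- x[, g == labs[2], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2); d <- n1 + n2 - 2
  rowvar <- function(z) rowSums((z - rowMeans(z))^2) / (ncol(z) - 1)
  v <- ((n1 - 1) * rowvar(x1) + (n2 - 1) * rowvar(x2)) / d
  m <- rowMeans(x)
  phi_hat <- pmax(v - m, 0) / pmax(m, 1e-8)^2
  use <- m > min_mean & phi_hat > 0
  z <- log(phi_hat[use])
  # E log(chi2_d / d) = digamma(d/2) - log(d/2); excess spread of z over
  # the chi-square sampling noise is the prior variance of log phi
  excess <- max(stats::var(z) - trigamma(d / 2), trigamma(500))
  f <- function(y) trigamma(y / 2) - excess
  d0 <- if (f(1) < 0) 1 else stats::uniroot(f, c(1, 1000))$root
  phi0 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  # one-sided squeeze: genes with underestimated dispersion are pulled up
  # toward the prior, but a gene is never assumed less dispersed than
  # observed (shrinking genuinely high dispersions down creates confident
  # false positives under the null)
  phi_mod <- pmax(phi_hat, (d0 * phi0 + d * phi_hat) / (d0 + d))
  r <- pmin(1 / pmax(phi_mod, 1e-8), 1e8)
  structure(stats::setNames(r, rownames(x)),
            prior = c(phi0 = phi0, d0 = d0))
}

#' Discretized empirical dispersion prior
#'
#' Fits a log-normal prior to the per-gene excess dispersions (central value
#' and spread by the same trigamma moment matching as
#' [moderate_size_params]) and discretizes it into `K` equal-probability
#' bins represented by their midpoint quantiles. [em_fit] can integrate its
#' Beta-NB marginals over this grid, so a gene whose own replicates happen
#' to look tight is still allowed, with prior probability, to be a
#' high-dispersion gene — which removes the confident false positives that
#' any point estimate of the dispersion produces at n = 3.
#'
#' @inheritParams estimate_size_params
#' @param K number of Gauss-Hermite nodes (the quadrature covers the far
#'   tails of the log-normal prior, which equal-probability binning would
#'   truncate).
#' @return list with `phi` (grid values) and `w` (weights summing to 1).
#' @export
dispersion_prior_grid <- function(norm, groups, K = 7) {
  x <- if (inherits(norm, "expression_matrix")) norm$values else norm
  g <- groups[colnames(x)]
  labs <- unique(g)
  x1 <- x[, g == labs[1], drop = FALSE]
  x2 <- x[, g == labs[2], drop = FALSE]
  d <- ncol(x1) + ncol(x2) - 2
  rowvar <- function(z) rowSums((z - rowMeans(z))^2) / (ncol(z) - 1)
  v <- ((ncol(x1) - 1) * rowvar(x1) + (ncol(x2) - 1) * rowvar(x2)) / d
  m <- rowMeans(x)
  phi_hat <- pmax(v - m, 0) / pmax(m, 1e-8)^2
  z <- log(phi_hat[m > 10 & phi_hat > 0])
  sd_prior <- sqrt(max(stats::var(z) - trigamma(d / 2), trigamma(500)))
  phi0 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  gh <- gauss_hermite(K)
  phi <- exp(log(phi0) + sqrt(2) * sd_prior * gh$nodes)
  list(phi = pmax(phi, 1e-6), w = gh$weights)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weights normalized to sum 1,
# i.e. probabilists' integration against the standard normal).
gauss_hermite <- function(K) {
  if (K == 1) return(list(nodes = 0, weights = 1))
  off <- sqrt(seq_len(K - 1) / 2)
  J <- matrix(0, K, K)
  J[cbind(1:(K - 1), 2:K)] <- off
  J[cbind(2:K, 1:(K - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord]^2))
}

#' Beta-negative-binomial marginal log-likelihood
#'
#' Closed form for a set of samples sharing one Beta(alpha, beta) prior on
#' the NB probability parameter:
#' `sum_j log C(x_j + r_j - 1, x_j) + log B(alpha + sum r_j, beta + sum x_j)
#'  - log B(alpha, beta)`.
#' Accepts non-integral `x` (normalized counts) through the gamma-function
#' form of the binomial coefficient.
#'
#' @param x counts for one gene across the sample set.
#' @param r NB size parameter(s); recycled to `length(x)`.
#' @param alpha,beta positive Beta prior shapes.
#' @return the marginal log-likelihood (scalar).
#' @export
beta_nb_loglik <- function(x, r, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  r <- rep_len(r, length(x))
  ll <- sum(lgamma(x + r) - lgamma(r) - lgamma(x + 1)) +
    lbeta(alpha + sum(r), beta + sum(x)) - lbeta(alpha, beta)
  if (!is.finite(ll))
    stop("non-finite Beta-NB marginal (x sum ", sum(x), ", r ", r[1], ")")
  ll
}

#' Fit the two-condition empirical-Bayes NB-Beta mixture by EM
#'
#' Each gene is either equally expressed (EE: one Beta prior pooled over all
#' samples) or differentially expressed (DE: independent priors per group,
#' sharing `alpha` with pattern-specific `beta`s). The E-step computes the
#' posterior DE probability from the closed-form Beta-NB marginals; the
#' M-step updates the mixing proportion as the mean posterior and the
#' hyperparameters by bounded quasi-Newton maximization of the expected
#' log-likelihood (log-parameterized, bounds `[1e-3, 1e3]`).
#'
#' @param norm normalized counts ([expression_matrix] or matrix).
#' @param groups named per-sample group labels (two groups).
#' @param r per-gene NB sizes; default [estimate_size_params]. Ignored when
#'   `phi_grid` is given.
#' @param phi_grid optional dispersion prior grid from
#'   [dispersion_prior_grid]; when supplied, both pattern marginals are
#'   integrated over the grid (each gene's replicates weight the grid
#'   through the likelihood) instead of conditioning on a per-gene point
#'   `r`.
#' @param init list with starting `p_de`, `alpha`, `beta` (shared start for
#'   the three pattern betas).
#' @param max_iter,tol EM stopping rule: stop when the relative change in
#'   `p_de` falls below `tol`.
#' @return object of class `eb_model`: `pp_de`, `p_de`, `alpha`, `beta_ee`,
#'   `beta_de1`, `beta_de2`, `r`, `converged`, `n_iter`, `loglik_trace`.
#' @export
em_fit <- function(norm, groups, r = NULL, phi_grid = NULL,
                   init = list(p_de = 0.2, alpha = 0.4, beta = 1.0),
                   max_iter = 50, tol = 1e-4) {
  x <- if (inherits(norm, "expression_matrix")) norm$values else norm
  g <- groups[colnames(x)]
  labs <- unique(g)
  if (length(labs) != 2) stop("two groups required")
  s1 <- which(g == labs[1]); s2 <- which(g == labs[2])
  x1 <- rowSums(x[, s1, drop = FALSE]); x2 <- rowSums(x[, s2, drop = FALSE])
  n1 <- length(s1); n2 <- length(s2)

  if (is.null(phi_grid)) {
    if (is.null(r)) r <- estimate_size_params(x, groups)
    r_list <- list(pmax(unname(r[rownames(x)]), 1e-8))
    lw <- 0
  } else {
    r_list <- lapply(phi_grid$phi, function(phi) 1 / phi)
    lw <- log(phi_grid$w)
  }
  # hyperparameter-free combinatorial term per grid component (identical
  # under EE and DE, so it cancels in the posterior but not the loglik)
  lconst <- lapply(r_list, function(rk)
    rowSums(lgamma(x + rk) - lgamma(rk) - lgamma(x + 1)))

  p_de <- init$p_de
  theta <- log(c(alpha = init$alpha, beta_ee = init$beta,
                 beta_de1 = init$beta, beta_de2 = init$beta))
  lo <- rep(log(1e-3), 4); hi <- rep(log(1e3), 4)

  # log-mixture over the dispersion grid (single component when phi_grid
  # is NULL); the combinatorial term must stay inside the mixture
  mix <- function(mats) {
    if (length(mats) == 1) return(mats[[1]] + lconst[[1]])
    terms <- mapply(function(lm, lc, w) lm + lc + w, mats, lconst, lw,
                    SIMPLIFY = FALSE)
    mx <- Reduce(pmax, terms)
    mx + log(Reduce(`+`, lapply(terms, function(t) exp(t - mx))))
  }
  x12 <- x1 + x2
  # hot path: lbeta(a + n*r_k, b + x_S) expanded so the k-independent
  # lgamma(b + x_S) vectors are computed once per evaluation
  parts <- function(th) {
    a <- exp(th[1]); bee <- exp(th[2]); b1 <- exp(th[3]); b2 <- exp(th[4])
    lg_bee <- lgamma(bee + x12)
    lg_b1 <- lgamma(b1 + x1); lg_b2 <- lgamma(b2 + x2)
    c_ee <- lgamma(a) + lgamma(bee) - lgamma(a + bee)
    c_1 <- lgamma(a) + lgamma(b1) - lgamma(a + b1)
    c_2 <- lgamma(a) + lgamma(b2) - lgamma(a + b2)
    ee <- mix(lapply(r_list, function(rk) {
      s <- (n1 + n2) * rk
      lgamma(a + s) + lg_bee - lgamma(a + s + bee + x12) - c_ee
    }))
    de <- mix(lapply(r_list, function(rk) {
      s1r <- n1 * rk; s2r <- n2 * rk
      (lgamma(a + s1r) + lg_b1 - lgamma(a + s1r + b1 + x1) - c_1) +
        (lgamma(a + s2r) + lg_b2 - lgamma(a + s2r + b2 + x2) - c_2)
    }))
    list(ee = ee, de = de)
  }
  obs_loglik <- function(pr, p) {
    lee <- pr$ee + log1p(-p)
    lde <- pr$de + log(p)
    mx <- pmax(lee, lde)
    sum(mx + log(exp(lee - mx) + exp(lde - mx)))
  }

  trace <- numeric(); pp <- rep(0, nrow(x)); n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    pr <- parts(theta)
    # E-step
    if (p_de <= 0) {
      pp <- rep(0, nrow(x))
    } else {
      d <- log(p_de) + pr$de - (log1p(-p_de) + pr$ee)
      pp <- 1 / (1 + exp(-d))
    }
    trace[it] <- obs_loglik(pr, p_de)
    # M-step: mixing proportion exactly, hyperparameters by bounded
    # quasi-Newton with numeric gradients (generalized EM)
    p_new <- mean(pp)
    q_fun <- function(th) {
      prt <- parts(th)
      -sum((1 - pp) * prt$ee + pp * prt$de)
    }
    opt <- stats::optim(theta, q_fun, method = "L-BFGS-B", lower = lo,
                        upper = hi, control = list(maxit = 8))
    if (opt$value <= q_fun(theta)) theta <- opt$par
    delta <- abs(p_new - p_de) / max(p_de, 1e-12)
    p_de <- p_new
    if (delta < tol) break
  }
  converged <- n_iter < max_iter ||
    abs(utils::tail(diff(trace), 1)) < tol * abs(utils::tail(trace, 1))
  if (!converged)
    warning("EM did not converge after ", max_iter, " iterations")
  # final E-step under the updated parameters
  pr <- parts(theta)
  if (p_de <= 0) pp <- rep(0, nrow(x)) else
    pp <- 1 / (1 + exp(-(log(p_de) + pr$de - log1p(-p_de) - pr$ee)))
  structure(list(pp_de = stats::setNames(pp, rownames(x)), p_de = p_de,
                 alpha = exp(theta[[1]]), beta_ee = exp(theta[[2]]),
                 beta_de1 = exp(theta[[3]]), beta_de2 = exp(theta[[4]]),
                 r = r, phi_grid = phi_grid, groups = labs,
                 converged = converged,
                 n_iter = n_iter, loglik_trace = trace),
            class = "eb_model")
}

#' @export
print.eb_model <- function(x, ...) {
  cat(sprintf(
    "eb_model: p_de=%.4f alpha=%.3g beta=(%.3g, %.3g, %.3g) %s in %d iter\n",
    x$p_de, x$alpha, x$beta_ee, x$beta_de1, x$beta_de2,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Posterior-probability FDR calls
#'
#' Genes are ranked by posterior DE probability; the FDR of calling the top
#' k is the cumulative mean of `1 - pp_de` over them. The call set is the
#' largest k with FDR below `target`; each gene's reported fdr is the FDR of
#' the smallest call set containing it.
#'
#' @param pp_de posterior DE probabilities in `[0, 1]`.
#' @param target nominal FDR (default 0.05, strict inequality).
#' @return list with `called` (logical, input order) and `fdr` (numeric,
#'   input order).
#' @export
fdr_call <- function(pp_de, target = 0.05) {
  stopifnot(all(pp_de >= 0 & pp_de <= 1))
  ord <- order(pp_de, decreasing = TRUE)
  cum <- cumsum(1 - pp_de[ord]) / seq_along(pp_de)
  k <- if (any(cum < target)) max(which(cum < target)) else 0L
  called <- logical(length(pp_de))
  if (k > 0) called[ord[seq_len(k)]] <- TRUE
  fdr <- numeric(length(pp_de))
  fdr[ord] <- cum
  names(fdr) <- names(pp_de)
  list(called = called, fdr = fdr)
}

#' Log2 fold change of group means
#'
#' `log2(mean_group2 / mean_group1)`. When either mean is zero a pseudo-count
#' of 1 is added to both; when both are zero the gene is undefined and `NA`
#' is returned (the caller logs and excludes it).
#'
#' @param mean_g1,mean_g2 non-negative group means (vectorized).
#' @param pseudo pseudo-count used when either mean is zero.
#' @return signed log2 fold changes (group 2 vs group 1).
#' @export
log2_fold_change <- function(mean_g1, mean_g2, pseudo = 1) {
  both_zero <- mean_g1 == 0 & mean_g2 == 0
  any_zero <- (mean_g1 == 0 | mean_g2 == 0) & !both_zero
  m1 <- ifelse(any_zero, mean_g1 + pseudo, mean_g1)
  m2 <- ifelse(any_zero, mean_g2 + pseudo, mean_g2)
  out <- log2(m2 / m1)
  out[both_zero] <- NA_real_
  out
}

#' Apply the fold-change / FDR call rule
#'
#' `up` when `log2fc > lfc_threshold` and `fdr < fdr_threshold`; `down` when
#' `log2fc < -lfc_threshold` and `fdr < fdr_threshold`; otherwise `none`.
#' Both inequalities are strict; `2^0.585` is the 1.5-fold threshold.
#'
#' @param de a `de_result` (from [de_test]) or a data.frame with `log2fc`
#'   and `fdr` columns.
#' @param lfc_threshold,fdr_threshold call thresholds.
#' @return list with the updated table (`result`) and counts `n_total`,
#'   `n_up`, `n_down`.
#' @export
classify_degs <- function(de, lfc_threshold = 0.585, fdr_threshold = 0.05) {
  tab <- if (inherits(de, "de_result")) de$table else de
  ok <- !is.na(tab$log2fc) & tab$fdr < fdr_threshold
  call <- ifelse(ok & tab$log2fc > lfc_threshold, "up",
                 ifelse(ok & tab$log2fc < -lfc_threshold, "down", "none"))
  tab$call <- call
  if (inherits(de, "de_result")) de$table <- tab else de <- tab
  list(result = de, n_total = sum(call != "none"),
       n_up = sum(call == "up"), n_down = sum(call == "down"))
}

#' Two-group differential expression test (full stage)
#'
#' Upper-quartile normalization, empirical-Bayes moderated NB sizes
#' ([moderate_size_params]), EM fit of the EE/DE mixture,
#' posterior-probability FDR, fold changes of normalized group means, and
#' the fold-change/FDR call rule. Genes with zero counts in every sample
#' are excluded (logged).
#'
#' @param cm a [count_matrix] with exactly two groups.
#' @param group_order optional two labels fixing direction: fold changes are
#'   group 2 vs group 1. Defaults to the order of first appearance.
#' @param norm optional precomputed [expression_matrix]; defaults to
#'   upper-quartile normalized counts.
#' @param lfc_threshold,fdr_threshold call thresholds.
#' @param ... passed to [em_fit].
#' @return object of class `de_result`: `table` (gene, group means, log2fc,
#'   pp_de, fdr, call), `model` (the `eb_model`), `groups`, `excluded`.
#' @export
de_test <- function(cm, group_order = NULL, norm = NULL,
                    lfc_threshold = 0.585, fdr_threshold = 0.05, ...) {
  stopifnot(inherits(cm, "count_matrix"))
  labs <- unique(unname(cm$groups))
  if (length(labs) != 2) stop("exactly two groups required for DE")
  if (!is.null(group_order)) {
    if (!setequal(group_order, labs)) stop("group_order must name both groups")
    labs <- group_order
  }
  if (is.null(norm)) norm <- normalize_counts(cm)
  v <- norm$values
  keep <- rowSums(cm$counts) > 0
  if (any(!keep))
    message(sum(!keep), " all-zero gene(s) excluded from the DE test")
  v <- v[keep, , drop = FALSE]
  g <- cm$groups
  m1 <- rowMeans(v[, g[colnames(v)] == labs[1], drop = FALSE])
  m2 <- rowMeans(v[, g[colnames(v)] == labs[2], drop = FALSE])
  model <- em_fit(v, g, phi_grid = dispersion_prior_grid(v, g), ...)
  fc <- fdr_call(model$pp_de, target = fdr_threshold)
  tab <- data.frame(gene = rownames(v), mean_g1 = m1, mean_g2 = m2,
                    log2fc = log2_fold_change(m1, m2),
                    pp_de = unname(model$pp_de), fdr = unname(fc$fdr),
                    row.names = NULL)
  names(tab)[2:3] <- paste0("mean_", labs)
  res <- structure(list(table = tab, model = model, groups = labs,
                        excluded = rownames(cm$counts)[!keep]),
                   class = "de_result")
  classify_degs(res, lfc_threshold, fdr_threshold)$result
}

#' @export
print.de_result <- function(x, ...) {
  n <- table(factor(x$table$call, levels = c("up", "down", "none")))
  cat(sprintf("de_result (%s vs %s): %d genes, %d up, %d down\n",
              x$groups[2], x$groups[1], nrow(x$table), n[["up"]],
              n[["down"]]))
  invisible(x)
}

#' Write the DE table as TSV
#'
#' Columns mirror the standard report: gene, normalized group means, log2
#' fold change (1 decimal), FDR (2 significant digits), style (up/down/none).
#'
#' @param de a `de_result`.
#' @param path output TSV.
#' @param rounded apply report rounding (default TRUE); FALSE writes full
#'   precision.
#' @return invisibly, `path`.
#' @export
write_de_table <- function(de, path, rounded = TRUE) {
  tab <- de$table
  out <- data.frame(gene = tab$gene, tab[, 2:3],
                    log2fc = if (rounded) round(tab$log2fc, 1) else tab$log2fc,
                    fdr = if (rounded) signif(tab$fdr, 2) else tab$fdr,
                    style = tab$call, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
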