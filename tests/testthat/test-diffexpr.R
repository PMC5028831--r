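test_that("moment estimator of NB size follows the contract", {
  a <- sqrt(200)
  x <- rbind(g1 = c(100 - a, 100, 100 + a, 100 - a, 100, 100 + a),
             g2 = c(50, 50, 50, 50, 50, 50))
  colnames(x) <- c(paste0("A", 1:3), paste0("B", 1:3))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), colnames(x))
  r <- estimate_size_params(x, groups)
  expect_equal(unname(r["g1"]), 100^2 / (200 - 100))  # mean 100, var 200
  expect_equal(unname(r["g2"]), 1e8)                  # zero variance: capped
  g_bad <- stats::setNames(c("A", "A", "A", "B"), colnames(x)[1:4])
  expect_error(estimate_size_params(x[, 1:4], g_bad), "two samples")
})

test_that("moment estimator recovers NB(r = 10) at n = 6", {
  set.seed(101)
  mu <- exp(runif(2000, log(50), log(5000)))
  x <- matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 10), ncol = 6,
              dimnames = list(paste0("g", 1:2000),
                              c(paste0("A", 1:3), paste0("B", 1:3))))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), colnames(x))
  r <- estimate_size_params(x, groups)
  expect_gte(median(r), 5)
  expect_lte(median(r), 20)
})

test_that("Beta-NB marginal: closed form, quadrature, additivity", {
  # x = 0, single sample: combinatorial term vanishes
  expect_equal(beta_nb_loglik(0, r = 2, alpha = 1.5, beta = 2.5),
               lbeta(1.5 + 2, 2.5) - lbeta(1.5, 2.5))
  # quadrature oracle on a 1e5-point grid
  expect_lt(abs(beta_nb_loglik(5, 2, 1.5, 2.5) -
                  beta_nb_quadrature(5, 2, 1.5, 2.5)), 1e-6)
  # additive over independent genes (same prior)
  l12 <- beta_nb_loglik(c(3), 2, 1.5, 2.5) +
    beta_nb_loglik(c(7), 4, 1.5, 2.5)
  expect_equal(l12, sum(vapply(list(c(3, 2), c(7, 4)), function(p)
    beta_nb_loglik(p[1], p[2], 1.5, 2.5), 1.0)))
  expect_error(beta_nb_loglik(5, 2, -1, 2), "alpha")
})

test_that("EM: p_de = 0 is a fixed point and the trace is monotone", {
  cfg <- sim_config(n_genes = 500, seed = 13)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$counts)
  fit0 <- em_fit(norm, sim$counts$groups,
                 init = list(p_de = 0, alpha = 0.4, beta = 1))
  expect_true(all(fit0$pp_de == 0))
  expect_equal(fit0$p_de, 0)

  fit <- em_fit(norm, sim$counts$groups)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-6 * pmax(abs(tr[-length(tr)]), 1)))
  expect_true(fit$converged)
  expect_true(all(fit$pp_de >= 0 & fit$pp_de <= 1))
})

test_that("swapping group labels negates lfc and keeps pp_de", {
  cfg <- sim_config(n_genes = 400, seed = 17)
  sim <- simulate_counts(cfg)
  de1 <- suppressMessages(de_test(sim$counts))
  flipped <- stats::setNames(
    ifelse(sim$counts$groups == "QHMM", "STH", "QHMM"),
    names(sim$counts$groups))
  cm2 <- count_matrix(sim$counts$counts, sim$counts$lengths, flipped)
  de2 <- suppressMessages(de_test(cm2, group_order = c("QHMM", "STH")))
  expect_equal(de2$table$log2fc, -de1$table$log2fc)
  expect_equal(de2$table$pp_de, de1$table$pp_de, tolerance = 1e-6)
})

test_that("posterior FDR calls match hand arithmetic", {
  r1 <- fdr_call(c(1, 1, 1), target = 0.05)
  expect_true(all(r1$called))
  expect_equal(r1$fdr, c(0, 0, 0))

  r2 <- fdr_call(c(0.99, 0.98, 0.50), target = 0.05)
  expect_equal(sum(r2$called), 2)
  expect_equal(r2$fdr, c(0.01, 0.015, (0.01 + 0.02 + 0.50) / 3))

  r3 <- fdr_call(rep(0.5, 10), target = 0.05)
  expect_false(any(r3$called))
})

test_that("log2 fold changes reproduce printed worked examples", {
  expect_equal(round(log2_fold_change(232.5, 37.5), 1), -2.6)   # MYOD1
  expect_equal(round(log2_fold_change(670.5, 3228.5), 1), 2.3)  # BTG1
  expect_equal(log2_fold_change(100, 100), 0)
  # pseudo-count when one mean is zero; NA when both are
  expect_equal(log2_fold_change(0, 3), log2(4 / 1))
  expect_true(is.na(log2_fold_change(0, 0)))
})

test_that("call rule boundaries are strict and 2^0.585 is the 1.5-fold cut", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(0.585, 0.586, -0.586, -0.585),
                    fdr = c(0.01, 0.01, 0.01, 0.049))
  cl <- classify_degs(tab)
  expect_equal(cl$result$call, c("none", "up", "down", "none"))
  expect_equal(cl$n_total, 2)
  expect_equal(cl$n_up, 1)
  expect_equal(cl$n_down, 1)
  # fdr boundary strict
  tab2 <- data.frame(gene = "a", log2fc = 2, fdr = 0.05)
  expect_equal(classify_degs(tab2)$n_total, 0)
  expect_equal(round(2^0.585, 1), 1.5)
})
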