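test_that("mapping rates reproduce the published summary arithmetic", {
  ms <- read_mapping_fixture()
  rates <- mapping_rates(ms)
  expect_equal(rates$mapped_rate[rates$sample == "A1"], 0.925)
  expect_equal(rates$unique_rate[rates$sample == "A1"], 0.877)
  # unique rates span the reported 0.853-0.877 band
  expect_equal(range(rates$unique_rate), c(0.853, 0.877))
  # degenerate cases
  full <- mapping_summary(data.frame(
    sample = "s", all_reads = 100, mapped = 100, unmapped = 0,
    unique_mapped = 100, repeat_mapped = 0))
  expect_equal(mapping_rates(full)$mapped_rate, 1)
  full$all_reads <- 0; full$mapped <- 0
  expect_error(mapping_rates(full), "positive")
})

test_that("mapping summary bookkeeping is enforced", {
  df <- data.frame(sample = "s", all_reads = 100, mapped = 90,
                   unmapped = 9, unique_mapped = 80, repeat_mapped = 10)
  expect_error(mapping_summary(df), "exactly")
  df$unmapped <- 10
  df$repeat_mapped <- 10 + 200  # unique + repeat drifts past tolerance
  expect_error(mapping_summary(df), "100 reads")
  df$repeat_mapped <- 10 + 13   # the published-scale 13-read discrepancy
  expect_s3_class(mapping_summary(df), "mapping_summary")
})

test_that("rpkm follows the formula and preserves zeros", {
  counts <- matrix(c(1000, 9999000, 0, 10), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cm <- count_matrix(counts, lengths = c(2000, 1000),
                     groups = c(s1 = "A", s2 = "B"))
  rp <- rpkm(cm, totals = c(s1 = 1e7, s2 = 1e7))
  expect_equal(rp$values["g1", "s1"], 50)      # 1e9*1000/(1e7*2000)
  expect_equal(rp$values["g1", "s2"], 0)
  # default totals are column sums
  expect_equal(rpkm(cm)$values["g1", "s1"], 1e9 * 1000 / (1e7 * 2000))
  # proportionally scaled columns give identical RPKM
  counts2 <- cbind(s1 = counts[, 1], s2 = counts[, 1] * 2)
  cm2 <- count_matrix(counts2, c(2000, 1000), c(s1 = "A", s2 = "B"))
  rp2 <- rpkm(cm2)
  expect_equal(rp2$values[, "s1"], rp2$values[, "s2"])
})

test_that("upper-quartile factors: values, order-invariance, equivariance", {
  counts <- matrix(c(rep(0, 5), rep(100, 5), rep(0, 5), rep(200, 5)),
                   nrow = 10,
                   dimnames = list(paste0("g", 1:10), c("s1", "s2")))
  cm <- count_matrix(counts, rep(1000, 10), c(s1 = "A", s2 = "B"))
  f <- upper_quartile_factors(cm)
  expect_equal(unname(f), c(100, 200) / sqrt(2e4), tolerance = 1e-6)
  expect_equal(unname(round(f, 4)), c(0.7071, 1.4142))
  expect_equal(prod(f), 1)  # geometric mean 1

  # identical columns -> all factors 1
  same <- count_matrix(cbind(s1 = counts[, 2], s2 = counts[, 2]),
                       rep(1000, 10), c(s1 = "A", s2 = "B"))
  expect_equal(unname(upper_quartile_factors(same)), c(1, 1))

  # permuting genes leaves factors unchanged
  perm <- count_matrix(counts[sample(10), ], rep(1000, 10),
                       c(s1 = "A", s2 = "B"))
  expect_equal(unname(upper_quartile_factors(perm)), unname(f))

  # all-zero sample errors with its name
  bad <- count_matrix(cbind(s1 = counts[, 2], s2 = rep(0, 10)),
                      rep(1000, 10), c(s1 = "A", s2 = "B"))
  expect_error(upper_quartile_factors(bad), "s2")

  # scaling one column by c rescales every normalized column by c^(1/J)
  # so all expression ratios (and fold changes) are invariant
  cm_s <- tiny_cm()
  n1 <- normalize_counts(cm_s)$values
  counts_c <- cm_s$counts
  counts_c[, "B_1"] <- counts_c[, "B_1"] * 8
  cm_c <- count_matrix(counts_c, cm_s$lengths, cm_s$groups)
  n2 <- normalize_counts(cm_c)$values
  expect_equal(n2, n1 * 8^(1 / 4), tolerance = 1e-10)
})

test_that("normalize_counts divides by factors and preserves zeros", {
  cm <- tiny_cm()
  f1 <- stats::setNames(rep(1, 4), cm$sample_ids)
  expect_equal(normalize_counts(cm, f1)$values, cm$counts + 0)
  f2 <- stats::setNames(c(2, 1, 1, 1), cm$sample_ids)
  expect_equal(normalize_counts(cm, f2)$values[, 1], cm$counts[, 1] / 2)
  expect_true(all(normalize_counts(cm)$values[cm$counts == 0] == 0))
  expect_error(normalize_counts(cm, f1 * 0), "positive")
})

test_that("published normalized-count means are reproduced by inversion", {
  # counts = 10x the printed group means, size factors 10: the normalized
  # group means then equal the printed table exactly
  deg <- read_degs_fixture()
  counts <- cbind(q1 = deg$mean_qhmm * 10, q2 = deg$mean_qhmm * 10,
                  s1 = deg$mean_sth * 10, s2 = deg$mean_sth * 10)
  rownames(counts) <- deg$gene
  cm <- count_matrix(counts, rep(1000, nrow(deg)),
                     c(q1 = "QHMM", q2 = "QHMM", s1 = "STH", s2 = "STH"))
  norm <- normalize_counts(cm, stats::setNames(rep(10, 4), cm$sample_ids))
  m_q <- rowMeans(norm$values[, 1:2])
  m_s <- rowMeans(norm$values[, 3:4])
  expect_equal(unname(m_q), deg$mean_qhmm)
  expect_equal(unname(m_s), deg$mean_sth)
  # and their fold changes match the recomputed column
  expect_equal(log2_fold_change(m_q, m_s),
               log2(deg$mean_sth / deg$mean_qhmm), ignore_attr = TRUE)
})
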