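test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 300, seed = 7, n_terms = 12,
                    planted_terms = 2, relation_density = 5e-3)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  ann1 <- simulate_annotation(cfg, a$truth)
  ann2 <- simulate_annotation(cfg, b$truth)
  expect_identical(ann1$genesets, ann2$genesets)
  expect_identical(as.data.frame(simulate_relations(cfg, a$truth)),
                   as.data.frame(simulate_relations(cfg, a$truth)))
  genes <- names(which(a$truth$de_flags))[1:3]
  expect_identical(simulate_qpcr(a$truth, genes, cfg)$records,
                   simulate_qpcr(a$truth, genes, cfg)$records)
})

test_that("p_de = 0 plants nothing and the DE fraction is binomial", {
  cfg0 <- sim_config(n_genes = 200, p_de = 0, seed = 3)
  sim0 <- simulate_counts(cfg0)
  expect_false(any(sim0$truth$de_flags))
  expect_identical(unname(sim0$truth$true_lfc), rep(0, 200))

  cfg <- sim_config(n_genes = 5000, p_de = 0.1, seed = 42)
  sim <- simulate_counts(cfg)
  n_de <- sum(sim$truth$de_flags)
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.1)
  expect_gte(n_de, bounds[1])
  expect_lte(n_de, bounds[2])
  # planted genes have nonzero lfc, all with |lfc| above the location
  expect_true(all(abs(sim$truth$true_lfc[sim$truth$de_flags]) > 0.585))
  expect_true(all(sim$truth$true_lfc[!sim$truth$de_flags] == 0))
})

test_that("column sums track the size-factor-scaled expectation", {
  cfg <- sim_config(n_genes = 2000, n_modules = 0, seed = 11)
  sim <- simulate_counts(cfg)
  cs <- colSums(sim$counts$counts)
  expected <- sim$truth$expected_colsums
  phi <- sim$truth$dispersion
  # plug-in NB standard deviation of the column total
  for (j in seq_along(cs)) {
    mu <- sim$counts$counts[, j]
    sd_j <- sqrt(sum(mu + phi * mu^2))
    expect_lt(abs(cs[j] - expected[j]), 3 * sd_j)
  }
})

test_that("annotation hierarchy is a forest and plants are recorded", {
  cfg <- sim_config(n_genes = 400, seed = 5, n_terms = 30,
                    planted_terms = 4)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  expect_s3_class(ann, "annotation_set")  # constructor enforces acyclicity
  for (ns in unique(ann$hierarchy$namespace)) {
    h <- ann$hierarchy[ann$hierarchy$namespace == ns, ]
    expect_lte(nrow(h), 30 - 1)
    expect_true(all(h$child != h$parent))
  }
  expect_length(attr(ann, "enriched_terms"), 4)

  ann0 <- simulate_annotation(sim_config(n_genes = 400, seed = 5,
                                         n_terms = 30, planted_terms = 0),
                              sim$truth)
  expect_length(attr(ann0, "enriched_terms"), 0)
  expect_error(sim_config(n_terms = 3, planted_terms = 5), "planted_terms")
})

test_that("planted terms are recovered by the hypergeometric test", {
  # reduced seed count relative to the acceptance suite; same construction
  hits <- 0L
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    lfc <- ifelse(runif(5000) < 0.1, 1, 0)
    truth <- make_truth(lfc)
    cfg <- sim_config(n_genes = 5000, seed = s, n_terms = 20,
                      planted_terms = 1, planted_odds = 10)
    ann <- simulate_annotation(cfg, truth)
    planted <- attr(ann, "enriched_terms")
    res <- suppressMessages(
      fisher_enrich(names(which(truth$de_flags)), ann, "all"))
    hits <- hits + (res$p_value[res$term == planted] < 0.05)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("relation sampler respects density, vocabulary and simplicity", {
  cfg <- sim_config(n_genes = 60, seed = 9)
  truth <- make_truth(numeric(60))
  expect_equal(nrow(simulate_relations(cfg, truth, density = 0)), 0)
  rel <- simulate_relations(cfg, truth, density = 0.1)
  expect_true(all(rel$type %in% relation_types()))
  expect_true(all(rel$src != rel$dst))
  key <- paste(pmin(rel$src, rel$dst), pmax(rel$src, rel$dst))
  expect_false(any(duplicated(key)))
  n_pairs <- 60 * 59 / 2
  bounds <- qbinom(c(0.0005, 0.9995), n_pairs, 0.1)
  expect_gte(nrow(rel), bounds[1])
  expect_lte(nrow(rel), bounds[2])
})

test_that("qPCR plates encode expression and refuse a DE reference", {
  truth <- make_truth(c(0, 2, -1.2, 0.9), paste0("G", 1:4))
  cfg <- sim_config(n_genes = 4, seed = 2)
  plate <- simulate_qpcr(truth, c("G1", "G2"), cfg, noise_sd = 0)
  # slope-1, noiseless: ddCt is exactly -true_lfc, rq is 2^true_lfc
  q1 <- ddct(plate, "G1")
  expect_equal(q1$ddct, 0)
  expect_equal(q1$rq, 1)
  q2 <- ddct(plate, "G2")
  expect_equal(q2$ddct, -2)
  expect_equal(q2$rq, 4)
  expect_error(simulate_qpcr(truth, "G1", cfg, reference_gene = "G2"),
               "house-keeping")
})
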