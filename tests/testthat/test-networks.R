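net_from_edges <- function(edges, extra_nodes = character()) {
  ids <- unique(c(edges$src, edges$dst, extra_nodes))
  network(data.frame(id = ids), edges)
}

test_that("k-core: worked examples by hand", {
  tri <- net_from_edges(data.frame(src = c("a", "b", "c"),
                                   dst = c("b", "c", "a")))
  expect_equal(sort(unique(kcore_decompose(tri)$core)), 2)

  path3 <- net_from_edges(data.frame(src = c("a", "b"),
                                     dst = c("b", "c")))
  expect_true(all(kcore_decompose(path3)$core == 1))

  k4 <- as.data.frame(t(utils::combn(c("a", "b", "c", "d"), 2)))
  names(k4) <- c("src", "dst")
  k4p <- net_from_edges(rbind(k4, data.frame(src = "a", dst = "pend")))
  kc <- kcore_decompose(k4p)
  expect_equal(unname(kc$core[c("a", "b", "c", "d")]), rep(3L, 4))
  expect_equal(unname(kc$core["pend"]), 1L)
  expect_setequal(kc$hubs, c("a", "b", "c", "d"))
  expect_equal(kc$max_core, 3L)
})

test_that("k-core equals the brute-force peeling oracle", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    net <- random_network(n, runif(1, 0.05, 0.4))
    kc <- kcore_decompose(net)
    oracle <- kcore_bruteforce(net$nodes$id, net$edges)
    expect_equal(kc$core, oracle[names(kc$core)])
  }
})

test_that("core numbers never decrease when an edge is added", {
  set.seed(33)
  for (i in 1:20) {
    net <- random_network(12, 0.2)
    before <- kcore_decompose(net)$core
    ids <- net$nodes$id
    pairs <- t(utils::combn(ids, 2))
    key <- paste(pairs[, 1], pairs[, 2])
    have <- paste(pmin(net$edges$src, net$edges$dst),
                  pmax(net$edges$src, net$edges$dst))
    free <- which(!(key %in% have))
    if (!length(free)) next
    pick <- pairs[sample(free, 1), ]
    net$edges <- rbind(net$edges,
                       data.frame(src = pick[1], dst = pick[2]))
    after <- kcore_decompose(net)$core
    expect_true(all(after[names(before)] >= before))
  }
})

test_that("BH q-values: hand arithmetic, monotonicity, oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(44)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(q, stats::p.adjust(p, "BH"))  # independent implementation
})

test_that("co-expression network edges carry sign, r and q", {
  set.seed(55)
  base <- rnorm(5, 10, 2)
  expr <- rbind(g1 = base, g2 = base,            # duplicated gene: r = 1
                g3 = rnorm(5), g4 = rnorm(5))
  colnames(expr) <- paste0("s", 1:5)
  net <- suppressWarnings(coexpression_network(expr))
  e <- net$edges[net$edges$src == "g1" & net$edges$dst == "g2", ]
  expect_equal(nrow(e), 1)
  expect_equal(e$r, 1)
  expect_equal(e$q, 0)
  expect_equal(e$sign, "positive")

  # perfect anticorrelation -> negative edge
  expr2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(8, 6, 4, 2),
                 g3 = c(5, 1, 4, 2))
  colnames(expr2) <- paste0("s", 1:4)
  net2 <- suppressWarnings(coexpression_network(expr2))
  e2 <- net2$edges[net2$edges$src == "g1" & net2$edges$dst == "g2", ]
  expect_equal(e2$r, -1)
  expect_equal(e2$sign, "negative")

  # affine rescaling of a gene's vector changes nothing
  expr3 <- expr
  expr3["g3", ] <- expr3["g3", ] * 7 + 3
  net3 <- suppressWarnings(coexpression_network(expr3))
  expect_equal(net3$edges, net$edges)

  # zero-variance gene excluded with a log entry
  expr4 <- rbind(expr, g5 = rep(2, 5))
  expect_message(net4 <- suppressWarnings(coexpression_network(expr4)),
                 "zero-variance")
  expect_false("g5" %in% net4$nodes$id)
})

test_that("n = 3 feasibility bound: |r| > 0.997 needed for raw p < 0.05", {
  t_crit <- qt(0.975, df = 1)
  expect_equal(round(t_crit, 3), 12.706)
  r_min <- sqrt(t_crit^2 / (t_crit^2 + 1))  # invert t = r sqrt(df/(1-r^2))
  expect_equal(round(r_min, 3), 0.997)
  # pairs just below the bound are not significant at n = 3
  p_at <- function(r) 2 * pt(abs(r) * sqrt(1 / (1 - r^2)), df = 1,
                             lower.tail = FALSE)
  expect_gt(p_at(0.996), 0.05)
  expect_lt(p_at(0.9975), 0.05)
})

test_that("pathway-act network is the induced subgraph with degree", {
  rel <- relation_table(data.frame(
    src = c("A", "A", "X"), dst = c("B", "C", "B"),
    type = "activation", directed = TRUE))
  net <- pathway_act_network(c("A", "B", "C"), rel)
  expect_equal(nrow(net$edges), 2)
  expect_equal(attr(net, "central"), "A")
  expect_equal(net$nodes$degree[net$nodes$id == "A"], 2)
  # relations of non-significant pathways are irrelevant
  rel2 <- relation_table(data.frame(
    src = c("A", "A"), dst = c("B", "C"),
    type = "activation", directed = TRUE))
  net2 <- pathway_act_network(c("A", "B", "C"), rel2)
  expect_equal(net$edges$src, net2$edges$src)
  empty <- pathway_act_network(c("A", "B"), rel[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 2)
})

test_that("gene-act network keeps DEG-only typed edges", {
  rel <- relation_table(data.frame(
    src = c("g1", "g2", "g9"), dst = c("g2", "g3", "g1"),
    type = c("activation", "compound", "inhibition"),
    directed = c(TRUE, FALSE, TRUE)))
  calls <- c(g1 = "up", g2 = "down", g3 = "up")
  expect_message(net <- gene_act_network(calls, rel), "skipped")
  expect_equal(nrow(net$edges), 2)
  expect_equal(attr(net, "n_skipped"), 1)
  expect_equal(net$edges$type, c("activation", "compound"))
  expect_equal(net$nodes$direction[net$nodes$id == "g2"], "down")
  none <- gene_act_network(c(g1 = "none"), rel)
  expect_equal(nrow(none$edges), 0)
})

test_that("relation tables reject bad input", {
  expect_error(relation_table(data.frame(src = "a", dst = "a",
                                         type = "activation")), "self-loop")
  expect_error(relation_table(data.frame(src = "a", dst = "b",
                                         type = "frobnication")),
               "vocabulary")
})
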