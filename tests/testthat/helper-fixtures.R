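# Shared fixtures and independent oracles for the test suite.

extfile <- function(name) system.file("extdata", name, package = "ovitx")

read_mapping_fixture <- function() {
  read_mapping_summary(extfile("mapping_summary.tsv"))
}

read_degs_fixture <- function() {
  utils::read.delim(extfile("muscle_degs.tsv"), stringsAsFactors = FALSE)
}

read_focus_fixture <- function() {
  utils::read.delim(extfile("muscle_focus_terms.tsv"),
                    stringsAsFactors = FALSE)
}

# Small hand-made count matrix: 4 genes x 4 samples, two groups.
tiny_cm <- function() {
  counts <- matrix(c(10, 0, 5, 100,
                     12, 0, 6, 110,
                     50, 2, 4, 80,
                     55, 1, 6, 90), nrow = 4,
                   dimnames = list(paste0("g", 1:4),
                                   c("A_1", "A_2", "B_1", "B_2")))
  count_matrix(counts, lengths = c(1000, 2000, 500, 4000),
               groups = stats::setNames(c("A", "A", "B", "B"),
                                        c("A_1", "A_2", "B_1", "B_2")))
}

# Minimal sim_truth for generators that only need planted flags.
make_truth <- function(lfc, gene_ids = sprintf("G%05d", seq_along(lfc))) {
  structure(list(
    de_flags = stats::setNames(lfc != 0, gene_ids),
    true_lfc = stats::setNames(lfc, gene_ids),
    module_membership = stats::setNames(integer(length(lfc)), gene_ids),
    enriched_terms = character(),
    true_size_factors = numeric()), class = "sim_truth")
}

# Oracle: hypergeometric upper tail by direct enumeration of 2x2 tables.
hyper_tail_bruteforce <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Oracle: k-core by brute force - for each k, repeatedly delete any node
# with degree < k until stable; a node's core is the largest k at which it
# survives.
kcore_bruteforce <- function(nodes, edges) {
  core <- stats::setNames(integer(length(nodes)), nodes)
  k <- 1L
  repeat {
    alive <- nodes
    e <- edges
    repeat {
      deg <- table(factor(c(e$src, e$dst), levels = alive))
      drop <- names(deg)[deg < k]
      if (!length(drop)) break
      alive <- setdiff(alive, drop)
      e <- e[e$src %in% alive & e$dst %in% alive, , drop = FALSE]
    }
    if (!length(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# Random simple undirected graph as a network object.
random_network <- function(n_nodes, p_edge) {
  ids <- paste0("n", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2))
  pick <- stats::runif(nrow(pairs)) < p_edge
  network(data.frame(id = ids),
          data.frame(src = pairs[pick, 1], dst = pairs[pick, 2]))
}

# Oracle: Beta-NB marginal by trapezoid quadrature on a fine grid.
beta_nb_quadrature <- function(x, r, alpha, beta, grid_n = 1e5) {
  q <- seq(1e-9, 1 - 1e-9, length.out = grid_n)
  f <- stats::dbeta(q, alpha, beta)
  lik <- rep(1, grid_n)
  for (xi in seq_along(x))
    lik <- lik * stats::dnbinom(x[xi], size = r, prob = q)
  log(sum((lik * f)[-1] + (lik * f)[-grid_n]) / 2 * diff(q)[1])
}
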