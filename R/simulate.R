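#' Configuration for the two-breed synthetic study
#'
#' Describes the world the generators emulate: two groups of three biological
#' replicates, library sizes in the range of the study's unique-mapped totals,
#' negative-binomial counts with a planted fraction of DE genes whose effect
#' sizes straddle the 1.5-fold threshold, planted within-group co-expression
#' modules, planted enriched annotation terms, and Ct values consistent with
#' expression.
#'
#' @param n_genes number of genes.
#' @param n_reps_per_group biological replicates per group.
#' @param groups two group labels; fold-change direction is group 2 vs group 1.
#' @param lib_size_range range the per-sample expected totals are drawn from
#'   (defaults match the study's unique-mapped read totals).
#' @param p_de fraction of genes planted as differentially expressed.
#' @param lfc_location minimum planted |log2 fold change|.
#' @param lfc_scale mean of the exponential excess over `lfc_location`.
#' @param dispersion_shape,dispersion_rate gamma parameters of the per-gene
#'   dispersion sampler: phi = 0.005 + 1/Gamma(shape, rate).
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline expression
#'   (log2 scale); defaults span the observed normalized-count dynamic range.
#' @param length_log_mean,length_log_sd log-normal gene lengths (bp), around
#'   2.5 kb.
#' @param n_modules,module_size,module_rho planted co-expression modules:
#'   count, genes per module, and target within-module correlation.
#' @param n_terms annotation terms per namespace.
#' @param planted_terms number of terms with inflated DE membership odds.
#' @param planted_odds membership odds multiplier for DE genes in planted terms.
#' @param relation_density expected fraction of gene pairs with a typed
#'   relation.
#' @param qpcr_slope,qpcr_noise_sd Ct model: Ct = intercept - slope * log2
#'   (relative expression) + Normal(0, noise_sd).
#' @param seed master seed; each generator derives its own stream from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       n_reps_per_group = 3,
                       groups = c("QHMM", "STH"),
                       lib_size_range = c(12.8e6, 16.4e6),
                       p_de = 0.1,
                       lfc_location = 0.585,
                       lfc_scale = 0.8,
                       dispersion_shape = 3,
                       dispersion_rate = 0.15,
                       baseline_log2_mean = 5,
                       baseline_log2_sd = 2,
                       length_log_mean = log(2500),
                       length_log_sd = 0.6,
                       n_modules = 2,
                       module_size = 20,
                       module_rho = 0.9,
                       n_terms = 50,
                       planted_terms = 5,
                       planted_odds = 10,
                       relation_density = 2e-4,
                       qpcr_slope = 1.0,
                       qpcr_noise_sd = 0.15,
                       seed = 1L) {
  stopifnot(n_genes >= 1, n_reps_per_group >= 1, length(groups) == 2,
            length(lib_size_range) == 2, all(lib_size_range > 0),
            p_de >= 0, p_de < 1, lfc_location >= 0, lfc_scale > 0,
            module_rho > 0, module_rho < 1, n_modules >= 0, module_size >= 2,
            n_terms >= 1, planted_terms >= 0, planted_odds >= 1,
            relation_density >= 0, relation_density <= 1)
  if (planted_terms > n_terms)
    stop("planted_terms must not exceed n_terms")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Derive a deterministic per-stage stream from the master seed so stages are
# decoupled: regenerating the annotation never perturbs the counts.
stage_seed <- function(cfg, stage) {
  offset <- c(counts = 1L, annotation = 2L, relations = 3L, qpcr = 4L)[stage]
  as.integer((as.numeric(cfg$seed) * 48271 + offset * 10007) %% 2147483647)
}

#' Simulate a two-group NB count matrix with planted ground truth
#'
#' Counts are drawn gene-wise from a negative binomial with mean
#' `baseline_g * size_factor_j * 2^(lfc_g * [group == group2])` and per-gene
#' dispersion. Genes in a planted module additionally share a per-sample
#' latent factor scaling their means, inducing within-group correlation close
#' to `module_rho`.
#'
#' @param cfg a [sim_config].
#' @return list with elements `counts` (a [count_matrix]) and `truth` (class
#'   `sim_truth`: `de_flags`, `true_lfc`, `module_membership`,
#'   `enriched_terms` (filled by [simulate_annotation]), `true_size_factors`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, "counts"))
  G <- cfg$n_genes
  n <- cfg$n_reps_per_group
  gene_ids <- sprintf("G%05d", seq_len(G))
  samples <- c(paste0(cfg$groups[1], "_", seq_len(n)),
               paste0(cfg$groups[2], "_", seq_len(n)))
  groups <- stats::setNames(rep(cfg$groups, each = n), samples)

  baseline <- 2^stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  if (any(!is.finite(baseline)))
    stop("baseline sampler produced non-finite means; check configuration")
  lengths <- stats::rlnorm(G, cfg$length_log_mean, cfg$length_log_sd)
  phi <- 0.005 + 1 / stats::rgamma(G, cfg$dispersion_shape,
                                   rate = cfg$dispersion_rate)

  de_flags <- stats::runif(G) < cfg$p_de
  lfc <- numeric(G)
  nde <- sum(de_flags)
  if (nde) {
    mag <- cfg$lfc_location + stats::rexp(nde, rate = 1 / cfg$lfc_scale)
    lfc[de_flags] <- mag * sample(c(-1, 1), nde, replace = TRUE)
  }

  membership <- integer(G)
  if (cfg$n_modules > 0) {
    need <- cfg$n_modules * cfg$module_size
    if (need > G) stop("modules need more genes than simulated")
    # co-expression modules are planted among adequately expressed genes
    # (real hub genes are well expressed; shot noise at low counts would
    # also make the target correlation unreachable)
    eligible <- which(baseline >= stats::median(baseline))
    if (length(eligible) < need) eligible <- order(-baseline)[seq_len(need)]
    picked <- sample(eligible, need)
    membership[picked] <- rep(seq_len(cfg$n_modules), each = cfg$module_size)
  }

  lib_sizes <- stats::runif(2 * n, cfg$lib_size_range[1], cfg$lib_size_range[2])
  is_g2 <- groups == cfg$groups[2]
  # size factors make the expected column sum equal the drawn library size
  expr <- outer(baseline, as.numeric(is_g2), function(b, g) b) *
    2^outer(lfc, as.numeric(is_g2))
  sf <- lib_sizes / colSums(expr)
  mu <- sweep(expr, 2, sf, `*`)

  # Shared per-sample latent factors induce within-module correlation on
  # the linear (Pearson) scale. For module genes the factor IS the
  # biological variability, so their conditional dispersion is reduced to
  # the technical floor (otherwise NB noise, which scales with the factor,
  # caps the attainable correlation at 1/(1+phi)). Each gene's log-normal
  # loading a_i solves signal_CV2 / (signal_CV2 + NB_CV2) = rho exactly:
  # s = R*(1/mu + phi_c) / (1 - R*phi_c), R = rho/(1-rho), a = sqrt(log1p(s)).
  if (cfg$n_modules > 0) {
    phi_floor <- 0.005
    R <- cfg$module_rho / (1 - cfg$module_rho)
    for (m in seq_len(cfg$n_modules)) {
      idx <- which(membership == m)
      phi[idx] <- phi_floor
      nb_cv2 <- 1 / pmax(rowMeans(mu[idx, , drop = FALSE]), 1) + phi_floor
      s_sig <- R * nb_cv2 / (1 - R * phi_floor)
      a <- sqrt(log1p(s_sig))
      # the factor is drawn per sample but standardized within each group,
      # so the realized (not just population) within-group factor spread is
      # on target even with only a handful of replicates; groups get
      # independent factor realizations (no cross-group sharing)
      z <- stats::rnorm(2 * n)
      z <- as.vector(vapply(split(z, rep(1:2, each = n)),
                            function(u) (u - mean(u)) / stats::sd(u),
                            numeric(n)))
      mu[idx, ] <- mu[idx, ] * exp(a %o% z - a^2 / 2)
    }
  }
  if (any(!is.finite(mu))) stop("non-finite NB means; misconfigured sampler")

  counts <- matrix(stats::rnbinom(G * 2 * n, mu = mu,
                                  size = rep(1 / phi, 2 * n)),
                   nrow = G, dimnames = list(gene_ids, samples))
  truth <- structure(list(
    de_flags = stats::setNames(de_flags, gene_ids),
    true_lfc = stats::setNames(lfc, gene_ids),
    module_membership = stats::setNames(membership, gene_ids),
    enriched_terms = character(),
    true_size_factors = stats::setNames(sf, samples),
    dispersion = stats::setNames(phi, gene_ids),
    expected_colsums = stats::setNames(lib_sizes, samples)
  ), class = "sim_truth")
  list(counts = count_matrix(counts, lengths, groups), truth = truth)
}

#' Simulate an annotation collection with planted enriched terms
#'
#' Random term memberships over the simulated universe; the planted terms
#' sample their members with inflated odds for DE genes, so their
#' hypergeometric enrichment P is small by construction. The hierarchy is a
#' random forest over the terms of each namespace.
#'
#' @param cfg a [sim_config].
#' @param truth the `sim_truth` from [simulate_counts] run on the same config.
#' @return an [annotation_set]; planted term ids are also recorded in
#'   `attr(, "enriched_terms")`.
#' @export
simulate_annotation <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (cfg$planted_terms > cfg$n_terms)
    stop("planted_terms must not exceed n_terms")
  set.seed(stage_seed(cfg, "annotation"))
  universe <- names(truth$de_flags)
  namespaces <- c("biological_process", "molecular_function",
                  "cellular_component", "pathway")
  de <- truth$de_flags

  terms <- list(); genesets <- list(); hier <- list()
  planted <- character()
  for (ns in namespaces) {
    ids <- sprintf("%s:%04d", toupper(substr(ns, 1, 2)), seq_len(cfg$n_terms))
    n_planted <- if (cfg$planted_terms > 0 && ns == "biological_process")
      cfg$planted_terms else 0L
    sizes <- pmax(5L, pmin(length(universe),
                           round(exp(stats::runif(cfg$n_terms,
                                                  log(10), log(100))))))
    gs <- lapply(seq_len(cfg$n_terms), function(i) {
      w <- if (i <= n_planted) ifelse(de, cfg$planted_odds, 1) else
        rep(1, length(universe))
      sample(universe, sizes[i], prob = w)
    })
    names(gs) <- ids
    if (n_planted) planted <- c(planted, ids[seq_len(n_planted)])
    terms[[ns]] <- data.frame(
      id = ids,
      name = paste0("simulated ", gsub("_", " ", ns), " term ",
                    seq_len(cfg$n_terms)),
      namespace = ns)
    genesets <- c(genesets, gs)
    # random forest: first few terms are roots, the rest pick one earlier
    # parent within the namespace
    n_roots <- min(3L, cfg$n_terms)
    if (cfg$n_terms > n_roots) {
      child_idx <- (n_roots + 1L):cfg$n_terms
      parent_idx <- vapply(child_idx,
                           function(i) sample.int(i - 1L, 1L), 1L)
      hier[[ns]] <- data.frame(child = ids[child_idx],
                               parent = ids[parent_idx], namespace = ns)
    }
  }
  ann <- annotation_set(do.call(rbind, terms), genesets,
                        do.call(rbind, hier), universe)
  attr(ann, "enriched_terms") <- planted
  ann
}

#' Simulate a typed gene-gene (or pathway-pathway) relation table
#'
#' Edges are sampled uniformly over unordered id pairs at the configured
#' density, with types drawn from the closed interaction vocabulary.
#'
#' @param cfg a [sim_config].
#' @param truth the matching `sim_truth` (supplies the gene universe), or a
#'   character vector of ids via `ids`.
#' @param ids optional explicit id set overriding the gene universe.
#' @param density edge density; defaults to `cfg$relation_density`.
#' @return a [relation_table].
#' @export
simulate_relations <- function(cfg, truth = NULL, ids = NULL,
                               density = cfg$relation_density) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(ids)) ids <- names(truth$de_flags)
  set.seed(stage_seed(cfg, "relations"))
  G <- length(ids)
  n_pairs <- G * (G - 1) / 2
  n_edges <- stats::rbinom(1, n_pairs, density)
  if (n_edges == 0)
    return(relation_table(data.frame(src = character(), dst = character(),
                                     type = character(),
                                     directed = logical())))
  # sample unordered pairs without replacement via linear pair indices
  k <- sample(n_pairs, n_edges)
  i <- ceiling((2 * G - 1 - sqrt((2 * G - 1)^2 - 8 * k)) / 2)
  j <- k - (i - 1) * (2 * G - i) / 2 + i
  directed_types <- c("activation", "expression", "indirect effect",
                      "inhibition", "phosphorylation", "dephosphorylation",
                      "ubiquitination")
  type <- sample(RELATION_TYPES, n_edges, replace = TRUE)
  relation_table(data.frame(src = ids[i], dst = ids[j], type = type,
                            directed = type %in% directed_types))
}

#' Simulate a qPCR plate consistent with the planted expression truth
#'
#' Ct values follow `Ct = intercept - slope * log2(relative expression) +
#' Normal(0, noise_sd)`; the reference gene's expression is constant across
#' groups. Three animals by three technical replicates per group.
#'
#' @param truth the `sim_truth` from [simulate_counts].
#' @param genes gene ids to assay (must be simulated genes).
#' @param cfg the matching [sim_config].
#' @param reference_gene housekeeping gene id; defaults to `"ACTB"`, a
#'   synthetic constant-expression gene added to the plate. Passing a planted
#'   DE gene is refused.
#' @param noise_sd Ct noise; defaults to `cfg$qpcr_noise_sd`. Set 0 for a
#'   noiseless plate.
#' @return a [qpcr_plate] with the second group as test and the first as
#'   calibrator.
#' @export
simulate_qpcr <- function(truth, genes, cfg,
                          reference_gene = "ACTB",
                          noise_sd = cfg$qpcr_noise_sd) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  if (!all(genes %in% names(truth$de_flags)))
    stop("unknown gene(s): ",
         paste(setdiff(genes, names(truth$de_flags)), collapse = ", "))
  if (reference_gene %in% names(truth$de_flags) &&
      truth$de_flags[reference_gene])
    stop("reference gene ", reference_gene,
         " is planted DE; violates the house-keeping assumption")
  set.seed(stage_seed(cfg, "qpcr"))
  n <- cfg$n_reps_per_group
  samples <- c(paste0(cfg$groups[1], "_", seq_len(n)),
               paste0(cfg$groups[2], "_", seq_len(n)))
  grp <- rep(cfg$groups, each = n)
  all_genes <- unique(c(reference_gene, genes))
  intercept <- stats::setNames(stats::runif(length(all_genes), 22, 30),
                               all_genes)
  recs <- expand.grid(gene = all_genes, s = seq_along(samples),
                      replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  lfc <- ifelse(recs$gene == reference_gene, 0,
                truth$true_lfc[recs$gene])
  rel <- ifelse(grp[recs$s] == cfg$groups[2], lfc, 0)  # group1 = baseline
  ct <- intercept[recs$gene] - cfg$qpcr_slope * rel +
    stats::rnorm(nrow(recs), 0, noise_sd)
  qpcr_plate(data.frame(gene = recs$gene, sample = samples[recs$s],
                        group = grp[recs$s], replicate = recs$replicate,
                        ct = as.numeric(ct)),
             reference_gene = reference_gene,
             calibrator_group = cfg$groups[1])
}

#' Write a complete simulated input directory
#'
#' Generates counts, design, GMT annotation, OBO-lite hierarchy, relations,
#' qPCR plate and a ground-truth JSON, in the formats [run_pipeline] reads.
#'
#' @param cfg a [sim_config].
#' @param dir output directory (created if needed).
#' @param n_qpcr_genes how many planted-DE genes to put on the qPCR plate.
#' @return invisibly, a named character vector of the files written.
#' @export
simulate_to_dir <- function(cfg, dir, n_qpcr_genes = 9) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  sim$truth$enriched_terms <- attr(ann, "enriched_terms")
  rel <- simulate_relations(cfg, sim$truth)
  de_genes <- names(which(sim$truth$de_flags))
  qpcr_genes <- utils::head(de_genes[order(-abs(sim$truth$true_lfc[de_genes]))],
                            n_qpcr_genes)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             gmt = file.path(dir, "annotation.gmt"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             relations = file.path(dir, "relations.tsv"),
             qpcr = file.path(dir, "qpcr.tsv"),
             truth = file.path(dir, "truth.json"))
  write_counts_tsv(sim$counts, paths["counts"], paths["design"])
  write_gmt(ann, paths["gmt"], paths["hierarchy"])
  write_relations(rel, paths["relations"])
  if (length(qpcr_genes) >= 1) {
    plate <- simulate_qpcr(sim$truth, qpcr_genes, cfg)
    write_qpcr_tsv(plate, paths["qpcr"])
  } else paths <- paths[names(paths) != "qpcr"]
  jsonlite::write_json(
    list(de_flags = as.list(sim$truth$de_flags),
         true_lfc = as.list(sim$truth$true_lfc),
         module_membership = as.list(sim$truth$module_membership),
         enriched_terms = sim$truth$enriched_terms,
         true_size_factors = as.list(sim$truth$true_size_factors)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
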