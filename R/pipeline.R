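#' Pipeline configuration
#'
#' Single configuration object driving [run_pipeline]; can be loaded from a
#' YAML file and overridden by CLI flags. Fold-change direction is fixed
#' project-wide as group 2 vs group 1 (so "up" means higher in group 2).
#'
#' @param counts,design,annotation,hierarchy,relations,pathway_relations,qpcr
#'   input paths; `hierarchy`, `relations`, `pathway_relations` and `qpcr`
#'   may be `NULL` (stages degrade gracefully).
#' @param out_dir output directory.
#' @param groups two group labels in direction order; defaults to the order
#'   of first appearance in the design.
#' @param lfc_threshold,de_fdr,enrich_p,coexpr_fdr,top_k thresholds.
#' @param coexpr_samples `"per-group"` (faithful default) or `"pooled"`.
#' @param qpcr_reference,qpcr_calibrator reference gene and calibrator group
#'   for the validation stage.
#' @param focus_patterns optional name patterns selecting focus terms.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, annotation = NULL,
                            hierarchy = NULL, relations = NULL,
                            pathway_relations = NULL, qpcr = NULL,
                            out_dir = "ovitx_out", groups = NULL,
                            lfc_threshold = 0.585, de_fdr = 0.05,
                            enrich_p = 0.05, coexpr_fdr = 0.05,
                            top_k = 15,
                            coexpr_samples = c("per-group", "pooled"),
                            qpcr_reference = "ACTB",
                            qpcr_calibrator = NULL,
                            focus_patterns = NULL, seed = 1L) {
  coexpr_samples <- match.arg(coexpr_samples)
  stopifnot(lfc_threshold >= 0, de_fdr > 0, de_fdr < 1, enrich_p > 0,
            enrich_p < 1, coexpr_fdr > 0, coexpr_fdr < 1, top_k >= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config] arguments.
#' @param overrides named list of values taking precedence over the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Stages in order: quantification (upper-quartile factors + RPKM), the
#' empirical-Bayes DE test, term enrichment of the all/up/down DEG sets,
#' GO-tree construction, pathway-act / gene-act / per-group co-expression
#' networks with k-core numbers, and ddCt qPCR validation with concordance.
#' Every output is written under `cfg$out_dir` and listed in a checksum
#' manifest; identical config + inputs give an identical manifest.
#'
#' @param cfg a [pipeline_config].
#' @param skip_qpcr drop the qPCR stage even when an input is configured.
#' @return invisibly, a list with the manifest data.frame and the main
#'   in-memory results (`de`, `enrichment`, `networks`, ...).
#' @export
run_pipeline <- function(cfg, skip_qpcr = is.null(cfg$qpcr)) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  artifacts <- character()
  log_lines <- c(sprintf("thresholds: lfc=%g de_fdr=%g enrich_p=%g coexpr_fdr=%g top_k=%d",
                         cfg$lfc_threshold, cfg$de_fdr, cfg$enrich_p,
                         cfg$coexpr_fdr, cfg$top_k),
                 sprintf("coexpr_samples=%s seed=%d", cfg$coexpr_samples,
                         as.integer(cfg$seed)))

  cm <- read_counts_tsv(cfg$counts, cfg$design)
  groups <- cfg$groups
  if (is.null(groups)) groups <- unique(unname(cm$groups))

  # --- quantify ---------------------------------------------------------
  rp <- rpkm(cm)
  artifacts <- c(artifacts, write_expression_tsv(rp, out("rpkm.tsv")))
  uq <- upper_quartile_factors(cm)
  utils::write.table(data.frame(sample = names(uq), size_factor = uq),
                     out("uq_factors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts <- c(artifacts, out("uq_factors.tsv"))
  norm <- normalize_counts(cm, uq)

  # --- diffexpr ---------------------------------------------------------
  de <- de_test(cm, group_order = groups, norm = norm,
                lfc_threshold = cfg$lfc_threshold,
                fdr_threshold = cfg$de_fdr)
  artifacts <- c(artifacts, write_de_table(de, out("de_table.tsv")))
  calls <- stats::setNames(de$table$call, de$table$gene)
  degs <- names(calls)[calls != "none"]
  log_lines <- c(log_lines, sprintf("DEGs: %d total, %d up, %d down",
                                    length(degs), sum(calls == "up"),
                                    sum(calls == "down")))

  enr_all <- NULL; ann <- NULL
  if (!is.null(cfg$annotation)) {
    universe <- cm$gene_ids[rowSums(cm$counts) > 0]
    ann <- read_gmt(cfg$annotation, cfg$hierarchy, universe = NULL)
    # expression-aware universe: genes present in the matrix with counts
    ann$universe <- union(universe, unlist(ann$genesets))
    sets <- list(all = degs, up = names(calls)[calls == "up"],
                 down = names(calls)[calls == "down"])
    enr <- do.call(rbind, lapply(names(sets), function(lbl)
      fisher_enrich(intersect(sets[[lbl]], ann$universe), ann, lbl)))
    class(enr) <- c("enrichment_result", "data.frame")
    enr_all <- enr
    artifacts <- c(artifacts,
                   write_enrichment_tsv(enr, out("enrichment.tsv")))
    sig <- significant_terms(enr[enr$subset == "all", ], cfg$enrich_p)
    artifacts <- c(artifacts,
                   write_enrichment_tsv(top_k_report(
                     significant_terms(enr, cfg$enrich_p), cfg$top_k),
                     out("enrichment_topk.tsv")))

    # --- ontology_graph -------------------------------------------------
    go_sig <- sig[sig$namespace != "pathway", ]
    enr_sub <- enr[enr$subset == "all", ]
    tinfo <- ann$terms
    tinfo$p_value <- enr_sub$p_value[match(tinfo$id, enr_sub$term)]
    tree <- build_go_tree(go_sig$term, ann$hierarchy, term_info = tinfo)
    tn <- term_graph_as_network(tree)
    artifacts <- c(artifacts,
                   write_network_graphml(tn, out("go_tree.graphml")),
                   write_dot(tn, out("go_tree.dot"), "go_tree"))

    # --- pathway-act network --------------------------------------------
    if (!is.null(cfg$pathway_relations)) {
      prel <- read_relations(cfg$pathway_relations)
      psig <- sig[sig$namespace == "pathway", ]
      pnet <- pathway_act_network(
        psig$term, prel, stats::setNames(psig$p_value, psig$term))
      artifacts <- c(artifacts, write_sif(pnet, out("pathway_act.sif")),
                     write_network_graphml(pnet, out("pathway_act.graphml")))
    }
  }

  # --- gene-act network --------------------------------------------------
  if (!is.null(cfg$relations)) {
    rel <- read_relations(cfg$relations)
    gnet <- gene_act_network(calls[degs], rel)
    artifacts <- c(artifacts, write_sif(gnet, out("gene_act.sif")),
                   write_network_graphml(gnet, out("gene_act.graphml")))
  }

  # --- co-expression networks -------------------------------------------
  sel_genes <- if (!is.null(enr_all)) {
    sig_terms <- significant_terms(enr_all[enr_all$subset == "all", ],
                                   cfg$enrich_p)$term
    union_members <- unique(unlist(ann$genesets[sig_terms]))
    intersect(degs, union_members)
  } else degs
  coexpr <- list()
  if (length(sel_genes) >= 2) {
    expr_sel <- norm$values[sel_genes, , drop = FALSE]
    sample_sets <- if (cfg$coexpr_samples == "pooled")
      list(pooled = colnames(expr_sel)) else
        split(names(cm$groups), unname(cm$groups))
    for (gname in names(sample_sets)) {
      sub <- expr_sel[, sample_sets[[gname]], drop = FALSE]
      if (ncol(sub) < 3) next
      cnet <- suppressWarnings(
        coexpression_network(sub, alpha = cfg$coexpr_fdr))
      cnet <- with_core_numbers(cnet)
      coexpr[[gname]] <- cnet
      base <- paste0("coexpr_", gname)
      artifacts <- c(artifacts,
                     write_sif(cnet, out(paste0(base, ".sif")),
                               type_col = "sign"),
                     write_network_graphml(cnet, out(paste0(base, ".graphml"))))
      log_lines <- c(log_lines,
                     sprintf("coexpr %s: %d nodes, %d edges, max core %d",
                             gname, nrow(cnet$nodes), nrow(cnet$edges),
                             max(c(0L, cnet$nodes$core))))
    }
  }

  # --- qpcr --------------------------------------------------------------
  conc <- NULL
  if (!skip_qpcr && !is.null(cfg$qpcr)) {
    calib <- if (is.null(cfg$qpcr_calibrator)) groups[1] else
      cfg$qpcr_calibrator
    plate <- read_qpcr_tsv(cfg$qpcr, cfg$qpcr_reference, calib)
    rq <- rq_table(plate, test_group = setdiff(groups, calib)[1])
    artifacts <- c(artifacts, write_rq_tsv(rq, out("rq_table.tsv")))
    conc <- concordance(rq, de)
    log_lines <- c(log_lines, sprintf("qPCR concordance: %.3f",
                                      conc$fraction))
  }

  writeLines(log_lines, out("pipeline_log.txt"))
  artifacts <- c(artifacts, out("pipeline_log.txt"))
  manifest <- write_manifest(artifacts, out("manifest.json"))
  invisible(list(manifest = manifest, de = de, enrichment = enr_all,
                 coexpr = coexpr, concordance = conc,
                 out_dir = cfg$out_dir))
}
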