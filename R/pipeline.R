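# End-to-end orchestration: simulate -> differential expression ->
# categorization and impact score -> peak co-occupancy and annotation ->
# enrichment statistics -> interactome calls -> summary. Deterministic
# given the configuration's seed; every stage can also be run standalone
# on files through the io_* readers.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with every downstream threshold.
#' All randomness is funneled through `sim$seed`.
#'
#' @param sim A [sim_config()].
#' @param alpha Adjusted-p threshold for gene categorization.
#' @param fc_threshold Linear fold-change threshold for categorization.
#' @param is_cutoff Impact-score cutoff (default `-log2(1.5)`).
#' @param window Peak-annotation window in bp.
#' @param promoter_halfwidth Promoter halfwidth in bp.
#' @param qplex_lfc_cut,qplex_alpha Interactome call thresholds.
#' @param pseudocount Pseudocount for the DE stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05,
                            fc_threshold = 1.5, is_cutoff = -log2(1.5),
                            window = 10000, promoter_halfwidth = 3000,
                            qplex_lfc_cut = 0.5, qplex_alpha = 0.05,
                            pseudocount = 1) {
  stopifnot(inherits(sim, "sim_config"), fc_threshold > 1,
            alpha > 0, alpha <= 1, window >= 0, promoter_halfwidth >= 0)
  structure(list(sim = sim, alpha = alpha, fc_threshold = fc_threshold,
                 is_cutoff = is_cutoff, window = window,
                 promoter_halfwidth = promoter_halfwidth,
                 qplex_lfc_cut = qplex_lfc_cut, qplex_alpha = qplex_alpha,
                 pseudocount = pseudocount),
            class = "pipeline_config")
}

#' Run the full analysis on simulated inputs
#'
#' Generates the synthetic experiment, computes the two induction
#' contrasts (control and knockdown genotype), categorizes genes, scores
#' knockdown impact, intersects impaired genes with co-bound target genes,
#' tests preferential TF-peak loss at co-bound sites (observed/expected
#' chi-square), tests the multi-way overlap of the UP / impaired /
#' co-bound gene sets (exact multi-set intersection test), and calls the
#' bait interactome and its condition rewiring. When ground truth is
#' available (always, for simulated inputs), sensitivity and precision of
#' the recovered target and interactor sets are reported.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, per-stage TSVs and a
#'   `summary.tsv` are written there.
#' @return List with per-stage results (`contrast_scr`, `contrast_kd`,
#'   `categories`, `impact`, `targets`, `chi2`, `multiset`, `qplex_enrich`,
#'   `qplex_contrast`) and a flat `summary` (named numeric vector).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim

  rna <- simulate_counts(sim)
  genes <- simulate_gene_models(sim)
  pk <- simulate_peaks(sim, genes, rna$truth)
  tmt <- simulate_tmt(sim)

  contrast_scr <- de_contrast(rna$counts, rna$design, c("SCR", "Dox"),
                              c("SCR", "Con"), config$pseudocount)
  contrast_kd <- de_contrast(rna$counts, rna$design, c("KD", "Dox"),
                             c("KD", "Con"), config$pseudocount)
  categories <- categorize_genes(contrast_scr, config$fc_threshold,
                                 config$alpha)
  impact <- impact_score(contrast_scr, contrast_kd)
  impaired <- filter_impaired_activation(impact, categories,
                                         config$is_cutoff)
  cobound <- cobound_gene_set(pk$peaks$tf$dox, pk$peaks$cofactor$dox,
                              genes, config$window)
  targets <- select_dependent_targets(impaired, cobound)

  # preferential TF-peak loss at co-bound sites (knockdown vs induced)
  cs <- condition_specific_peaks(pk$peaks$tf$dox, pk$peaks$tf$kd)
  lost <- cs$a_only
  is_cobound <- overlap_hits(pk$peaks$tf$dox, pk$peaks$cofactor$dox)
  is_lost <- !overlap_hits(pk$peaks$tf$dox, pk$peaks$tf$kd)
  tab <- matrix(c(sum(is_cobound & is_lost), sum(is_cobound & !is_lost),
                  sum(!is_cobound & is_lost), sum(!is_cobound & !is_lost)),
                2, 2, byrow = TRUE,
                dimnames = list(c("cobound", "not_cobound"),
                                c("lost", "retained")))
  chi2 <- observed_expected_chi2(tab)

  up_set <- categories$gene_id[categories$category == "UP"]
  multiset <- multiset_intersection_test(
    list(up = up_set, impaired = impaired, cobound = cobound),
    n_universe = sim$n_genes
  )

  tmt_norm <- normalize_channels(tmt$intensities)
  qplex_enrich <- enrichment_call(tmt_norm, tmt$design, "Con",
                                  config$qplex_lfc_cut, config$qplex_alpha)
  qplex_contrast <- condition_contrast(tmt_norm, tmt$design,
                                       config$qplex_lfc_cut,
                                       config$qplex_alpha)

  recov <- function(called, truth_set) {
    tp <- length(intersect(called, truth_set))
    c(sensitivity = if (length(truth_set) > 0) tp / length(truth_set)
      else NA_real_,
      precision = if (length(called) > 0) tp / length(called) else NA_real_)
  }
  planted_targets <- rna$truth$gene_id[rna$truth$dependent]
  target_rec <- recov(targets, planted_targets)
  enriched_called <- qplex_enrich$protein[qplex_enrich$call == "enriched"]
  tmt_rec <- recov(enriched_called,
                   tmt$truth$protein_id[tmt$truth$enriched])

  summary <- c(
    n_genes = sim$n_genes,
    n_up = sum(categories$category == "UP"),
    n_down = sum(categories$category == "DOWN"),
    n_impaired = length(impaired),
    n_cobound_genes = length(cobound),
    n_targets = length(targets),
    target_sensitivity = unname(target_rec["sensitivity"]),
    target_precision = unname(target_rec["precision"]),
    cobound_lost = tab["cobound", "lost"],
    chi2 = chi2$chi2,
    chi2_oe_ratio = chi2$oe_ratio,
    chi2_log10p = log10(max(chi2$p, .Machine$double.xmin)),
    multiset_fold = multiset$fold,
    multiset_log10p = log10(max(multiset$p, .Machine$double.xmin)),
    n_interactors = sum(qplex_enrich$call == "enriched"),
    n_rewired_up = sum(qplex_contrast$call == "enriched"),
    n_rewired_down = sum(qplex_contrast$call == "depleted"),
    tmt_sensitivity = unname(tmt_rec["sensitivity"]),
    tmt_precision = unname(tmt_rec["precision"])
  )

  res <- list(config = config, contrast_scr = contrast_scr,
              contrast_kd = contrast_kd, categories = categories,
              impact = impact, impaired = impaired, cobound = cobound,
              targets = targets, lost_peaks = lost, chi2 = chi2,
              multiset = multiset, qplex_enrich = qplex_enrich,
              qplex_contrast = qplex_contrast, truth = rna$truth,
              tmt_truth = tmt$truth, summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_contrast_table(contrast_scr, file.path(outdir, "contrast_scr.tsv"))
    write_contrast_table(contrast_kd, file.path(outdir, "contrast_kd.tsv"))
    write_tsv_plain(categories, file.path(outdir, "categories.tsv"))
    imp <- impact
    imp$category <- categories$category[match(imp$gene_id,
                                              categories$gene_id)]
    imp$passes_filter <- imp$gene_id %in% impaired
    write_tsv_plain(imp, file.path(outdir, "impact_score.tsv"))
    writeLines(targets, file.path(outdir, "targets.txt"))
    write_tsv_plain(qplex_enrich, file.path(outdir, "interactome.tsv"))
    write_tsv_plain(qplex_contrast,
                    file.path(outdir, "interactome_contrast.tsv"))
    s <- data.frame(metric = names(summary),
                    value = sprintf("%.10g", summary))
    write_tsv_plain(s, file.path(outdir, "summary.tsv"))
  }
  res
}
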