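# Gene categorization, the knockdown impact score, and selection of
# cofactor-dependent TF targets. The impact score of a gene is the
# induction log2 fold change under knockdown minus the induction log2 fold
# change under control; negative values mean the knockdown attenuates
# activation (or enhances inhibition).

#' Categorize genes from an induction contrast
#'
#' UP iff `adj_p <= alpha` and `log2fc >= log2(fc_threshold)`; DOWN iff
#' `adj_p <= alpha` and `log2fc <= -log2(fc_threshold)`; otherwise
#' UNCHANGED. Genes with undefined p-values are NOT_TESTED. Thresholds are
#' applied inclusively and recorded in the result's attributes.
#'
#' @param contrast A `contrast_result` data frame.
#' @param fc_threshold Linear fold-change threshold (> 1); default 1.5.
#' @param alpha Adjusted-p threshold; default 0.05.
#' @return Data frame (`gene_id`, `category`) with thresholds in
#'   `attr(, "thresholds")`.
#' @export
categorize_genes <- function(contrast, fc_threshold = 1.5, alpha = 0.05) {
  if (fc_threshold <= 1)
    stop("configuration error: fc_threshold must exceed 1")
  lcut <- log2(fc_threshold)
  cat <- rep("UNCHANGED", nrow(contrast))
  tested <- !is.na(contrast$p) & !is.na(contrast$adj_p)
  cat[!tested] <- "NOT_TESTED"
  sig <- tested & contrast$adj_p <= alpha
  cat[sig & contrast$log2fc >= lcut] <- "UP"
  cat[sig & contrast$log2fc <= -lcut] <- "DOWN"
  out <- data.frame(gene_id = contrast$gene, category = cat,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(fc_threshold = fc_threshold, alpha = alpha)
  out
}

#' Knockdown impact score
#'
#' Joins two induction contrasts by gene id and computes, per gene,
#' `IS = log2fc(knockdown induction) - log2fc(control induction)`. Genes
#' missing from either contrast are dropped and their count reported via
#' a message and `attr(, "n_dropped")`.
#'
#' @param contrast_scr Induction contrast in the control genotype
#'   (e.g. SCR+Dox vs SCR-Con).
#' @param contrast_kd Induction contrast in the knockdown genotype.
#' @return Data frame (`gene_id`, `lfc_scr`, `lfc_kd`, `impact_score`).
#' @export
impact_score <- function(contrast_scr, contrast_kd) {
  common <- intersect(contrast_scr$gene, contrast_kd$gene)
  if (length(common) == 0) stop("no genes shared between the two contrasts")
  n_dropped <- length(union(contrast_scr$gene, contrast_kd$gene)) -
    length(common)
  if (n_dropped > 0)
    message(n_dropped, " gene(s) absent from one contrast were dropped")
  lfc_scr <- contrast_scr$log2fc[match(common, contrast_scr$gene)]
  lfc_kd <- contrast_kd$log2fc[match(common, contrast_kd$gene)]
  out <- data.frame(gene_id = common, lfc_scr = lfc_scr, lfc_kd = lfc_kd,
                    impact_score = lfc_kd - lfc_scr,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Genes whose activation is impaired by the knockdown
#'
#' Returns the genes that are categorized UP in the control induction and
#' whose impact score is at most `is_cutoff` (default `-log2(1.5)`,
#' a 1.5-fold reduction in activation), sorted by impact score ascending
#' (most impaired first), ties broken by gene id.
#'
#' @param records Impact-score data frame from [impact_score()].
#' @param categories Category data frame from [categorize_genes()].
#' @param is_cutoff Impact-score cutoff (log2 units); default `-log2(1.5)`.
#' @return Character vector of gene ids.
#' @export
filter_impaired_activation <- function(records, categories,
                                       is_cutoff = -log2(1.5)) {
  up <- categories$gene_id[categories$category == "UP"]
  hit <- records[records$gene_id %in% up &
                   records$impact_score <= is_cutoff, , drop = FALSE]
  hit <- hit[order(hit$impact_score, hit$gene_id), , drop = FALSE]
  hit$gene_id
}

#' Intersect impaired genes with co-bound target genes
#'
#' The final cofactor-dependent TF target list: genes whose activation is
#' impaired by the knockdown and whose promoter-proximal region carries a
#' co-bound peak. Order of `impaired` (impact score ascending) is
#' preserved.
#'
#' @param impaired Character vector from [filter_impaired_activation()].
#' @param cobound_genes Character vector of co-bound gene ids, typically
#'   from [cobound_gene_set()].
#' @return Character vector of target gene ids.
#' @export
select_dependent_targets <- function(impaired, cobound_genes) {
  impaired[impaired %in% cobound_genes]
}
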