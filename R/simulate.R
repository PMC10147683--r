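# Synthetic-data generator: negative-binomial counts under a 2x2
# genotype x treatment factorial, peak sets with planted co-binding and
# knockdown-specific loss, and log-normal TMT intensities, all with
# recorded ground truth. One RNG stream per modality (derived from the
# master seed by fixed offsets) so modalities can be regenerated
# independently.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic experiment: a 2x2
#' factorial (control vs knockdown genotype, untreated vs induced) with
#' planted induction-responsive genes, a subset of induced genes whose
#' activation is attenuated in the knockdown ("dependent" genes), promoter
#' co-binding of a transcription factor and a cofactor at dependent genes,
#' preferential loss of TF peaks at co-bound sites upon knockdown, and a
#' TMT interactome with bait-enriched and condition-rewired proteins.
#'
#' @param n_genes Number of genes.
#' @param n_chroms Number of synthetic chromosomes (named `chrS1...`).
#' @param chrom_length Length of each chromosome in bp.
#' @param samples_per_cell Replicates per factorial cell.
#' @param nb_dispersion Shared negative-binomial dispersion; variance is
#'   `mu + dispersion * mu^2`.
#' @param base_mean_log2 Mean of the log2 baseline expression; per-gene
#'   baselines are drawn around it with unit spread.
#' @param frac_up,frac_down Proportions of induction-responsive genes
#'   (up- and downregulated by treatment); must sum to at most 1.
#' @param lfc_up,lfc_down Planted log2 fold changes for up/down genes
#'   (`lfc_down` is negative).
#' @param frac_dependent Proportion of planted-up genes whose induction is
#'   attenuated in the knockdown genotype.
#' @param attenuation_lfc Planted reduction (log2 units) of the induction
#'   fold change in the knockdown, for dependent genes.
#' @param peak_width Width of every simulated peak in bp.
#' @param frac_cobound Proportion of dependent genes given a co-bound
#'   (TF + cofactor) promoter peak.
#' @param n_background_peaks Background peaks per factor, placed uniformly
#'   in TSS-free regions.
#' @param loss_cobound,loss_other Probability that a TF peak is lost in the
#'   knockdown condition, for co-bound and non-co-bound peaks respectively.
#' @param tmt_n_proteins,tmt_n_enriched,tmt_n_rewired TMT design: total
#'   proteins, bait-enriched proteins, and enriched proteins additionally
#'   rewired between conditions.
#' @param tmt_lfc Planted bait-over-IgG log2 enrichment.
#' @param tmt_rewire_lfc Additional log2 shift of rewired proteins in the
#'   induced condition.
#' @param seed Master integer seed; fixed seed implies byte-identical
#'   outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, n_chroms = 5, chrom_length = 4e7,
                       samples_per_cell = 3, nb_dispersion = 0.02,
                       base_mean_log2 = 9, frac_up = 0.10, frac_down = 0.10,
                       lfc_up = 2, lfc_down = -2, frac_dependent = 0.08,
                       attenuation_lfc = 1.5, peak_width = 400,
                       frac_cobound = 1, n_background_peaks = 1000,
                       loss_cobound = 0.44, loss_other = 0.07,
                       tmt_n_proteins = 500, tmt_n_enriched = 30,
                       tmt_n_rewired = 10, tmt_lfc = 2,
                       tmt_rewire_lfc = 1.5, seed = 1) {
  cfg <- list(
    n_genes = n_genes, n_chroms = n_chroms, chrom_length = chrom_length,
    samples_per_cell = samples_per_cell, nb_dispersion = nb_dispersion,
    base_mean_log2 = base_mean_log2, frac_up = frac_up,
    frac_down = frac_down, lfc_up = lfc_up, lfc_down = lfc_down,
    frac_dependent = frac_dependent, attenuation_lfc = attenuation_lfc,
    peak_width = peak_width, frac_cobound = frac_cobound,
    n_background_peaks = n_background_peaks, loss_cobound = loss_cobound,
    loss_other = loss_other, tmt_n_proteins = tmt_n_proteins,
    tmt_n_enriched = tmt_n_enriched, tmt_n_rewired = tmt_n_rewired,
    tmt_lfc = tmt_lfc, tmt_rewire_lfc = tmt_rewire_lfc,
    seed = as.integer(seed)
  )
  props <- c("frac_up", "frac_down", "frac_dependent", "frac_cobound",
             "loss_cobound", "loss_other")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop("configuration error: ", p, " must lie in [0, 1]")
  }
  if (cfg$frac_up + cfg$frac_down > 1)
    stop("configuration error: frac_up + frac_down > 1")
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be positive")
  if (cfg$chrom_length <= 20 * cfg$peak_width)
    stop("configuration error: chrom_length must exceed 20 * peak_width")
  if (cfg$tmt_n_enriched > cfg$tmt_n_proteins)
    stop("configuration error: tmt_n_enriched > tmt_n_proteins")
  if (cfg$tmt_n_rewired > cfg$tmt_n_enriched)
    stop("configuration error: tmt_n_rewired > tmt_n_enriched")
  if (cfg$samples_per_cell < 2)
    stop("configuration error: need >= 2 replicates per cell")
  class(cfg) <- "sim_config"
  cfg
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# modality-specific RNG streams derived from the master seed
seed_for <- function(config, modality) {
  offset <- c(counts = 101L, peaks = 202L, tmt = 303L)[[modality]]
  (config$seed + offset) %% .Machine$integer.max
}

#' Simulate a factorial RNA-seq count matrix
#'
#' Draws gene-by-sample counts from a negative binomial with gene-specific
#' mean `2^(baseline + planted lfc terms) * library-size factor` and a
#' shared dispersion. The design covers four cells: SCR-Con, SCR+Dox,
#' KD-Con and KD+Dox. Library-size factors are drawn log-uniform in
#' [0.7, 1.4] to exercise normalization.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (integer matrix), `design` (sample design
#'   data frame) and `truth` (per-gene data frame: `gene_id`, `category`
#'   in up/down/null, `dependent` flag, planted `lfc_scr` and `lfc_kd`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_for(config, "counts"))
  n <- config$n_genes
  ids <- gene_ids(n)

  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  category <- rep("null", n)
  responsive <- sample.int(n, n_up + n_down)
  category[responsive[seq_len(n_up)]] <- "up"
  if (n_down > 0) category[responsive[n_up + seq_len(n_down)]] <- "down"
  dependent <- rep(FALSE, n)
  up_idx <- which(category == "up")
  n_dep <- round(config$frac_dependent * n_up)
  if (n_dep > 0) dependent[sample(up_idx, n_dep)] <- TRUE

  lfc_scr <- ifelse(category == "up", config$lfc_up,
                    ifelse(category == "down", config$lfc_down, 0))
  lfc_kd <- lfc_scr
  lfc_kd[dependent] <- lfc_kd[dependent] - config$attenuation_lfc

  base_log2 <- stats::rnorm(n, config$base_mean_log2, 1)

  cells <- expand.grid(replicate = seq_len(config$samples_per_cell),
                       treatment = c("Con", "Dox"),
                       genotype = c("SCR", "KD"),
                       stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = paste(cells$genotype, cells$treatment, cells$replicate,
                      sep = "_"),
    genotype = cells$genotype, treatment = cells$treatment,
    replicate = cells$replicate, stringsAsFactors = FALSE
  )
  n_s <- nrow(design)
  size_factor <- exp(stats::runif(n_s, log(0.7), log(1.4)))

  counts <- matrix(0L, n, n_s, dimnames = list(ids, design$sample_id))
  for (j in seq_len(n_s)) {
    eff <- if (design$treatment[j] == "Con") 0 else
      if (design$genotype[j] == "SCR") lfc_scr else lfc_kd
    mu <- 2^(base_log2 + eff) * size_factor[j]
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }

  truth <- data.frame(gene_id = ids, category = category,
                      dependent = dependent, lfc_scr = lfc_scr,
                      lfc_kd = lfc_kd, stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth,
       size_factor = stats::setNames(size_factor, design$sample_id))
}

#' Place gene models on the synthetic genome
#'
#' TSSs are laid out deterministically at even spacing along chromosomes
#' `chrS1..chrSn`, with alternating strand, leaving TSS-free gaps where
#' background peaks can be placed without falling inside any annotation
#' window.
#'
#' @param config A [sim_config()].
#' @return A gene-model data frame (`gene_id`, `chrom`, `strand`, `tss`)
#'   in the same gene order as [simulate_counts()].
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chroms)
  spacing <- floor(config$chrom_length / (per_chrom + 1))
  if (spacing <= 4 * config$peak_width)
    stop("generation error: genome too small for the requested gene count")
  idx <- seq_len(n) - 1
  chrom_i <- idx %/% per_chrom + 1
  pos_i <- idx %% per_chrom + 1
  data.frame(
    gene_id = gene_ids(n),
    chrom = paste0("chrS", chrom_i),
    strand = ifelse(idx %% 2 == 0, "+", "-"),
    tss = pos_i * spacing,
    stringsAsFactors = FALSE
  )
}

# non-overlapping background peak placement: partition the TSS-free gaps
# into slots of 2*peak_width and sample slots without replacement
place_background <- function(config, genes, n_peaks, tss_clear) {
  w <- config$peak_width
  slot <- 2 * w
  slots <- list()
  for (ch in unique(genes$chrom)) {
    tss <- sort(genes$tss[genes$chrom == ch])
    bounds <- c(0, tss, config$chrom_length)
    for (i in seq_len(length(bounds) - 1)) {
      lo <- bounds[i] + tss_clear
      hi <- bounds[i + 1] - tss_clear - w
      if (hi - lo >= slot) {
        starts <- seq(lo, hi, by = slot)
        slots[[length(slots) + 1]] <-
          data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
      }
    }
  }
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_peaks)
    stop("generation error: genome too small to place ", n_peaks,
         " background peaks without overlap")
  pick <- slots[sample.int(nrow(slots), n_peaks), , drop = FALSE]
  pick[order(pick$chrom, pick$start), , drop = FALSE]
}

#' Simulate TF and cofactor peak sets
#'
#' Dependent genes (a `frac_cobound` fraction of them) receive overlapping
#' cofactor and TF peaks centered on their TSS in the induced condition;
#' background peaks for each factor are placed uniformly in TSS-free
#' regions with at least one peak-width of separation. In the knockdown
#' condition each TF peak is retained independently, with loss probability
#' `loss_cobound` at co-bound sites and `loss_other` elsewhere.
#'
#' @param config A [sim_config()].
#' @param genes Gene models from [simulate_gene_models()].
#' @param truth Gene-level ground truth from [simulate_counts()].
#' @param tss_clear Minimum distance (bp) between a background peak and any
#'   TSS; defaults to 12000 so background peaks fall outside a 10 kb
#'   annotation window.
#' @return A list with `peaks` (nested list: `cofactor$dox`, `tf$dox`,
#'   `tf$kd`, each a [peak_set()]) and `peak_truth` (per TF peak: name,
#'   `cobound` flag, `target_gene`, `lost_in_kd` flag).
#' @export
simulate_peaks <- function(config, genes, truth, tss_clear = 12000) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_for(config, "peaks"))
  w <- config$peak_width
  half <- floor(w / 2)

  dep <- truth$gene_id[truth$dependent]
  n_cb <- round(config$frac_cobound * length(dep))
  cb_genes <- if (n_cb > 0) sort(sample(dep, n_cb)) else character()
  gi <- match(cb_genes, genes$gene_id)
  prom_start <- genes$tss[gi] - half
  prom_start[prom_start < 0] <- 0
  promoter <- data.frame(chrom = genes$chrom[gi], start = prom_start,
                         gene = cb_genes, stringsAsFactors = FALSE)

  bg_tf <- place_background(config, genes, config$n_background_peaks,
                            tss_clear)
  bg_cf <- place_background(config, genes, config$n_background_peaks,
                            tss_clear)

  tf_chrom <- c(promoter$chrom, bg_tf$chrom)
  tf_start <- c(promoter$start, bg_tf$start)
  # sprintf (unlike paste0) keeps zero-length inputs zero-length
  tf_name <- c(sprintf("tf_prom_%s", promoter$gene),
               sprintf("tf_bg_%04d", seq_len(nrow(bg_tf))))
  tf_cobound <- c(rep(TRUE, nrow(promoter)), rep(FALSE, nrow(bg_tf)))
  tf_target <- c(promoter$gene, rep(NA_character_, nrow(bg_tf)))

  loss_p <- ifelse(tf_cobound, config$loss_cobound, config$loss_other)
  lost <- stats::runif(length(loss_p)) < loss_p

  tf_dox <- peak_set(tf_chrom, tf_start, tf_start + w, name = tf_name)
  keep <- !lost
  tf_kd <- peak_set(tf_chrom[keep], tf_start[keep], tf_start[keep] + w,
                    name = tf_name[keep])
  cf_dox <- peak_set(c(promoter$chrom, bg_cf$chrom),
                     c(promoter$start, bg_cf$start),
                     c(promoter$start, bg_cf$start) + w,
                     name = c(sprintf("cf_prom_%s", promoter$gene),
                              sprintf("cf_bg_%04d", seq_len(nrow(bg_cf)))))

  peak_truth <- data.frame(name = tf_name, cobound = tf_cobound,
                           target_gene = tf_target, lost_in_kd = lost,
                           stringsAsFactors = FALSE)
  list(peaks = list(cofactor = list(dox = cf_dox),
                    tf = list(dox = tf_dox, kd = tf_kd)),
       peak_truth = peak_truth)
}

#' Simulate a TMT interactome experiment
#'
#' Log-normal intensities over a 10-channel design (3 bait + 2 IgG channels
#' per condition). Planted-enriched proteins are elevated by `tmt_lfc` in
#' bait channels over IgG; a subset is additionally shifted by
#' `tmt_rewire_lfc` in the induced-condition bait channels. Channel totals
#' are perturbed by known log-uniform scaling factors.
#'
#' @param config A [sim_config()].
#' @return A list with `intensities` (protein x channel matrix), `design`
#'   (channel design), `truth` (per protein: `enriched`, `rewired`) and
#'   `channel_factor` (the planted scaling factors).
#' @export
simulate_tmt <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_for(config, "tmt"))
  np <- config$tmt_n_proteins
  ids <- sprintf("P%04d", seq_len(np))
  enriched <- rep(FALSE, np)
  # a zero planted effect means nothing is enriched, whatever the count
  if (config$tmt_lfc != 0 && config$tmt_n_enriched > 0)
    enriched[sample.int(np, config$tmt_n_enriched)] <- TRUE
  rewired <- rep(FALSE, np)
  if (config$tmt_n_rewired > 0 && any(enriched))
    rewired[sample(which(enriched), min(config$tmt_n_rewired,
                                        sum(enriched)))] <- TRUE

  design <- data.frame(
    channel_id = c(paste0("bait_Con_", 1:3), paste0("bait_Dox_", 1:3),
                   paste0("IgG_Con_", 1:2), paste0("IgG_Dox_", 1:2)),
    pulldown = c(rep("bait", 6), rep("IgG", 4)),
    condition = c(rep("Con", 3), rep("Dox", 3), rep("Con", 2),
                  rep("Dox", 2)),
    replicate = c(1:3, 1:3, 1:2, 1:2), stringsAsFactors = FALSE
  )
  nc <- nrow(design)
  base <- stats::rnorm(np, 20, 2)
  m <- matrix(0, np, nc, dimnames = list(ids, design$channel_id))
  for (j in seq_len(nc)) {
    lv <- base
    if (design$pulldown[j] == "bait") {
      lv <- lv + enriched * config$tmt_lfc
      if (design$condition[j] == "Dox")
        lv <- lv + rewired * config$tmt_rewire_lfc
    }
    m[, j] <- 2^(lv + stats::rnorm(np, 0, 0.3))
  }
  channel_factor <- exp(stats::runif(nc, log(0.7), log(1.4)))
  m <- sweep(m, 2, channel_factor, `*`)
  truth <- data.frame(protein_id = ids, enriched = enriched,
                      rewired = rewired, stringsAsFactors = FALSE)
  list(intensities = m, design = design, truth = truth,
       channel_factor = stats::setNames(channel_factor, design$channel_id))
}

#' Write all synthetic inputs to a directory
#'
#' Emits the counts TSV, sample design, gene models, BED peak files per
#' factor/condition, TMT intensities, channel design and the ground-truth
#' tables, so the full pipeline can be rerun from files alone.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_to_dir <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rna <- simulate_counts(config)
  genes <- simulate_gene_models(config)
  pk <- simulate_peaks(config, genes, rna$truth)
  tmt <- simulate_tmt(config)
  write_counts(rna$counts, file.path(dir, "counts.tsv"))
  write_design(rna$design, file.path(dir, "design.tsv"))
  write_gene_models(genes, file.path(dir, "gene_models.tsv"))
  write_bed(pk$peaks$cofactor$dox, file.path(dir, "cofactor_dox.bed"))
  write_bed(pk$peaks$tf$dox, file.path(dir, "tf_dox.bed"))
  write_bed(pk$peaks$tf$kd, file.path(dir, "tf_kd.bed"))
  write_tmt(tmt$intensities, file.path(dir, "tmt.tsv"))
  write_channel_design(tmt$design, file.path(dir, "channel_design.tsv"))
  write_tsv_plain(rna$truth, file.path(dir, "gene_truth.tsv"))
  write_tsv_plain(pk$peak_truth, file.path(dir, "peak_truth.tsv"))
  write_tsv_plain(tmt$truth, file.path(dir, "protein_truth.tsv"))
  invisible(list(rna = rna, genes = genes, peaks = pk, tmt = tmt))
}
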