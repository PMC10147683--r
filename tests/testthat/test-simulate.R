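test_that("simulation is deterministic and validates its configuration", {
  cfg <- sim_config(n_genes = 300, n_background_peaks = 50, seed = 7)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_tmt(cfg)$intensities,
                   simulate_tmt(cfg)$intensities)
  g <- simulate_gene_models(cfg)
  pa <- simulate_peaks(cfg, g, a$truth)
  pb <- simulate_peaks(cfg, g, a$truth)
  expect_identical(pa$peaks, pb$peaks)

  expect_error(sim_config(frac_up = 1.2), "frac_up")
  expect_error(sim_config(frac_up = 0.6, frac_down = 0.6),
               "frac_up \\+ frac_down")
  expect_error(sim_config(tmt_n_enriched = 10, tmt_n_proteins = 5),
               "tmt_n_enriched")
  expect_error(sim_config(chrom_length = 100, peak_width = 400),
               "chrom_length")
})

test_that("degenerate configurations plant no effects", {
  cfg <- sim_config(n_genes = 200, frac_up = 0, frac_down = 0,
                    n_background_peaks = 10, seed = 3)
  rna <- simulate_counts(cfg)
  expect_true(all(rna$truth$lfc_scr == 0))
  expect_true(all(rna$truth$lfc_kd == 0))
  expect_true(all(rna$truth$category == "null"))

  g <- simulate_gene_models(cfg)
  pk <- simulate_peaks(sim_config(n_genes = 200, frac_up = 0,
                                  frac_down = 0, n_background_peaks = 0,
                                  seed = 3), g, rna$truth)
  expect_equal(nrow(pk$peaks$tf$dox), 0)
  expect_equal(nrow(pk$peaks$cofactor$dox), 0)

  tmt0 <- simulate_tmt(sim_config(n_genes = 200, tmt_lfc = 0, seed = 3))
  expect_false(any(tmt0$truth$enriched))
})

test_that("negative-binomial means and planted effects are recoverable", {
  # NB draws at mu = 100, dispersion 0.1 recover the mean within MC error
  set.seed(11)
  n_draws <- 10000
  mu <- 100; disp <- 0.1
  draws <- matrix(stats::rnbinom(20 * n_draws, mu = mu, size = 1 / disp),
                  nrow = 20)
  se <- sqrt(mu + disp * mu^2) / sqrt(n_draws)
  expect_true(all(abs(rowMeans(draws) - mu) < 3 * se))

  # empirical induction log2FC of planted-up genes converges to lfc_up
  cfg <- sim_config(n_genes = 400, samples_per_cell = 50,
                    nb_dispersion = 0.05, lfc_up = 2, seed = 5)
  rna <- simulate_counts(cfg)
  sf <- rna$size_factor
  norm <- sweep(rna$counts, 2, sf, `/`)
  dox <- rna$design$sample_id[rna$design$genotype == "SCR" &
                                rna$design$treatment == "Dox"]
  con <- rna$design$sample_id[rna$design$genotype == "SCR" &
                                rna$design$treatment == "Con"]
  up <- rna$truth$category == "up"
  lfc_hat <- log2(rowMeans(norm[up, dox]) / rowMeans(norm[up, con]))
  # 3 standard errors of the mean across planted-up genes
  expect_lt(abs(mean(lfc_hat) - 2), 3 * sd(lfc_hat) / sqrt(sum(up)))
})

test_that("planted co-binding and knockdown loss follow the configuration", {
  cfg <- sim_config(n_genes = 1000, frac_cobound = 1,
                    n_background_peaks = 2000, loss_cobound = 0.44,
                    loss_other = 0.07, seed = 9)
  rna <- simulate_counts(cfg)
  genes <- simulate_gene_models(cfg)
  pk <- simulate_peaks(cfg, genes, rna$truth)

  # every planted-dependent gene has a co-bound promoter peak in range
  dep <- rna$truth$gene_id[rna$truth$dependent]
  cb <- cobound_gene_set(pk$peaks$tf$dox, pk$peaks$cofactor$dox, genes,
                         window = 10000)
  expect_true(all(dep %in% cb))
  # planted co-bound peaks sit inside the annotation window of their gene
  tr <- pk$peak_truth[pk$peak_truth$cobound, ]
  tss <- genes$tss[match(tr$target_gene, genes$gene_id)]
  prom <- pk$peaks$tf$dox[match(tr$name, pk$peaks$tf$dox$name), ]
  mid <- floor((prom$start + prom$end) / 2)
  expect_true(all(abs(mid - tss) <= 10000))

  # empirical loss rates near the configured ones (binomial 3 SE)
  lost_cb <- mean(pk$peak_truth$lost_in_kd[pk$peak_truth$cobound])
  lost_bg <- mean(pk$peak_truth$lost_in_kd[!pk$peak_truth$cobound])
  n_cb <- sum(pk$peak_truth$cobound)
  n_bg <- sum(!pk$peak_truth$cobound)
  expect_lt(abs(lost_cb - 0.44), 3 * sqrt(0.44 * 0.56 / n_cb))
  expect_lt(abs(lost_bg - 0.07), 3 * sqrt(0.07 * 0.93 / n_bg))
  expect_gt(lost_cb, lost_bg)

  # same-factor peaks never overlap each other
  for (ps in list(pk$peaks$tf$dox, pk$peaks$cofactor$dox)) {
    by_chr <- split(ps, ps$chrom)
    for (x in by_chr) {
      if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
    }
  }
})

test_that("TMT channel totals carry the planted scaling factors", {
  cfg <- sim_config(n_genes = 100, seed = 13)
  tmt <- simulate_tmt(cfg)
  unscaled <- sweep(tmt$intensities, 2, tmt$channel_factor, `/`)
  expect_equal(colSums(tmt$intensities) / colSums(unscaled),
               tmt$channel_factor, tolerance = 1e-12)
  # bait channels of enriched proteins exceed IgG by about tmt_lfc
  lg <- log2(unscaled)
  bait <- tmt$design$channel_id[tmt$design$pulldown == "bait"]
  igg <- tmt$design$channel_id[tmt$design$pulldown == "IgG"]
  enr <- tmt$truth$enriched & !tmt$truth$rewired
  gap <- rowMeans(lg[enr, bait]) - rowMeans(lg[enr, igg])
  expect_lt(abs(mean(gap) - cfg$tmt_lfc), 0.3)
})

test_that("written simulation directories close over the ground truth", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 200, n_background_peaks = 20, seed = 21)
  obj <- simulate_to_dir(cfg, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  genes <- read_gene_models(file.path(dir, "gene_models.tsv"))
  truth <- utils::read.delim(file.path(dir, "gene_truth.tsv"))
  expect_setequal(truth$gene_id, rownames(counts))
  expect_setequal(truth$gene_id, genes$gene_id)
  tf <- read_bed(file.path(dir, "tf_dox.bed"))
  ptruth <- utils::read.delim(file.path(dir, "peak_truth.tsv"),
                              na.strings = ".")
  expect_true(all(ptruth$name %in% tf$name))
  expect_true(all(stats::na.omit(ptruth$target_gene) %in% genes$gene_id))
  tmt <- read_tmt(file.path(dir, "tmt.tsv"))
  prot <- utils::read.delim(file.path(dir, "protein_truth.tsv"))
  expect_setequal(prot$protein_id, rownames(tmt))
  # files reproduce the in-memory objects
  expect_equal(counts, obj$rna$counts + 0, ignore_attr = TRUE)
})
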