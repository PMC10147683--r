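# Independent oracles and small fixture builders shared across tests.

# all-pairs O(n*m) overlap oracle (half-open: >= 1 shared base)
brute_overlap_any <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          pmax(subject$start, query$start[i]) <
          pmin(subject$end, query$end[i]))
  }, logical(1))
}

# random valid peak set on a couple of chromosomes
random_peaks <- function(n, chroms = c("chrS1", "chrS2"), max_pos = 1000,
                         max_width = 50) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), start, start + width)
}

# BH step-up written straight from its definition
bh_by_definition <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Monte-Carlo oracle for the m-way intersection-size upper tail:
# draws independent uniform fixed-size subsets and counts the full
# intersection directly
mc_multiset_tail <- function(sizes, n_universe, observed, n_draws, seed) {
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_draws)) {
    tab <- tabulate(unlist(lapply(sizes, function(k)
      sample.int(n_universe, k))), n_universe)
    if (sum(tab == length(sizes)) >= observed) hits <- hits + 1L
  }
  hits / n_draws
}

# tiny deterministic contrast_result builder
make_contrast <- function(gene, log2fc, p = rep(0.5, length(gene)),
                          adj_p = NULL) {
  if (is.null(adj_p)) adj_p <- bh_adjust(p)
  df <- data.frame(gene = gene, log2fc = log2fc, p = p, adj_p = adj_p,
                   mean_expr = 0, stringsAsFactors = FALSE)
  class(df) <- c("contrast_result", "data.frame")
  df
}

# NB count matrix with a fixed mean and a 2x2 design, for DE tests
nb_counts <- function(n_genes, mu, dispersion, lfc = NULL, reps = 3,
                      seed = 1) {
  set.seed(seed)
  design <- data.frame(
    sample_id = paste0(rep(c("SCR_Con_", "SCR_Dox_"), each = reps),
                       seq_len(reps)),
    genotype = "SCR",
    treatment = rep(c("Con", "Dox"), each = reps),
    replicate = rep(seq_len(reps), 2), stringsAsFactors = FALSE
  )
  if (is.null(lfc)) lfc <- rep(0, n_genes)
  counts <- sapply(seq_len(nrow(design)), function(j) {
    m <- if (design$treatment[j] == "Dox") mu * 2^lfc else rep(mu, n_genes)
    stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
  })
  dimnames(counts) <- list(sprintf("g%04d", seq_len(n_genes)),
                           design$sample_id)
  list(counts = counts, design = design)
}
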