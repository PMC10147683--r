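# Minimal internal differential-expression surrogate: median-of-ratios
# normalization, per-gene Welch t on log2(normalized count + pseudocount),
# BH adjustment. Externally produced DE tables enter through
# read_contrast_table() and are schema-identical downstream.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the sample's
#' count to the gene's geometric-mean reference count. Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named positive numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("normalization error: no gene has nonzero counts in all samples")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- exp(apply(logc - ref, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  sf
}

welch_t <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate: both groups constant
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  p
}

#' Two-cell contrast on a factorial count matrix
#'
#' For the two factorial cells `a` and `b` (each given as
#' `c(genotype, treatment)`), computes per gene the difference of mean
#' `log2(normalized count + pseudocount)` (a minus b), a Welch two-sample
#' t p-value on those log values, and BH-adjusted p-values.
#'
#' @param counts Gene-by-sample count matrix.
#' @param design Sample design data frame (`sample_id`, `genotype`,
#'   `treatment`, `replicate`).
#' @param a,b Character vectors `c(genotype, treatment)` naming the two
#'   cells; the reported log2 fold change is a minus b.
#' @param pseudocount Added to normalized counts before log2 (default 1).
#' @return A `contrast_result` data frame (`gene`, `log2fc`, `p`, `adj_p`,
#'   `mean_expr`) with the contrast name stored in
#'   `attr(, "contrast")`.
#' @export
de_contrast <- function(counts, design, a, b, pseudocount = 1) {
  stopifnot(is.matrix(counts), length(a) == 2, length(b) == 2)
  pick <- function(cell) {
    ids <- design$sample_id[design$genotype == cell[1] &
                              design$treatment == cell[2]]
    if (length(ids) < 2)
      stop("cell ", paste(cell, collapse = "+"), " has < 2 replicates")
    if (!all(ids %in% colnames(counts)))
      stop("design samples missing from count matrix")
    ids
  }
  ids_a <- pick(a)
  ids_b <- pick(b)
  sf <- size_factors(counts[, unique(c(ids_a, ids_b)), drop = FALSE])
  norm <- sweep(counts[, names(sf), drop = FALSE], 2, sf, `/`)
  lg <- log2(norm + pseudocount)
  la <- lg[, ids_a, drop = FALSE]
  lb <- lg[, ids_b, drop = FALSE]
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- apply(la, 1, stats::var); v2 <- apply(lb, 1, stats::var)
  p <- welch_t(m1, v1, length(ids_a), m2, v2, length(ids_b))
  res <- data.frame(
    gene = rownames(counts), log2fc = m1 - m2, p = p,
    adj_p = bh_adjust(p), mean_expr = rowMeans(cbind(la, lb)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "contrast") <- paste(paste(a, collapse = "."), "vs",
                                 paste(b, collapse = "."))
  class(res) <- c("contrast_result", "data.frame")
  res
}
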