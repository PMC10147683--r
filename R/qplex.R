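# Interactome quantification for multiplexed IP mass spectrometry:
# total-intensity channel normalization, moderated bait-vs-IgG enrichment
# calls, and a bait-only condition contrast for interactome rewiring.
# Variance moderation uses empirical-Bayes shrinkage of per-protein pooled
# variances (prior df estimated by method of moments via
# limma::squeezeVar, falling back to a fixed prior df of 4 when the
# estimate is unavailable).

#' Normalize TMT channels to equal totals
#'
#' Scales every channel so its total intensity equals the mean
#' pre-normalization channel total. Idempotent; scaling factors are
#' recorded in `attr(, "scaling")`.
#'
#' @param m Protein-by-channel intensity matrix with positive channel
#'   totals.
#' @return Normalized matrix of the same shape.
#' @export
normalize_channels <- function(m) {
  stopifnot(is.matrix(m))
  totals <- colSums(m)
  if (any(totals <= 0)) stop("zero-total channel")
  target <- mean(totals)
  scaling <- target / totals
  out <- sweep(m, 2, scaling, `*`)
  attr(out, "scaling") <- scaling
  out
}

moderated_two_group <- function(lg, ids1, ids2, prior_df_fallback = 4) {
  n1 <- length(ids1); n2 <- length(ids2)
  x1 <- lg[, ids1, drop = FALSE]; x2 <- lg[, ids2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  sq <- tryCatch(limma::squeezeVar(s2, df = df), error = function(e) NULL)
  if (!is.null(sq) && (is.na(sq$df.prior[1]) || sq$df.prior[1] <= 0))
    sq <- NULL
  if (is.null(sq)) {
    d0 <- prior_df_fallback
    var_post <- (d0 * mean(s2) + df * s2) / (d0 + df)
    df_total <- df + d0
  } else {
    var_post <- sq$var.post
    d0 <- sq$df.prior
    df_total <- if (is.finite(d0)) df + d0 else 10 * df
  }
  t <- (m1 - m2) / sqrt(var_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df_total)
  list(log2fc = m1 - m2, t = t, p = p)
}

call_records <- function(proteins, fit, lfc_cut, alpha) {
  adj_p <- bh_adjust(fit$p)
  call <- rep("unchanged", length(proteins))
  call[fit$log2fc >= lfc_cut & adj_p < alpha] <- "enriched"
  call[fit$log2fc <= -lfc_cut & adj_p < alpha] <- "depleted"
  out <- data.frame(protein = proteins, log2fc = fit$log2fc, p = fit$p,
                    adj_p = adj_p, call = call, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(lfc_cut = lfc_cut, alpha = alpha)
  out
}

#' Bait-vs-IgG enrichment calls for one condition
#'
#' Per protein, `log2fc = mean log2(bait + pseudocount) - mean
#' log2(IgG + pseudocount)` within the stated condition, a moderated
#' two-sample t p-value, BH adjustment across proteins, and a call:
#' enriched iff `log2fc >= lfc_cut` and `adj_p < alpha` (depleted
#' symmetric).
#'
#' @param m Normalized protein-by-channel matrix (see
#'   [normalize_channels()]).
#' @param design Channel design (`channel_id`, `pulldown`, `condition`,
#'   `replicate`).
#' @param condition Condition to analyze (e.g. `"Con"`).
#' @param lfc_cut Log2 fold-change cutoff (default 0.5, inclusive).
#' @param alpha Adjusted-p cutoff (default 0.05, strict).
#' @param pseudocount Added to intensities before log2 (default 1).
#' @param pool_igg If TRUE, IgG channels from all conditions serve as the
#'   control; default FALSE (per-condition IgG).
#' @return Data frame (`protein`, `log2fc`, `p`, `adj_p`, `call`).
#' @export
enrichment_call <- function(m, design, condition, lfc_cut = 0.5,
                            alpha = 0.05, pseudocount = 1,
                            pool_igg = FALSE) {
  bait <- design$channel_id[design$pulldown == "bait" &
                              design$condition == condition]
  igg <- if (pool_igg) design$channel_id[design$pulldown == "IgG"] else
    design$channel_id[design$pulldown == "IgG" &
                        design$condition == condition]
  if (length(bait) < 2) stop("need >= 2 bait replicates in ", condition)
  if (length(igg) < 2) stop("need >= 2 IgG channels for the contrast")
  lg <- log2(m[, c(bait, igg), drop = FALSE] + pseudocount)
  fit <- moderated_two_group(lg, bait, igg)
  call_records(rownames(m), fit, lfc_cut, alpha)
}

#' Condition contrast of the bait interactome
#'
#' Dox-vs-Con contrast on bait channels only, with the same moderated test
#' and symmetric enriched/depleted calls, identifying interactors gained
#' or lost between the two states.
#'
#' @inheritParams enrichment_call
#' @return Data frame (`protein`, `log2fc`, `p`, `adj_p`, `call`), where
#'   `log2fc` is Dox minus Con.
#' @export
condition_contrast <- function(m, design, lfc_cut = 0.5, alpha = 0.05,
                               pseudocount = 1) {
  dox <- design$channel_id[design$pulldown == "bait" &
                             design$condition == "Dox"]
  con <- design$channel_id[design$pulldown == "bait" &
                             design$condition == "Con"]
  if (length(dox) < 2 || length(con) < 2)
    stop("need >= 2 bait replicates per condition")
  lg <- log2(m[, c(dox, con), drop = FALSE] + pseudocount)
  fit <- moderated_two_group(lg, dox, con)
  call_records(rownames(m), fit, lfc_cut, alpha)
}
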