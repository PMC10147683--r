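# Bespoke enrichment statistics: exact multi-set intersection test,
# observed/expected chi-square on 2x2 tables, hypergeometric
# over-representation, preranked GSEA with gene-label permutations,
# Spearman correlation, and BH adjustment.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Exact multi-set intersection test
#'
#' Tests whether the common intersection of m fixed-size gene sets is
#' larger than expected under independent uniform sampling of subsets of
#' the stated sizes from a universe of size N. The expected intersection
#' size is `N * prod(n_i / N)`; the p-value is the exact upper-tail
#' probability `P(X >= observed)` of the intersection-size null
#' distribution, computed by iterated pairwise hypergeometric convolution
#' in log space (for m = 2 this reduces to the hypergeometric upper tail).
#'
#' @param sets List of >= 2 character vectors (gene sets).
#' @param n_universe Universe size N (>= every set size).
#' @param universe Optional character vector; when supplied, containment
#'   of every set is checked and `n_universe` defaults to its length.
#' @return List of class `multiset_test`: `m`, `n_universe`, `set_sizes`,
#'   `observed`, `expected`, `fold`, `p`.
#' @export
multiset_intersection_test <- function(sets, n_universe = NULL,
                                       universe = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  if (!is.null(universe)) {
    for (s in sets) {
      if (!all(s %in% universe)) stop("set not contained in universe")
    }
    if (is.null(n_universe)) n_universe <- length(unique(universe))
  }
  if (is.null(n_universe)) stop("n_universe is required")
  n_universe <- as.integer(n_universe)
  if (n_universe <= 0) stop("universe size must be positive")
  sizes <- lengths(sets)
  if (any(sizes > n_universe)) stop("set larger than universe")
  observed <- length(Reduce(intersect, sets))
  expected <- n_universe * prod(sizes / n_universe)

  # log-pmf of the running intersection size, convolved one set at a time:
  # given the current intersection has size j, its overlap with the next
  # (uniform) subset of size n_k is Hypergeometric(N, j, n_k)
  lp <- rep(-Inf, n_universe + 1)
  lp[sizes[1] + 1] <- 0
  for (k in 2:length(sizes)) {
    nk <- sizes[k]
    new <- rep(-Inf, n_universe + 1)
    support <- which(lp > -Inf) - 1
    for (j in support) {
      t_max <- min(j, nk)
      t_vals <- 0:t_max
      contrib <- lp[j + 1] +
        stats::dhyper(t_vals, j, n_universe - j, nk, log = TRUE)
      for (t in t_vals) {
        new[t + 1] <- logsumexp(c(new[t + 1], contrib[t + 1]))
      }
    }
    lp <- new
  }
  p <- if (observed == 0) 1 else
    min(1, exp(logsumexp(lp[(observed + 1):(n_universe + 1)])))
  structure(list(m = length(sets), n_universe = n_universe,
                 set_sizes = sizes, observed = observed,
                 expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 p = p),
            class = "multiset_test")
}

#' Observed/expected chi-square on a 2x2 table
#'
#' Pearson chi-square without continuity correction, with the
#' observed-to-expected ratio reported for the focal cell `[1, 1]`
#' (e.g. co-bound AND lost). Expected counts come from the margins under
#' independence.
#'
#' @param table 2x2 numeric matrix of non-negative counts; row 1 / column
#'   1 hold the focal categories.
#' @return List of class `oe_chi2`: `observed`, `expected`, `oe_ratio`,
#'   `chi2`, `p` (1 df).
#' @export
observed_expected_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in 2x2 table")
  expected <- outer(rs, cs) / sum(table)
  chi2 <- sum((table - expected)^2 / expected)
  structure(list(observed = table, expected = expected,
                 oe_ratio = table[1, 1] / expected[1, 1], chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "oe_chi2")
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and a named gene set within a universe.
#'
#' @param query,gene_set Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List: `overlap`, `fold` (observed/expected overlap), `p`.
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); gene_set <- unique(gene_set)
  if (!all(query %in% universe) || !all(gene_set %in% universe))
    stop("query and gene_set must be subsets of the universe")
  N <- length(universe); n <- length(query); K <- length(gene_set)
  k <- length(intersect(query, gene_set))
  expected <- n * K / N
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = k, fold = if (expected > 0) k / expected else NA_real_,
       p = min(1, p))
}

#' Over-representation across a gene-set collection
#'
#' Runs [ora_test()] for every set in a collection and BH-adjusts the
#' p-values across sets.
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of all eligible genes.
#' @return Data frame (`set`, `size`, `overlap`, `fold`, `p`, `adj_p`).
#' @export
ora_collection <- function(query, collection, universe) {
  res <- lapply(collection, function(s)
    ora_test(query, intersect(s, universe), universe))
  out <- data.frame(
    set = names(collection),
    size = vapply(collection, function(s) length(intersect(s, universe)), 0L),
    overlap = vapply(res, `[[`, 0, "overlap"),
    fold = vapply(res, `[[`, 0, "fold"),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

# Enrichment score from sorted |scores| and hit positions. Hits increment
# the running sum proportionally to |score| (weight exponent 1); misses
# decrement uniformly by 1/(N - n_hits). Only values at hit boundaries can
# be extrema, so the running sum is evaluated there.
es_from_positions <- function(abs_sorted, idx) {
  N <- length(abs_sorted)
  k <- length(idx)
  if (k == N) return(1)   # degenerate: every gene is a hit
  idx <- sort(idx)
  w <- abs_sorted[idx]
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / k, k) else w <- w / sw
  cw <- cumsum(w)
  miss <- 1 / (N - k)
  after <- cw - (idx - seq_len(k)) * miss           # just after each hit
  before <- c(0, cw[-k]) - (idx - 1 - (seq_len(k) - 1)) * miss
  lo <- min(before, 0)
  hi <- max(after, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment
#'
#' Classic weighted running-sum enrichment score (weight exponent 1) on a
#' preranked gene list, with a gene-label permutation null. The p-value
#' uses the +1 correction and is one-sided toward the observed sign:
#' `p = (1 + #{same-sign permutations with |ES| >= |ES_obs|}) /
#' (1 + #{same-sign permutations})`.
#'
#' @param scores Named numeric vector (gene -> ranking score); names must
#'   be unique.
#' @param gene_set Character vector; must share at least one gene with
#'   `scores`.
#' @param n_perm Number of gene-label permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `gsea_result`: `es`, `p`, `n_hits`, `n_perm`,
#'   `degenerate` (TRUE when the set covers the whole list and ES is +1 by
#'   convention).
#' @export
gsea_preranked <- function(scores, gene_set, n_perm = 10000, seed = 1) {
  if (anyDuplicated(names(scores))) stop("duplicate gene names in scores")
  hits <- names(scores) %in% gene_set
  if (!any(hits)) stop("gene set shares no genes with the ranked list")
  ord <- order(scores, decreasing = TRUE)
  abs_sorted <- abs(scores[ord])
  idx <- which(hits[ord])
  k <- length(idx)
  N <- length(scores)
  if (k == N) {
    return(structure(list(es = 1, p = NA_real_, n_hits = k,
                          n_perm = 0L, degenerate = TRUE),
                     class = "gsea_result"))
  }
  es <- es_from_positions(abs_sorted, idx)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(n_perm), function(i)
    es_from_positions(abs_sorted, sample.int(N, k)), 0)
  same_sign <- sign(perm) == sign(es) | perm == 0 & es == 0
  p <- (1 + sum(same_sign & abs(perm) >= abs(es))) / (1 + sum(same_sign))
  structure(list(es = es, p = p, n_hits = k, n_perm = n_perm,
                 degenerate = FALSE),
            class = "gsea_result")
}

#' Preranked GSEA across a collection
#'
#' Runs [gsea_preranked()] per set (sets with no gene in the ranked list
#' are skipped with a warning) and BH-adjusts p-values across sets.
#'
#' @inheritParams gsea_preranked
#' @param collection Named list of gene sets.
#' @return Data frame (`set`, `n_hits`, `es`, `p`, `adj_p`).
#' @export
gsea_collection <- function(scores, collection, n_perm = 10000, seed = 1) {
  keep <- vapply(collection, function(s) any(names(scores) %in% s), TRUE)
  if (!all(keep))
    warning(sum(!keep), " set(s) share no genes with the ranked list")
  collection <- collection[keep]
  res <- lapply(seq_along(collection), function(i)
    gsea_preranked(scores, collection[[i]], n_perm = n_perm,
                   seed = seed + i))
  out <- data.frame(
    set = names(collection),
    n_hits = vapply(res, `[[`, 0L, "n_hits"),
    es = vapply(res, `[[`, 0, "es"),
    p = vapply(res, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

# all permutations of 1..n (Heap's algorithm), for the exact Spearman null
all_perms <- function(n) {
  out <- matrix(0L, factorial(n), n)
  a <- seq_len(n)
  c_ <- rep(1L, n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_[i] < i) {
      if (i %% 2 == 1) {
        tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i]]; a[c_[i]] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 1L
      i <- i + 1L
    }
  }
  out
}

#' Spearman rank correlation
#'
#' Correlation of mid-ranks (average ranks for ties). For n >= 10 the
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`;
#' below 10 it is computed by exact enumeration of all rank permutations
#' (two-sided on |rho|).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List: `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    method <- "t-approximation"
  } else {
    perms <- all_perms(n)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
    # permute one rank vector against the fixed centered other ranks;
    # the mean term cancels because rxc is centered
    rho_null <- (matrix(ry[perms], nrow(perms)) %*% rxc) / denom
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  list(rho = rho, p = min(1, p), n = n, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1 and mapped back to the input order.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
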