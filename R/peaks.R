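# Interval-level ChIP-seq logic: co-occupancy with unique-report
# semantics, presence/absence condition-specific peaks, nearest-TSS
# annotation within a window, and promoter/gene-body/distal context.
# Intervals are 0-based half-open; overlap means >= 1 shared base.
# Overlap queries go through IRanges (converted to 1-based closed).

overlap_hits <- function(query, subject) {
  # logical vector: does each query interval overlap any subject interval
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(subject) == 0) return(hit)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1,
                           end = subject$end[si])
    hit[qi] <- IRanges::overlapsAny(qr, sr)
  }
  hit
}

#' Query peaks overlapping any subject peak
#'
#' Unique-report co-occupancy: every query interval that overlaps at least
#' one subject interval is reported once, with its original coordinates
#' (the interval-file idiom `intersect -u -wa`).
#'
#' @param query,subject [peak_set()] objects.
#' @return The overlapping subset of `query`.
#' @export
intersect_unique <- function(query, subject) {
  out <- query[overlap_hits(query, subject), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Query peaks with no subject overlap
#'
#' Complement of [intersect_unique()]: query intervals with zero overlaps
#' in the subject set (the idiom `intersect -v -wa`).
#'
#' @param query,subject [peak_set()] objects.
#' @return The non-overlapping subset of `query`.
#' @export
subtract_unique <- function(query, subject) {
  out <- query[!overlap_hits(query, subject), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Condition-specific and common peaks
#'
#' Presence/absence comparison of one factor's peaks between two
#' conditions: `a_only = subtract_unique(a, b)`,
#' `b_only = subtract_unique(b, a)`, `common = intersect_unique(a, b)`.
#'
#' @param set_a,set_b [peak_set()] objects from the two conditions.
#' @return List with elements `a_only`, `b_only`, `common`.
#' @export
condition_specific_peaks <- function(set_a, set_b) {
  list(a_only = subtract_unique(set_a, set_b),
       b_only = subtract_unique(set_b, set_a),
       common = intersect_unique(set_a, set_b))
}

#' Annotate peaks to the nearest TSS within a window
#'
#' Each peak is assigned to the gene whose TSS minimizes
#' `|midpoint - tss|` (midpoint = `floor((start + end) / 2)`), provided
#' that minimum distance is at most `window`; otherwise the peak is left
#' unassigned. Exact distance ties are broken toward the lexicographically
#' smaller gene id. The signed distance is `midpoint - tss` in genomic
#' coordinates.
#'
#' @param peaks A [peak_set()].
#' @param genes Gene-model data frame (`gene_id`, `chrom`, `strand`,
#'   `tss`).
#' @param window Maximum assignment distance in bp (default 10000).
#' @return Data frame: peak columns plus `midpoint`, `gene_id` (NA when
#'   unassigned) and `signed_distance`.
#' @export
annotate_peaks <- function(peaks, genes, window = 10000) {
  stopifnot(nrow(genes) > 0)
  mid <- floor((peaks$start + peaks$end) / 2)
  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    pi <- which(peaks$chrom == ch)
    if (nrow(g) == 0) next
    # sort TSS; for equal TSS keep the lexicographically smaller id first
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    m <- mid[pi]
    right <- findInterval(m, g$tss) + 1   # first TSS >= midpoint (approx)
    left <- right - 1
    left_ok <- left >= 1
    right_ok <- right <= nrow(g)
    dl <- ifelse(left_ok, m - g$tss[pmax(left, 1)], Inf)
    dr <- ifelse(right_ok, g$tss[pmin(right, nrow(g))] - m, Inf)
    # pick nearer neighbor; on exact ties the smaller gene id
    use_left <- dl < dr |
      (dl == dr & left_ok & right_ok &
         g$gene_id[pmax(left, 1)] < g$gene_id[pmin(right, nrow(g))])
    idx <- ifelse(use_left, pmax(left, 1), pmin(right, nrow(g)))
    d <- pmin(dl, dr)
    assign <- is.finite(d) & d <= window
    gene_id[pi[assign]] <- g$gene_id[idx[assign]]
    dist[pi[assign]] <- m[assign] - g$tss[idx[assign]]
  }
  out <- as.data.frame(peaks)
  out$midpoint <- mid
  out$gene_id <- gene_id
  out$signed_distance <- dist
  rownames(out) <- NULL
  out
}

#' Classify genomic context of annotated peaks
#'
#' A peak is `promoter` iff its midpoint lies within
#' `TSS +/- promoter_halfwidth` of any gene; otherwise `gene_body` iff it
#' falls inside any supplied gene span; otherwise `distal`.
#'
#' @param annotation Output of [annotate_peaks()].
#' @param genes Gene-model data frame.
#' @param promoter_halfwidth Promoter halfwidth in bp (default 3000).
#' @param gene_spans Optional data frame (`gene_id`, `chrom`, `start`,
#'   `end`) of gene bodies; when absent no peak is classified `gene_body`.
#' @return `annotation` with an added `context` column.
#' @export
classify_context <- function(annotation, genes, promoter_halfwidth = 3000,
                             gene_spans = NULL) {
  ctx <- rep("distal", nrow(annotation))
  for (ch in unique(annotation$chrom)) {
    tss <- sort(genes$tss[genes$chrom == ch])
    pi <- which(annotation$chrom == ch)
    if (length(tss) == 0) next
    m <- annotation$midpoint[pi]
    right <- findInterval(m, tss) + 1
    left <- right - 1
    dl <- ifelse(left >= 1, m - tss[pmax(left, 1)], Inf)
    dr <- ifelse(right <= length(tss), tss[pmin(right, length(tss))] - m, Inf)
    ctx[pi[pmin(dl, dr) <= promoter_halfwidth]] <- "promoter"
  }
  if (!is.null(gene_spans)) {
    body <- ctx == "distal"
    if (any(body)) {
      q <- annotation[body, , drop = FALSE]
      inside <- logical(nrow(q))
      for (ch in intersect(unique(q$chrom), unique(gene_spans$chrom))) {
        qi <- which(q$chrom == ch)
        sp <- gene_spans[gene_spans$chrom == ch, , drop = FALSE]
        qr <- IRanges::IRanges(q$midpoint[qi] + 1, q$midpoint[qi] + 1)
        sr <- IRanges::IRanges(sp$start + 1, sp$end)
        inside[qi] <- IRanges::overlapsAny(qr, sr)
      }
      ctx[which(body)[inside]] <- "gene_body"
    }
  }
  annotation$context <- ctx
  annotation
}

#' Genes near co-bound peaks
#'
#' Intersects the two factors' peak sets (unique-report, in both query
#' directions so the result is symmetric in its arguments), annotates the
#' co-bound peaks to the nearest TSS within `window`, and returns the
#' distinct assigned gene ids.
#'
#' @param factor1,factor2 [peak_set()] objects for the two factors in one
#'   condition.
#' @param genes Gene-model data frame.
#' @param window Annotation window in bp (default 10000).
#' @return Sorted character vector of gene ids.
#' @export
cobound_gene_set <- function(factor1, factor2, genes, window = 10000) {
  ann1 <- annotate_peaks(intersect_unique(factor1, factor2), genes, window)
  ann2 <- annotate_peaks(intersect_unique(factor2, factor1), genes, window)
  sort(unique(stats::na.omit(c(ann1$gene_id, ann2$gene_id))))
}
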