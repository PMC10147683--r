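# Readers/writers for the plain-text formats the pipeline touches.
# All genomic coordinates are 0-based half-open internally; BED files are
# read and written verbatim in that convention.

#' Construct a peak set
#'
#' A peak set is a data frame of genomic intervals in 0-based half-open
#' coordinates, sorted by (chrom, start, end). Two intervals overlap iff
#' `max(starts) < min(ends)`, i.e. they share at least one base.
#'
#' @param chrom Character vector of chromosome names (compared by exact
#'   string match, no normalization).
#' @param start,end Integer vectors; `0 <= start < end`.
#' @param name Optional interval names (default `"."`).
#' @param score Optional numeric scores (default `NA`).
#' @param strand Optional strand (`"+"`, `"-"` or `"."`).
#' @return A `peak_set` data frame with columns chrom, start, end, name,
#'   score, strand.
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     name = NULL, score = NULL, strand = NULL) {
  n <- length(chrom)
  stopifnot(length(start) == n, length(end) == n)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (n > 0) {
    if (any(start != floor(start)) || any(end != floor(end)))
      stop("peak coordinates must be integers")
    if (any(start < 0)) stop("negative start coordinate")
    if (any(start >= end)) stop("interval with start >= end")
  }
  if (is.null(name)) name <- rep(".", n)
  if (is.null(score)) score <- rep(NA_real_, n)
  if (is.null(strand)) strand <- rep(".", n)
  ps <- data.frame(
    chrom = as.character(chrom), start = start, end = end,
    name = as.character(name), score = as.numeric(score),
    strand = as.character(strand), stringsAsFactors = FALSE
  )
  ps <- ps[order(ps$chrom, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Read a BED or narrowPeak file
#'
#' Accepts BED3-BED6 and narrowPeak (extra columns beyond the sixth are
#' preserved as opaque character payload). Coordinates are validated
#' (integer, `start >= 0`, `start < end`); violations raise an error that
#' names the offending line.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return A [peak_set()] data frame; extra columns, when present, appear
#'   after `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(peak_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop("line ", which(ncol < 3)[1], ": BED requires >= 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start_chr <- vapply(fields, `[[`, "", 2)
  end_chr <- vapply(fields, `[[`, "", 3)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad) > 0)
    stop("line ", bad[1], ": non-integer coordinate")
  bad <- which(start < 0)
  if (length(bad) > 0)
    stop("line ", bad[1], ": negative start coordinate")
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop("line ", bad[1], ": start >= end")
  k <- max(ncol)   # ragged lines are padded with "."
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else ".", "")
  }
  name <- get_col(4)
  score_chr <- get_col(5)
  score <- suppressWarnings(as.numeric(ifelse(score_chr == ".", NA, score_chr)))
  strand <- get_col(6)
  ps <- data.frame(
    chrom = chrom, start = start, end = end, name = name,
    score = score, strand = strand, stringsAsFactors = FALSE
  )
  if (k > 6) {
    for (i in 7:k) ps[[paste0("extra", i - 6)]] <- get_col(i)
  }
  ps <- ps[order(ps$chrom, ps$start, ps$end), , drop = FALSE]
  rownames(ps) <- NULL
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Write a peak set as BED
#'
#' Writes chrom/start/end/name/score/strand plus any extra payload columns,
#' tab-separated, without header or quoting. Missing scores are written as
#' `"."`; round-tripping through [read_bed()] preserves coordinates exactly.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "data.frame"))
  out <- as.data.frame(peaks)
  if (nrow(out) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  out$score <- ifelse(is.na(out$score), ".",
                      format(out$score, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = ".")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         "; expected header containing: ", paste(required, collapse = ", "))
  }
  df
}

write_tsv_plain <- function(df, path, row_label = NULL) {
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                row_label),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' Expects a TSV with a header row of sample ids and a first column of gene
#' ids. Counts must be non-negative integers; duplicate gene ids are an
#' error.
#'
#' @param path Path to the counts TSV.
#' @return Integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path) {
  df <- read_tsv_checked(path, character())
  if (ncol(df) < 2) stop("counts table needs a gene column and >= 1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in counts table")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric or missing count value")
  if (any(m < 0)) stop("negative count value")
  if (any(m != floor(m))) stop("non-integer count value")
  rownames(m) <- genes
  m
}

#' Write a count matrix
#' @param counts Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  write_tsv_plain(counts, path, row_label = "gene_id")
}

#' Read a factorial sample design
#'
#' Columns: `sample_id`, `genotype` (SCR/KD), `treatment` (Con/Dox),
#' `replicate`.
#'
#' @param path Path to the design TSV.
#' @return Data frame with those columns.
#' @export
read_design <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "genotype", "treatment",
                                 "replicate"))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  df
}

#' Write a sample design table
#' @param design Data frame as returned by [read_design()].
#' @param path Output path.
#' @export
write_design <- function(design, path) write_tsv_plain(design, path)

#' Read gene models (TSS anchors)
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss` (0-based). Gene ids must be
#' unique and TSS coordinates non-negative.
#'
#' @param path Path to the gene-model TSV.
#' @return Data frame of gene models.
#' @export
read_gene_models <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "chrom", "strand", "tss"))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in gene models")
  if (any(df$tss < 0)) stop("negative TSS coordinate")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' Write gene models
#' @param genes Data frame as returned by [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) write_tsv_plain(genes, path)

#' Read a GMT gene-set collection
#'
#' Each line is `set_name<TAB>description<TAB>member1<TAB>member2...`.
#' Empty sets are rejected.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) stop("line ", bad[1], ": GMT set with no members")
  sets <- lapply(fields, function(f) unique(f[-c(1, 2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-by-channel TMT intensity matrix
#'
#' First column `protein_id`, remaining columns one per TMT channel.
#' Intensities must be non-negative.
#'
#' @param path Path to the TMT TSV.
#' @return Numeric matrix with protein rownames and channel colnames.
#' @export
read_tmt <- function(path) {
  df <- read_tsv_checked(path, character())
  if (ncol(df) < 2) stop("TMT table needs a protein column and >= 1 channel")
  prot <- as.character(df[[1]])
  if (anyDuplicated(prot)) stop("duplicate protein ids in TMT table")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric or missing intensity")
  if (any(m < 0)) stop("negative intensity")
  rownames(m) <- prot
  m
}

#' Write a TMT intensity matrix
#' @param m Matrix with protein rownames and channel colnames.
#' @param path Output path.
#' @export
write_tmt <- function(m, path) write_tsv_plain(m, path, row_label = "protein_id")

#' Read a TMT channel design
#'
#' Columns: `channel_id`, `pulldown` (bait/IgG), `condition` (Con/Dox),
#' `replicate`.
#'
#' @param path Path to the channel-design TSV.
#' @return Data frame with those columns.
#' @export
read_channel_design <- function(path) {
  df <- read_tsv_checked(path, c("channel_id", "pulldown", "condition",
                                 "replicate"))
  if (anyDuplicated(df$channel_id)) stop("duplicate channel ids")
  if (!all(df$pulldown %in% c("bait", "IgG")))
    stop("pulldown must be 'bait' or 'IgG'")
  df
}

#' Write a TMT channel design
#' @param design Data frame as returned by [read_channel_design()].
#' @param path Output path.
#' @export
write_channel_design <- function(design, path) write_tsv_plain(design, path)

#' Read a per-contrast differential-expression table
#'
#' Adapter for externally produced DE tables. Requires columns `gene`,
#' `log2fc`, `p`, `adj_p`; unknown columns are preserved.
#'
#' @param path Path to the contrast TSV.
#' @return A `contrast_result` data frame.
#' @export
read_contrast_table <- function(path) {
  df <- read_tsv_checked(path, c("gene", "log2fc", "p", "adj_p"))
  if (anyDuplicated(df$gene)) stop("duplicate gene ids in contrast table")
  for (col in c("log2fc", "p", "adj_p")) df[[col]] <- as.numeric(df[[col]])
  ok <- is.na(df$p) | (df$p >= 0 & df$p <= 1)
  if (!all(ok)) stop("p outside [0, 1]")
  class(df) <- c("contrast_result", "data.frame")
  df
}

#' Write a contrast table
#' @param contrast A `contrast_result` data frame.
#' @param path Output path.
#' @export
write_contrast_table <- function(contrast, path) {
  df <- as.data.frame(contrast)
  # full double precision so read -> write -> read is the identity
  for (col in c("log2fc", "p", "adj_p"))
    df[[col]] <- ifelse(is.na(df[[col]]), ".", sprintf("%.17g", df[[col]]))
  write_tsv_plain(df, path)
}
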