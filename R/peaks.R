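## ChIP-seq peak sets: BED-family IO and co-enrichment set algebra.

#' Construct a peak set
#'
#' @param chrom,start,end peak coordinates, 1-based inclusive.
#' @param name,score optional per-peak name and score.
#' @param label set label (conventionally mark + cell line).
#' @return Object of class `peak_set`: a list with a `peaks` data.frame
#'   sorted by (chrom, start) and the `label`.
#' @export
peak_set <- function(chrom, start, end, name = NA_character_,
                     score = NA_real_, label = "peaks") {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom)) .check_intervals(chrom, start, end, "peak")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = rep_len(as.character(name), length(chrom)),
                   score = rep_len(as.numeric(score), length(chrom)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(label = label, peaks = df), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d peaks on %d chromosome(s), %d bp total\n",
              x$label, nrow(x$peaks), length(unique(x$peaks$chrom)),
              total_bp(x)))
  invisible(x)
}

#' Total base pairs covered by a peak set (after merging overlaps)
#' @param x a `peak_set`.
#' @return Integer number of covered base pairs.
#' @export
total_bp <- function(x) {
  gr <- GenomicRanges::reduce(.ps_to_gr(x))
  sum(GenomicRanges::width(gr))
}

.ps_to_gr <- function(x) {
  GenomicRanges::GRanges(x$peaks$chrom,
                         IRanges::IRanges(x$peaks$start, x$peaks$end))
}

.gr_to_ps <- function(gr, label) {
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr), label = label)
}

#' Read ChIP-seq peak calls
#'
#' Reads BED3, BED6 or ENCODE narrowPeak files. BED coordinates (0-based
#' half-open) are converted to the package's 1-based inclusive convention,
#' so the BED line `chr1 99 200` becomes the peak `chr1:100-200`.
#'
#' @param path file path.
#' @param dialect `"bed3"`, `"bed6"` or `"narrowPeak"`.
#' @param label label for the resulting set (defaults to the file name).
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("bed3", "bed6", "narrowPeak"),
                       label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("peak file not found: %s", path)
  if (is.null(label)) label <- basename(path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "[ \t]+")
  need <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  nf <- lengths(fields)
  if (any(nf != need))
    .stopf("%s: line %d: expected %d columns for %s, found %d",
           path, which(keep)[which(nf != need)[1L]], need, dialect,
           nf[nf != need][1L])
  if (!length(fields))
    return(peak_set(character(0), integer(0), integer(0), label = label))
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  if (any(is.na(start0)) || any(is.na(end0)))
    .stopf("%s: non-numeric coordinates", path)
  if (any(end0 <= start0))
    .stopf("%s: zero- or negative-length peak (start >= end)", path)
  name <- if (need >= 6L) m[, 4L] else NA_character_
  score <- if (need >= 6L) suppressWarnings(as.numeric(m[, 5L])) else NA_real_
  if (dialect == "narrowPeak") score <- suppressWarnings(as.numeric(m[, 7L]))
  peak_set(m[, 1L], start0 + 1L, end0, name = name, score = score,
           label = label)
}

#' Write a peak set as BED
#'
#' Output follows the BED standard (0-based half-open); name and score
#' columns are included when any peak carries them.
#'
#' @param x a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  p <- x$peaks
  if (all(is.na(p$name)) && all(is.na(p$score))) {
    writeLines(sprintf("%s\t%d\t%d", p$chrom, p$start - 1L, p$end), path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", p$chrom, p$start - 1L, p$end,
                       ifelse(is.na(p$name), ".", p$name),
                       ifelse(is.na(p$score), "0", format(p$score))), path)
  }
  invisible(path)
}

#' Merge overlapping or book-ended peaks within a set
#' @param x a `peak_set`.
#' @return A `peak_set` of disjoint, merged intervals.
#' @export
merge_peaks <- function(x) {
  stopifnot(inherits(x, "peak_set"))
  .gr_to_ps(GenomicRanges::reduce(.ps_to_gr(x)), x$label)
}

#' Intersect two peak sets into co-enriched regions
#'
#' Computes the genomic segment intersection of two peak sets: every output
#' base pair is covered by both inputs, and book-ended segments are merged.
#' Each set is merged internally first, so duplicate input peaks cannot
#' produce duplicate segments. This is the operation used to define regions
#' co-enriched for two chromatin marks (e.g. EZH2 and H3K27me3).
#'
#' @param a,b `peak_set` objects on the same assembly (chromosome names must
#'   match to intersect).
#' @param mode `"segments"` (default) for genomic intersection; `"peaks_a"`
#'   to instead return the merged peaks of `a` that touch `b`.
#' @return A `peak_set` of co-enriched regions.
#' @export
intersect_peaksets <- function(a, b, mode = c("segments", "peaks_a")) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  mode <- match.arg(mode)
  ga <- GenomicRanges::reduce(.ps_to_gr(a))
  gb <- GenomicRanges::reduce(.ps_to_gr(b))
  label <- paste(a$label, "&", b$label)
  if (mode == "segments") {
    suppressWarnings(
      out <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))
  } else {
    suppressWarnings(
      hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE))
    out <- ga[unique(S4Vectors::queryHits(hits))]
  }
  .gr_to_ps(out, label)
}

#' Partition two gene target sets
#'
#' Splits two sets of target gene ids into exclusive and shared parts, the
#' comparison used to contrast cell-line-specific targets.
#'
#' @param targets_a,targets_b character vectors of gene ids.
#' @return List with sorted components `a_only`, `b_only`, `shared`.
#' @export
gene_target_difference <- function(targets_a, targets_b) {
  a <- unique(as.character(targets_a))
  b <- unique(as.character(targets_b))
  list(a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}
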