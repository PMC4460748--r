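## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Validate a set of genomic intervals given as parallel vectors.
## 1-based inclusive coordinates throughout the package (GFF convention).
.check_intervals <- function(chrom, start, end, what = "interval") {
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop(sprintf("%s: chromosome names must be non-empty", what), call. = FALSE)
  if (any(start < 1L))
    stop(sprintf("%s: start positions must be >= 1 (1-based inclusive)", what),
         call. = FALSE)
  if (any(end < start))
    stop(sprintf("%s: end must be >= start", what), call. = FALSE)
  invisible(TRUE)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Deterministic ordering used everywhere a tie could occur:
## primary keys in order, final tie-break on a character id.
.order_by <- function(..., id) {
  keys <- list(...)
  do.call(order, c(keys, list(id), list(method = "radix")))
}

## Signed gap between a query region and a feature span on the same
## chromosome: 0 when they overlap, negative when the feature lies left
## (upstream in reference orientation) of the region, positive when right.
.signed_gap <- function(q_start, q_end, f_start, f_end) {
  d <- numeric(length(f_start))
  left <- f_end < q_start
  right <- f_start > q_end
  d[left] <- (f_end - q_start)[left]     # negative
  d[right] <- (f_start - q_end)[right]   # positive
  d
}
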