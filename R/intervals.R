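#' Genomic interval
#'
#' A 1-based, fully closed genomic interval (the GFF3 / pileup
#' convention used throughout the package).
#'
#' @param chrom Chromosome identifier.
#' @param start 1-based inclusive start.
#' @param end 1-based inclusive end (must be >= start).
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A `genomic_interval` object.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid interval: require 1 <= start <= end, got [",
         start, ", ", end, "]", call. = FALSE)
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be +, - or *")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

interval_length <- function(x) x$end - x$start + 1L

#' Capture-region length in megabases
#'
#' Length of a capture target region as printed in region summary
#' tables: `(end - start) / 1e6`, rounded half-up to 2 decimals. Note
#' the span convention is the coordinate difference (not the closed
#' interval length `end - start + 1`), matching how such region tables
#' are conventionally printed; at Mb scale the 1-bp difference is
#' invisible anyway.
#'
#' @param region A [genomic_interval()].
#' @return Length in Mb, rounded half-up to 2 decimals.
#' @examples
#' region_length_mb(genomic_interval("11", 4412041, 5661311)) # 1.25
#' @export
region_length_mb <- function(region) {
  stopifnot(inherits(region, "genomic_interval"))
  round_half_up((region$end - region$start) / 1e6, 2)
}
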