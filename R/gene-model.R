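#' Gene model
#'
#' Strand-aware single-transcript gene structure driving all annotation:
#' TSS, exons, CDS segments and UTRs. Interval lists are stored as
#' two-column data frames (`start`, `end`; 1-based closed) sorted in
#' transcription order, i.e. ascending start on the `+` strand and
#' descending on `-`.
#'
#' Invariants enforced: exons are non-overlapping; CDS segments lie
#' within exons; UTRs lie within exons and outside the CDS; the TSS
#' equals the transcription-start coordinate implied by the strand
#' (minimum start on `+`, maximum end on `-`).
#'
#' @param gene_id Gene/transcript identifier.
#' @param chrom Chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`.
#' @param cds Data frame with columns `start`, `end` (may have 0 rows
#'   for a non-coding model).
#' @param utr5,utr3 Optional UTR data frames; when `NULL` they are
#'   derived as the exonic space upstream/downstream of the CDS.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL,
                       utr5 = NULL, utr3 = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- normalize_segments(exons, strand)
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons", call. = FALSE)
  gsort <- exons[order(exons$start), , drop = FALSE]
  if (nrow(gsort) > 1L && any(gsort$start[-1L] <= gsort$end[-nrow(gsort)])) {
    stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
  }
  cds <- normalize_segments(cds, strand)
  if (!segments_within(cds, exons)) {
    stop("gene ", gene_id, ": CDS segment outside exons", call. = FALSE)
  }
  if (is.null(utr5) || is.null(utr3)) {
    utrs <- derive_utrs(exons, cds, strand)
    if (is.null(utr5)) utr5 <- utrs$utr5
    if (is.null(utr3)) utr3 <- utrs$utr3
  }
  utr5 <- normalize_segments(utr5, strand)
  utr3 <- normalize_segments(utr3, strand)
  for (u in list(utr5, utr3)) {
    if (!segments_within(u, exons)) {
      stop("gene ", gene_id, ": UTR outside exons", call. = FALSE)
    }
    if (nrow(u) && nrow(cds) && segments_overlap_any(u, cds)) {
      stop("gene ", gene_id, ": UTR overlaps CDS", call. = FALSE)
    }
  }
  tss <- if (strand == "+") min(exons$start) else max(exons$end)
  structure(list(gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 strand = strand, tss = as.integer(tss),
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

# coerce a segment table to integer start/end sorted in transcription order
normalize_segments <- function(segs, strand) {
  if (is.null(segs) || (is.data.frame(segs) && nrow(segs) == 0L)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  segs <- data.frame(start = as.integer(segs$start), end = as.integer(segs$end))
  if (any(segs$start > segs$end)) stop("segment with start > end", call. = FALSE)
  segs[order(segs$start, decreasing = (strand == "-")), , drop = FALSE]
}

segments_within <- function(inner, outer) {
  if (nrow(inner) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(inner)), function(i) {
    any(outer$start <= inner$start[i] & outer$end >= inner$end[i])
  }, logical(1)))
}

segments_overlap_any <- function(a, b) {
  any(outer(a$start, b$end, "<=") & outer(a$end, b$start, ">="))
}

# exonic space upstream/downstream of the CDS, in transcription order
derive_utrs <- function(exons, cds, strand) {
  empty <- data.frame(start = integer(0), end = integer(0))
  if (nrow(cds) == 0L) return(list(utr5 = empty, utr3 = empty))
  cds_lo <- min(cds$start)
  cds_hi <- max(cds$end)
  left <- empty   # exonic space genomically left of the CDS
  right <- empty  # ... and right of it
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (e < cds_lo) left <- rbind(left, data.frame(start = s, end = e))
    else if (s < cds_lo) left <- rbind(left, data.frame(start = s, end = cds_lo - 1L))
    if (s > cds_hi) right <- rbind(right, data.frame(start = s, end = e))
    else if (e > cds_hi) right <- rbind(right, data.frame(start = cds_hi + 1L, end = e))
  }
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

# genomic span of the gene body (closed interval over all exons)
gene_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

# intronic intervals: gene span minus exons, genomic order
model_introns <- function(model) {
  ex <- model$exons[order(model$exons$start), , drop = FALSE]
  if (nrow(ex) < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

# total CDS length in bp
cds_length <- function(model) {
  if (nrow(model$cds) == 0L) return(0L)
  sum(model$cds$end - model$cds$start + 1L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s  %s:%d-%d (%s)  %d exon(s), CDS %d bp, TSS %d\n",
              x$gene_id, x$chrom, gene_span(x)[["start"]],
              gene_span(x)[["end"]], x$strand, nrow(x$exons),
              cds_length(x), x$tss))
  invisible(x)
}
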