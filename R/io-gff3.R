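#' Read gene models from GFF3
#'
#' Parses a GFF3 file (via [rtracklayer::import()]) containing
#' `gene`/`mRNA`/`exon`/`CDS`/`five_prime_UTR`/`three_prime_UTR`
#' features linked by `ID`/`Parent`, and assembles one [gene_model()]
#' per mRNA. When UTR features are absent they are derived by
#' projecting the CDS onto the exons. The TSS follows from the strand.
#'
#' @param path GFF3 file.
#' @return List of `gene_model` objects, named by gene id.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parents <- vapply(
    as.list(gr$Parent %||% replicate(length(gr), character(0))),
    function(p) if (length(p)) p[[1]] else NA_character_, character(1)
  )
  known_ids <- ids[!is.na(ids)]
  bad <- !is.na(parents) & !(parents %in% known_ids)
  if (any(bad)) {
    stop("GFF3 feature(s) with orphan Parent: ",
         paste(unique(parents[bad]), collapse = ", "), call. = FALSE)
  }
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  models <- lapply(mrna_idx, function(i) {
    mid <- ids[i]
    if (is.na(mid)) stop("mRNA feature without ID", call. = FALSE)
    kid <- which(parents == mid)
    seg <- function(what) {
      k <- kid[type[kid] %in% what]
      if (!length(k)) return(NULL)
      data.frame(start = GenomicRanges::start(gr)[k],
                 end = GenomicRanges::end(gr)[k])
    }
    exons <- seg("exon")
    if (is.null(exons)) stop("mRNA ", mid, " has no exons", call. = FALSE)
    gene_id <- if (!is.na(parents[i])) parents[i] else mid
    gene_model(
      gene_id = gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons,
      cds = seg("CDS"),
      utr5 = seg("five_prime_UTR"),
      utr3 = seg("three_prime_UTR")
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon`, `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` features with `ID`/`Parent` links, such that
#' `read_gff3(write_gff3(models, path))` reproduces every field the
#' pipeline uses.
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- list()
  for (m in models) {
    gid <- m$gene_id
    mid <- paste0(gid, ".t1")
    span <- gene_span(m)
    add <- function(type, start, end, id = NA_character_,
                    parent = NA_character_, phase = NA_integer_) {
      data.frame(chrom = m$chrom, start = start, end = end,
                 strand = m$strand, type = type, id = id, parent = parent,
                 phase = phase, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      add("gene", span[["start"]], span[["end"]], id = gid)
    rows[[length(rows) + 1L]] <-
      add("mRNA", span[["start"]], span[["end"]], id = mid, parent = gid)
    if (nrow(m$exons)) {
      rows[[length(rows) + 1L]] <- add("exon", m$exons$start, m$exons$end,
                                       parent = mid)
    }
    if (nrow(m$cds)) {
      len <- m$cds$end - m$cds$start + 1L
      before <- cumsum(c(0L, len))[seq_len(nrow(m$cds))]
      rows[[length(rows) + 1L]] <- add("CDS", m$cds$start, m$cds$end,
                                       parent = mid,
                                       phase = (3L - before %% 3L) %% 3L)
    }
    if (nrow(m$utr5)) {
      rows[[length(rows) + 1L]] <- add("five_prime_UTR", m$utr5$start,
                                       m$utr5$end, parent = mid)
    }
    if (nrow(m$utr3)) {
      rows[[length(rows) + 1L]] <- add("three_prime_UTR", m$utr3$start,
                                       m$utr3$end, parent = mid)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  gr$source <- "poolvar"
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- ifelse(is.na(df$parent), "", df$parent)
  gr$Parent <- S4Vectors::unname(IRanges::CharacterList(
    lapply(gr$Parent, function(p) if (nzchar(p)) p else character(0))
  ))
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read capture target regions from BED
#'
#' BED input is 0-based half-open; the returned intervals are 1-based
#' closed like everything else in the package.
#'
#' @param path BED file (3+ columns).
#' @return List of [genomic_interval()] objects.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  lapply(seq_along(gr), function(i) {
    genomic_interval(as.character(GenomicRanges::seqnames(gr))[i],
                     GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])
  })
}

#' Write capture target regions to BED
#'
#' @param regions List of [genomic_interval()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(regions, `[[`, character(1), "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(regions, `[[`, integer(1), "start"),
      end = vapply(regions, `[[`, integer(1), "end")
    )
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
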