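#' Write per-pool variant calls to VCF
#'
#' Emits a minimal VCFv4.2 with one sample column named after the pool.
#' INFO carries `DP` (site depth), `AC` (alternate observation count),
#' `AF` (alternate fraction) and `PV` (binomial site p-value); the
#' pool-level zygosity class is encoded in the sample `GT` (`1/1` for
#' pool-homozygous, `0/1` for pool-heterozygous); `FILTER` is always
#' `PASS` since only calls surviving every gate are written. Optional
#' annotation columns (`gene_hits`, `effect`, `indel_class`) present in
#' `calls` are written as INFO keys `GENEHITS`, `EFFECT`, `ICLASS`.
#'
#' Deletions are written left-anchored (REF = anchor base plus deleted
#' sequence, ALT = anchor base) and insertions as anchor vs anchor plus
#' inserted sequence, the standard VCF indel convention.
#'
#' @param calls Variant-call data frame (see [call_variants()]), sorted
#'   by `(chrom, pos)`; a single pool.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path) {
  pool <- unique(calls$pool_id)
  if (length(pool) > 1L) stop("write_vcf: mixed pool_ids", call. = FALSE)
  if (length(pool) == 0L) pool <- "POOL"
  if (nrow(calls) > 1L) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("write_vcf: calls must be sorted by (chrom, pos)", call. = FALSE)
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolvar",
    paste0("##pool=", pool),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Pool read depth at site">',
    '##INFO=<ID=AC,Number=1,Type=Integer,Description="Alternate allele observation count">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele fraction in pool">',
    '##INFO=<ID=PV,Number=1,Type=Float,Description="Binomial upper-tail site p-value">'
  )
  has_ann <- all(c("gene_hits", "effect", "indel_class") %in% names(calls))
  if (has_ann) {
    hdr <- c(hdr,
      '##INFO=<ID=GENEHITS,Number=1,Type=String,Description="gene:component hits, comma separated; . if intergenic">',
      '##INFO=<ID=EFFECT,Number=1,Type=String,Description="synonymous|non-synonymous|non-coding">',
      '##INFO=<ID=ICLASS,Number=1,Type=String,Description="insertion|deletion|not-applicable">')
  }
  hdr <- c(hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Pool-level genotype class: 1/1 fixed (pool-homozygous), 0/1 segregating (pool-heterozygous)">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", pool, sep = "\t"))
  body <- character(0)
  if (nrow(calls)) {
    info <- sprintf("DP=%d;AC=%d;AF=%.10g;PV=%.10g", calls$depth,
                    calls$alt_count, calls$alt_fraction, calls$p_value)
    if (has_ann) {
      gh <- ifelse(is.na(calls$gene_hits) | !nzchar(calls$gene_hits), ".",
                   calls$gene_hits)
      info <- paste0(info, ";GENEHITS=", gh, ";EFFECT=", calls$effect,
                     ";ICLASS=", calls$indel_class)
    }
    gt <- ifelse(calls$zygosity == "pool-homozygous", "1/1", "0/1")
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT", gt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-pool VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return Variant-call data frame; `read_vcf(write_vcf(x))` reproduces
#'   every field of `x` that the pipeline uses.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hline <- grep("^#CHROM", lines)
  if (length(hline) != 1L) stop("malformed VCF: missing #CHROM header line",
                                call. = FALSE)
  cols <- strsplit(lines[hline], "\t", fixed = TRUE)[[1]]
  pool <- if (length(cols) >= 10L) cols[10] else NA_character_
  body <- lines[-seq_len(hline)]
  body <- body[nzchar(body)]
  parse_info <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "",
                    character(1)),
             vapply(kv, `[`, character(1), 1))
  }
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("malformed VCF line ", hline + i, ": fewer than 8 columns",
           call. = FALSE)
    }
    info <- parse_info(f[8])
    need <- c("DP", "AC", "AF", "PV")
    if (!all(need %in% names(info))) {
      stop("malformed VCF line ", hline + i, ": missing INFO key(s) ",
           paste(setdiff(need, names(info)), collapse = ","), call. = FALSE)
    }
    ref <- f[4]; alt <- f[5]
    vt <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
          else if (nchar(alt) > nchar(ref)) "INS" else "DEL"
    gt <- if (length(f) >= 10L) strsplit(f[10], ":", fixed = TRUE)[[1]][1]
          else "0/1"
    out <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = ref, alt = alt,
      var_type = vt, pool_id = pool,
      depth = as.integer(info[["DP"]]),
      alt_count = as.integer(info[["AC"]]),
      alt_fraction = as.numeric(info[["AF"]]),
      zygosity = if (gt == "1/1") "pool-homozygous" else "pool-heterozygous",
      p_value = as.numeric(info[["PV"]]),
      passed_fdr = TRUE,
      stringsAsFactors = FALSE
    )
    if ("GENEHITS" %in% names(info)) {
      out$gene_hits <- ifelse(info[["GENEHITS"]] == ".", "",
                              info[["GENEHITS"]])
      out$effect <- info[["EFFECT"]]
      out$indel_class <- info[["ICLASS"]]
    }
    out
  })
  if (!length(rows)) return(empty_calls())
  do.call(rbind, rows)
}

empty_calls <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), var_type = character(0),
             pool_id = character(0), depth = integer(0),
             alt_count = integer(0), alt_fraction = numeric(0),
             zygosity = character(0), p_value = numeric(0),
             passed_fdr = logical(0), stringsAsFactors = FALSE)
}
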