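#' Proximal promoter interval of a gene
#'
#' The proximal promoter is defined as the `promoter_length` bp
#' immediately upstream of the transcription start site, TSS excluded:
#' `[tss - L, tss - 1]` on the `+` strand, `[tss + 1, tss + L]` on
#' `-`, clipped at the chromosome bounds.
#'
#' @param gene A [gene_model()].
#' @param promoter_length Promoter length in bp (default 2000).
#' @param chrom_length Optional chromosome length for right-side
#'   clipping of `-` strand promoters.
#' @return A [genomic_interval()], or `NULL` when clipping leaves
#'   nothing (TSS at the chromosome edge).
#' @export
promoter_interval <- function(gene, promoter_length = 2000L,
                              chrom_length = NULL) {
  L <- as.integer(promoter_length)
  if (gene$strand == "+") {
    s <- max(1L, gene$tss - L)
    e <- gene$tss - 1L
  } else {
    s <- gene$tss + 1L
    e <- gene$tss + L
    if (!is.null(chrom_length)) e <- min(e, as.integer(chrom_length))
  }
  if (s > e) return(NULL)
  genomic_interval(gene$chrom, s, e, gene$strand)
}

# component precedence used when a variant hits several components of
# one gene: most specific wins
COMPONENT_PRECEDENCE <- c("CDS", "utr5", "utr3", "intron", "promoter")

# Build a GRanges index of every gene component (promoter, utr5, utr3,
# CDS, intron) over a list of gene models.
annotation_index <- function(models, promoter_length = 2000L,
                             chrom_lengths = NULL) {
  rows <- list()
  push <- function(chrom, start, end, gene, comp) {
    if (!length(start)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, gene = gene, comp = comp,
      stringsAsFactors = FALSE)
  }
  for (m in models) {
    cl <- if (!is.null(chrom_lengths)) chrom_lengths[[m$chrom]] else NULL
    pr <- promoter_interval(m, promoter_length, cl)
    if (!is.null(pr)) push(m$chrom, pr$start, pr$end, m$gene_id, "promoter")
    push(m$chrom, m$cds$start, m$cds$end, m$gene_id, "CDS")
    push(m$chrom, m$utr5$start, m$utr5$end, m$gene_id, "utr5")
    push(m$chrom, m$utr3$start, m$utr3$end, m$gene_id, "utr3")
    intr <- model_introns(m)
    push(m$chrom, intr$start, intr$end, m$gene_id, "intron")
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$gene <- df$gene
  gr$comp <- df$comp
  gr
}

# reference footprint of a variant key: the genomic span of its REF
# allele (a deletion spans the deleted bases; an insertion sits on its
# anchor base)
variant_footprint <- function(chrom, pos, ref) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(pos, pos + nchar(ref) - 1L))
}

#' Locate a variant within gene components
#'
#' For each gene whose body or proximal promoter overlaps the variant's
#' reference footprint, reports the single most specific overlapped
#' component with precedence CDS > UTR > intron > promoter. A variant
#' overlapping several genes (e.g. a deletion in one gene's 3'UTR that
#' also lies in an overlapping gene's intron) yields one hit per gene.
#' Empty hits mean the variant is intergenic.
#'
#' @param chrom,pos,ref Variant key components (ref allele string sets
#'   the footprint length).
#' @param models List of [gene_model()] objects, or a prebuilt index.
#' @param promoter_length Promoter length in bp.
#' @return Data frame with columns `gene`, `component`.
#' @export
locate_variant <- function(chrom, pos, ref, models,
                           promoter_length = 2000L) {
  idx <- if (methods::is(models, "GRanges")) models
         else annotation_index(models, promoter_length)
  hits_df(variant_footprint(chrom, pos, ref), idx)
}

hits_df <- function(fp, idx) {
  if (!length(idx)) return(data.frame(gene = character(0),
                                      component = character(0)))
  # a variant chromosome absent from the models is simply intergenic
  ov <- suppressWarnings(GenomicRanges::findOverlaps(fp, idx))
  if (!length(ov)) return(data.frame(gene = character(0),
                                     component = character(0)))
  h <- S4Vectors::subjectHits(ov)
  df <- data.frame(gene = idx$gene[h], comp = idx$comp[h],
                   stringsAsFactors = FALSE)
  # most specific component per gene
  df$rank <- match(df$comp, COMPONENT_PRECEDENCE)
  df <- df[order(df$gene, df$rank), , drop = FALSE]
  df <- df[!duplicated(df$gene), , drop = FALSE]
  data.frame(gene = df$gene, component = df$comp, stringsAsFactors = FALSE)
}

#' Coding effect of a SNP in a gene's CDS
#'
#' Locates the affected codon from the SNP's cumulative CDS position in
#' transcription order (on the `-` strand both the codon and the
#' alternate base are reverse-complemented), translates reference and
#' alternate codons with the standard genetic code, and classes the
#' change as `synonymous` or `non-synonymous` (stop gain/loss counts as
#' non-synonymous).
#'
#' @param pos,alt SNP position and alternate base.
#' @param gene A [gene_model()] whose CDS contains `pos`; total CDS
#'   length must be divisible by 3.
#' @param genome Named character vector of chromosome sequences.
#' @return `"synonymous"` or `"non-synonymous"`.
#' @export
cds_effect <- function(pos, alt, gene, genome) {
  if (cds_length(gene) %% 3L != 0L) {
    stop("gene ", gene$gene_id, ": CDS length not divisible by 3",
         call. = FALSE)
  }
  cds <- gene$cds  # already in transcription order
  seg <- which(cds$start <= pos & cds$end >= pos)
  if (!length(seg)) {
    stop("cds_effect: position ", pos, " not in CDS of ", gene$gene_id,
         call. = FALSE)
  }
  seg <- seg[1]
  seq <- genome[[gene$chrom]]
  seg_seqs <- substring(seq, cds$start, cds$end)
  if (gene$strand == "-") seg_seqs <- revcomp(seg_seqs)
  cds_seq <- paste(seg_seqs, collapse = "")
  lens <- cds$end - cds$start + 1L
  before <- if (seg > 1L) sum(lens[seq_len(seg - 1L)]) else 0L
  offset <- if (gene$strand == "+") pos - cds$start[seg] + 1L
            else cds$end[seg] - pos + 1L
  cds_pos <- before + offset
  alt_tx <- if (gene$strand == "+") alt else complement_base(alt)
  codon_i <- (cds_pos - 1L) %/% 3L
  within <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substring(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  alt_codon <- ref_codon
  substring(alt_codon, within, within) <- alt_tx
  code <- Biostrings::GENETIC_CODE
  if (code[[ref_codon]] == code[[alt_codon]]) "synonymous"
  else "non-synonymous"
}

#' Insertion/deletion class of an indel key
#'
#' @param ref,alt Key allele strings (left-anchored; equal lengths are
#'   a contract error since that is a SNP, not an indel).
#' @return List with `class` (`"insertion"` or `"deletion"`) and
#'   `length` (inserted/deleted bp).
#' @examples
#' indel_class("GCCACTGCCA", "G") # 9-bp deletion
#' @export
indel_class <- function(ref, alt) {
  if (nchar(ref) == nchar(alt)) {
    stop("indel_class: equal-length alleles are not an indel",
         call. = FALSE)
  }
  if (nchar(alt) > nchar(ref)) {
    list(class = "insertion", length = nchar(alt) - nchar(ref))
  } else {
    list(class = "deletion", length = nchar(ref) - nchar(alt))
  }
}

#' Annotate variant calls against gene models
#'
#' Produces one annotation record per distinct variant key: per-gene
#' component hits (promoter / utr5 / utr3 / CDS / intron, most specific
#' per gene, all overlapping genes kept), the coding effect for CDS
#' SNPs, the indel class for indels, and the `in_gene` / `in_mRNA`
#' flags used by the distribution reports (`in_gene` = overlapping any
#' gene body; `in_mRNA` = overlapping any exon).
#'
#' @param calls Variant-call data frame (any mix of pools; annotation
#'   is per distinct key).
#' @param models List of [gene_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param config A [pipeline_config()] (promoter length).
#' @return Data frame keyed by `(chrom, pos, ref, alt)` with columns
#'   `var_type`, `gene_hits` (encoded `"gene:component"` comma-joined,
#'   `""` if intergenic), `effect`, `indel_class`, `in_gene`,
#'   `in_mRNA`.
#' @export
annotate_variants <- function(calls, models, genome,
                              config = pipeline_config()) {
  keys <- unique(calls[, c("chrom", "pos", "ref", "alt", "var_type")])
  if (!nrow(keys)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      var_type = character(0), gene_hits = character(0),
                      effect = character(0), indel_class = character(0),
                      in_gene = logical(0), in_mRNA = logical(0)))
  }
  idx <- annotation_index(models, config$promoter_length,
                          chrom_lengths = vapply(genome, nchar, numeric(1)))
  fp <- variant_footprint(keys$chrom, keys$pos, keys$ref)

  # gene bodies and exons for the in_gene / in_mRNA flags
  body_gr <- GenomicRanges::GRanges(
    vapply(models, `[[`, character(1), "chrom"),
    IRanges::IRanges(
      vapply(models, function(m) gene_span(m)[["start"]], numeric(1)),
      vapply(models, function(m) gene_span(m)[["end"]], numeric(1))))
  exon_gr <- GenomicRanges::GRanges(
    rep(vapply(models, `[[`, character(1), "chrom"),
        vapply(models, function(m) nrow(m$exons), integer(1))),
    IRanges::IRanges(
      unlist(lapply(models, function(m) m$exons$start)),
      unlist(lapply(models, function(m) m$exons$end))))
  in_gene <- suppressWarnings(IRanges::overlapsAny(fp, body_gr))
  in_mRNA <- suppressWarnings(IRanges::overlapsAny(fp, exon_gr))

  ov <- suppressWarnings(GenomicRanges::findOverlaps(fp, idx))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)

  gene_hits <- character(nrow(keys))
  effect <- rep("non-coding", nrow(keys))
  iclass <- rep("not-applicable", nrow(keys))
  by_key <- split(sh, qh)
  model_by_id <- setNames(models, vapply(models, `[[`, character(1),
                                         "gene_id"))
  for (nm in names(by_key)) {
    i <- as.integer(nm)
    h <- by_key[[nm]]
    df <- data.frame(gene = idx$gene[h], comp = idx$comp[h],
                     stringsAsFactors = FALSE)
    df$rank <- match(df$comp, COMPONENT_PRECEDENCE)
    df <- df[order(df$gene, df$rank), , drop = FALSE]
    df <- df[!duplicated(df$gene), , drop = FALSE]
    df <- df[order(df$gene), , drop = FALSE]
    gene_hits[i] <- paste(paste0(df$gene, ":", df$comp), collapse = ",")
    if (keys$var_type[i] == "SNP" && any(df$comp == "CDS")) {
      effs <- vapply(df$gene[df$comp == "CDS"], function(g) {
        cds_effect(keys$pos[i], keys$alt[i], model_by_id[[g]], genome)
      }, character(1))
      effect[i] <- if (any(effs == "non-synonymous")) "non-synonymous"
                   else "synonymous"
    }
  }
  is_indel <- keys$var_type != "SNP"
  iclass[is_indel] <- vapply(which(is_indel), function(i) {
    indel_class(keys$ref[i], keys$alt[i])$class
  }, character(1))

  data.frame(keys, gene_hits = gene_hits, effect = effect,
             indel_class = iclass, in_gene = in_gene, in_mRNA = in_mRNA,
             stringsAsFactors = FALSE, row.names = NULL)
}
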