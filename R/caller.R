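#' Binomial upper-tail site p-value
#'
#' Probability of observing at least `alt_count` alternate reads out of
#' `depth` if every mismatch were an independent sequencing error with
#' probability `error_rate`: `P[X >= alt_count | X ~ Bin(depth,
#' error_rate)]`. This is the per-site test statistic the caller feeds
#' into Benjamini-Hochberg FDR control; it is monotone non-increasing
#' in `alt_count` at fixed depth.
#'
#' @param alt_count Alternate read count(s), `0 <= alt_count <= depth`.
#' @param depth Site read depth(s).
#' @param error_rate Per-base error probability in (0, 1).
#' @return Upper-tail probabilities.
#' @examples
#' site_pvalue(0, 30, 0.01)   # 1: the whole distribution
#' site_pvalue(10, 10, 0.01)  # 0.01^10 = 1e-20
#' @export
site_pvalue <- function(alt_count, depth, error_rate) {
  if (any(alt_count < 0 | alt_count > depth)) {
    stop("site_pvalue: require 0 <= alt_count <= depth", call. = FALSE)
  }
  if (length(error_rate) != 1L || error_rate <= 0 || error_rate >= 1) {
    stop("site_pvalue: error_rate must lie in (0, 1)", call. = FALSE)
  }
  pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up flags
#'
#' Standard BH step-up at level `q`: sort the p-values ascending, find
#' the largest rank `i` with `p(i) <= i q / m`, and flag all ranks up
#' to `i` (ties share a fate; the original order is restored).
#' Implemented through [stats::p.adjust()] (`adjusted p <= q` is
#' exactly the step-up rule).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
bh_fdr <- function(p_values, q) {
  if (length(q) != 1L || q <= 0 || q >= 1) {
    stop("bh_fdr: q must lie in (0, 1)", call. = FALSE)
  }
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Classify pool-level zygosity from the alternate-allele fraction
#'
#' A pooled call is classed `pool-homozygous` -- effectively fixed in
#' the pool -- when its alternate fraction is at least
#' `hom_fraction_min` (default 0.8), and `pool-heterozygous`
#' (segregating) otherwise. The caller guarantees every emitted call
#' has fraction at least `het_fraction_min`; fractions below that are a
#' contract violation.
#'
#' @param alt_fraction Alternate-allele fraction(s) in `(0, 1]`.
#' @param config A [pipeline_config()].
#' @return Character vector of zygosity classes.
#' @export
classify_zygosity <- function(alt_fraction, config = pipeline_config()) {
  if (any(alt_fraction < config$het_fraction_min | alt_fraction > 1)) {
    stop("classify_zygosity: fraction below het_fraction_min (",
         config$het_fraction_min, ") or above 1", call. = FALSE)
  }
  ifelse(alt_fraction >= config$hom_fraction_min,
         "pool-homozygous", "pool-heterozygous")
}

#' Left-align an indel key against the reference
#'
#' Canonicalises an indel's `(pos, ref, alt)` by shifting it left one
#' base at a time while the base preceding the anchor equals the last
#' base of the inserted/deleted sequence. SNPs are returned unchanged.
#' Exact set matching across pools relies on every key being in this
#' canonical form.
#'
#' @param chrom,pos,ref,alt Variant key components (scalar).
#' @param genome Named character vector of chromosome sequences.
#' @return List with `chrom`, `pos`, `ref`, `alt`.
#' @export
left_align_key <- function(chrom, pos, ref, alt, genome) {
  if (nchar(ref) == nchar(alt)) {
    return(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt))
  }
  seq <- genome[[chrom]]
  # indel sequence beyond the shared anchor base
  ind <- if (nchar(ref) > nchar(alt)) substring(ref, 2) else substring(alt, 2)
  pos <- as.integer(pos)
  k <- nchar(ind)
  # shifting the event one base left is valid while the anchor base
  # equals the last base of the indel sequence (the indel rotates)
  while (pos > 1L) {
    anchor <- substring(seq, pos, pos)
    if (anchor != substring(ind, k, k)) break
    ind <- paste0(anchor, substring(ind, 1L, k - 1L))
    pos <- pos - 1L
  }
  anchor <- substring(seq, pos, pos)
  if (nchar(ref) > nchar(alt)) {
    list(chrom = chrom, pos = pos, ref = paste0(anchor, ind), alt = anchor)
  } else {
    list(chrom = chrom, pos = pos, ref = anchor, alt = paste0(anchor, ind))
  }
}

#' Call SNPs and indels in one pool
#'
#' Applies the three calling gates to every pileup site of a single
#' pool: (1) coverage strictly greater than
#' `config$min_depth_exclusive`; (2) modal non-reference allele
#' fraction at least `config$het_fraction_min`; (3) Benjamini-Hochberg
#' FDR below `config$fdr_q` over the binomial site p-values of all
#' gate-1/gate-2 candidates jointly. At multi-allelic sites only the
#' modal alternate allele is considered, ties broken lexicographically
#' (substitution alleles before indel alleles on equal counts).
#'
#' @param sites Per-site table from [read_pileup()], or a list of
#'   `pileup_site` objects from [parse_pileup_line()]. Must be sorted
#'   by `(chrom, pos)` and belong to one pool.
#' @param config A [pipeline_config()].
#' @param genome Optional named character vector of reference
#'   sequences; when supplied, indel keys are left-aligned against it.
#' @return Variant-call data frame sorted by `(chrom, pos)` with
#'   columns `chrom, pos, ref, alt, var_type, pool_id, depth,
#'   alt_count, alt_fraction, zygosity, p_value, passed_fdr`.
#' @export
call_variants <- function(sites, config = pipeline_config(), genome = NULL) {
  if (is.list(sites) && !is.data.frame(sites)) {
    sites <- pileup_sites_to_df(sites)
  }
  if (!nrow(sites)) return(empty_calls())
  if (length(unique(sites$pool_id)) > 1L) {
    stop("call_variants: sites from more than one pool", call. = FALSE)
  }
  o <- order(sites$chrom, sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) {
    stop("call_variants: sites must be sorted by (chrom, pos)", call. = FALSE)
  }

  # modal non-reference substitution allele per site, lexicographic ties
  bases <- c("A", "C", "G", "T")
  sub <- as.matrix(sites[, bases])
  ref_i <- match(sites$ref, bases)
  ok <- !is.na(ref_i)  # a ref of N has no column to mask
  sub[cbind(seq_len(nrow(sub))[ok], ref_i[ok])] <- -1L  # mask ref base
  best_sub_i <- max.col(sub, ties.method = "first")  # first = lexicographic
  best_sub_n <- sub[cbind(seq_len(nrow(sub)), best_sub_i)]
  alt_allele <- bases[best_sub_i]
  alt_count <- best_sub_n

  # compare against the modal indel allele where present
  has_ind <- which(!vapply(sites$indels, is.null, logical(1)))
  for (i in has_ind) {
    ind <- sites$indels[[i]]
    ind <- ind[order(-ind, names(ind))]  # modal, lexicographic tie-break
    if (ind[1] > alt_count[i]) {
      alt_allele[i] <- names(ind)[1]
      alt_count[i] <- ind[1]
    }
  }

  depth_ok <- sites$depth > config$min_depth_exclusive
  frac <- ifelse(sites$depth > 0, alt_count / sites$depth, 0)
  cand <- which(depth_ok & alt_count > 0 & frac >= config$het_fraction_min)
  if (!length(cand)) return(empty_calls())

  pv_cand <- site_pvalue(alt_count[cand], sites$depth[cand],
                         config$base_error_rate)
  flags <- bh_fdr(pv_cand, config$fdr_q)
  keep <- cand[flags]
  pv <- pv_cand[flags]
  if (!length(keep)) return(empty_calls())

  calls <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    a <- alt_allele[i]
    anchor <- sites$ref[i]
    if (substring(a, 1, 1) == "+") {
      ref <- anchor; alt <- paste0(anchor, substring(a, 2)); vt <- "INS"
    } else if (substring(a, 1, 1) == "-") {
      ref <- paste0(anchor, substring(a, 2)); alt <- anchor; vt <- "DEL"
    } else {
      ref <- anchor; alt <- a; vt <- "SNP"
    }
    key <- list(chrom = sites$chrom[i], pos = sites$pos[i],
                ref = ref, alt = alt)
    if (!is.null(genome) && vt != "SNP") {
      key <- left_align_key(key$chrom, key$pos, key$ref, key$alt, genome)
    }
    data.frame(chrom = key$chrom, pos = key$pos, ref = key$ref,
               alt = key$alt, var_type = vt,
               pool_id = sites$pool_id[i], depth = sites$depth[i],
               alt_count = alt_count[i],
               alt_fraction = alt_count[i] / sites$depth[i],
               zygosity = classify_zygosity(alt_count[i] / sites$depth[i],
                                            config),
               p_value = pv[j], passed_fdr = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
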