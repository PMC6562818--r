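#' Per-group phenotype statistics
#'
#' Mean and sample standard deviation of the phenotype per
#' (breed, group) and per breed overall, rounded half-up to 2 decimals.
#' Empty groups are omitted with a warning.
#'
#' @param phenotypes Data frame with columns `breed`, `group`
#'   (`"high"`/`"low"`), `value` (one row per bird).
#' @return Data frame `breed`, `group` (including `"all"`), `n`,
#'   `mean`, `sd`.
#' @export
group_stats <- function(phenotypes) {
  stopifnot(all(c("breed", "group", "value") %in% names(phenotypes)))
  out <- list()
  for (b in unique(phenotypes$breed)) {
    sub <- phenotypes[phenotypes$breed == b, , drop = FALSE]
    for (g in c("all", "high", "low")) {
      v <- if (g == "all") sub$value else sub$value[sub$group == g]
      if (!length(v)) {
        warning("group_stats: empty group ", b, "/", g, " omitted",
                call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        breed = b, group = g, n = length(v),
        mean = round_half_up(mean(v), 2),
        sd = round_half_up(if (length(v) > 1L) sd(v) else 0, 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fold change between group means
#'
#' @param high_mean,low_mean Group phenotype means; `low_mean` must be
#'   positive.
#' @return `high_mean / low_mean` rounded half-up to 1 decimal.
#' @examples
#' fold_change(1501.70, 293.91) # 5.1
#' fold_change(1888.84, 302.55) # 6.2
#' @export
fold_change <- function(high_mean, low_mean) {
  if (any(low_mean <= 0)) stop("fold_change: low_mean must be > 0",
                               call. = FALSE)
  round_half_up(high_mean / low_mean, 1)
}

#' Distribution table with percentages
#'
#' The common shape of the component-distribution reports: ordered
#' `(label, count)` pairs with each percentage recomputed as
#' `100 * count / total`, rounded half-up to 1 decimal.
#'
#' @param labels Character vector of row labels.
#' @param counts Integer vector of counts.
#' @param total Denominator count.
#' @return Data frame `label`, `count`, `percent` with attribute
#'   `total`.
#' @export
distribution_table <- function(labels, counts, total) {
  stopifnot(length(labels) == length(counts), total >= 0)
  out <- data.frame(label = labels, count = as.integer(counts),
                    percent = if (total > 0) {
                      round_half_up(100 * counts / total, 1)
                    } else {
                      rep(NA_real_, length(counts))
                    },
                    stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  out
}

# deduplicate calls across pools to the union key set; union-level
# zygosity: homozygous only if pool-homozygous in every pool carrying it
dedupe_union <- function(calls) {
  if (!nrow(calls)) {
    u <- calls[, c("chrom", "pos", "ref", "alt", "var_type")]
    u$zygosity <- character(0)
    return(u)
  }
  kk <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  hom <- tapply(calls$zygosity == "pool-homozygous", kk, all)
  u <- calls[!duplicated(kk), c("chrom", "pos", "ref", "alt", "var_type"),
             drop = FALSE]
  u$zygosity <- ifelse(hom[variant_key(u$chrom, u$pos, u$ref, u$alt)],
                       "homozygous", "heterozygous")
  u <- u[order(u$chrom, u$pos, u$ref, u$alt), , drop = FALSE]
  rownames(u) <- NULL
  u
}

# attach annotation columns to a unique-key table
join_annotations <- function(keys, annotations) {
  i <- match(variant_key(keys$chrom, keys$pos, keys$ref, keys$alt),
             variant_key(annotations$chrom, annotations$pos,
                         annotations$ref, annotations$alt))
  cbind(keys, annotations[i, c("gene_hits", "effect", "indel_class",
                               "in_gene", "in_mRNA"), drop = FALSE])
}

#' SNP distribution across genomic components
#'
#' Counts (and percentages of the SNP total) of union-deduplicated
#' SNPs that are homozygous / heterozygous at the union level,
#' non-synonymous / synonymous, inside any gene body, and inside any
#' mRNA (exon). "Homozygous" at the union level means pool-homozygous
#' in every pool carrying the variant.
#'
#' @param calls Combined calls from all pools (data frame).
#' @param annotations Output of [annotate_variants()].
#' @return A [distribution_table()].
#' @export
snp_distribution <- function(calls, annotations) {
  u <- join_annotations(dedupe_union(calls[calls$var_type == "SNP", ,
                                           drop = FALSE]),
                        annotations)
  distribution_table(
    c("homozygous", "heterozygous", "non_synonymous", "synonymous",
      "gene", "mRNA"),
    c(sum(u$zygosity == "homozygous"), sum(u$zygosity == "heterozygous"),
      sum(u$effect == "non-synonymous"), sum(u$effect == "synonymous"),
      sum(u$in_gene), sum(u$in_mRNA)),
    nrow(u))
}

#' Indel distribution across genomic components
#'
#' Counts (and percentages of the indel total) of union-deduplicated
#' indels by class (insertion / deletion) and location (CDS, UTR,
#' mRNA).
#'
#' @inheritParams snp_distribution
#' @return A [distribution_table()].
#' @export
indel_distribution <- function(calls, annotations) {
  u <- join_annotations(dedupe_union(calls[calls$var_type != "SNP", ,
                                           drop = FALSE]),
                        annotations)
  in_comp <- function(comp) {
    vapply(u$gene_hits, function(h) {
      any(grepl(paste0(":", comp, "$"),
                strsplit(h, ",", fixed = TRUE)[[1]]))
    }, logical(1), USE.NAMES = FALSE)
  }
  distribution_table(
    c("insertion", "deletion", "CDS", "UTR", "mRNA"),
    c(sum(u$indel_class == "insertion"), sum(u$indel_class == "deletion"),
      sum(in_comp("CDS")), sum(in_comp("utr5") | in_comp("utr3")),
      sum(u$in_mRNA)),
    nrow(u))
}

#' Sanger validation consistency rate
#'
#' Percentage of SNP validation rows confirmed by resequencing; indel
#' rows are excluded from the denominator. Half-up, 1 decimal.
#'
#' @param validation Data frame with columns `variant_type`
#'   (`"SNP"` rows counted) and `consistent` (`"yes"`/`"no"` or
#'   logical).
#' @return Percentage (scalar).
#' @export
validation_rate <- function(validation) {
  snp <- validation[toupper(validation$variant_type) == "SNP", ,
                    drop = FALSE]
  if (!nrow(snp)) stop("validation_rate: no SNP rows", call. = FALSE)
  ok <- if (is.logical(snp$consistent)) snp$consistent
        else tolower(snp$consistent) %in% c("yes", "true", "y", "1")
  round_half_up(100 * sum(ok) / nrow(snp), 1)
}

#' Group-specific non-synonymous / promoter SNP counts
#'
#' For each breed's high- and low-specific SNP sets (present in that
#' group's pool and absent from the breed's other pool) and for the
#' cross-breed common sets, counts SNPs that are non-synonymous in a
#' CDS and SNPs in a proximal promoter.
#'
#' @param comparison Output of [compare_pools()].
#' @param annotations Output of [annotate_variants()].
#' @return Data frame `set`, `cds_non_synonymous`, `promoter`.
#' @export
nonsyn_promoter_counts <- function(comparison, annotations) {
  mat <- comparison$matrix
  kk <- variant_key(mat$chrom, mat$pos, mat$ref, mat$alt)
  ann_of <- function(keys) {
    i <- match(keys, variant_key(annotations$chrom, annotations$pos,
                                 annotations$ref, annotations$alt))
    annotations[i, , drop = FALSE]
  }
  count_set <- function(keys) {
    a <- ann_of(keys)
    a <- a[a$var_type == "SNP", , drop = FALSE]
    c(cds_non_synonymous = sum(a$effect == "non-synonymous"),
      promoter = sum(grepl(":promoter(,|$)", a$gene_hits)))
  }
  spec_keys <- function(high, low) kk[mat[[high]] & !mat[[low]]]
  sets <- list(
    `WL-high` = spec_keys("WL-H", "WL-L"),
    `BY-high` = spec_keys("BY-H", "BY-L"),
    `common-high` = unique(c(comparison$common_high$key_wl,
                             comparison$common_high$key_by)),
    `WL-low` = spec_keys("WL-L", "WL-H"),
    `BY-low` = spec_keys("BY-L", "BY-H"),
    `common-low` = unique(c(comparison$common_low$key_wl,
                            comparison$common_low$key_by))
  )
  out <- do.call(rbind, lapply(sets, count_set))
  data.frame(set = names(sets), out, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Gene-level map of cross-breed common variants
#'
#' Lists, for the common-high and common-low sets, the genes carrying
#' SNP hits split into proximal-promoter and CDS columns, and reports
#' each common indel with its sequence and every gene/component it
#' touches (an indel in one gene's 3'UTR overlapping another gene's
#' intron yields one row listing both).
#'
#' @param comparison Output of [compare_pools()].
#' @param annotations Output of [annotate_variants()].
#' @return List with `snp_genes` (data frame `igy_group`, `component`,
#'   `gene`) and `indels` (data frame `igy_group`, `indel_type`,
#'   `sequence`, `genes`, `components`).
#' @export
common_gene_map <- function(comparison, annotations) {
  akey <- variant_key(annotations$chrom, annotations$pos,
                      annotations$ref, annotations$alt)
  snp_rows <- list()
  indel_rows <- list()
  for (side in c("high", "low")) {
    cc <- comparison[[paste0("common_", side)]]
    keys <- unique(c(cc$key_wl, cc$key_by))
    for (k in keys) {
      a <- annotations[match(k, akey), , drop = FALSE]
      if (is.na(a$gene_hits) || !nzchar(a$gene_hits)) next
      hits <- strsplit(strsplit(a$gene_hits, ",", fixed = TRUE)[[1]],
                       ":", fixed = TRUE)
      genes <- vapply(hits, `[`, character(1), 1)
      comps <- vapply(hits, `[`, character(1), 2)
      if (a$var_type == "SNP") {
        sel <- comps %in% c("promoter", "CDS")
        if (any(sel)) {
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            igy_group = side, component = comps[sel], gene = genes[sel],
            stringsAsFactors = FALSE)
        }
      } else {
        ic <- indel_class(a$ref, a$alt)
        seqs <- if (ic$class == "deletion") substring(a$ref, 2)
                else substring(a$alt, 2)
        indel_rows[[length(indel_rows) + 1L]] <- data.frame(
          igy_group = side, indel_type = ic$class, sequence = seqs,
          genes = paste(genes, collapse = "/"),
          components = paste(comps, collapse = "/"),
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_snp <- data.frame(igy_group = character(0),
                          component = character(0), gene = character(0))
  empty_ind <- data.frame(igy_group = character(0),
                          indel_type = character(0),
                          sequence = character(0), genes = character(0),
                          components = character(0))
  list(
    snp_genes = if (length(snp_rows)) {
      unique(do.call(rbind, snp_rows))
    } else {
      empty_snp
    },
    indels = if (length(indel_rows)) {
      do.call(rbind, indel_rows)
    } else {
      empty_ind
    }
  )
}
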