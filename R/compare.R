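#' Build the variant-by-pool presence matrix
#'
#' Rows are distinct left-aligned variant keys (union over the four
#' pools), columns the pools `BY-H, BY-L, WL-H, WL-L`; a cell is `TRUE`
#' when the variant passed every calling gate in that pool. Absence of
#' a call is treated as absence of the variant.
#'
#' @param call_sets Named list of per-pool variant-call data frames;
#'   names must be the four pool ids.
#' @return Data frame with key columns `chrom, pos, ref, alt,
#'   var_type` and one logical column per pool, sorted by
#'   `(chrom, pos, ref, alt)`.
#' @export
build_matrix <- function(call_sets) {
  if (!setequal(names(call_sets), POOL_IDS)) {
    stop("build_matrix: call_sets must be named ",
         paste(POOL_IDS, collapse = ", "), call. = FALSE)
  }
  keyed <- lapply(POOL_IDS, function(p) {
    cs <- call_sets[[p]]
    if (!nrow(cs)) return(character(0))
    k <- variant_key(cs$chrom, cs$pos, cs$ref, cs$alt)
    if (anyDuplicated(k)) {
      stop("build_matrix: duplicate key in pool ", p, ": ",
           k[duplicated(k)][1], call. = FALSE)
    }
    k
  })
  names(keyed) <- POOL_IDS
  all_calls <- do.call(rbind, lapply(call_sets, function(cs) {
    cs[, c("chrom", "pos", "ref", "alt", "var_type"), drop = FALSE]
  }))
  if (is.null(all_calls) || !nrow(all_calls)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      var_type = character(0))
    for (p in POOL_IDS) out[[p]] <- logical(0)
    return(out)
  }
  keys <- all_calls[!duplicated(variant_key(all_calls$chrom, all_calls$pos,
                                            all_calls$ref, all_calls$alt)),
                    , drop = FALSE]
  kk <- variant_key(keys$chrom, keys$pos, keys$ref, keys$alt)
  for (p in POOL_IDS) keys[[p]] <- kk %in% keyed[[p]]
  keys <- keys[order(keys$chrom, keys$pos, keys$ref, keys$alt), ,
               drop = FALSE]
  rownames(keys) <- NULL
  keys
}

# the seven per-variant breed/group categories
BREED_CATEGORIES <- c("BY-only-shared", "BY-only-high-specific",
                      "BY-only-low-specific", "WL-only-shared",
                      "WL-only-high-specific", "WL-only-low-specific",
                      "both-breeds")

#' Partition presence-matrix rows into breed/group categories
#'
#' Breed-only = present in at least one pool of that breed and no pool
#' of the other; within a breed-only set: shared = present in both of
#' its pools, high-specific = high pool only, low-specific = low pool
#' only. Variants seen in both breeds fall into `both-breeds`. The
#' seven categories partition the rows.
#'
#' @param matrix Presence matrix from [build_matrix()].
#' @return The matrix with an added `category` column.
#' @export
breed_partition <- function(matrix) {
  by <- matrix[["BY-H"]] | matrix[["BY-L"]]
  wl <- matrix[["WL-H"]] | matrix[["WL-L"]]
  cat <- character(nrow(matrix))
  cat[by & wl] <- "both-breeds"
  only_class <- function(high, low) {
    ifelse(high & low, "shared", ifelse(high, "high-specific",
                                        "low-specific"))
  }
  i <- by & !wl
  cat[i] <- paste0("BY-only-", only_class(matrix[["BY-H"]][i],
                                          matrix[["BY-L"]][i]))
  i <- wl & !by
  cat[i] <- paste0("WL-only-", only_class(matrix[["WL-H"]][i],
                                          matrix[["WL-L"]][i]))
  matrix$category <- cat
  matrix
}

#' Cross-breed common group-specific variants
#'
#' For each breed, the high-specific set is the variants present in its
#' high pool and absent from its low pool (and symmetrically for low).
#' The cross-breed common-high set pairs each White Leghorn
#' high-specific variant with a Beijing-You high-specific variant
#' either by identical key (`same-type`: the two breeds carry the same
#' mutation) or by identical `(chrom, pos, ref)` with differing
#' alternate allele for SNPs -- or anchor positions within
#' `indel_match_window` bp for indels -- (`different-type`). Pairing is
#' greedy in sorted position order and each key joins at most one
#' pair; symmetric for common-low.
#'
#' @param matrix Presence matrix from [build_matrix()].
#' @param config A [pipeline_config()] (indel match window).
#' @return List with data frames `common_high` and `common_low`, each
#'   with columns `key_wl`, `key_by`, `chrom`, `pos`, `match_type`.
#' @export
cross_breed_common <- function(matrix, config = pipeline_config()) {
  spec <- function(high, low) matrix[high & !low, , drop = FALSE]
  pair_sets <- function(a, b) {  # a = WL-specific rows, b = BY-specific rows
    if (!nrow(a) || !nrow(b)) {
      return(data.frame(key_wl = character(0), key_by = character(0),
                        chrom = character(0), pos = integer(0),
                        match_type = character(0)))
    }
    a <- a[order(a$chrom, a$pos, a$ref, a$alt), , drop = FALSE]
    b <- b[order(b$chrom, b$pos, b$ref, b$alt), , drop = FALSE]
    ka <- variant_key(a$chrom, a$pos, a$ref, a$alt)
    kb <- variant_key(b$chrom, b$pos, b$ref, b$alt)
    used_b <- logical(nrow(b))
    out <- list()
    # pass 1: identical keys (same-type)
    for (i in seq_len(nrow(a))) {
      j <- which(!used_b & kb == ka[i])
      if (length(j)) {
        used_b[j[1]] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          key_wl = ka[i], key_by = kb[j[1]], chrom = a$chrom[i],
          pos = a$pos[i], match_type = "same-type",
          stringsAsFactors = FALSE)
        ka[i] <- NA_character_
      }
    }
    # pass 2: same position (SNP) or nearby anchor (indel), different allele
    for (i in seq_len(nrow(a))) {
      if (is.na(ka[i])) next
      if (a$var_type[i] == "SNP") {
        j <- which(!used_b & b$var_type == "SNP" & b$chrom == a$chrom[i] &
                     b$pos == a$pos[i] & b$ref == a$ref[i] &
                     b$alt != a$alt[i])
      } else {
        j <- which(!used_b & b$var_type != "SNP" & b$chrom == a$chrom[i] &
                     abs(b$pos - a$pos[i]) <= config$indel_match_window)
      }
      if (length(j)) {
        used_b[j[1]] <- TRUE
        out[[length(out) + 1L]] <- data.frame(
          key_wl = ka[i], key_by = kb[j[1]], chrom = a$chrom[i],
          pos = a$pos[i], match_type = "different-type",
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      return(data.frame(key_wl = character(0), key_by = character(0),
                        chrom = character(0), pos = integer(0),
                        match_type = character(0)))
    }
    do.call(rbind, out)
  }
  list(
    common_high = pair_sets(spec(matrix[["WL-H"]], matrix[["WL-L"]]),
                            spec(matrix[["BY-H"]], matrix[["BY-L"]])),
    common_low = pair_sets(spec(matrix[["WL-L"]], matrix[["WL-H"]]),
                           spec(matrix[["BY-L"]], matrix[["BY-H"]]))
  )
}

#' Match two indel keys within a positional window
#'
#' Stand-in for the "same genomic region" criterion when comparing
#' group-specific indels across breeds: identical keys are
#' `same-type`; anchors within `window` bp (with a different position
#' or allele) are `different-type`; anything farther, or on different
#' chromosomes, is `no-match`.
#'
#' @param key_a,key_b Lists with `chrom`, `pos`, `ref`, `alt`.
#' @param window Match window in bp.
#' @return `"same-type"`, `"different-type"` or `"no-match"`.
#' @export
indel_match <- function(key_a, key_b, window = 10L) {
  if (!identical(key_a$chrom, key_b$chrom)) return("no-match")
  if (key_a$pos == key_b$pos && key_a$ref == key_b$ref &&
      key_a$alt == key_b$alt) {
    return("same-type")
  }
  if (abs(key_a$pos - key_b$pos) <= window) return("different-type")
  "no-match"
}

#' Full four-pool comparison
#'
#' Runs [build_matrix()], [breed_partition()] and
#' [cross_breed_common()] and attaches per-variant cross-breed match
#' labels: a variant that is a member of a common-high (or common-low)
#' pair gets `cross_group` `"common-high"`/`"common-low"` and its
#' pair's `match_type`.
#'
#' @param call_sets Named list of four per-pool call data frames.
#' @param config A [pipeline_config()].
#' @return List with `matrix` (presence + `category`, `cross_group`,
#'   `match_type` columns), `common_high`, `common_low`.
#' @export
compare_pools <- function(call_sets, config = pipeline_config()) {
  mat <- breed_partition(build_matrix(call_sets))
  common <- cross_breed_common(mat, config)
  kk <- variant_key(mat$chrom, mat$pos, mat$ref, mat$alt)
  mat$cross_group <- character(nrow(mat))
  mat$match_type <- character(nrow(mat))
  for (side in c("common_high", "common_low")) {
    cc <- common[[side]]
    lab <- if (side == "common_high") "common-high" else "common-low"
    for (col in c("key_wl", "key_by")) {
      i <- match(cc[[col]], kk)
      mat$cross_group[i] <- lab
      mat$match_type[i] <- cc$match_type
    }
  }
  list(matrix = mat, common_high = common$common_high,
       common_low = common$common_low)
}

#' Venn-style category counts
#'
#' Counts presence-matrix rows per breed/group category, split by
#' variant class (SNP vs indel), mirroring the two-breed Venn summary
#' figures.
#'
#' @param matrix Presence matrix with `category` column.
#' @return Data frame `class`, `category`, `count` (all category ×
#'   class combinations, zero-filled).
#' @export
venn_counts <- function(matrix) {
  cls <- ifelse(matrix$var_type == "SNP", "SNP", "Indel")
  out <- expand.grid(class = c("SNP", "Indel"),
                     category = BREED_CATEGORIES,
                     stringsAsFactors = FALSE)
  out$count <- mapply(function(cl, ca) {
    sum(cls == cl & matrix$category == ca)
  }, out$class, out$category)
  out[order(out$class, decreasing = TRUE), , drop = FALSE]
}
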