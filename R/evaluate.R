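#' Recover truth categories from a four-pool comparison
#'
#' Maps each presence-matrix row back to the planted-category
#' vocabulary of [plant_variants()]: members of a cross-breed
#' common pair become `common-high` / `common-low` when matched by
#' identical key, or `diff-allele-high` / `diff-allele-low` when
#' matched at the same position with a different allele; every other
#' row keeps its breed/group partition category.
#'
#' @param comparison Output of [compare_pools()].
#' @return The comparison matrix with a `recovered_category` column.
#' @export
recover_categories <- function(comparison) {
  mat <- comparison$matrix
  rec <- mat$category
  hi <- mat$cross_group == "common-high"
  lo <- mat$cross_group == "common-low"
  rec[hi & mat$match_type == "same-type"] <- "common-high"
  rec[hi & mat$match_type == "different-type"] <- "diff-allele-high"
  rec[lo & mat$match_type == "same-type"] <- "common-low"
  rec[lo & mat$match_type == "different-type"] <- "diff-allele-low"
  mat$recovered_category <- rec
  mat
}

#' Category precision and recall against a planted truth
#'
#' Recall is the fraction of truth records whose key was called and
#' assigned its planted category; precision is the fraction of called
#' keys that exist in the truth with the correct category.
#'
#' @param comparison Output of [compare_pools()].
#' @param truth Output of [plant_variants()].
#' @return List with `precision`, `recall`, `n_truth`, `n_called`.
#' @export
evaluate_recovery <- function(comparison, truth) {
  mat <- recover_categories(comparison)
  ck <- variant_key(mat$chrom, mat$pos, mat$ref, mat$alt)
  tk <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  i <- match(tk, ck)
  recall_ok <- !is.na(i) & mat$recovered_category[i] == truth$category
  j <- match(ck, tk)
  prec_ok <- !is.na(j) & truth$category[j] == mat$recovered_category
  list(precision = if (nrow(mat)) mean(prec_ok) else NA_real_,
       recall = if (nrow(truth)) mean(recall_ok) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(mat))
}

#' False-discovery proportion of a call set against a planted truth
#'
#' Proportion of distinct called variant keys absent from the truth.
#'
#' @param calls Combined call data frame (any pools).
#' @param truth Output of [plant_variants()].
#' @return Proportion in `[0, 1]` (`NA` when nothing was called).
#' @export
false_discovery_proportion <- function(calls, truth) {
  ck <- unique(variant_key(calls$chrom, calls$pos, calls$ref, calls$alt))
  if (!length(ck)) return(NA_real_)
  tk <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  mean(!(ck %in% tk))
}
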