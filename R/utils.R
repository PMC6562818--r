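#' Round half away from zero
#'
#' Decimal rounding where exact .5 ties go up (for positive input), the
#' convention used by the pipeline's printed report tables. Base R's
#' `round()` rounds half to even, which disagrees with printed table
#' values on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-up (half away from zero for
#'   negative input).
#' @examples
#' round_half_up(0.125, 2) # 0.13
#' round(0.125, 2)         # 0.12 (half-even)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are conceptually exact
  # ties but stored just below .5 in binary still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards. All randomised operations in the package route
# through this so a seed argument never leaks global state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stage offset, kept within
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of a plain character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

# Write a data.frame as a UTF-8 TSV with header, no quoting, no rownames.
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

# variant key as a single string, used for set membership everywhere
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
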