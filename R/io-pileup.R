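#' Parse one samtools-style text pileup line
#'
#' Reference implementation of the 6-column text pileup grammar
#' (`chrom  pos  ref  depth  read-bases  qualities`). In the read-bases
#' string `.`/`,` are reference matches, `ACGTacgt` mismatches,
#' `+n<seq>`/`-n<seq>` an insertion/deletion following the anchor base
#' (consuming exactly `n` sequence characters), `^X` a read start whose
#' mapping-quality character `X` is skipped, `$` a read end, and `*` a
#' deletion placeholder that is not counted as an observation. Case
#' (read strand) is folded since the caller is strand-agnostic.
#'
#' A depth column disagreeing with the parsed symbol tally produces a
#' warning, not an error (aligners emit such lines).
#'
#' @param line One pileup line.
#' @param pool_id Pool identifier to attach.
#' @return A `pileup_site`: list with `chrom`, `pos`, `ref_base`,
#'   `depth`, `base_counts` (named integer vector over `A/C/G/T` and
#'   `+SEQ`/`-SEQ` indel alleles) and `pool_id`.
#' @export
parse_pileup_line <- function(line, pool_id = NA_character_) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) < 6L) {
    stop("pileup parse error: expected 6 columns, got ", length(f),
         call. = FALSE)
  }
  ref <- toupper(f[3])
  counts <- parse_read_bases(f[5], ref)
  depth <- as.integer(f[4])
  nsub <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  if (nsub > depth) {
    warning("pileup depth column (", depth, ") below parsed base tally (",
            nsub, ") at ", f[1], ":", f[2], call. = FALSE)
  }
  structure(list(chrom = f[1], pos = as.integer(f[2]), ref_base = ref,
                 depth = depth, base_counts = counts, pool_id = pool_id),
            class = "pileup_site")
}

# char-by-char read-bases parser; returns named integer counts
parse_read_bases <- function(s, ref) {
  chars <- strsplit(s, "")[[1]]
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  indels <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "." || ch == ",") {
      counts[ref] <- counts[ref] + 1L
      i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "T", "a", "c", "g", "t")) {
      b <- toupper(ch)
      counts[b] <- counts[b] + 1L
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      if (j == i + 1L) {
        stop("pileup parse error at column ", i,
             ": indel sign without length", call. = FALSE)
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) {
        stop("pileup parse error at column ", i,
             ": truncated indel sequence", call. = FALSE)
      }
      seq <- toupper(paste(chars[j:(j + len - 1L)], collapse = ""))
      key <- paste0(ch, seq)
      indels[key] <- (if (key %in% names(indels)) indels[key] else 0L) + 1L
      i <- j + len
    } else if (ch == "^") {
      if (i == n) {
        stop("pileup parse error at column ", i,
             ": dangling read-start mark", call. = FALSE)
      }
      i <- i + 2L  # skip the mapping-quality character
    } else if (ch == "$" || ch == "*" || ch == "N" || ch == "n") {
      i <- i + 1L
    } else {
      stop("pileup parse error at column ", i,
           ": unexpected character '", ch, "'", call. = FALSE)
    }
  }
  c(counts, indels)
}

#' Read a text pileup file into a per-site table
#'
#' Bulk, vectorised counterpart of [parse_pileup_line()] (the two agree
#' symbol-for-symbol; this one processes whole files efficiently).
#'
#' @param path Pileup file (tab-separated, 6 columns).
#' @param pool_id Pool identifier to attach to every site.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T` (observation counts per base, reference matches
#'   counted under the reference base) and a list-column `indels`
#'   (named integer vector of `+SEQ`/`-SEQ` allele counts, `NULL` where
#'   none), plus the `pool_id`. Attribute `pool_id` is set as well.
#' @export
read_pileup <- function(path, pool_id = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), depth = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), pool_id = character(0))
    out$indels <- list()
    attr(out, "pool_id") <- pool_id
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 6L)) {
    stop("pileup parse error at line ", which(ncol < 6L)[1],
         ": expected 6 columns", call. = FALSE)
  }
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  chrom <- m[, 1]
  pos <- as.integer(m[, 2])
  ref <- toupper(m[, 3])
  depth <- as.integer(m[, 4])
  bases <- m[, 5]

  indels <- vector("list", length(bases))
  has_indel <- grepl("[+-]", bases)
  if (any(has_indel)) {
    for (i in which(has_indel)) {
      cnt <- parse_read_bases(bases[i], ref[i])
      ind <- cnt[!(names(cnt) %in% c("A", "C", "G", "T"))]
      if (length(ind)) indels[[i]] <- ind
      # drop indel specs (and ^/$ marks) so flat counting sees bases only
      bases[i] <- strip_indel_seqs(bases[i], ref[i])
    }
  }
  # strip read-start marks (each consumes its quality char) and read ends
  bases <- gsub("\\^.", "", bases, perl = TRUE)
  bases <- gsub("$", "", bases, fixed = TRUE)

  count_char <- function(s, ch) {
    nchar(s) - nchar(gsub(ch, "", s, fixed = TRUE))
  }
  nref <- count_char(bases, ".") + count_char(bases, ",")
  up <- toupper(bases)
  cnt <- sapply(c("A", "C", "G", "T"), function(b) count_char(up, b))
  if (length(bases) == 1L) cnt <- matrix(cnt, nrow = 1L,
                                         dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T")) {
    cnt[ref == b, b] <- cnt[ref == b, b] + nref[ref == b]
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, depth = depth,
                    A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
                    T = cnt[, "T"], pool_id = pool_id,
                    stringsAsFactors = FALSE)
  out$indels <- indels
  attr(out, "pool_id") <- pool_id
  out
}

# remove indel specs (+n<seq>/-n<seq>) from a read-bases string so the
# remaining characters can be counted flat; mirrors the grammar exactly
strip_indel_seqs <- function(s, ref) {
  chars <- strsplit(s, "")[[1]]
  keep <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && chars[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else if (ch == "^") {
      i <- i + 2L
    } else {
      if (ch != "$") keep <- c(keep, ch)
      i <- i + 1L
    }
  }
  paste(keep, collapse = "")
}

# convert a list of pileup_site objects into the wide per-site table
pileup_sites_to_df <- function(sites) {
  stopifnot(all(vapply(sites, inherits, logical(1), "pileup_site")))
  pool <- unique(vapply(sites, `[[`, character(1), "pool_id"))
  if (length(pool) > 1L) stop("mixed pool_ids in pileup sites", call. = FALSE)
  rows <- lapply(sites, function(s) {
    bc <- s$base_counts
    sub <- setNames(integer(4), c("A", "C", "G", "T"))
    for (b in names(sub)) if (b %in% names(bc)) sub[b] <- bc[[b]]
    data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref_base,
               depth = s$depth, A = sub[["A"]], C = sub[["C"]],
               G = sub[["G"]], T = sub[["T"]], pool_id = s$pool_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$indels <- lapply(sites, function(s) {
    ind <- s$base_counts[!(names(s$base_counts) %in% c("A", "C", "G", "T"))]
    if (length(ind)) ind else NULL
  })
  attr(out, "pool_id") <- pool
  out
}
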