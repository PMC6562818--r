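# Independent brute-force oracles and random-case generators.
# Everything here is deliberately naive and separate from the package
# implementation paths it checks.

# Literal O(m^2) Benjamini-Hochberg step-up: for every candidate rank k
# (scanning all m ranks each time) find the largest k with
# p_(k) <= k q / m, then reject every p <= p_(k).
bh_oracle <- function(p, q) {
  m <- length(p)
  if (m == 0L) return(logical(0))
  ps <- sort(p)
  k_star <- 0L
  for (k in seq_len(m)) {
    if (ps[k] <= k * q / m) k_star <- k
  }
  if (k_star == 0L) return(rep(FALSE, m))
  p <= ps[k_star]
}

# Exact binomial upper tail by explicit summation
tail_oracle <- function(k, n, e) {
  sum(vapply(k:n, function(x) choose(n, x) * e^x * (1 - e)^(n - x),
             numeric(1)))
}

# Brute-force three-gate caller: enumerate sites, apply the depth,
# fraction and BH gates literally. Sites are rows of a plain table with
# columns chrom, pos, ref, counts for A/C/G/T and optional indel allele
# plus count.
caller_oracle <- function(sites, config) {
  n <- nrow(sites)
  cand <- list()
  for (i in seq_len(n)) {
    counts <- c(A = sites$A[i], C = sites$C[i], G = sites$G[i],
                T = sites$T[i])
    counts[sites$ref[i]] <- -1L  # the reference is never a candidate
    # modal allele, ties lexicographic, substitution preferred over an
    # indel of equal count (the stated tie-break rule, applied literally)
    best <- names(counts)[which.max(counts)]  # names ordered A<C<G<T
    ac <- counts[[best]]
    if (!is.na(sites$indel_allele[i]) && sites$indel_count[i] > ac) {
      best <- sites$indel_allele[i]
      ac <- sites$indel_count[i]
    }
    if (sites$depth[i] > config$min_depth_exclusive && ac > 0 &&
        ac / sites$depth[i] >= config$het_fraction_min) {
      cand[[length(cand) + 1L]] <- list(i = i, allele = best, ac = ac)
    }
  }
  if (!length(cand)) return(data.frame(i = integer(0),
                                       allele = character(0)))
  pv <- vapply(cand, function(cc) {
    tail_oracle(cc$ac, sites$depth[cc$i], config$base_error_rate)
  }, numeric(1))
  keep <- bh_oracle(pv, config$fdr_q)
  out <- do.call(rbind, lapply(which(keep), function(j) {
    data.frame(i = cand[[j]]$i, allele = cand[[j]]$allele,
               ac = cand[[j]]$ac, stringsAsFactors = FALSE)
  }))
  out[order(out$i), , drop = FALSE]
}

# Random per-site count table for caller oracle comparisons, plus the
# equivalent pileup-site data frame the package caller consumes.
random_site_table <- function(n_sites) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  depth <- sample(0:40, n_sites, replace = TRUE)
  tab <- data.frame(chrom = "chrZ", pos = seq_len(n_sites) * 50L,
                    ref = ref, depth = depth, A = 0L, C = 0L, G = 0L,
                    T = 0L, indel_allele = NA_character_,
                    indel_count = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n_sites)) {
    nonref <- rbinom(1, depth[i], runif(1, 0, 0.6))
    alt <- sample(setdiff(bases, ref[i]), 1)
    tab[i, alt] <- nonref
    tab[i, ref[i]] <- depth[i] - nonref
    if (runif(1) < 0.15 && depth[i] > 0) {
      tab$indel_allele[i] <- paste0(sample(c("+", "-"), 1),
                                    paste(sample(bases,
                                                 sample(1:4, 1),
                                                 replace = TRUE),
                                          collapse = ""))
      tab$indel_count[i] <- sample.int(depth[i], 1)
    }
  }
  tab
}

site_table_to_pileup_df <- function(tab, pool_id = "BY-H") {
  out <- tab[, c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")]
  out$pool_id <- pool_id
  out$indels <- lapply(seq_len(nrow(tab)), function(i) {
    if (is.na(tab$indel_allele[i])) NULL
    else setNames(tab$indel_count[i], tab$indel_allele[i])
  })
  attr(out, "pool_id") <- pool_id
  out
}

# Random pileup read-bases string assembled from the grammar, with the
# generator's own tally of what it emitted.
random_pileup_line <- function(chrom = "chr1", pos = 1000L) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  n_sym <- sample(0:25, 1)
  toks <- character(0)
  tally <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  indels <- integer(0)
  n_reads <- 0L
  for (k in seq_len(n_sym)) {
    what <- sample(c("match", "mismatch", "ins", "del", "start", "end",
                     "star"), 1,
                   prob = c(0.5, 0.2, 0.07, 0.07, 0.06, 0.06, 0.04))
    if (what == "match") {
      toks <- c(toks, sample(c(".", ","), 1))
      tally[ref] <- tally[ref] + 1L
      n_reads <- n_reads + 1L
    } else if (what == "mismatch") {
      b <- sample(setdiff(bases, ref), 1)
      toks <- c(toks, sample(c(b, tolower(b)), 1))
      tally[b] <- tally[b] + 1L
      n_reads <- n_reads + 1L
    } else if (what %in% c("ins", "del")) {
      # indels follow an anchor match
      toks <- c(toks, ".")
      tally[ref] <- tally[ref] + 1L
      n_reads <- n_reads + 1L
      seq <- paste(sample(c(bases, tolower(bases)), sample(1:12, 1),
                          replace = TRUE), collapse = "")
      sign <- if (what == "ins") "+" else "-"
      toks <- c(toks, paste0(sign, nchar(seq), seq))
      key <- paste0(sign, toupper(seq))
      indels[key] <- (if (key %in% names(indels)) indels[key] else 0L) + 1L
    } else if (what == "start") {
      # mapping quality char may be anything printable, even ^ $ + .
      toks <- c(toks, paste0("^", sample(c("!", "I", "~", "$", "^", "+",
                                           "."), 1)))
    } else if (what == "end") {
      toks <- c(toks, "$")
    } else {
      toks <- c(toks, "*")
    }
  }
  if (!length(toks)) {  # a pileup line never has an empty bases column
    toks <- "."
    tally[ref] <- tally[ref] + 1L
    n_reads <- 1L
  }
  depth <- max(n_reads, 1L)
  list(line = paste(chrom, pos, ref, depth, paste(toks, collapse = ""),
                    strrep("I", depth), sep = "\t"),
       ref = ref, depth = depth,
       expected = c(tally, indels))
}

# Small study design used where a full-size simulation is unnecessary
small_design <- function(...) {
  truth_design(chrom_lengths = c(cA = 12000L, cB = 10000L),
               n_genes = 3L, overlapping_gene_pairs = 1L,
               n_breed_shared = 6L, n_breed_high_only = 4L,
               n_breed_low_only = 4L, n_common_high = 3L,
               n_common_low = 3L, n_diff_allele_pairs = 2L, ...)
}

# Reflect a gene model and genome through position L+1-x so that a -
# strand gene becomes the equivalent + strand construct
mirror_model <- function(model, L) {
  flip <- function(d) {
    if (!nrow(d)) return(d)
    data.frame(start = L + 1L - d$end, end = L + 1L - d$start)
  }
  gene_model(model$gene_id, model$chrom,
             if (model$strand == "+") "-" else "+",
             exons = flip(model$exons), cds = flip(model$cds),
             utr5 = flip(model$utr5), utr3 = flip(model$utr3))
}

# random single-chromosome gene model for property tests
random_gene_model <- function(L = 12000L, strand = sample(c("+", "-"), 1)) {
  n_ex <- sample(2:4, 1)
  ex_len <- sample(150:400, n_ex, replace = TRUE)
  in_len <- sample(100:400, n_ex - 1L, replace = TRUE)
  s <- sample(2500:4000, 1)
  starts <- s + cumsum(c(0L, head(ex_len, -1L) + in_len))
  ends <- starts + ex_len - 1L
  lead <- sample(30:90, 1)
  trail <- sample(30:90, 1)
  cds <- data.frame(start = pmax(starts, starts[1] + lead),
                    end = pmin(ends, ends[n_ex] - trail))
  cds <- cds[cds$start <= cds$end, , drop = FALSE]
  extra <- sum(cds$end - cds$start + 1L) %% 3L
  if (extra > 0L) {
    if (strand == "+") cds$end[nrow(cds)] <- cds$end[nrow(cds)] - extra
    else cds$start[1] <- cds$start[1] + extra
  }
  gene_model("gX", "chrM", strand,
             exons = data.frame(start = starts, end = ends), cds = cds)
}

random_genome_string <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}
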