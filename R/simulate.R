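#' Synthetic study design
#'
#' Parameters of a synthetic pooled capture-sequencing study with the
#' two-breed (Beijing-You, White Leghorn) by two-IgY-group (high, low)
#' structure. Category counts control how many truth variants are
#' planted in each partition of the four-pool presence space;
#' `n_diff_allele_pairs` plants pairs of SNPs sharing one position but
#' carrying different alternate alleles, one per breed's high pool.
#' Pool allele fractions are multiples of `1/(2 *
#' n_individuals_per_pool)` (10 diploid birds per pool by default),
#' drawn uniformly between `min_allele_fraction` and 1.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in
#'   bp (each >= 10 kb).
#' @param n_genes Total gene count (>= 2 per overlap pair).
#' @param overlapping_gene_pairs Number of gene pairs where one gene's
#'   3'UTR lies inside another gene's intron.
#' @param n_breed_shared,n_breed_high_only,n_breed_low_only Counts of
#'   breed-specific variants (per breed): present in both of the
#'   breed's pools / its high pool only / its low pool only.
#' @param n_common_high,n_common_low Counts of cross-breed common
#'   variants (present in both breeds' high pools, absent from lows;
#'   and vice versa).
#' @param n_diff_allele_pairs Count of same-position different-allele
#'   SNP pairs (one allele in BY-H, the other in WL-H).
#' @param snp_fraction Fraction of planted variants that are SNPs (the
#'   rest are indels, insertions and deletions in equal measure).
#' @param component_weights Named weights over
#'   `cds/promoter/utr/intron/intergenic` giving where variants land.
#' @param depth_mean Mean per-site pool read depth (Poisson).
#' @param n_individuals_per_pool Diploid individuals pooled per group.
#' @param min_allele_fraction Smallest intended pool allele fraction.
#' @return A `truth_design` object (validated list).
#' @export
truth_design <- function(chrom_lengths = c(chr1 = 36000L, chr2 = 24000L),
                         n_genes = 8L,
                         overlapping_gene_pairs = 1L,
                         n_breed_shared = 40L,
                         n_breed_high_only = 20L,
                         n_breed_low_only = 20L,
                         n_common_high = 12L,
                         n_common_low = 12L,
                         n_diff_allele_pairs = 8L,
                         snp_fraction = 0.7,
                         component_weights = c(cds = 0.2, promoter = 0.2,
                                               utr = 0.15, intron = 0.2,
                                               intergenic = 0.25),
                         depth_mean = 30,
                         n_individuals_per_pool = 10L,
                         min_allele_fraction = 0.5) {
  d <- list(chrom_lengths = chrom_lengths,
            n_genes = as.integer(n_genes),
            overlapping_gene_pairs = as.integer(overlapping_gene_pairs),
            n_breed_shared = as.integer(n_breed_shared),
            n_breed_high_only = as.integer(n_breed_high_only),
            n_breed_low_only = as.integer(n_breed_low_only),
            n_common_high = as.integer(n_common_high),
            n_common_low = as.integer(n_common_low),
            n_diff_allele_pairs = as.integer(n_diff_allele_pairs),
            snp_fraction = snp_fraction,
            component_weights = component_weights,
            depth_mean = depth_mean,
            n_individuals_per_pool = as.integer(n_individuals_per_pool),
            min_allele_fraction = min_allele_fraction)
  stopifnot(all(d$chrom_lengths >= 10000L),
            !is.null(names(d$chrom_lengths)),
            d$n_genes >= 0L,
            d$overlapping_gene_pairs * 2L <= d$n_genes,
            d$n_breed_shared >= 0L, d$n_breed_high_only >= 0L,
            d$n_breed_low_only >= 0L, d$n_common_high >= 0L,
            d$n_common_low >= 0L, d$n_diff_allele_pairs >= 0L,
            d$snp_fraction >= 0, d$snp_fraction <= 1,
            all(d$component_weights >= 0), sum(d$component_weights) > 0,
            d$depth_mean > 0, d$n_individuals_per_pool >= 1L,
            d$min_allele_fraction > 0, d$min_allele_fraction <= 1)
  class(d) <- "truth_design"
  d
}

#' Generate a random genome
#'
#' I.i.d. uniform ACGT sequence per chromosome, reproducible for a
#' fixed seed.
#'
#' @param design A [truth_design()].
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
make_genome <- function(design, seed) {
  with_seed(seed, {
    setNames(vapply(design$chrom_lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, character(1)), names(design$chrom_lengths))
  })
}

#' Generate gene models on a synthetic genome
#'
#' Places multi-exon genes on both strands with at least 2 kb of
#' intergenic space plus a 2 kb promoter margin between neighbours.
#' The first `overlapping_gene_pairs` pairs are built as a host gene
#' with a long intron and a nested gene whose 3'UTR lies inside that
#' intron (the overlapping-gene situation where one variant must be
#' reported under two genes). CDS lengths are multiples of 3.
#'
#' @param genome Output of [make_genome()].
#' @param design A [truth_design()].
#' @param seed Integer seed.
#' @return Named list of [gene_model()] objects.
#' @export
make_gene_models <- function(genome, design, seed) {
  if (design$n_genes == 0L) return(list())
  with_seed(seed, {
    models <- list()
    gid <- 0L
    next_id <- function() {
      gid <<- gid + 1L
      sprintf("gene%02d", gid)
    }
    chroms <- names(genome)
    cursors <- setNames(rep(2500L, length(chroms)), chroms)
    lens <- setNames(nchar(genome), chroms)
    ci <- 1L

    place <- function(span_needed) {
      # find a chromosome with room, round-robin
      for (k in seq_along(chroms)) {
        ch <- chroms[ci]
        ci <<- ci %% length(chroms) + 1L
        if (cursors[ch] + span_needed + 2500L <= lens[ch]) return(ch)
      }
      stop("make_gene_models: genome too small for requested genes; ",
           "increase chrom_lengths", call. = FALSE)
    }

    n_overlap <- design$overlapping_gene_pairs
    n_plain <- design$n_genes - 2L * n_overlap

    for (p in seq_len(n_overlap)) {
      ch <- place(7000L)
      s <- cursors[ch]
      # host gene: two exons around a 4.6 kb intron, + strand
      # CDS segment lengths 340 + 701 = 1041 and 410 + 502 = 912, both
      # multiples of 3
      host <- gene_model(next_id(), ch, "+",
        exons = data.frame(start = c(s, s + 5000L),
                           end = c(s + 399L, s + 5899L)),
        cds = data.frame(start = c(s + 60L, s + 5000L),
                         end = c(s + 399L, s + 5700L)))
      # nested gene inside the host intron, 3'UTR well inside it
      ns <- s + 2600L
      nested <- gene_model(next_id(), ch, "+",
        exons = data.frame(start = c(ns, ns + 800L),
                           end = c(ns + 499L, ns + 1599L)),
        cds = data.frame(start = c(ns + 90L, ns + 800L),
                         end = c(ns + 499L, ns + 1301L)))
      models[[host$gene_id]] <- host
      models[[nested$gene_id]] <- nested
      cursors[ch] <- s + 5900L + 2500L
    }

    for (g in seq_len(n_plain)) {
      strand <- sample(c("+", "-"), 1L)
      n_ex <- sample(2:4, 1L)
      ex_len <- sample(250:500, n_ex, replace = TRUE)
      in_len <- sample(200:600, max(n_ex - 1L, 0L), replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      ch <- place(span)
      s <- cursors[ch]
      starts <- s + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len - 1L
      utr5_len <- sample(60:150, 1L)
      utr3_len <- sample(100:250, 1L)
      # genomic-left/right trims depend on strand
      lead <- if (strand == "+") utr5_len else utr3_len
      trail <- if (strand == "+") utr3_len else utr5_len
      cds_lo <- starts[1] + lead
      cds_hi <- ends[n_ex] - trail
      cds <- data.frame(start = pmax(starts, cds_lo),
                        end = pmin(ends, cds_hi))
      cds <- cds[cds$start <= cds$end, , drop = FALSE]
      # trim the transcription-end segment so total CDS length is %% 3
      total <- sum(cds$end - cds$start + 1L)
      extra <- total %% 3L
      if (extra > 0L) {
        if (strand == "+") {
          cds$end[nrow(cds)] <- cds$end[nrow(cds)] - extra
        } else {
          cds$start[1] <- cds$start[1] + extra
        }
      }
      models[[length(models) + 1L]] <- gene_model(
        next_id(), ch, strand,
        exons = data.frame(start = starts, end = ends), cds = cds)
      names(models)[length(models)] <- models[[length(models)]]$gene_id
      cursors[ch] <- ends[n_ex] + 2500L
    }
    models
  })
}

# pool sets per truth category
category_pools <- list(
  "BY-only-shared" = c("BY-H", "BY-L"),
  "BY-only-high-specific" = "BY-H",
  "BY-only-low-specific" = "BY-L",
  "WL-only-shared" = c("WL-H", "WL-L"),
  "WL-only-high-specific" = "WL-H",
  "WL-only-low-specific" = "WL-L",
  "common-high" = c("BY-H", "WL-H"),
  "common-low" = c("BY-L", "WL-L")
)

#' Plant truth variants with a known category structure
#'
#' Plants SNPs and indels across the genome so that the per-category
#' counts of the design are met exactly, positions are unique and well
#' separated, variants fall into CDS / promoter / UTR / intron /
#' intergenic space according to the design's component weights, and
#' every same-position different-allele pair places two distinct
#' alternate SNP alleles at one position (one intended for BY-H, the
#' other for WL-H). Indel keys are left-aligned against the genome, as
#' the caller will report them.
#'
#' @param genome Output of [make_genome()].
#' @param models Output of [make_gene_models()].
#' @param design A [truth_design()].
#' @param seed Integer seed.
#' @return Truth data frame: `chrom, pos, ref, alt, var_type,
#'   category, pools` (comma-joined intended pools), `fraction`
#'   (intended pool allele fraction), `component`.
#' @export
plant_variants <- function(genome, models, design, seed) {
  with_seed(seed, {
    # candidate positions per component class
    comp_pos <- component_positions(genome, models)
    weights <- design$component_weights
    bases <- c("A", "C", "G", "T")
    used <- list()  # per chrom: integer vector of blocked positions
    for (ch in names(genome)) used[[ch]] <- integer(0)

    draw_pos <- function() {
      # sample a component (by weight, among non-empty classes), then a
      # position at least 20 bp from every previously planted footprint
      for (attempt in 1:200) {
        w <- weights[vapply(names(weights),
                            function(k) nrow(comp_pos[[k]]) > 0, logical(1))]
        if (!length(w)) stop("plant_variants: no candidate space left",
                             call. = FALSE)
        comp <- sample(names(w), 1L, prob = w)
        tab <- comp_pos[[comp]]
        i <- sample.int(nrow(tab), 1L)
        ch <- tab$chrom[i]; p <- tab$pos[i]
        if (!any(abs(used[[ch]] - p) < 20L)) {
          used[[ch]] <<- c(used[[ch]], p)
          return(list(chrom = ch, pos = p, component = comp))
        }
      }
      stop("plant_variants: could not place variant; genome too dense",
           call. = FALSE)
    }

    fracs <- function(n) {
      # multiples of 1 / (2 * individuals): allele counts in the pool
      half <- 2L * design$n_individuals_per_pool
      choices <- seq.int(ceiling(design$min_allele_fraction * half), half)
      choices[sample.int(length(choices), n, replace = TRUE)] / half
    }

    draw_allele <- function(ch, p) {
      ref <- substring(genome[[ch]], p, p)
      is_snp <- runif(1) < design$snp_fraction
      if (is_snp) {
        alt <- sample(setdiff(bases, ref), 1L)
        list(ref = ref, alt = alt, var_type = "SNP")
      } else if (runif(1) < 0.5) {
        ins <- paste(sample(bases, sample(1:9, 1L), replace = TRUE),
                     collapse = "")
        k <- left_align_key(ch, p, ref, paste0(ref, ins), genome)
        list(ref = k$ref, alt = k$alt, var_type = "INS", pos = k$pos)
      } else {
        len <- sample(1:9, 1L)
        del <- substring(genome[[ch]], p + 1L, p + len)
        k <- left_align_key(ch, p, paste0(ref, del), ref, genome)
        list(ref = k$ref, alt = k$alt, var_type = "DEL", pos = k$pos)
      }
    }

    rows <- list()
    add_category <- function(category, n) {
      pools <- paste(category_pools[[category]], collapse = ",")
      for (i in seq_len(n)) {
        loc <- draw_pos()
        al <- draw_allele(loc$chrom, loc$pos)
        rows[[length(rows) + 1L]] <<- data.frame(
          chrom = loc$chrom, pos = al$pos %||% loc$pos, ref = al$ref,
          alt = al$alt, var_type = al$var_type, category = category,
          pools = pools, fraction = fracs(1L), component = loc$component,
          stringsAsFactors = FALSE)
      }
    }

    add_category("BY-only-shared", design$n_breed_shared)
    add_category("WL-only-shared", design$n_breed_shared)
    add_category("BY-only-high-specific", design$n_breed_high_only)
    add_category("WL-only-high-specific", design$n_breed_high_only)
    add_category("BY-only-low-specific", design$n_breed_low_only)
    add_category("WL-only-low-specific", design$n_breed_low_only)
    add_category("common-high", design$n_common_high)
    add_category("common-low", design$n_common_low)

    for (i in seq_len(design$n_diff_allele_pairs)) {
      loc <- draw_pos()
      ref <- substring(genome[[loc$chrom]], loc$pos, loc$pos)
      alts <- sample(setdiff(bases, ref), 2L)
      for (j in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = loc$chrom, pos = loc$pos, ref = ref, alt = alts[j],
          var_type = "SNP", category = "diff-allele-high",
          pools = c("BY-H", "WL-H")[j], fraction = fracs(1L),
          component = loc$component, stringsAsFactors = FALSE)
      }
    }

    if (!length(rows)) {
      return(data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        var_type = character(0), category = character(0),
                        pools = character(0), fraction = numeric(0),
                        component = character(0)))
    }
    truth <- do.call(rbind, rows)
    kk <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
    stopifnot(!anyDuplicated(kk))
    truth[order(truth$chrom, truth$pos, truth$ref, truth$alt), ,
          drop = FALSE]
  })
}

# candidate planting positions per component class; keeps 100 bp off
# chromosome ends and 12 bp off component boundaries so indel
# footprints and left-alignment stay inside their class
component_positions <- function(genome, models) {
  idx <- annotation_index(models, 2000L,
                          chrom_lengths = vapply(genome, nchar,
                                                 numeric(1)))
  classes <- c(cds = "CDS", promoter = "promoter", intron = "intron")
  out <- list()
  pos_in <- function(gr) {
    if (!length(gr)) {
      return(data.frame(chrom = character(0), pos = integer(0)))
    }
    do.call(rbind, lapply(seq_along(gr), function(i) {
      s <- GenomicRanges::start(gr)[i] + 12L
      e <- GenomicRanges::end(gr)[i] - 12L
      if (s > e) return(NULL)
      data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[i],
                 pos = s:e, stringsAsFactors = FALSE)
    }))
  }
  for (k in names(classes)) {
    out[[k]] <- pos_in(idx[idx$comp == classes[[k]]])
  }
  out[["utr"]] <- pos_in(idx[idx$comp %in% c("utr5", "utr3")])
  # intergenic: everything at least 50 bp away from any indexed feature
  inter <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    covered <- rep(FALSE, L)
    sel <- as.character(GenomicRanges::seqnames(idx)) == ch
    if (any(sel)) {
      for (i in which(sel)) {
        s <- max(1L, GenomicRanges::start(idx)[i] - 50L)
        e <- min(L, GenomicRanges::end(idx)[i] + 50L)
        covered[s:e] <- TRUE
      }
    }
    p <- which(!covered)
    p <- p[p > 100L & p < L - 100L]
    if (length(p)) {
      inter[[ch]] <- data.frame(chrom = ch, pos = p,
                                stringsAsFactors = FALSE)
    }
  }
  out[["intergenic"]] <- if (length(inter)) do.call(rbind, inter)
                         else data.frame(chrom = character(0),
                                         pos = integer(0))
  out
}

#' Simulate one pool's pileup
#'
#' Per site the depth is Poisson with the design's mean. At truth
#' sites intended for the pool, alternate reads are Binomial(depth,
#' `f * (1 - error_rate)`) with intended fraction `f`; the remaining
#' reads are reference matches. At all other sites, mismatches are
#' Binomial(depth, `error_rate`) spread uniformly over the three
#' non-reference bases. Indels are rendered with the `+n<seq>` /
#' `-n<seq>` grammar on their anchor base. Zero-depth sites are
#' omitted, as aligners do.
#'
#' @param genome Output of [make_genome()].
#' @param truth Output of [plant_variants()].
#' @param pool_id One of `POOL_IDS`.
#' @param config A [pipeline_config()] (`base_error_rate`).
#' @param design A [truth_design()] (`depth_mean`).
#' @param seed Integer seed.
#' @param path Output pileup path.
#' @return `path`, invisibly.
#' @export
simulate_pool_pileup <- function(genome, truth, pool_id, config, design,
                                 seed, path) {
  stopifnot(pool_id %in% POOL_IDS)
  eps <- config$base_error_rate
  mine <- truth[vapply(strsplit(truth$pools, ",", fixed = TRUE),
                       function(p) pool_id %in% p, logical(1)), ,
                drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  with_seed(seed, {
    for (ch in names(genome)) {
      L <- nchar(genome[[ch]])
      refs <- strsplit(genome[[ch]], "")[[1]]
      depth <- rpois(L, design$depth_mean)

      t_ch <- mine[mine$chrom == ch, , drop = FALSE]
      tpos <- t_ch$pos
      is_truth <- rep(FALSE, L)
      is_truth[tpos] <- TRUE

      # error-bearing non-truth sites: mismatches spread over the three
      # non-ref bases (k1 of the first, k2 of the second, rest third)
      nerr <- integer(L)
      if (eps > 0) nerr <- rbinom(L, depth, eps)
      nerr[is_truth] <- 0L
      alt3 <- matrix(c("C", "G", "T",
                       "A", "G", "T",
                       "A", "C", "T",
                       "A", "C", "G"), nrow = 4L, byrow = TRUE,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
      base_i <- match(refs, rownames(alt3))
      base_i[is.na(base_i)] <- 1L  # N reference: error spectrum arbitrary
      om <- alt3[base_i, , drop = FALSE]
      k1 <- rbinom(L, nerr, 1 / 3)
      k2 <- rbinom(L, nerr - k1, 1 / 2)
      k3 <- nerr - k1 - k2
      bases_str <- paste0(strrep(".", depth - nerr),
                          strrep(om[, 1], k1), strrep(om[, 2], k2),
                          strrep(om[, 3], k3))

      # truth sites: alt reads at f (1 - eps), remainder reference
      if (nrow(t_ch)) {
        a <- rbinom(nrow(t_ch), depth[tpos],
                    t_ch$fraction * (1 - eps))
        unit <- character(nrow(t_ch))  # per-read alt rendering
        for (i in seq_len(nrow(t_ch))) {
          r <- t_ch$ref[i]; al <- t_ch$alt[i]
          unit[i] <- if (t_ch$var_type[i] == "SNP") {
            al
          } else if (nchar(al) > nchar(r)) {
            ins <- substring(al, 2)
            paste0(".", "+", nchar(ins), ins)
          } else {
            del <- substring(r, 2)
            paste0(".", "-", nchar(del), del)
          }
        }
        bases_str[tpos] <- paste0(strrep(".", depth[tpos] - a),
                                  strrep(unit, a))
      }

      keep <- depth > 0L
      lines <- paste(ch, seq_len(L)[keep], refs[keep], depth[keep],
                     bases_str[keep], strrep("I", depth[keep]),
                     sep = "\t")
      writeLines(lines, con)
    }
  })
  invisible(path)
}

#' Simulate phenotype measurements for the four groups
#'
#' Per-bird IgY-like values drawn lognormally so that each
#' (breed, group) matches a target mean and standard deviation.
#' Defaults emulate a strong divergent-selection contrast (high groups
#' roughly five to six times the low groups).
#'
#' @param seed Integer seed.
#' @param n_per_group Birds per (breed, group).
#' @param targets Data frame `breed`, `group`, `mean`, `sd`.
#' @return Data frame `bird`, `breed`, `group`, `value`.
#' @export
simulate_phenotypes <- function(seed, n_per_group = 40L,
                                targets = data.frame(
                                  breed = c("WL", "WL", "BY", "BY"),
                                  group = c("high", "low", "high", "low"),
                                  mean = c(1500, 295, 1890, 300),
                                  sd = c(1650, 60, 1200, 25))) {
  with_seed(seed, {
    out <- lapply(seq_len(nrow(targets)), function(i) {
      m <- targets$mean[i]; s <- targets$sd[i]
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      data.frame(
        bird = sprintf("%s-%s-%02d", targets$breed[i], targets$group[i],
                       seq_len(n_per_group)),
        breed = targets$breed[i], group = targets$group[i],
        value = rlnorm(n_per_group, meanlog, sdlog),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate and write a complete synthetic study
#'
#' Runs [make_genome()], [make_gene_models()], [plant_variants()],
#' [simulate_phenotypes()] and [simulate_pool_pileup()] for all four
#' pools, writing `genome.fasta`, `genes.gff3`, `targets.bed` (whole
#' chromosomes), `truth.tsv` (seed recorded in its header),
#' `phenotypes.tsv`, `design.yaml` and `pools/<pool>.pileup` under
#' `out_dir`.
#'
#' @param design A [truth_design()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return List with the in-memory `genome`, `models`, `truth`,
#'   `phenotypes` and the output `paths`.
#' @export
simulate_study <- function(design = truth_design(),
                           config = pipeline_config(),
                           out_dir, seed) {
  dir.create(file.path(out_dir, "pools"), recursive = TRUE,
             showWarnings = FALSE)
  genome <- make_genome(design, derive_seed(seed, 1L))
  models <- make_gene_models(genome, design, derive_seed(seed, 2L))
  truth <- plant_variants(genome, models, design, derive_seed(seed, 3L))
  pheno <- simulate_phenotypes(derive_seed(seed, 4L))

  paths <- list(
    genome = file.path(out_dir, "genome.fasta"),
    gff3 = file.path(out_dir, "genes.gff3"),
    bed = file.path(out_dir, "targets.bed"),
    truth = file.path(out_dir, "truth.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    design = file.path(out_dir, "design.yaml"),
    pileups = setNames(file.path(out_dir, "pools",
                                 paste0(POOL_IDS, ".pileup")), POOL_IDS)
  )
  write_fasta(genome, paths$genome)
  write_gff3(models, paths$gff3)
  write_bed(lapply(names(genome), function(ch) {
    genomic_interval(ch, 1L, nchar(genome[[ch]]))
  }), paths$bed)
  write_tsv(truth, paths$truth, comment = paste0("seed=", seed))
  write_tsv(pheno, paths$phenotypes)
  yaml::write_yaml(design_to_list(design), paths$design)
  for (p in POOL_IDS) {
    simulate_pool_pileup(genome, truth, p, config, design,
                         derive_seed(seed, 10L + match(p, POOL_IDS)),
                         paths$pileups[[p]])
  }
  list(genome = genome, models = models, truth = truth,
       phenotypes = pheno, paths = paths)
}

design_to_list <- function(design) {
  d <- unclass(design)
  d$chrom_lengths <- as.list(d$chrom_lengths)
  d$component_weights <- as.list(d$component_weights)
  d
}

#' Read a design file written by [simulate_study()]
#' @param path `design.yaml` path.
#' @return A [truth_design()].
#' @export
read_design <- function(path) {
  d <- yaml::read_yaml(path)
  d$chrom_lengths <- unlist(d$chrom_lengths)
  d$component_weights <- unlist(d$component_weights)
  do.call(truth_design, d)
}
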