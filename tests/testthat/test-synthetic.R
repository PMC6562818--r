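test_that("genome generation is seed-deterministic", {
  d <- truth_design(chrom_lengths = c(c1 = 10000L))
  g1 <- make_genome(d, 9)
  g2 <- make_genome(d, 9)
  g3 <- make_genome(d, 10)
  expect_identical(g1, g2)
  expect_false(identical(g1, g3))
  expect_identical(nchar(g1[["c1"]]), 10000L)
  expect_true(all(strsplit(g1[["c1"]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("gene models pack validly and contain the requested overlap pair", {
  d <- small_design()
  g <- make_genome(d, 21)
  models <- make_gene_models(g, d, 22)
  expect_length(models, d$n_genes)

  # every CDS length is translatable
  for (m in models) expect_identical(poolvar:::cds_length(m) %% 3L, 0L)

  # one gene's 3'UTR lies inside another gene's intron
  found <- FALSE
  for (a in models) for (b in models) {
    if (a$gene_id == b$gene_id || a$chrom != b$chrom) next
    intr <- poolvar:::model_introns(b)
    if (nrow(a$utr3) && nrow(intr) &&
        poolvar:::segments_overlap_any(a$utr3, intr)) found <- TRUE
  }
  expect_true(found)
})

test_that("infeasible gene packing and degenerate designs are handled", {
  d <- truth_design(chrom_lengths = c(c1 = 10000L), n_genes = 10L,
                    overlapping_gene_pairs = 0L)
  g <- make_genome(d, 1)
  expect_error(make_gene_models(g, d, 2), "too small")
  d0 <- truth_design(chrom_lengths = c(c1 = 10000L), n_genes = 0L,
                     overlapping_gene_pairs = 0L)
  expect_length(make_gene_models(make_genome(d0, 1), d0, 2), 0L)
})

test_that("planted truth matches the design's category counts exactly", {
  d <- small_design()
  g <- make_genome(d, 31)
  models <- make_gene_models(g, d, 32)
  truth <- plant_variants(g, models, d, 33)

  counts <- table(truth$category)
  expect_identical(unname(counts[["BY-only-shared"]]), d$n_breed_shared)
  expect_identical(unname(counts[["WL-only-shared"]]), d$n_breed_shared)
  expect_identical(unname(counts[["BY-only-high-specific"]]),
                   d$n_breed_high_only)
  expect_identical(unname(counts[["WL-only-low-specific"]]),
                   d$n_breed_low_only)
  expect_identical(unname(counts[["common-high"]]), d$n_common_high)
  expect_identical(unname(counts[["common-low"]]), d$n_common_low)
  expect_identical(unname(counts[["diff-allele-high"]]),
                   2L * d$n_diff_allele_pairs)

  # keys unique; same-position pairs carry two distinct alt alleles
  kk <- poolvar:::variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  expect_false(anyDuplicated(kk) > 0)
  pairs <- truth[truth$category == "diff-allele-high", ]
  split_pos <- split(pairs, paste(pairs$chrom, pairs$pos))
  expect_length(split_pos, d$n_diff_allele_pairs)
  for (pp in split_pos) {
    expect_identical(nrow(pp), 2L)
    expect_false(pp$alt[1] == pp$alt[2])
    expect_setequal(pp$pools, c("BY-H", "WL-H"))
  }

  # intended pools are consistent with categories
  ch <- truth[truth$category == "common-high", ]
  expect_true(all(ch$pools == "BY-H,WL-H"))

  # fractions are multiples of 1/20 at or above the design minimum
  expect_true(all(abs(truth$fraction * 20 -
                        round(truth$fraction * 20)) < 1e-9))
  expect_true(all(truth$fraction >= d$min_allele_fraction))

  # all-zero design yields empty truth
  d0 <- truth_design(chrom_lengths = c(c1 = 10000L), n_genes = 0L,
                     overlapping_gene_pairs = 0L, n_breed_shared = 0L,
                     n_breed_high_only = 0L, n_breed_low_only = 0L,
                     n_common_high = 0L, n_common_low = 0L,
                     n_diff_allele_pairs = 0L)
  expect_identical(nrow(plant_variants(make_genome(d0, 1), list(), d0, 2)),
                   0L)
})

test_that("noise-free pileups contain exactly the planted signal", {
  d <- small_design(min_allele_fraction = 1)  # fixed variants only
  cfg0 <- pipeline_config(base_error_rate = 1e-12)  # effectively zero
  g <- make_genome(d, 41)
  models <- make_gene_models(g, d, 42)
  truth <- plant_variants(g, models, d, 43)
  f <- withr::local_tempfile(fileext = ".pileup")
  simulate_pool_pileup(g, truth, "BY-H", cfg0, d, 44, f)
  df <- read_pileup(f, "BY-H")

  tk <- truth[grepl("BY-H", truth$pools), ]
  tpos <- paste(tk$chrom, tk$pos)
  at_truth <- paste(df$chrom, df$pos) %in% tpos

  # non-truth sites: every observation is the reference base
  cntm <- as.matrix(df[, c("A", "C", "G", "T")])
  ref_obs <- cntm[cbind(seq_len(nrow(df)), match(df$ref, colnames(cntm)))]
  clean <- df$A + df$C + df$G + df$T - ref_obs == 0
  expect_true(all(clean[!at_truth]))
  expect_true(all(vapply(df$indels[!at_truth], is.null, logical(1))))

  # truth SNP sites with intended fraction 1: all reads are alternate
  snp <- tk[tk$var_type == "SNP", ]
  i <- match(paste(snp$chrom, snp$pos), paste(df$chrom, df$pos))
  ok <- !is.na(i)
  alt_obs <- cntm[cbind(i[ok], match(snp$alt[ok], colnames(cntm)))]
  expect_true(all(alt_obs == df$depth[i[ok]]))
})

test_that("simulated alternate counts follow the binomial noise model", {
  # aggregate alternate fraction over many f = 0.5 truth sites must sit
  # within 3 standard errors of 0.5 * (1 - error rate)
  d <- truth_design(chrom_lengths = c(c1 = 10000L), n_genes = 0L,
                    overlapping_gene_pairs = 0L, n_breed_shared = 50L,
                    n_breed_high_only = 0L, n_breed_low_only = 0L,
                    n_common_high = 0L, n_common_low = 0L,
                    n_diff_allele_pairs = 0L, snp_fraction = 1,
                    depth_mean = 200,
                    component_weights = c(cds = 0, promoter = 0, utr = 0,
                                          intron = 0, intergenic = 1),
                    min_allele_fraction = 0.5)
  cfg <- pipeline_config(base_error_rate = 0.01)
  g <- make_genome(d, 51)
  truth <- plant_variants(g, list(), d, 52)
  truth$fraction <- 0.5
  f <- withr::local_tempfile(fileext = ".pileup")
  simulate_pool_pileup(g, truth, "BY-H", cfg, d, 53, f)
  df <- read_pileup(f, "BY-H")
  truth <- truth[grepl("BY-H", truth$pools), ]  # sites seen by this pool
  i <- match(paste(truth$chrom, truth$pos), paste(df$chrom, df$pos))
  cntm <- as.matrix(df[, c("A", "C", "G", "T")])
  alt_obs <- cntm[cbind(i, match(truth$alt, colnames(cntm)))]
  n_tot <- sum(df$depth[i])
  p_exp <- 0.5 * 0.99
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(sum(alt_obs) / n_tot - p_exp), 3 * se)
})

test_that("a written study is complete, parseable and seed-stamped", {
  dir <- withr::local_tempdir()
  d <- small_design()
  sim <- simulate_study(d, pipeline_config(), dir, seed = 61)
  expect_true(all(file.exists(unlist(sim$paths))))
  expect_match(readLines(sim$paths$truth, n = 1), "seed=61")
  expect_identical(read_fasta(sim$paths$genome), sim$genome)
  expect_length(read_gff3(sim$paths$gff3), d$n_genes)
  d2 <- read_design(sim$paths$design)
  expect_equal(d2, d, ignore_attr = TRUE)
  beds <- read_bed(sim$paths$bed)
  expect_length(beds, length(d$chrom_lengths))
  expect_identical(beds[[1]]$start, 1L)
})
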