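test_that("group statistics use sample sd and half-up 2-decimal rounding", {
  ph <- data.frame(breed = "WL", group = c("high", "high", "high"),
                   value = c(1, 1, 1))
  gs <- suppressWarnings(group_stats(ph))  # warns for the empty low group
  expect_identical(gs$mean[gs$group == "high"], 1)
  expect_identical(gs$sd[gs$group == "high"], 0)

  ph2 <- data.frame(breed = "WL", group = "high", value = c(0, 2))
  gs2 <- suppressWarnings(group_stats(ph2))
  expect_identical(gs2$mean[gs2$group == "high"], 1)
  expect_identical(gs2$sd[gs2$group == "high"], 1.41)
  expect_warning(group_stats(ph2), "empty group")
  expect_false("low" %in% suppressWarnings(group_stats(ph2))$group)
})

test_that("fold changes reproduce the reported group contrasts", {
  expect_identical(fold_change(1501.70, 293.91), 5.1)
  expect_identical(fold_change(1888.84, 302.55), 6.2)
  expect_identical(fold_change(7, 7), 1)
  expect_error(fold_change(10, 0), "low_mean")
  # reciprocal consistency within the attainable 1-decimal rounding bound
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 100, 2000); b <- runif(1, 100, 2000)
    r <- a / b
    bound <- 0.05 * (r + 1 / r) + 0.0025
    expect_lte(abs(fold_change(a, b) * fold_change(b, a) - 1), bound)
  }
})

test_that("distribution tables recompute their percent cells", {
  tab <- distribution_table(c("homozygous", "heterozygous"),
                            c(28862L, 6292L), 35154L)
  expect_identical(tab$percent, c(82.1, 17.9))
  tab <- distribution_table("synonymous", 2190L, 35154L)
  expect_identical(tab$percent, 6.2)
  tab <- distribution_table(c("insertion", "deletion"),
                            c(11211L, 12098L), 23309L)
  expect_identical(tab$percent, c(48.1, 51.9))
  expect_identical(distribution_table("CDS", 1051L, 23309L)$percent, 4.5)
  # degenerate single-class inputs
  expect_identical(distribution_table(c("hom", "het"), c(10L, 0L),
                                      10L)$percent, c(100, 0))
  expect_identical(distribution_table(c("ins", "del"), c(0L, 7L),
                                      7L)$percent, c(0, 100))
})

test_that("the Sanger consistency rate counts SNP rows only", {
  f <- system.file("extdata", "reported", "sanger_validation.tsv",
                   package = "poolvar")
  v <- read.delim(f)
  expect_identical(validation_rate(v), 87.5)
  expect_identical(sum(toupper(v$variant_type) == "SNP"), 24L)

  expect_identical(validation_rate(
    data.frame(variant_type = "SNP", consistent = "yes")), 100)
  expect_identical(validation_rate(
    data.frame(variant_type = c("SNP", "SNP"),
               consistent = c("yes", "no"))), 50)
  expect_error(validation_rate(
    data.frame(variant_type = "deletion", consistent = "yes")),
    "no SNP rows")
})

test_that("pipeline-derived tables are self-consistent and order-invariant", {
  d <- small_design()
  cfg <- pipeline_config()
  sim <- simulate_study(d, cfg, withr::local_tempdir(), seed = 101)
  calls <- do.call(rbind, call_pools(sim$paths$pileups, sim$genome, cfg))
  ann <- annotate_variants(calls, sim$models, sim$genome, cfg)

  st <- snp_distribution(calls, ann)
  it <- indel_distribution(calls, ann)
  for (tab in list(st, it)) {
    expect_identical(tab$percent,
                     round_half_up(100 * tab$count / attr(tab, "total"),
                                   1))
  }
  # hom/het partitions the SNP union; ins/del partitions the indels
  expect_identical(sum(st$count[st$label %in% c("homozygous",
                                                "heterozygous")]),
                   attr(st, "total"))
  expect_identical(sum(it$count[it$label %in% c("insertion",
                                                "deletion")]),
                   attr(it, "total"))
  # syn + non-syn equals the number of CDS SNPs
  u <- poolvar:::dedupe_union(calls[calls$var_type == "SNP", ])
  ua <- poolvar:::join_annotations(u, ann)
  expect_identical(sum(st$count[st$label %in% c("non_synonymous",
                                                "synonymous")]),
                   sum(grepl(":CDS(,|$)", ua$gene_hits)))

  # shuffling the input rows changes nothing
  set.seed(1)
  calls2 <- calls[sample.int(nrow(calls)), ]
  expect_identical(snp_distribution(calls2, ann), st)
  expect_identical(indel_distribution(calls2, ann), it)
})

test_that("common-variant gene maps report promoter/CDS genes and dual hits", {
  fx_host <- gene_model("BF1like", "c16", "+",
                        exons = data.frame(start = c(1000L, 9000L),
                                           end = c(1400L, 9900L)),
                        cds = data.frame(start = c(1100L, 9000L),
                                         end = c(1400L, 9397L)))
  fx_nested <- gene_model("TAP1like", "c16", "+",
                          exons = data.frame(start = c(3000L, 4000L),
                                             end = c(3500L, 5000L)),
                          cds = data.frame(start = c(3100L, 4000L),
                                           end = c(3500L, 4597L)))
  models <- list(BF1like = fx_host, TAP1like = fx_nested)
  genome <- c(c16 = random_genome_string(12000L))

  mk <- function(chrom, pos, ref, alt, pool) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               var_type = if (nchar(ref) == nchar(alt)) "SNP" else "DEL",
               pool_id = pool, depth = 30L, alt_count = 30L,
               alt_fraction = 1, zygosity = "pool-homozygous",
               p_value = 1e-30, passed_fdr = TRUE,
               stringsAsFactors = FALSE)
  }
  # a promoter SNP and a dual-gene deletion, both high-specific in both
  # breeds (same type)
  prom_ref <- substring(genome[["c16"]], 500L, 500L)
  prom_alt <- setdiff(c("A", "C", "G", "T"), prom_ref)[1]
  del_ref <- substring(genome[["c16"]], 4700L, 4709L)
  snp <- function(pool) mk("c16", 500L, prom_ref, prom_alt, pool)
  del <- function(pool) mk("c16", 4700L, del_ref,
                           substring(del_ref, 1, 1), pool)
  sets <- list("BY-H" = rbind(snp("BY-H"), del("BY-H")),
               "BY-L" = poolvar:::empty_calls(),
               "WL-H" = rbind(snp("WL-H"), del("WL-H")),
               "WL-L" = poolvar:::empty_calls())
  cfg <- pipeline_config()
  cmpr <- compare_pools(sets, cfg)
  ann <- annotate_variants(do.call(rbind, sets), models, genome, cfg)
  gm <- common_gene_map(cmpr, ann)

  expect_true(any(gm$snp_genes$gene == "BF1like" &
                    gm$snp_genes$component == "promoter" &
                    gm$snp_genes$igy_group == "high"))
  expect_identical(nrow(gm$indels), 1L)
  expect_match(gm$indels$genes, "BF1like")
  expect_match(gm$indels$genes, "TAP1like")
  expect_match(gm$indels$components, "intron")
  expect_match(gm$indels$components, "utr3")
  expect_identical(gm$indels$sequence, substring(del_ref, 2))

  # counts table sees the promoter SNP in both high-specific sets
  npc <- nonsyn_promoter_counts(cmpr, ann)
  expect_identical(npc$promoter[npc$set == "WL-high"], 1L)
  expect_identical(npc$promoter[npc$set == "common-high"], 1L)

  # empty comparison produces empty maps
  empty <- compare_pools(list("BY-H" = poolvar:::empty_calls(),
                              "BY-L" = poolvar:::empty_calls(),
                              "WL-H" = poolvar:::empty_calls(),
                              "WL-L" = poolvar:::empty_calls()), cfg)
  gm0 <- common_gene_map(empty, ann)
  expect_identical(nrow(gm0$snp_genes), 0L)
  expect_identical(nrow(gm0$indels), 0L)
})
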