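test_that("FASTA reading truncates headers, folds case, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr16", "ACGT"), f)
  expect_identical(read_fasta(f), c(chr16 = "ACGT"))
  writeLines(c(">a extra words", "acgt"), f)
  expect_identical(read_fasta(f), c(a = "ACGT"))
  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("FASTA round-trips the synthetic genome", {
  g <- make_genome(truth_design(chrom_lengths = c(k1 = 10000L)), seed = 3)
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g, f)
  expect_identical(read_fasta(f), g)
})

test_that("GFF3 assembly derives UTRs and the strand-dependent TSS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  gff <- function(strand) c(
    "##gff-version 3",
    sprintf("c1\t.\tgene\t101\t400\t.\t%s\t.\tID=g1", strand),
    sprintf("c1\t.\tmRNA\t101\t400\t.\t%s\t.\tID=m1;Parent=g1", strand),
    sprintf("c1\t.\texon\t101\t200\t.\t%s\t.\tParent=m1", strand),
    sprintf("c1\t.\texon\t301\t400\t.\t%s\t.\tParent=m1", strand),
    sprintf("c1\t.\tCDS\t151\t200\t.\t%s\t0\tParent=m1", strand),
    sprintf("c1\t.\tCDS\t301\t350\t.\t%s\t2\tParent=m1", strand))

  writeLines(gff("+"), f)
  m <- read_gff3(f)[[1]]
  expect_identical(m$tss, 101L)
  expect_equal(m$utr5, data.frame(start = 101L, end = 150L),
               ignore_attr = TRUE)
  expect_equal(m$utr3, data.frame(start = 351L, end = 400L),
               ignore_attr = TRUE)

  writeLines(gff("-"), f)
  m <- read_gff3(f)[[1]]
  expect_identical(m$tss, 400L)
  expect_equal(m$utr5, data.frame(start = 351L, end = 400L),
               ignore_attr = TRUE)
  expect_equal(m$utr3, data.frame(start = 101L, end = 150L),
               ignore_attr = TRUE)
})

test_that("GFF3 structural errors are reported", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1;Parent=ghost"), f)
  expect_error(read_gff3(f), "orphan Parent")
  writeLines(c("##gff-version 3",
               "c1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1",
               "c1\t.\texon\t101\t200\t.\t+\t.\tParent=m1",
               "c1\t.\tCDS\t90\t95\t.\t+\t0\tParent=m1"), f)
  expect_error(read_gff3(f), "CDS segment outside exons")
})

test_that("gene models survive a GFF3 write/read round trip", {
  d <- small_design()
  g <- make_genome(d, 5)
  models <- make_gene_models(g, d, 6)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(models, f)
  back <- read_gff3(f)
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    a <- models[[id]]
    b <- back[[id]]
    for (fld in c("chrom", "strand", "tss")) {
      expect_identical(a[[fld]], b[[fld]], label = paste(id, fld))
    }
    for (fld in c("exons", "cds", "utr5", "utr3")) {
      expect_equal(a[[fld]], b[[fld]], ignore_attr = TRUE,
                   label = paste(id, fld))
    }
  }
})

test_that("pileup lines parse per the grammar", {
  s <- parse_pileup_line("chr16\t74016\tA\t6\t.,.,.,\tIIIIII")
  expect_identical(s$depth, 6L)
  expect_identical(s$base_counts[["A"]], 6L)

  s <- parse_pileup_line("chr16\t74015\tG\t10\t.....-9CCACTGCCA.....\tIIIIIIIIII")
  expect_identical(s$base_counts[["-CCACTGCCA"]], 1L)
  expect_identical(s$base_counts[["G"]], 10L)

  s <- parse_pileup_line("chr11\t4464202\tG\t8\t..AAAA,,\tIIIIIIII")
  expect_identical(s$base_counts[["G"]], 4L)
  expect_identical(s$base_counts[["A"]], 4L)

  # read starts/ends and deletion placeholders are not observations
  s <- parse_pileup_line("c\t5\tT\t4\t^I.$,*t\tIIII")
  expect_identical(s$base_counts[["T"]], 3L)
  expect_identical(sum(s$base_counts), 3L)
})

test_that("malformed pileup input errors; depth mismatch only warns", {
  expect_error(parse_pileup_line("c\t5\tT\t4\t..+\tIIII"), "indel")
  expect_error(parse_pileup_line("c\t5\tT\t4\t..+5AC\tIIII"), "truncated")
  expect_error(parse_pileup_line("c\t5\tT\t2\t..^\tII"), "read-start")
  expect_error(parse_pileup_line("c\t5\tT"), "6 columns")
  expect_warning(parse_pileup_line("c\t5\tT\t2\t....\tIIII"), "depth")
})

test_that("parsed counts equal the generator tally on random grammar strings", {
  set.seed(402)
  for (i in 1:1000) {
    rl <- random_pileup_line()
    s <- parse_pileup_line(rl$line, "BY-H")
    exp <- rl$expected[rl$expected > 0 |
                         names(rl$expected) %in% c("A", "C", "G", "T")]
    expect_identical(s$base_counts[order(names(s$base_counts))],
                     exp[order(names(exp))],
                     label = paste("line", i, rl$line))
  }
})

test_that("the bulk pileup reader agrees with the per-line parser", {
  set.seed(77)
  rls <- lapply(1:300, function(i) random_pileup_line(pos = i * 10L))
  f <- withr::local_tempfile(fileext = ".pileup")
  writeLines(vapply(rls, `[[`, character(1), "line"), f)
  df <- read_pileup(f, pool_id = "WL-L")
  expect_identical(nrow(df), 300L)
  for (i in seq_along(rls)) {
    s <- parse_pileup_line(rls[[i]]$line, "WL-L")
    for (b in c("A", "C", "G", "T")) {
      expect_identical(df[[b]][i], s$base_counts[[b]],
                       label = paste("site", i, "base", b))
    }
    ind <- s$base_counts[!(names(s$base_counts) %in%
                             c("A", "C", "G", "T"))]
    got <- df$indels[[i]]
    if (length(ind)) {
      expect_identical(got[order(names(got))], ind[order(names(ind))],
                       label = paste("site", i, "indels"))
    } else {
      expect_null(got)
    }
  }
})

test_that("VCF uses left-anchored indel representation and round-trips", {
  calls <- data.frame(
    chrom = "chr16", pos = c(74015L, 213135L),
    ref = c("GCCACTGCCA", "C"), alt = c("G", "G"),
    var_type = c("DEL", "SNP"), pool_id = "BY-H",
    depth = c(30L, 28L), alt_count = c(25L, 20L),
    alt_fraction = c(25 / 30, 20 / 28),
    zygosity = c("pool-homozygous", "pool-heterozygous"),
    p_value = c(1e-30, 2.5e-12), passed_fdr = TRUE,
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  txt <- readLines(f)
  del <- grep("74015", txt, value = TRUE)
  expect_match(del, "GCCACTGCCA\tG")
  expect_equal(read_vcf(f), calls, ignore_attr = TRUE)

  expect_error(write_vcf(calls[2:1, ], f), "sorted")
})

test_that("reading a foreign or malformed VCF fails with a line number", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
               "c1\t10\t.\tA"), f)
  expect_error(read_vcf(f), "line 3")
  writeLines("no header at all", f)
  expect_error(read_vcf(f), "#CHROM")
})

test_that("written VCF is readable by an independent VCF parser", {
  # VariantAnnotation as an external conformance check on the dialect
  calls <- data.frame(
    chrom = "chr1", pos = c(100L, 200L), ref = c("A", "TGC"),
    alt = c("G", "T"), var_type = c("SNP", "DEL"), pool_id = "WL-H",
    depth = c(20L, 31L), alt_count = c(20L, 16L),
    alt_fraction = c(1, 16 / 31),
    zygosity = c("pool-homozygous", "pool-heterozygous"),
    p_value = c(1e-40, 1e-22), passed_fdr = TRUE,
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, f)
  v <- suppressWarnings(VariantAnnotation::readVcf(f))
  expect_identical(unname(as.integer(VariantAnnotation::info(v)$DP)),
                   c(20L, 31L))
  rr <- SummarizedExperiment::rowRanges(v)
  expect_identical(as.character(GenomicRanges::start(rr)), c("100", "200"))
  expect_identical(as.character(rr$REF), c("A", "TGC"))
})
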