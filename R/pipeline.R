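#' Run the calling stage over the four pool pileups
#'
#' @param pileup_paths Named character vector (pool id -> pileup path).
#' @param genome Named character vector of reference sequences.
#' @param config A [pipeline_config()].
#' @return Named list of per-pool variant-call data frames.
#' @export
call_pools <- function(pileup_paths, genome, config = pipeline_config()) {
  setNames(lapply(names(pileup_paths), function(p) {
    sites <- read_pileup(pileup_paths[[p]], pool_id = p)
    call_variants(sites, config, genome)
  }), names(pileup_paths))
}

#' Write all summary reports for a comparison
#'
#' Emits the pipeline's report TSVs under `out_dir`: per-group
#' phenotype statistics with fold changes, SNP and indel
#' component-distribution tables, group-specific non-synonymous /
#' promoter counts, the gene-level map of cross-breed common variants,
#' common indels, the per-variant comparison table and the Venn-style
#' category counts.
#'
#' @param comparison Output of [compare_pools()].
#' @param calls Combined call data frame (all pools).
#' @param annotations Output of [annotate_variants()].
#' @param phenotypes Per-bird phenotype data frame (`breed`, `group`,
#'   `value`).
#' @param out_dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_reports <- function(comparison, calls, annotations, phenotypes,
                          out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  emit <- function(name, df, comment = NULL) {
    p <- file.path(out_dir, name)
    write_tsv(df, p, comment = comment)
    paths[[name]] <<- p
  }

  gs <- group_stats(phenotypes)
  fc <- do.call(rbind, lapply(unique(gs$breed), function(b) {
    hi <- gs$mean[gs$breed == b & gs$group == "high"]
    lo <- gs$mean[gs$breed == b & gs$group == "low"]
    data.frame(breed = b,
               fold_change = if (length(hi) && length(lo)) {
                 fold_change(hi, lo)
               } else {
                 NA_real_
               })
  }))
  emit("group_stats.tsv", merge(gs, fc, by = "breed", all.x = TRUE))

  snp_tab <- snp_distribution(calls, annotations)
  emit("snp_distribution.tsv",
       cbind(snp_tab, total = attr(snp_tab, "total")),
       comment = paste("union of pools; homozygous = pool-homozygous in",
                       "every pool carrying the variant; gene = overlaps",
                       "any gene body; mRNA = overlaps any exon"))
  ind_tab <- indel_distribution(calls, annotations)
  emit("indel_distribution.tsv",
       cbind(ind_tab, total = attr(ind_tab, "total")),
       comment = "union of pools; component = any overlapping gene hit")

  emit("nonsyn_promoter_counts.tsv",
       nonsyn_promoter_counts(comparison, annotations))
  gm <- common_gene_map(comparison, annotations)
  emit("common_gene_map.tsv", gm$snp_genes)
  emit("common_indels.tsv", gm$indels)
  emit("comparison.tsv",
       recover_categories(comparison)[, c("chrom", "pos", "ref", "alt",
                                          "var_type", POOL_IDS,
                                          "category", "cross_group",
                                          "match_type")])
  emit("venn_counts.tsv", venn_counts(comparison$matrix))
  invisible(paths)
}

#' Run the full pipeline end to end
#'
#' Simulates (or reuses) a study, calls variants in every pool,
#' annotates the union call set, compares the four pools, writes every
#' report and a run manifest (`manifest.json`: config snapshot, input
#' digests, package version, seed, per-stage row counts). Re-running
#' with the same seed and config writes byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param design A [truth_design()] for the simulation stage.
#' @param seed Integer master seed (defaults to `config$random_seed`).
#' @return List with `calls`, `annotations`, `comparison`, `recovery`,
#'   `paths`.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         design = truth_design(),
                         seed = config$random_seed) {
  sim <- simulate_study(design, config, out_dir, seed)

  call_sets <- call_pools(sim$paths$pileups, sim$genome, config)
  vcf_dir <- file.path(out_dir, "calls")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (p in names(call_sets)) {
    write_vcf(call_sets[[p]], file.path(vcf_dir, paste0(p, ".vcf")))
  }

  calls <- do.call(rbind, call_sets)
  annotations <- annotate_variants(calls, sim$models, sim$genome, config)
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_tsv(annotations, ann_path)

  comparison <- compare_pools(call_sets, config)
  report_paths <- write_reports(comparison, calls, annotations,
                                sim$phenotypes,
                                file.path(out_dir, "reports"))
  recovery <- evaluate_recovery(comparison, sim$truth)

  manifest <- list(
    tool = "poolvar",
    version = as.character(utils::packageVersion("poolvar")),
    seed = as.integer(seed),
    config = unclass(config),
    inputs = {
      md5 <- tools::md5sum(unlist(sim$paths[c("genome", "gff3",
                                              "truth")]))
      as.list(setNames(md5, basename(names(md5))))
    },
    stage_rows = list(
      truth = nrow(sim$truth),
      calls_per_pool = lapply(call_sets, nrow),
      annotations = nrow(annotations),
      comparison = nrow(comparison$matrix)
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(calls = calls, annotations = annotations, comparison = comparison,
       recovery = recovery,
       paths = c(sim$paths,
                 list(vcfs = setNames(file.path(vcf_dir,
                                                paste0(names(call_sets),
                                                       ".vcf")),
                                      names(call_sets)),
                      annotations = ann_path, manifest = manifest_path),
                 report_paths))
}
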