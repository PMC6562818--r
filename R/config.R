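#' Pipeline configuration
#'
#' Thresholds and symbols shared by every stage of the pipeline. Values
#' mirror the study design this pipeline implements: a site must have
#' coverage strictly greater than `min_depth_exclusive` reads to be
#' considered (coverage > 4), candidate calls are filtered at a
#' Benjamini-Hochberg false discovery rate below `fdr_q` (0.01), and the
#' proximal promoter is the `promoter_length` (2000) bp immediately
#' upstream of the TSS.
#'
#' @param min_depth_exclusive Integer; sites with depth strictly greater
#'   than this pass the coverage gate (default 4, i.e. depth >= 5).
#' @param fdr_q Benjamini-Hochberg false discovery rate threshold
#'   (default 0.01).
#' @param base_error_rate Per-base sequencing error probability used by
#'   the binomial site test and the simulator (default 0.01).
#' @param het_fraction_min Minimum pool alternate-allele fraction for a
#'   candidate call (default 0.2).
#' @param hom_fraction_min Alternate-allele fraction at or above which a
#'   pooled call is classed pool-homozygous, i.e. effectively fixed in
#'   the pool (default 0.8).
#' @param promoter_length Proximal promoter length in bp upstream of the
#'   TSS (default 2000).
#' @param indel_match_window Maximum distance in bp at which two indels
#'   on one chromosome are treated as occupying the same genomic region
#'   (default 10).
#' @param random_seed Integer seed used when a stage needs randomness
#'   and no explicit seed is given (default 1).
#' @return An object of class `pipeline_config` (a validated named list).
#' @seealso [load_config()], [write_config()]
#' @export
pipeline_config <- function(min_depth_exclusive = 4L,
                            fdr_q = 0.01,
                            base_error_rate = 0.01,
                            het_fraction_min = 0.2,
                            hom_fraction_min = 0.8,
                            promoter_length = 2000L,
                            indel_match_window = 10L,
                            random_seed = 1L) {
  cfg <- list(
    min_depth_exclusive = as.integer(min_depth_exclusive),
    fdr_q = as.numeric(fdr_q),
    base_error_rate = as.numeric(base_error_rate),
    het_fraction_min = as.numeric(het_fraction_min),
    hom_fraction_min = as.numeric(hom_fraction_min),
    promoter_length = as.integer(promoter_length),
    indel_match_window = as.integer(indel_match_window),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v)) fail(f, "must be a single non-missing value")
  }
  if (!(cfg$fdr_q > 0 && cfg$fdr_q < 1)) fail("fdr_q", "must lie in (0, 1)")
  if (!(cfg$base_error_rate > 0 && cfg$base_error_rate < 0.5)) {
    fail("base_error_rate", "must lie in (0, 0.5)")
  }
  if (!(cfg$het_fraction_min > 0)) fail("het_fraction_min", "must be > 0")
  if (!(cfg$het_fraction_min <= cfg$hom_fraction_min)) {
    fail("het_fraction_min", "must be <= hom_fraction_min")
  }
  if (!(cfg$hom_fraction_min <= 1)) fail("hom_fraction_min", "must be <= 1")
  if (cfg$min_depth_exclusive < 0L) fail("min_depth_exclusive", "must be >= 0")
  if (cfg$promoter_length <= 0L) fail("promoter_length", "must be > 0")
  if (cfg$indel_match_window < 0L) fail("indel_match_window", "must be >= 0")
  cfg
}

#' Load a pipeline configuration from a flat key-value file
#'
#' The file is a flat YAML document of `key: value` pairs. Missing keys
#' take their defaults (see [pipeline_config()]); unknown keys are an
#' error so typos cannot silently fall back to defaults. An empty file
#' yields the all-defaults configuration.
#'
#' @param path Path to the config file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("config parse error in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) {
    stop("config parse error in ", path,
         ": expected flat key: value pairs", call. = FALSE)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to a flat key-value file
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces every field exactly.
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}
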