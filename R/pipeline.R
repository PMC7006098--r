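## Workflow composition: one call running the mapping pipeline in the
## conventional order (simulate/load -> QC -> coding -> GREML -> cLDLA scan
## + permutation thresholds -> MLMA congruence -> power), writing all
## artifacts and a summary report to an output directory.

#' Validate a pipeline configuration
#'
#' Checks a configuration list before any stage runs; failures name the
#' offending field. Fields and defaults:
#' `coding_id` ("CC"), `window_size` (40), `step` (1), `n_individuals`
#' (232), `n_snps_per_chrom` (c(2000, 2000, 2000)), `qtl_chrom` ("1"),
#' `qtl_snp` (1000), `qtl_variance` (0.3), `h2_poly` (0.25),
#' `n_datasets` (20), `n_midpoints` (20), `k` (5),
#' `n_permutations_greml` (100), `power_reps` (2000),
#' `thresholds_mode` ("permutation" or "bonferroni"), `seed` (1).
#'
#' @param config named list of configuration values (missing entries take
#'   the defaults above).
#' @return the completed configuration list, invisibly classed
#'   `run_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    coding_id = "CC", window_size = 40, step = 1,
    n_individuals = 232, n_snps_per_chrom = c(2000, 2000, 2000),
    qtl_chrom = "1", qtl_snp = 1000, qtl_variance = 0.3, h2_poly = 0.25,
    n_datasets = 20, n_midpoints = 20, k = 5,
    n_permutations_greml = 100, power_reps = 2000,
    thresholds_mode = "permutation", seed = 1)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$coding_id %in% c("CC", "CCL", "BC1", "BC2")) {
    stop("config field 'coding_id' must be one of CC, CCL, BC1, BC2",
         call. = FALSE)
  }
  if (cfg$window_size %% 2 != 0 || cfg$window_size < 2) {
    stop("config field 'window_size' must be even and >= 2", call. = FALSE)
  }
  if (!cfg$thresholds_mode %in% c("permutation", "bonferroni")) {
    stop("config field 'thresholds_mode' must be 'permutation' or 'bonferroni'",
         call. = FALSE)
  }
  for (f in c("n_individuals", "qtl_variance", "h2_poly", "n_datasets",
              "n_midpoints", "k", "power_reps", "seed", "step")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L) {
      stop("config field '", f, "' must be a single number", call. = FALSE)
    }
  }
  invisible(structure(cfg, class = "run_config"))
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`, requires the \pkg{yaml} package) or JSON
#' configuration file and validates it with [validate_config()].
#'
#' @param path configuration file path.
#' @return a validated `run_config` list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' Run the full mapping workflow on simulated data
#'
#' Composes the package's stages in the conventional order on a simulated
#' panel with a known embedded QTL: panel simulation, genotype QC,
#' phenotype coding, GREML SNP-heritability with permutation validation,
#' cLDLA scan with empirical (or Bonferroni-based) significance threshold,
#' region merging, MLMA-LOCO with the smoothed congruence curve, and the
#' power grid. All randomness derives from `config$seed`. Artifacts
#' (config JSON, phenotype TSV, scan TSV, regions BED, association TSV,
#' report JSON) are written to `out_dir`.
#'
#' @param config configuration list, see [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return the report list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("scurmap_run_")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  map <- genome_map(cfg$n_snps_per_chrom)
  panel <- simulate_panel(cfg$n_individuals, map, seed = cfg$seed)
  qc <- qc_filter(panel)
  truth <- truth_record(qtl_chrom = cfg$qtl_chrom, qtl_snp = cfg$qtl_snp,
                        qtl_variance = cfg$qtl_variance,
                        h2_poly = cfg$h2_poly, seed = cfg$seed)
  ph <- simulate_phenotypes(panel, truth)
  write_phenotypes(ph, file.path(out_dir, "phenotypes.tsv"))
  trait <- code_trait(ph, cfg$coding_id)
  X_age <- cbind(age_days = ph$age_days)

  G <- grm(panel)
  h2 <- greml_h2(trait$values, .design_matrix(X_age, nrow(ph)), G,
                 n_permutations = cfg$n_permutations_greml,
                 seed = cfg$seed + 1L)

  scan <- cldla_scan(panel, trait, covariates = X_age,
                     window_size = cfg$window_size, step = cfg$step)
  write_scan_tsv(scan, file.path(out_dir, "scan.tsv"))

  if (cfg$thresholds_mode == "permutation") {
    perm <- permutation_thresholds(panel, trait, covariates = X_age,
                                   window_size = cfg$window_size,
                                   n_datasets = cfg$n_datasets,
                                   n_midpoints = cfg$n_midpoints,
                                   k = cfg$k, seed = cfg$seed + 2L)
    lrt_threshold <- perm$threshold
    alpha <- perm$alpha
  } else {
    ## chi-squared(1) quantile matching the Bonferroni genome-wide p
    alpha <- unname(bonferroni_thresholds(n_snps(panel))[["genomewide"]])
    lrt_threshold <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  }
  regions <- significant_regions(scan, lrt_threshold)
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))

  assoc <- mlma_loco(panel, trait, covariates = X_age)
  utils::write.table(assoc, file.path(out_dir, "assoc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  smoothed <- smooth_neglog10(assoc)
  congruence <- congruence_pairs(scan, smoothed)

  power <- power_grid(reps = cfg$power_reps, seed = cfg$seed + 3L)

  report <- list(
    config = unclass(cfg),
    qc = qc$report[c("n_snps_in", "n_snps_out", "n_individuals_in",
                     "n_individuals_out")],
    h2 = list(estimate = h2$h2, se = h2$se, p_empirical = h2$p_empirical),
    threshold = list(lrt = lrt_threshold, alpha = alpha,
                     mode = cfg$thresholds_mode),
    n_midpoints_scanned = nrow(scan),
    regions = regions,
    top_mlma = assoc[which.min(assoc$p),
                     c("chrom", "snp", "bp", "beta", "p")],
    congruence_cor = if (nrow(congruence) > 1) {
      stats::cor(congruence$cldla_neglog10p,
                 congruence$mlma_neglog10p_smooth)
    } else NA_real_,
    power = power)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
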