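#' Ground truth for a simulated phenotype architecture
#'
#' Records the QTL placement and variance decomposition used by
#' [simulate_phenotypes()], so parameter-recovery tests can compare
#' estimates against known truth. All variance arguments are fractions of
#' the unit liability variance and must sum to at most 1; the remainder is
#' independent residual variance.
#'
#' @param qtl_chrom,qtl_snp chromosome label and SNP index (within that
#'   chromosome) of the causal variant, or `NULL` for no QTL.
#' @param qtl_variance fraction of liability variance explained by the QTL.
#' @param h2_poly fraction of liability variance explained by a polygenic
#'   term (a sum of small effects across all SNPs).
#' @param age_variance fraction of liability variance explained by age at
#'   phenotyping (default 0.05: a small positive age effect).
#' @param sex_effect liability shift for males (0 in the all-female
#'   mapping design).
#' @param seed integer master seed for phenotype simulation.
#' @return a list of class `truth_record`.
#' @export
truth_record <- function(qtl_chrom = NULL, qtl_snp = NULL, qtl_variance = 0,
                         h2_poly = 0, age_variance = 0.05, sex_effect = 0,
                         seed = 1) {
  vs <- c(qtl_variance = qtl_variance, h2_poly = h2_poly,
          age_variance = age_variance)
  if (any(vs < 0) || any(vs > 1) || sum(vs) > 1) {
    stop("variance fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (qtl_variance > 0 && (is.null(qtl_chrom) || is.null(qtl_snp))) {
    stop("a QTL with positive variance needs 'qtl_chrom' and 'qtl_snp'",
         call. = FALSE)
  }
  structure(list(qtl_chrom = qtl_chrom, qtl_snp = qtl_snp,
                 qtl_variance = qtl_variance, h2_poly = h2_poly,
                 age_variance = age_variance, sex_effect = sex_effect,
                 seed = as.integer(seed)),
            class = "truth_record")
}

#' Phenotype categories of the mapping design
#'
#' The five ordered horn-status categories used for the genotyped mapping
#' subset, and the six categories of the on-farm survey scale. The two
#' scales are distinct enumerations; no implicit conversion is performed.
#'
#' @format character vectors.
#' @export
mapping_categories <- c("smoothly_polled", "frontal_bumps", "scabs",
                        "small_scurs", "medium_scurs")

#' @rdname mapping_categories
#' @export
survey_categories <- c("smoothly_polled", "small_frontal_bumps",
                       "frontal_bumps", "scurs", "horns", "others")

#' Simulate categorical horn phenotypes on a liability scale
#'
#' Generates a standard-normal liability for each panel individual as the
#' sum of a scaled QTL dosage effect, a polygenic term (small random effects
#' of all SNPs), an age covariate effect and an independent residual, in the
#' proportions recorded in `truth`. The liability is standardized
#' empirically (centred, divided by its realized SD) so that the category
#' thresholds -- the standard-normal quantiles of the cumulative category
#' frequencies -- land exactly on the simulated scale, and the realized
#' category distribution matches `category_freqs` in expectation.
#'
#' @param panel a [haplotype_panel()].
#' @param truth a [truth_record()].
#' @param category_freqs five ordered category frequencies summing to 1;
#'   the default is the 75/130/19/7/1 distribution of the mapping design.
#' @param male_fraction fraction of males (default 0: all-female design).
#' @return a `data.frame` with columns `id`, `category` (ordered factor on
#'   the mapping scale), `sex`, `age_days`, `polled_genotype`, and
#'   `liability` (the latent variable, kept for tests and diagnostics).
#' @examples
#' panel <- simulate_panel(50, genome_map(60), seed = 2)
#' ph <- simulate_phenotypes(panel, truth_record(seed = 2))
#' table(ph$category)
#' @export
simulate_phenotypes <- function(panel, truth = truth_record(),
                                category_freqs = c(75, 130, 19, 7, 1) / 232,
                                male_fraction = 0) {
  if (!inherits(panel, "haplotype_panel")) stop("'panel' must be a haplotype_panel",
                                               call. = FALSE)
  if (!inherits(truth, "truth_record")) stop("'truth' must be a truth_record",
                                             call. = FALSE)
  if (length(category_freqs) != 5L || any(category_freqs <= 0) ||
      abs(sum(category_freqs) - 1) > 1e-8) {
    stop("'category_freqs' must be 5 positive frequencies summing to 1",
         call. = FALSE)
  }
  n <- n_individuals(panel)
  set.seed(truth$seed + 1000003L)

  age <- stats::runif(n, 700, 3000)
  sex <- rep("female", n)
  if (male_fraction > 0) {
    sex[stats::runif(n) < male_fraction] <- "male"
  }

  liab <- stats::rnorm(n) * sqrt(max(0, 1 - truth$qtl_variance -
                                       truth$h2_poly - truth$age_variance))
  if (truth$age_variance > 0) {
    a <- (age - mean(age)) / stats::sd(age)
    liab <- liab + a * sqrt(truth$age_variance)
  }
  if (truth$h2_poly > 0) {
    d <- dosages(panel)
    p <- colMeans(d) / 2
    poly_ok <- p > 0 & p < 1
    w <- sweep(d[, poly_ok, drop = FALSE], 2, 2 * p[poly_ok])
    w <- sweep(w, 2, sqrt(2 * p[poly_ok] * (1 - p[poly_ok])), "/")
    u <- as.vector(w %*% stats::rnorm(ncol(w))) / sqrt(ncol(w))
    u <- (u - mean(u)) / max(stats::sd(u), 1e-12)
    liab <- liab + u * sqrt(truth$h2_poly)
  }
  if (truth$qtl_variance > 0) {
    idx <- .chrom_index(panel$map, truth$qtl_chrom)
    if (truth$qtl_snp < 1L || truth$qtl_snp > length(idx)) {
      stop("'qtl_snp' outside chromosome ", truth$qtl_chrom, call. = FALSE)
    }
    j <- idx[truth$qtl_snp]
    d <- dosages(panel)[, j]
    if (stats::sd(d) == 0) stop("QTL SNP is monomorphic in this panel",
                                call. = FALSE)
    z <- (d - mean(d)) / stats::sd(d)
    liab <- liab + z * sqrt(truth$qtl_variance)
  }
  if (truth$sex_effect != 0) {
    liab <- liab + truth$sex_effect * (sex == "male")
  }
  liab <- (liab - mean(liab)) / stats::sd(liab)

  cuts <- c(-Inf, stats::qnorm(cumsum(category_freqs)[1:4]), Inf)
  cat_idx <- cut(liab, breaks = cuts, labels = FALSE)
  data.frame(
    id = panel$ids,
    category = factor(mapping_categories[cat_idx], levels = mapping_categories,
                      ordered = TRUE),
    sex = sex,
    age_days = age,
    polled_genotype = rep("PF/p", n),
    liability = liab,
    stringsAsFactors = FALSE
  )
}
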