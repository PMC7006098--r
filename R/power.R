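## Liability-threshold power simulation for single-marker regression.

#' Define a power-simulation scenario
#'
#' Each replicate draws `n` independent liabilities on the N(0,1) scale as
#' the sum of a biallelic QTL effect explaining
#' `qtl_fraction * h2` of the liability variance and an independent
#' residual; the liability is discretized into the coding's classes using
#' thresholds fixed from the reference category counts (so the realized
#' phenotype distribution matches the mapping design), a marker in linkage
#' disequilibrium with the QTL at haplotype-level r-squared `marker_r2` is
#' generated, and the coded phenotype is regressed on marker dosage.
#'
#' @param n individuals per replicate.
#' @param h2 assumed trait heritability.
#' @param qtl_fraction fraction of the genetic variance explained by the
#'   QTL (conventionally 0.10, 0.20 or 0.30).
#' @param coding_id `"CC"`, `"CCL"` or `"BC1"`.
#' @param marker_r2 haplotype-level linkage disequilibrium between marker
#'   and QTL, in (0, 1].
#' @param reps replicates per scenario.
#' @param thresholds named p-value thresholds `c(genomewide=, suggestive=)`;
#'   default the Bonferroni pair for 762,966 SNPs.
#' @param qtl_freq QTL (and marker) allele frequency.
#' @param category_counts reference counts fixing the liability thresholds.
#' @param seed integer seed; scenarios sharing a seed share their latent
#'   liability draws, so codings can be compared replicate by replicate.
#' @return list of class `power_scenario`.
#' @export
power_scenario <- function(n = 232, h2 = 0.6, qtl_fraction = 0.3,
                           coding_id = c("CC", "CCL", "BC1"),
                           marker_r2 = 0.8, reps = 10000,
                           thresholds = bonferroni_thresholds(762966),
                           qtl_freq = 0.5,
                           category_counts = c(75, 130, 19, 7, 1),
                           seed = 1) {
  coding_id <- match.arg(coding_id)
  if (qtl_fraction < 0 || qtl_fraction * h2 > 1) {
    stop("'qtl_fraction * h2' must lie in [0, 1]", call. = FALSE)
  }
  if (marker_r2 <= 0 || marker_r2 > 1) {
    stop("'marker_r2' must lie in (0, 1]; at equal allele frequencies any ",
         "value up to 1 is feasible", call. = FALSE)
  }
  if (qtl_freq <= 0 || qtl_freq >= 1) {
    stop("'qtl_freq' must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(names(thresholds)) ||
      !all(c("genomewide", "suggestive") %in% names(thresholds))) {
    stop("'thresholds' needs elements 'genomewide' and 'suggestive'",
         call. = FALSE)
  }
  structure(list(n = n, h2 = h2, qtl_fraction = qtl_fraction,
                 coding_id = coding_id, marker_r2 = marker_r2,
                 reps = as.integer(reps), thresholds = thresholds,
                 qtl_freq = qtl_freq, category_counts = category_counts,
                 seed = as.integer(seed)),
            class = "power_scenario")
}

#' Run a liability-threshold power simulation
#'
#' Power is the proportion of replicates in which the Wald chi-squared(1)
#' p-value of the single-marker regression passes the scenario's
#' significance thresholds (computed on shared replicates, so power at the
#' suggestive threshold can never fall below genome-wide power).
#'
#' @param scenario a [power_scenario()].
#' @return object of class `power_result`: `power_genomewide`,
#'   `power_suggestive`, `mc_se` (Monte-Carlo standard errors),
#'   `realized_marker_r2`, plus the scenario.
#' @examples
#' run_power(power_scenario(qtl_fraction = 0.3, reps = 500))
#' @export
run_power <- function(scenario) {
  stopifnot(inherits(scenario, "power_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n
  reps <- sc$reps
  p <- sc$qtl_freq
  a <- sqrt(sc$marker_r2)  # per-haplotype copy probability giving r = a
  vq <- sc$qtl_fraction * sc$h2

  ## haplotype-level draws: 2 QTL alleles per individual; the linked marker
  ## copies each QTL allele with probability a, else redraws at frequency p
  q1 <- matrix(stats::rbinom(n * reps, 1L, p), n)
  q2 <- matrix(stats::rbinom(n * reps, 1L, p), n)
  copy1 <- matrix(stats::runif(n * reps) < a, n)
  copy2 <- matrix(stats::runif(n * reps) < a, n)
  m1 <- ifelse(copy1, q1, matrix(stats::rbinom(n * reps, 1L, p), n))
  m2 <- ifelse(copy2, q2, matrix(stats::rbinom(n * reps, 1L, p), n))
  qd <- q1 + q2
  md <- m1 + m2

  b <- sqrt(vq / (2 * p * (1 - p)))
  liab <- b * (qd - 2 * p) + matrix(stats::rnorm(n * reps, 0, sqrt(1 - vq)), n)

  lc <- liability_transform(sc$category_counts)
  cat_idx <- matrix(findInterval(liab, lc$thresholds) + 1L, n)
  y <- switch(sc$coding_id,
              CC = cat_idx,
              CCL = matrix(lc$section_means[cat_idx], n),
              BC1 = ifelse(cat_idx == 1L, 1, 2))

  ## per-replicate OLS of coded phenotype on marker dosage, vectorized
  mx <- colMeans(md)
  my <- colMeans(y)
  sxx <- colSums(md^2) - n * mx^2
  sxy <- colSums(md * y) - n * mx * my
  syy <- colSums(y^2) - n * my^2
  testable <- sxx > 0 & syy > 0
  beta <- sxy / sxx
  rss <- syy - beta^2 * sxx
  se2 <- pmax(rss, 0) / (n - 2) / sxx
  wald <- beta^2 / se2
  pv <- lrt_to_p(ifelse(testable, wald, 0))
  pv[!testable] <- 1

  ## realized marker-QTL haplotype r^2 pooled over replicates
  r2 <- stats::cor(as.vector(rbind(q1, q2)), as.vector(rbind(m1, m2)))^2

  pw <- function(th) mean(pv < th)
  pg <- pw(sc$thresholds[["genomewide"]])
  ps <- pw(sc$thresholds[["suggestive"]])
  structure(list(power_genomewide = pg, power_suggestive = ps,
                 mc_se = c(genomewide = sqrt(pg * (1 - pg) / reps),
                           suggestive = sqrt(ps * (1 - ps) / reps)),
                 realized_marker_r2 = r2, p_values = pv,
                 scenario = sc),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Power (%s, QTL %.0f%% of genetic variance, h2 %.2f, n %d, %d reps):\n",
    sc$coding_id, 100 * sc$qtl_fraction, sc$h2, sc$n, sc$reps))
  cat(sprintf("  genome-wide (p < %.3g): %.3f (MC SE %.3f)\n",
              sc$thresholds[["genomewide"]], x$power_genomewide,
              x$mc_se[["genomewide"]]))
  cat(sprintf("  suggestive  (p < %.3g): %.3f (MC SE %.3f)\n",
              sc$thresholds[["suggestive"]], x$power_suggestive,
              x$mc_se[["suggestive"]]))
  cat(sprintf("  realized marker-QTL r2: %.3f\n", x$realized_marker_r2))
  invisible(x)
}

#' Power over a grid of scenarios
#'
#' Convenience wrapper running [run_power()] for every combination of QTL
#' fraction and coding, sharing one seed so codings are compared on the
#' same latent replicates.
#'
#' @param qtl_fractions numeric vector of QTL variance fractions.
#' @param coding_ids character vector of codings.
#' @param ... further arguments to [power_scenario()].
#' @return data frame with one row per scenario (tidy layout:
#'   `qtl_fraction`, `coding_id`, `power_genomewide`, `power_suggestive`,
#'   `mc_se_genomewide`, `mc_se_suggestive`).
#' @export
power_grid <- function(qtl_fractions = c(0.1, 0.2, 0.3),
                       coding_ids = c("CC", "CCL", "BC1"), ...) {
  rows <- list()
  for (f in qtl_fractions) {
    for (cid in coding_ids) {
      r <- run_power(power_scenario(qtl_fraction = f, coding_id = cid, ...))
      rows[[length(rows) + 1L]] <- data.frame(
        qtl_fraction = f, coding_id = cid,
        power_genomewide = r$power_genomewide,
        power_suggestive = r$power_suggestive,
        mc_se_genomewide = r$mc_se[["genomewide"]],
        mc_se_suggestive = r$mc_se[["suggestive"]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
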