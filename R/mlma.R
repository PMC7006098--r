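## Mixed linear model association with leave-one-chromosome-out control.

#' Single-SNP mixed linear model association (MLMA-LOCO)
#'
#' Per chromosome, the polygenic and residual variances are estimated once
#' by REML under the leave-one-chromosome-out genomic relationship matrix
#' (the standard MLMA-LOCO approximation) and then held fixed across that
#' chromosome's SNPs. Each SNP's additive dosage effect is estimated by
#' generalized least squares in the whitened basis, with the residual scale
#' re-estimated per SNP; the test statistic is the squared Wald ratio
#' referred to chi-squared(1). With an identity relationship matrix this
#' reduces exactly to single-SNP ordinary least squares. SNPs with zero
#' dosage variance are untestable and flagged (`flag = "monomorphic"`);
#' REML non-convergence for a chromosome flags all its SNPs rather than
#' dropping them.
#'
#' @param panel a [haplotype_panel()].
#' @param trait coded trait (continuous codings are the intended input;
#'   binary codings are accepted but prone to convergence problems).
#' @param covariates optional fixed covariates (intercept always added).
#' @param chroms chromosomes to test (default all).
#' @return object of class `mlma_result`: data frame with one row per SNP
#'   (`chrom`, `snp`, `bp`, `effect_allele`, `af`, `beta`, `se`, `chisq`,
#'   `p`, `neglog10p`, `flag`).
#' @export
mlma_loco <- function(panel, trait, covariates = NULL, chroms = NULL) {
  y <- if (inherits(trait, "coded_trait")) trait$values else as.numeric(trait)
  n <- n_individuals(panel)
  if (length(y) != n) stop("trait length must match the panel", call. = FALSE)
  X <- .design_matrix(covariates, n)
  if (is.null(chroms)) chroms <- unique(panel$map$chrom)
  geno <- dosages(panel)

  res <- list()
  for (cc in chroms) {
    idx <- .chrom_index(panel$map, cc)
    G <- grm(panel, exclude_chrom = cc)
    setup <- .reml_eigen_setup(y, X, G)
    core <- .reml_core(y, X, list(G), method = "eigen", eigen_setup = setup)
    w <- 1 / (core$vc[1L] * setup$lam + core$vc[2L])
    sw <- sqrt(w)
    Xw <- setup$Xst * sw
    z <- as.vector(setup$yst) * sw
    qrX <- qr(Xw)
    zr <- qr.resid(qrX, z)
    Gs <- crossprod(setup$U, geno[, idx, drop = FALSE]) * sw
    Gr <- qr.resid(qrX, Gs)
    gg <- colSums(Gr^2)
    gz <- colSums(Gr * zr)
    testable <- gg > 1e-10
    beta <- ifelse(testable, gz / gg, NA_real_)
    dfree <- n - ncol(X) - 1L
    rss <- sum(zr^2) - ifelse(testable, beta^2 * gg, 0)
    se <- ifelse(testable, sqrt(pmax(rss, 0) / dfree / gg), NA_real_)
    chisq <- (beta / se)^2
    p <- lrt_to_p(ifelse(is.na(chisq), 0, chisq))
    p[!testable] <- NA_real_
    flag <- rep("", length(idx))
    flag[!testable] <- "monomorphic"
    if (!core$converged) flag <- paste0(flag, ";reml_unconverged")
    af <- colMeans(geno[, idx, drop = FALSE]) / 2
    res[[as.character(cc)]] <- data.frame(
      chrom = cc, snp = panel$map$snp[idx], bp = panel$map$pos[idx],
      effect_allele = "1", af = af, beta = beta, se = se, chisq = chisq,
      p = p, neglog10p = ifelse(is.na(p), NA_real_, -log10(p)),
      flag = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("mlma_result", "data.frame"))
}

#' @export
print.mlma_result <- function(x, ...) {
  ok <- !is.na(x$p)
  cat("MLMA-LOCO association:", nrow(x), "SNPs (", sum(!ok), "untestable )\n")
  top <- which.min(x$p)
  cat(sprintf("  top SNP %s (%s:%d bp): beta %.3f, p %.3g\n",
              x$snp[top], x$chrom[top], x$bp[top], x$beta[top], x$p[top]))
  invisible(x)
}

#' Bonferroni significance thresholds for single-SNP tests
#'
#' Genome-wide threshold `0.05 / N` and suggestive threshold `1 / N` for
#' `N` tested SNPs (one expected false positive genome-wide).
#'
#' @param n_snps number of SNPs tested.
#' @return named numeric vector `c(genomewide=, suggestive=)`.
#' @examples
#' bonferroni_thresholds(762966)
#' @export
bonferroni_thresholds <- function(n_snps) {
  if (n_snps < 1) stop("'n_snps' must be at least 1", call. = FALSE)
  c(genomewide = 0.05 / n_snps, suggestive = 1 / n_snps)
}

#' Sliding average of -log10(p) aligned to SNP-interval midpoints
#'
#' To compare single-SNP association signals with midpoint-based scan
#' curves, the mean of `k` consecutive -log10(p) values is computed per
#' chromosome and aligned to the midpoint between the window's SNPs
#' `k/2` and `k/2 + 1`. Edges are truncated, not padded; chromosomes with
#' fewer than `k` testable SNPs are skipped with a message.
#'
#' @param assoc an [mlma_loco()] result (or data frame with `chrom`, `bp`,
#'   `neglog10p`).
#' @param k window length (even).
#' @return data frame with columns `chrom`, `bp`, `neglog10p_smooth`.
#' @export
smooth_neglog10 <- function(assoc, k = 10) {
  if (k < 2 || k %% 2 != 0) stop("'k' must be even and >= 2", call. = FALSE)
  out <- list()
  for (cc in unique(assoc$chrom)) {
    a <- assoc[assoc$chrom == cc & !is.na(assoc$neglog10p), , drop = FALSE]
    a <- a[order(a$bp), , drop = FALSE]
    m <- nrow(a)
    if (m < k) {
      message("chromosome ", cc, " has fewer than ", k, " testable SNPs; skipped")
      next
    }
    cs <- cumsum(c(0, a$neglog10p))
    sm <- (cs[(k + 1):(m + 1)] - cs[1:(m - k + 1)]) / k
    ctr <- seq_len(m - k + 1L) + k / 2 - 1L
    out[[as.character(cc)]] <- data.frame(
      chrom = cc, bp = (a$bp[ctr] + a$bp[ctr + 1L]) / 2,
      neglog10p_smooth = sm, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), bp = numeric(),
                      neglog10p_smooth = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair scan midpoints with smoothed single-SNP signals
#'
#' Matches each scanned midpoint to the nearest smoothed -log10(p) value
#' on the same chromosome, giving the plot-ready congruence table used to
#' compare the two mapping approaches.
#'
#' @param scan a [cldla_scan()] result.
#' @param smoothed output of [smooth_neglog10()].
#' @return data frame with `chrom`, `bp`, `cldla_neglog10p`,
#'   `mlma_neglog10p_smooth`.
#' @export
congruence_pairs <- function(scan, smoothed) {
  out <- list()
  for (cc in unique(scan$chrom)) {
    s <- scan[scan$chrom == cc & !is.na(scan$lrt), , drop = FALSE]
    m <- smoothed[smoothed$chrom == cc, , drop = FALSE]
    if (nrow(s) == 0L || nrow(m) == 0L) next
    j <- vapply(s$midpoint_bp, function(b) which.min(abs(m$bp - b)), integer(1))
    out[[as.character(cc)]] <- data.frame(
      chrom = cc, bp = s$midpoint_bp,
      cldla_neglog10p = -log10(lrt_to_p(s$lrt)),
      mlma_neglog10p_smooth = m$neglog10p_smooth[j],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
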