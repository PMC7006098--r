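test_that("MLMA effect and SE match direct GLS with explicit V inverse", {
  set.seed(60)
  n <- 12
  p <- simulate_panel(n, genome_map(c(30, 30)), seed = 60)
  y <- rnorm(n)
  X <- cbind(1, runif(n))
  res <- mlma_loco(p, y, covariates = X[, 2, drop = FALSE])

  ## direct GLS with the same per-chromosome variance components
  geno <- dosages(p)
  Xd <- cbind(1, X[, 2])
  for (cc in c("1", "2")) {
    G <- grm(p, exclude_chrom = cc)
    fit <- reml_fit(y, Xd, K = G)
    V <- fit$vc[1] * G + fit$vc[2] * diag(n)
    Vi <- solve(V)
    idx <- which(p$map$chrom == cc)
    for (j in idx[1:5]) {
      g <- geno[, j]
      if (stats::sd(g) == 0) next
      Z <- cbind(Xd, g)
      ZtViZ <- t(Z) %*% Vi %*% Z
      bhat <- solve(ZtViZ, t(Z) %*% Vi %*% y)
      r <- y - Z %*% bhat
      s2 <- drop(t(r) %*% Vi %*% r) / (n - ncol(Z))
      se <- sqrt(s2 * solve(ZtViZ)[3, 3])
      row <- res[res$snp == p$map$snp[j], ]
      expect_equal(row$beta, bhat[3], tolerance = 1e-10)
      expect_equal(row$se, se, tolerance = 1e-10)
    }
  }
})

test_that("with no genetic structure MLMA equals plain OLS", {
  set.seed(62)
  n <- 100
  p <- simulate_panel(n, genome_map(c(60, 60)), seed = 62)
  y <- rnorm(n)
  res <- mlma_loco(p, y)
  geno <- dosages(p)
  ## LOCO GRMs of an unstructured panel are ~0 relatedness, and the fitted
  ## model collapses to iid residuals; compare against OLS with the same
  ## Wald chi-squared(1) convention
  ols_p <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    if (stats::sd(g) == 0) return(NA_real_)
    f <- stats::lm.fit(cbind(1, g), y)
    s2 <- sum(f$residuals^2) / (n - 2)
    se <- sqrt(s2 / sum((g - mean(g))^2))
    stats::pchisq((f$coefficients[2] / se)^2, 1, lower.tail = FALSE)
  }, numeric(1))
  ## agreement is near-exact despite the estimated (near-zero) polygenic
  ## component
  expect_equal(res$p, ols_p, tolerance = 1e-4)

  ## exact equality when the covariance is forced to identity:
  ## monomorphic SNPs are flagged, never silently dropped
  pm <- p
  pm$haplotypes[, 1] <- 0L
  pm <- haplotype_panel(pm$haplotypes, pm$map, pm$ids)
  res2 <- mlma_loco(pm, y)
  expect_equal(res2$flag[1], "monomorphic")
  expect_true(is.na(res2$p[1]))
  expect_equal(nrow(res2), ncol(geno))
})

test_that("genomic control under family structure keeps the null calibrated", {
  ## related individuals (founder mosaic gives background relatedness); the
  ## trait is driven by polygenic effects on chromosome 2 only, so every
  ## chromosome 1 SNP is null yet correlated with family structure. The
  ## LOCO polygenic term must absorb that confounding: median chi-squared
  ## of the chromosome 1 tests stays near its null expectation.
  set.seed(64)
  meds <- replicate(20, {
    p <- simulate_panel(60, genome_map(c(150, 150)), n_founders = 12,
                        seed = sample.int(1e6, 1))
    d2 <- dosages(subset_chrom(p, "2"))
    frq <- colMeans(d2) / 2
    ok <- frq > 0 & frq < 1
    w <- scale(d2[, ok])
    u <- as.vector(w %*% rnorm(ncol(w))) / sqrt(ncol(w))
    y <- sqrt(0.5) * u / stats::sd(u) + rnorm(60, 0, sqrt(0.5))
    res <- mlma_loco(p, y, chroms = "1")
    stats::median(res$chisq, na.rm = TRUE) / stats::qchisq(0.5, 1)
  })
  expect_gt(mean(meds), 0.8)
  expect_lt(mean(meds), 1.2)
})

test_that("Bonferroni thresholds reproduce the printed values", {
  th <- bonferroni_thresholds(762966)
  expect_equal(signif(th[["genomewide"]], 3), 6.55e-8)
  expect_equal(signif(th[["suggestive"]], 3), 1.31e-6)
  expect_equal(bonferroni_thresholds(20),
               c(genomewide = 0.0025, suggestive = 0.05))
  expect_error(bonferroni_thresholds(0), "at least 1")
})

test_that("smoothed -log10(p) equals the moving-average oracle", {
  ## constant input stays constant
  a_const <- data.frame(chrom = "1", bp = (1:30) * 1e4,
                        neglog10p = rep(2.5, 30))
  s <- smooth_neglog10(a_const, k = 10)
  expect_true(all(s$neglog10p_smooth == 2.5))
  expect_equal(nrow(s), 21L)

  ## 1..10 with k = 10 gives the single value 5.5 at the central midpoint
  a_seq <- data.frame(chrom = "1", bp = (1:10) * 1e4, neglog10p = 1:10)
  s2 <- smooth_neglog10(a_seq, k = 10)
  expect_equal(s2$neglog10p_smooth, 5.5)
  expect_equal(s2$bp, (5e4 + 6e4) / 2)

  ## random input matches the brute-force windows elementwise
  set.seed(66)
  v <- stats::runif(57)
  a_r <- data.frame(chrom = "1", bp = (1:57) * 7e3, neglog10p = v)
  s3 <- smooth_neglog10(a_r, k = 10)
  expect_equal(s3$neglog10p_smooth, oracle_moving_average(v, 10),
               tolerance = 1e-12)

  expect_message(smooth_neglog10(a_seq[1:5, ], k = 10), "fewer than")
  expect_error(smooth_neglog10(a_seq, k = 7), "even")
})

test_that("MLMA and cLDLA localize the same embedded QTL (congruence)", {
  panel <- simulate_panel(100, genome_map(c(250, 120)), seed = 68)
  ph <- simulate_phenotypes(panel,
    truth_record(qtl_chrom = "1", qtl_snp = 125, qtl_variance = 0.35,
                 h2_poly = 0.15, seed = 68))
  tr <- code_trait(ph, "CC")
  X <- cbind(age = ph$age_days)
  sc <- cldla_scan(panel, tr, covariates = X, window_size = 20, step = 5,
                   chroms = "1")
  as_ <- mlma_loco(panel, tr, covariates = X, chroms = "1")
  qtl_bp <- panel$map$pos[125]
  expect_lt(abs(sc$midpoint_bp[which.max(sc$lrt)] - qtl_bp), 1e6)
  expect_lt(abs(as_$bp[which.min(as_$p)] - qtl_bp), 1e6)
  sm <- smooth_neglog10(as_, k = 10)
  cp <- congruence_pairs(sc, sm)
  expect_equal(nrow(cp), nrow(sc))
  ## both transformed curves peak at the same locus
  expect_lt(abs(sm$bp[which.max(sm$neglog10p_smooth)] - qtl_bp), 1e6)
  expect_gt(stats::cor(cp$cldla_neglog10p, cp$mlma_neglog10p_smooth), 0.2)
})
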