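test_that("engine log-likelihood equals the dense projection-matrix oracle", {
  set.seed(30)
  for (rep in 1:6) {
    n <- sample(8:20, 1)
    p <- sample(1:2, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    nk <- sample(1:2, 1)
    Ks <- replicate(nk, {
      B <- matrix(rnorm(n * n), n)
      crossprod(B) / n
    }, simplify = FALSE)
    y <- rnorm(n)
    ## at arbitrary parameter values (grid), both paths match the oracle
    for (theta1 in c(0.2, 1, 3)) {
      theta <- c(rep(theta1, nk), 0.7)
      want <- oracle_reml_loglik(y, X, Ks, theta)
      got_dense <- scurmap:::.reml_dense_eval(theta, y, X, Ks, n, ncol(X),
                                              full = FALSE)
      expect_equal(got_dense, as.numeric(want), tolerance = 1e-8)
      if (nk == 1) {
        su <- scurmap:::.reml_eigen_setup(y, X, Ks[[1]])
        got_eig <- scurmap:::.reml_eigen_eval(theta, su, n, ncol(X),
                                              full = FALSE)
        expect_equal(got_eig, as.numeric(want), tolerance = 1e-8)
      }
    }
    ## and the fitted object reports the oracle likelihood at its optimum
    fit <- reml_fit(y, X, K = Ks)
    expect_equal(fit$logLik,
                 as.numeric(oracle_reml_loglik(y, X, Ks, unname(fit$vc))),
                 tolerance = 1e-8)
  }
})

test_that("identity covariance collapses to the residual model", {
  set.seed(32)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 0.5) + rnorm(n)
  fit <- reml_fit(y, X, K = diag(n))
  ## total variance equals the REML residual variance of the linear model
  s2 <- sum(stats::lm.fit(X, y)$residuals^2) / (n - 2)
  expect_equal(sum(fit$vc), s2, tolerance = 1e-6)
})

test_that("eigen and dense paths agree on the same fit", {
  set.seed(34)
  n <- 50
  G <- tcrossprod(matrix(rnorm(n * 100), n)) / 100
  y <- rnorm(n)
  fe <- reml_fit(y, K = G, method = "eigen")
  fd <- reml_fit(y, K = G, method = "dense")
  expect_equal(fe$logLik, fd$logLik, tolerance = 1e-6)
  expect_equal(fe$vc, fd$vc, tolerance = 1e-3)
})

test_that("REML recovers a simulated heritability (parameter recovery)", {
  ## moderate-size recovery check; the full-strength version is in the
  ## acceptance suite
  set.seed(36)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    p <- simulate_panel(200, genome_map(400, spacing_bp = 5e4), seed = 400 + r)
    G <- grm(p)
    e <- eigen(G, symmetric = TRUE)
    g <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(200)) * sqrt(0.6)
    y <- as.vector(g) + rnorm(200, 0, sqrt(0.4))
    fit <- reml_fit(y, K = G)
    h2 <- fit$vc[1] / sum(fit$vc)
    se <- sqrt(drop(t(c(fit$vc[2], -fit$vc[1]) / sum(fit$vc)^2) %*%
                      fit$vc_cov %*%
                      (c(fit$vc[2], -fit$vc[1]) / sum(fit$vc)^2)))
    if (abs(h2 - 0.6) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
})

test_that("LRT arithmetic, clamping and p-value conversion", {
  expect_equal(as.numeric(lrt(list(logLik = -92.5, converged = TRUE),
                              list(logLik = -100, converged = TRUE))), 15)
  same <- list(logLik = -50, converged = TRUE)
  expect_equal(as.numeric(lrt(same, same)), 0)
  neg <- lrt(list(logLik = -50.01, converged = TRUE),
             list(logLik = -50, converged = TRUE))
  expect_equal(as.numeric(neg), 0)
  expect_equal(attr(neg, "raw"), -0.02, tolerance = 1e-12)
  expect_warning(lrt(list(logLik = -5, converged = FALSE),
                     list(logLik = -6, converged = TRUE)), "unconverged")

  expect_equal(lrt_to_p(0), 1)
  expect_equal(lrt_to_p(3.841459), 0.05, tolerance = 1e-6)
  expect_equal(stats::qchisq(0.05, 1, lower.tail = FALSE), 3.841459,
               tolerance = 1e-6)
  expect_equal(p_to_neglog10(0.01), 2)
  expect_error(lrt_to_p(-1), "non-negative")
  expect_error(p_to_neglog10(0), "p-values")
})

test_that("null LRT values are stochastically dominated by chi-squared(1)", {
  ## no-QTL simulation: the locus variance sits on the boundary under the
  ## null, so the LRT distribution is a mixture of a point mass at 0 and
  ## (at most) chi-squared(1). Exceedance of the chi-squared(1) 90%
  ## quantile should therefore stay at or below 10% -- the 50:50 mixture
  ## predicts ~5%. Midpoints within a replicate are correlated, so the
  ## Monte-Carlo margin is taken between replicates.
  p <- make_test_panel(n = 50, snps = c(150, 100), seed = 38)
  set.seed(38)
  n_rep <- 10L
  exceed <- zero_frac <- numeric(n_rep)
  crit <- stats::qchisq(0.9, 1)
  for (r in seq_len(n_rep)) {
    ph <- simulate_phenotypes(p, truth_record(qtl_variance = 0, h2_poly = 0,
                                              age_variance = 0, seed = 380 + r))
    sc <- cldla_scan(p, ph$liability, window_size = 20, step = 15,
                     chroms = "1")
    exceed[r] <- mean(sc$lrt > crit)
    zero_frac[r] <- mean(sc$lrt < 1e-6)
  }
  margin <- 3 * stats::sd(exceed) / sqrt(n_rep)
  expect_lte(mean(exceed), 0.10 + max(margin, 0.02))
  ## a substantial point mass at zero, as the boundary mixture predicts
  expect_gte(mean(zero_frac), 0.25)
})

test_that("GREML estimates h2 with delta-method SE and permutation null", {
  set.seed(40)
  n <- 150
  p <- simulate_panel(n, genome_map(300, spacing_bp = 5e4), seed = 40)
  G <- grm(p)
  e <- eigen(G, symmetric = TRUE)
  g <- e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n)) * sqrt(0.65)
  y <- as.vector(g) + rnorm(n, 0, sqrt(0.35))
  gh <- greml_h2(y, G = G, n_permutations = 30, seed = 1)
  expect_lt(abs(gh$h2 - 0.65), 3 * gh$se)
  ## permutation destroys the signal
  expect_lte(mean(gh$permuted), 0.15)
  expect_lt(gh$p_empirical, 0.1)

  ## scaling invariance of h2
  gh2 <- greml_h2(10 * y, G = G, n_permutations = 0)
  expect_equal(gh2$h2, gh$h2, tolerance = 1e-6)
})

test_that("degenerate exact-fit input is flagged, not an error", {
  set.seed(42)
  n <- 40
  G <- tcrossprod(matrix(rnorm(n * 60), n)) / 60
  X <- cbind(1, rnorm(n))
  y <- as.vector(X %*% c(1, 2))  # no noise at all
  fit <- expect_no_error(reml_fit(y, X, K = G))
  expect_true(any(fit$boundary) || !fit$converged)
})

test_that("reml_fit methods behave like a classed model object", {
  set.seed(44)
  n <- 60
  G <- tcrossprod(matrix(rnorm(n * 90), n)) / 90
  X <- cbind(1, age = runif(n, 700, 3000))
  y <- rnorm(n) + 0.001 * X[, 2]
  fit <- reml_fit(y, X, K = list(genomic = G))
  expect_s3_class(fit, "reml_fit")
  expect_named(coef(fit), c("", "age"), ignore.order = TRUE)
  expect_length(residuals(fit), n)
  expect_length(residuals(fit, type = "conditional"), n)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_s3_class(logLik(fit), "logLik")
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(n, 3L))
  expect_output(print(fit), "REML")
  expect_output(print(summary(fit)), "Variance components")
  expect_length(random_effects(fit)$genomic, n)
  ## marginal residuals + fitted reconstruct y
  expect_equal(fitted(fit) + residuals(fit), y)
})

test_that("input validation catches malformed model specifications", {
  y <- rnorm(20)
  expect_error(reml_fit(y, K = diag(19)), "n x n")
  expect_error(reml_fit(y, X = cbind(1, 1:20, 2 * (1:20)), K = diag(20)),
               "full column rank")
  expect_error(reml_fit(rep(1, 20), K = diag(20)), "constant")
})
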