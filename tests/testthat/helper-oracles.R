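## Independent oracles used across the test suite. These deliberately use
## naive direct formulas (dense algebra, double loops, enumeration) and are
## kept separate from the package's computational paths.

## Restricted log-likelihood evaluated directly from the projection-matrix
## definition: logL = -1/2 [(n-p) log 2pi + log|V| + log|X'Vi X| + y'Py].
oracle_reml_loglik <- function(y, X, Ks, theta) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Ks)) V <- V + theta[i] * Ks[[i]]
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

## GRM by explicit double summation over individuals and SNPs.
oracle_grm <- function(geno) {
  n <- nrow(geno)
  p <- colMeans(geno) / 2
  keep <- p > 0 & p < 1
  geno <- geno[, keep, drop = FALSE]
  p <- p[keep]
  m <- ncol(geno)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(m)) {
        s <- s + (geno[i, k] - 2 * p[k]) * (geno[j, k] - 2 * p[k]) /
          (2 * p[k] * (1 - p[k]))
      }
      G[i, j] <- s / m
    }
  }
  G
}

## Haplotype-pair IBD probability evaluated directly from the documented
## coalescent approximation, one pair at a time.
oracle_ibd_pair <- function(hap1, hap2, pos, half, h, ne, t_gen) {
  w <- length(pos)
  mid <- (pos[half] + pos[half + 1]) / 2
  agree <- hap1 == hap2
  run <- function(ord) {
    L <- 0
    for (k in ord) {
      if (!agree[k]) break
      L <- L + 1
    }
    L
  }
  L <- run(half:1)
  R <- run((half + 1):w)
  d_left <- (mid - pos[half:1]) * 1e-8
  d_right <- (pos[(half + 1):w] - mid) * 1e-8
  side_lik <- function(L, d, t) {
    D <- c(0, d)
    half_side <- length(d)
    tot <- 0
    for (k in 0:min(L, half_side - 1)) {
      tot <- tot + (exp(-2 * t * D[k + 1]) - exp(-2 * t * D[k + 2])) *
        h^(L - k)
    }
    if (L < half_side) tot * (1 - h) else tot + exp(-2 * t * D[half_side + 1])
  }
  side_null <- function(L, half_side) {
    if (L < half_side) h^L * (1 - h) else h^L
  }
  num <- 0
  for (t in 1:t_gen) {
    pt <- (1 / (2 * ne)) * (1 - 1 / (2 * ne))^(t - 1)
    num <- num + pt * side_lik(L, d_left, t) * side_lik(R, d_right, t)
  }
  pi0 <- (1 - 1 / (2 * ne))^t_gen
  den <- num + pi0 * side_null(L, half) * side_null(R, half)
  num / den
}

## All pairwise r^2 between SNP columns of a haplotype matrix.
oracle_r2 <- function(H, j1, j2) {
  suppressWarnings(stats::cor(H[, j1], H[, j2])^2)
}

## Moving average of k consecutive values (brute-force windows).
oracle_moving_average <- function(x, k) {
  m <- length(x) - k + 1
  vapply(seq_len(m), function(j) mean(x[j:(j + k - 1)]), numeric(1))
}

## Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(xs, r1, r2, c1)
  sum(pr[pr <= stats::dhyper(x_obs, r1, r2, c1) * (1 + 1e-7)])
}

## Small simulated mapping dataset shared by several tests.
make_test_panel <- function(n = 60, snps = c(300, 200), seed = 42) {
  simulate_panel(n, genome_map(snps), seed = seed)
}

make_survey_table <- function(counts = c(265, 115, 259, 109, 127, 10)) {
  data.frame(
    id = sprintf("a%03d", seq_len(sum(counts))),
    category = rep(survey_categories, counts),
    sex = "female", age_days = 1000, polled_genotype = "PF/p",
    stringsAsFactors = FALSE)
}
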