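test_that("GRM matches the direct-summation oracle and handles duplicates", {
  set.seed(10)
  geno <- matrix(rbinom(5 * 50, 2, runif(50, 0.1, 0.9)), 5, 50, byrow = FALSE)
  G <- grm(geno)
  expect_equal(unclass(G), oracle_grm(geno), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(G)))

  ## duplicate individuals: off-diagonal equals the shared diagonal value
  geno2 <- rbind(geno[1, ], geno[1, ], geno[2:4, ])
  G2 <- grm(geno2)
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-12)
  expect_equal(G2[2, 2], G2[1, 1], tolerance = 1e-12)
})

test_that("LOCO GRM equals GRM on the physically reduced panel", {
  p <- make_test_panel(n = 25, snps = c(60, 80), seed = 12)
  Gl <- grm(p, exclude_chrom = "1")
  p2 <- subset_chrom(p, "1", invert = TRUE)
  Gr <- grm(p2)
  expect_equal(unclass(Gl), unclass(Gr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(Gl, "kind"), "LOCO_GRM")
  expect_error(grm(subset_chrom(p, "1"), exclude_chrom = "1"), "no SNPs")
})

test_that("GRM is invariant to SNP order and allele-label flips", {
  set.seed(14)
  geno <- matrix(rbinom(8 * 40, 2, runif(40, 0.2, 0.8)), 8, 40)
  G <- grm(geno)
  perm <- sample(40)
  expect_equal(unclass(grm(geno[, perm])), unclass(G), tolerance = 1e-12,
               ignore_attr = TRUE)
  flip <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  geno_f <- geno
  geno_f[, flip] <- 2 - geno_f[, flip]
  expect_equal(unclass(grm(geno_f)), unclass(G), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## realistic panels have mean diagonal near 1
  expect_equal(mean(diag(G)), 1, tolerance = 0.2)
})

test_that("window IBD matches the per-pair formula oracle", {
  p <- make_test_panel(n = 3, snps = c(30), seed = 16)
  ibd <- window_ibd(p, "1", 15, 4, ne = 100, t_gen = 10)
  idx <- p$map$chrom == "1"
  cols <- which(idx)[14:17]
  H <- p$haplotypes[, cols]
  pos <- p$map$pos[cols]
  f <- colMeans(H)
  h <- mean(f^2 + (1 - f)^2)
  for (a in 1:6) {
    for (b in 1:6) {
      want <- if (a == b) 1 else {
        oracle_ibd_pair(H[a, ], H[b, ], pos, 2, h, 100, 10)
      }
      expect_equal(ibd[a, b], want, tolerance = 1e-12)
    }
  }
})

test_that("window IBD endpoints behave as the model dictates", {
  set.seed(18)
  w <- 20
  p <- simulate_panel(30, genome_map(w + 10), seed = 18)
  ## force haplotype 2 identical to haplotype 1, and haplotype 3 to differ
  ## at both SNPs flanking the midpoint
  H <- p$haplotypes
  H[2, ] <- H[1, ]
  H[3, ] <- H[1, ]
  H[3, 15] <- 1L - H[3, 15]
  H[3, 16] <- 1L - H[3, 16]
  p2 <- haplotype_panel(H, p$map, p$ids)
  ibd <- window_ibd(p2, "1", 15, w)
  off <- ibd[upper.tri(ibd)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(ibd[1, 2], max(off))      # fully identical window: plateau
  expect_lte(ibd[1, 3], 0.05)            # discordant at both flanking SNPs
  expect_true(isSymmetric(ibd))
})

test_that("IBD probability is monotone in flanking agreement runs", {
  d <- rep(5e-5, 10) * (1:10)
  tab <- scurmap:::.ibd_table(d, d, h = 0.65, ne = 100, t_gen = 10)
  for (r in seq_len(nrow(tab))) {
    expect_true(all(diff(tab[r, ]) >= -1e-12))
    expect_true(all(diff(tab[, r]) >= -1e-12))
  }
  expect_true(all(tab >= 0 & tab <= 1))
})

test_that("window bounds are enforced with a classed condition", {
  p <- make_test_panel(n = 5, snps = c(30), seed = 20)
  expect_error(window_ibd(p, "1", 3, 20), class = "scurmap_window_oob")
  expect_error(window_ibd(p, "1", 29, 20), class = "scurmap_window_oob")
  expect_silent(window_ibd(p, "1", 10, 20))
  expect_error(window_ibd(p, "1", 10, 15), "even")
})

test_that("D_RM conversion implements the four-term average", {
  ## degenerate limits
  n <- 3
  P0 <- diag(1, 2 * n)
  expect_equal(unclass(drm_from_ibd(P0 * 0 + diag(0, 2 * n))),
               diag(1, n), ignore_attr = TRUE)
  P1 <- matrix(1, 2 * n, 2 * n)
  D1 <- drm_from_ibd(P1)
  expect_true(all(abs(D1 - 2) < 1e-12))

  ## random valid IBD matrix vs direct evaluation, n = 4
  set.seed(22)
  n <- 4
  B <- matrix(runif((2 * n)^2), 2 * n)
  P <- (B + t(B)) / 2
  diag(P) <- 1
  D <- drm_from_ibd(P)
  for (i in 1:n) {
    for (j in 1:n) {
      a1 <- 2 * i - 1; a2 <- 2 * i; b1 <- 2 * j - 1; b2 <- 2 * j
      want <- if (i == j) 1 + P[a1, a2] else {
        0.5 * (P[a1, b1] + P[a1, b2] + P[a2, b1] + P[a2, b2])
      }
      expect_equal(D[i, j], want, tolerance = 1e-12)
    }
  }
  expect_error(drm_from_ibd(P, diplotypes = cbind(1:4, 9:12)), "valid")
})

test_that("unique diplotypes give an identity D_RM", {
  ## construct windows where every individual's two haplotypes are unique
  ## and all mutually distinct: IBD off-diagonals ~ 0
  set.seed(24)
  w <- 20
  n <- 8
  H <- matrix(rbinom(2 * n * w, 1, 0.5), 2 * n, w)
  while (anyDuplicated(apply(H, 1, paste, collapse = ""))) {
    H <- matrix(rbinom(2 * n * w, 1, 0.5), 2 * n, w)
  }
  map <- genome_map(w)
  p <- haplotype_panel(H, map, sprintf("i%d", 1:n))
  D <- drm_from_ibd(window_ibd(p, "1", w / 2, w))
  expect_equal(unclass(D), diag(1, n), tolerance = 0.1, ignore_attr = TRUE)
})

test_that("PSD repair bends singular matrices and returns a true inverse", {
  r <- repair_psd(diag(3))
  expect_false(r$bent)
  expect_equal(r$matrix, diag(3))
  expect_equal(r$inverse, diag(3))

  ones <- matrix(1, 3, 3)
  r2 <- repair_psd(ones)
  expect_true(r2$bent)
  expect_gte(min(eigen(r2$matrix, symmetric = TRUE)$values), 1e-8)
  expect_equal(r2$matrix %*% r2$inverse, diag(3), tolerance = 1e-8)

  ## PSD input: output differs only on the diagonal
  set.seed(26)
  A <- crossprod(matrix(rnorm(12), 4, 3))  # rank 3, 3x3? make 4x4 rank 3
  B <- tcrossprod(matrix(rnorm(12), 4, 3))
  r3 <- repair_psd(B)
  offdiag <- function(m) m[row(m) != col(m)]
  expect_equal(offdiag(r3$matrix), offdiag(B), tolerance = 1e-12)
  expect_error(repair_psd(matrix(1:4, 2)), "symmetric")
})
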