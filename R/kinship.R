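#' Genomic relationship matrix (optionally leave-one-chromosome-out)
#'
#' Frequency-standardized additive relationship matrix
#' `G = W W' / m`, where column `j` of `W` is
#' `(x_j - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the observed allele
#' frequency -- the standard cross-product construction used for genomic
#' evaluation. Monomorphic SNPs carry no information and are skipped. With
#' `exclude_chrom` set, SNPs on that chromosome are omitted, giving the
#' leave-one-chromosome-out (LOCO) matrix used to avoid proximal
#' contamination in genome scans.
#'
#' @param x a [haplotype_panel()] or an `n x m` dosage matrix (0/1/2).
#' @param exclude_chrom optional chromosome label to leave out (requires a
#'   panel or a `map`).
#' @param map genome map, required for `exclude_chrom` with matrix input.
#' @return symmetric `n x n` matrix with attributes `kind` (`"GRM"` or
#'   `"LOCO_GRM"`), `m_snps` and `exclude_chrom`.
#' @examples
#' panel <- simulate_panel(10, genome_map(c(40, 40)), seed = 3)
#' G <- grm(panel)
#' G_loco <- grm(panel, exclude_chrom = "1")
#' @export
grm <- function(x, exclude_chrom = NULL, map = NULL) {
  if (inherits(x, "haplotype_panel")) {
    map <- x$map
    geno <- dosages(x)
  } else {
    geno <- as.matrix(x)
  }
  if (nrow(geno) < 2L) stop("need at least 2 individuals", call. = FALSE)
  keep <- rep(TRUE, ncol(geno))
  if (!is.null(exclude_chrom)) {
    if (is.null(map)) stop("'exclude_chrom' requires a genome map", call. = FALSE)
    keep <- map$chrom != exclude_chrom
  }
  p <- colMeans(geno) / 2
  keep <- keep & p > 0 & p < 1
  if (!any(keep)) stop("no SNPs left for the relationship matrix", call. = FALSE)
  p <- p[keep]
  w <- sweep(geno[, keep, drop = FALSE], 2, 2 * p)
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(w) / sum(keep)
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "kind") <- if (is.null(exclude_chrom)) "GRM" else "LOCO_GRM"
  attr(G, "m_snps") <- sum(keep)
  attr(G, "exclude_chrom") <- exclude_chrom
  G
}

#' Haplotype IBD probabilities at a SNP-interval midpoint
#'
#' Estimates, for every pair of haplotypes in the panel, the probability
#' that they are identical by descent (IBD) at the midpoint of SNP interval
#' `interval` on chromosome `chrom`, from the `window_size` surrounding
#' SNPs (`window_size/2` on each side of the interval). The estimator is a
#' deterministic coalescent approximation: two haplotypes coalesce within
#' `t_gen` generations with geometric rate `1/(2 ne)`; given coalescence at
#' generation `t`, the IBD segment around the midpoint extends left and
#' right by independent exponential genetic distances with rate `2 t`
#' (1 cM per Mb); markers inside the segment agree, markers outside agree
#' identically-by-state with probability equal to the mean window
#' homozygosity. Observed agreement runs on the two sides (truncated at the
#' first discordant marker) are combined by Bayes' rule against the
#' no-recent-coalescence alternative. The result depends only on the two
#' run lengths, so the whole matrix is filled from a small lookup table.
#'
#' Longer agreement runs never decrease the probability; two haplotypes
#' identical across the whole window attain the matrix's plateau value,
#' and haplotypes differing at both SNPs flanking the midpoint get a
#' probability near 0.
#'
#' @param panel a [haplotype_panel()].
#' @param chrom chromosome label.
#' @param interval SNP-interval index `i` (midpoint between SNPs `i` and
#'   `i+1` of that chromosome, 1-based).
#' @param window_size even window size in SNPs (20, 40, 80, 160 are the
#'   conventional choices; any even value >= 2 is accepted).
#' @param ne effective population size of the coalescent approximation.
#' @param t_gen maximum age (generations) of a haplotype considered IBD.
#' @return symmetric `2n x 2n` matrix of IBD probabilities (unit diagonal),
#'   with attributes `chrom`, `interval`, `midpoint_bp`, `window_snps`
#'   (first/last SNP index within chromosome) and `window_bp`.
#'   A window extending beyond the chromosome is an error of class
#'   `scurmap_window_oob` (genome scans skip such midpoints).
#' @export
window_ibd <- function(panel, chrom, interval, window_size = 40,
                       ne = 100, t_gen = 10) {
  if (window_size < 2 || window_size %% 2 != 0) {
    stop("'window_size' must be even and >= 2", call. = FALSE)
  }
  idx <- .chrom_index(panel$map, chrom)
  mc <- length(idx)
  half <- window_size / 2
  if (interval < 1 || interval >= mc) {
    stop("'interval' must lie in [1, ", mc - 1, "]", call. = FALSE)
  }
  first <- interval - half + 1L
  last <- interval + half
  if (first < 1L || last > mc) {
    cond <- structure(class = c("scurmap_window_oob", "error", "condition"),
                      list(message = sprintf(
                        "window of %d SNPs around interval %d exceeds chromosome %s",
                        window_size, interval, chrom), call = NULL))
    stop(cond)
  }
  cols <- idx[first:last]
  H <- panel$haplotypes[, cols, drop = FALSE]
  pos <- panel$map$pos[cols]
  mid_bp <- floor((pos[half] + pos[half + 1L]) / 2)

  ## genetic distances (Morgan, 1 cM/Mb) from the midpoint outward
  mid_exact <- (pos[half] + pos[half + 1L]) / 2
  d_left <- (mid_exact - pos[half:1L]) * 1e-8
  d_right <- (pos[(half + 1L):window_size] - mid_exact) * 1e-8

  f <- colMeans(H)
  h <- mean(f^2 + (1 - f)^2)

  tab <- .ibd_table(d_left, d_right, h, ne, t_gen)

  ## run lengths are computed on the unique window haplotypes only and then
  ## expanded -- window haplotype diversity is far below 2n
  nh <- nrow(H)
  key <- apply(H, 1L, paste, collapse = "")
  grp <- match(key, unique(key))
  Hu <- H[!duplicated(key), , drop = FALSE]
  nu <- nrow(Hu)
  runlen <- function(ord) {
    L <- matrix(0, nu, nu)
    A <- matrix(1, nu, nu)
    for (k in ord) {
      hk <- Hu[, k]
      A <- A * tcrossprod(cbind(hk, 1 - hk))  # IBS agreement at marker k
      L <- L + A
    }
    L
  }
  Lr <- runlen(half:1L)                  # left side: SNP half is adjacent
  Rr <- runlen((half + 1L):window_size)  # right side
  Pu <- matrix(tab[cbind(as.vector(Lr) + 1L, as.vector(Rr) + 1L)], nu, nu)
  P <- Pu[grp, grp, drop = FALSE]
  diag(P) <- 1
  dimnames(P) <- list(rownames(panel$haplotypes), rownames(panel$haplotypes))
  attr(P, "chrom") <- chrom
  attr(P, "interval") <- as.integer(interval)
  attr(P, "midpoint_bp") <- mid_bp
  attr(P, "window_snps") <- c(first, last)
  attr(P, "window_bp") <- c(pos[1L], pos[window_size])
  attr(P, "ne") <- ne
  attr(P, "t_gen") <- t_gen
  P
}

## IBD posterior lookup table over (left run, right run) in 0..half.
## d_left/d_right: distances (Morgan) from midpoint to the 1st, 2nd, ...
## marker on each side; h: mean homozygosity; geometric coalescence prior.
.ibd_table <- function(d_left, d_right, h, ne, t_gen) {
  t <- seq_len(t_gen)
  pt <- (1 / (2 * ne)) * (1 - 1 / (2 * ne))^(t - 1)
  pi0 <- 1 - sum(pt)

  side <- function(d) {
    half <- length(d)
    D <- c(0, d)
    ## S[L+1, t]: likelihood of an agreement run of L given coalescence at t
    S <- matrix(0, half + 1L, t_gen)
    E <- exp(-2 * outer(D, t))           # (half+1) x t_gen
    for (L in 0:half) {
      ks <- 0:min(L, half - 1L)
      hseg <- h^(L - ks)
      inner <- colSums(hseg * (E[ks + 1L, , drop = FALSE] -
                                 E[ks + 2L, , drop = FALSE]))
      if (L < half) {
        S[L + 1L, ] <- inner * (1 - h)   # run ended by a discordant marker
      } else {
        S[L + 1L, ] <- E[half + 1L, ] + inner  # run reaches the window edge
      }
    }
    null <- h^(0:half)
    null[seq_len(half)] <- null[seq_len(half)] * (1 - h)
    list(S = S, null = null)
  }
  ls <- side(d_left)
  rs <- side(d_right)
  num <- ls$S %*% (pt * t(rs$S))
  den <- num + pi0 * outer(ls$null, rs$null)
  num / den
}

#' Diplotype relationship matrix from haplotype IBD probabilities
#'
#' Converts a `2n x 2n` haplotype IBD matrix at a putative QTL into the
#' individual-level diplotype relationship matrix (D_RM) used as the
#' covariance of the locus-specific random effect: for individuals `i`
#' and `j` with haplotypes `(i1, i2)` and `(j1, j2)`,
#' `d_ij = (P(i1,j1) + P(i1,j2) + P(i2,j1) + P(i2,j2)) / 2` and
#' `d_ii = 1 + P(i1, i2)`.
#'
#' @param ibd `2n x 2n` IBD probability matrix (e.g. from [window_ibd()]).
#' @param diplotypes optional 2-column matrix mapping each individual to its
#'   two haplotype rows; defaults to consecutive pairs (1,2), (3,4), ...
#' @return symmetric `n x n` matrix with attribute `kind = "DRM"`; locus
#'   attributes of `ibd` are carried over.
#' @export
drm_from_ibd <- function(ibd, diplotypes = NULL) {
  nh <- nrow(ibd)
  if (nh != ncol(ibd)) stop("'ibd' must be square", call. = FALSE)
  if (is.null(diplotypes)) {
    if (nh %% 2 != 0) stop("odd number of haplotypes needs 'diplotypes'",
                           call. = FALSE)
    diplotypes <- cbind(seq(1L, nh, by = 2L), seq(2L, nh, by = 2L))
  }
  diplotypes <- as.matrix(diplotypes)
  if (ncol(diplotypes) != 2L || any(diplotypes < 1L) || any(diplotypes > nh)) {
    stop("'diplotypes' must map each individual to 2 valid haplotype rows",
         call. = FALSE)
  }
  a <- diplotypes[, 1L]; b <- diplotypes[, 2L]
  D <- 0.5 * (ibd[a, a, drop = FALSE] + ibd[a, b, drop = FALSE] +
                ibd[b, a, drop = FALSE] + ibd[b, b, drop = FALSE])
  diag(D) <- 1 + ibd[cbind(a, b)]
  D <- (D + t(D)) / 2
  for (at in c("chrom", "interval", "midpoint_bp", "window_snps", "window_bp")) {
    attr(D, at) <- attr(ibd, at)
  }
  attr(D, "kind") <- "DRM"
  D
}

#' Repair a relationship matrix to positive definiteness
#'
#' Diplotype relationship matrices built from near-duplicate diplotypes are
#' often singular. If the smallest eigenvalue of the (symmetric) input is
#' below `tol`, a ridge is added to the diagonal -- the smallest multiple of
#' `ridge` that lifts the minimum eigenvalue to at least `tol` -- and the
#' inverse is computed from the eigendecomposition.
#'
#' @param m symmetric matrix.
#' @param ridge ridge unit; default `1e-6 * mean(diag(m))`.
#' @param tol eigenvalue threshold below which bending is applied.
#' @return list with `matrix` (possibly bent), `inverse`, `bent` (logical)
#'   and `lambda` (total ridge added).
#' @export
repair_psd <- function(m, ridge = NULL, tol = 1e-8) {
  if (!isSymmetric(unclass(m), tol = 1e-8)) {
    stop("'m' must be symmetric", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (is.null(ridge)) ridge <- 1e-6 * mean(diag(m))
  if (ridge <= 0) ridge <- 1e-8
  e <- eigen(m, symmetric = TRUE)
  emin <- min(e$values)
  bent <- emin < tol
  lambda <- 0
  if (bent) {
    lambda <- ridge * ceiling((tol - emin) / ridge)
    m <- m + diag(lambda, nrow(m))
  }
  vals <- e$values + lambda
  inv <- e$vectors %*% (t(e$vectors) / vals)
  inv <- (inv + t(inv)) / 2
  list(matrix = m, inverse = inv, bent = bent, lambda = lambda)
}
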