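#' Phased haplotype panels
#'
#' A `haplotype_panel` holds phased biallelic haplotypes: a `(2n x m)` 0/1
#' integer matrix whose rows `2i-1` and `2i` are the two haplotypes of
#' individual `i`, together with a genome map (see [genome_map()]) and
#' individual ids. It stands in for a phased SNP-chip panel.
#'
#' @param haplotypes 0/1 matrix with `2 * length(ids)` rows.
#' @param map genome map data frame with one row per column of `haplotypes`.
#' @param ids character vector of individual ids.
#' @return an object of class `haplotype_panel`.
#' @seealso [simulate_panel()]
#' @export
haplotype_panel <- function(haplotypes, map, ids) {
  haplotypes <- as.matrix(haplotypes)
  .check_map(map)
  if (nrow(haplotypes) != 2L * length(ids)) {
    stop("'haplotypes' must have exactly 2 rows per individual",
         call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(map)) {
    stop("haplotype length (", ncol(haplotypes), ") does not match map (",
         nrow(map), " SNPs)", call. = FALSE)
  }
  if (!all(haplotypes %in% c(0L, 1L))) {
    stop("haplotype alleles must be 0/1", call. = FALSE)
  }
  storage.mode(haplotypes) <- "integer"
  rownames(haplotypes) <- paste0(rep(ids, each = 2L), "_", c(1L, 2L))
  colnames(haplotypes) <- map$snp
  structure(list(ids = as.character(ids), haplotypes = haplotypes, map = map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("Phased haplotype panel\n")
  cat("  individuals:", length(x$ids), "\n")
  cat("  SNPs:       ", nrow(x$map), "on", length(unique(x$map$chrom)),
      "chromosome(s)\n")
  maf <- panel_maf(x)
  cat("  MAF:         min", format(min(maf), digits = 3),
      " median", format(stats::median(maf), digits = 3), "\n")
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel a `haplotype_panel`.
#' @return an integer count.
#' @export
n_individuals <- function(panel) length(panel$ids)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) nrow(panel$map)

#' Genotype dosages of a phased panel
#'
#' Collapses the two haplotypes of each individual into an allele-1 dosage
#' matrix (`n x m`, values 0/1/2).
#'
#' @param panel a `haplotype_panel`.
#' @return integer matrix with one row per individual.
#' @export
dosages <- function(panel) {
  h <- panel$haplotypes
  odd <- seq(1L, nrow(h), by = 2L)
  d <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(d) <- panel$ids
  d
}

#' Per-SNP minor allele frequency of a panel
#' @param panel a `haplotype_panel`.
#' @return numeric vector in `[0, 0.5]`, one entry per SNP.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$haplotypes)
  pmin(f, 1 - f)
}

#' Simulate a phased haplotype panel with decaying linkage disequilibrium
#'
#' Haplotypes are mosaics of `n_founders` hidden founder haplotypes: each
#' sampled haplotype starts from a random founder and switches founders
#' between adjacent SNPs with probability `min(0.5, distance_bp * ld_decay)`.
#' This produces LD that decays with physical distance while being trivial to
#' generate at any panel size. Founder alleles are drawn per SNP at a random
#' frequency; SNP columns whose realized minor allele frequency falls below
#' `maf_floor` are redrawn (founder alleles only, mosaic kept), so every SNP
#' in the returned panel has MAF at or above the floor.
#'
#' @param n_individuals number of diploid individuals (>= 2).
#' @param map genome map from [genome_map()].
#' @param ld_decay founder-switch probability per bp between adjacent SNPs;
#'   the default 1e-6 gives a ~1% switch probability at 10 kb spacing.
#' @param maf_floor minimum per-SNP minor allele frequency, in (0, 0.5).
#' @param n_founders number of hidden founder haplotypes.
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return a [haplotype_panel()].
#' @examples
#' panel <- simulate_panel(20, genome_map(50), seed = 1)
#' panel
#' @export
simulate_panel <- function(n_individuals, map, ld_decay = 1e-6,
                           maf_floor = 0.05, n_founders = 30, seed = 1) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 2L) {
    stop("'n_individuals' must be at least 2", call. = FALSE)
  }
  if (!is.numeric(maf_floor) || maf_floor <= 0 || maf_floor >= 0.5) {
    stop("'maf_floor' must lie in (0, 0.5)", call. = FALSE)
  }
  if (!is.numeric(ld_decay) || ld_decay < 0) {
    stop("'ld_decay' must be non-negative", call. = FALSE)
  }
  .check_map(map)
  m <- nrow(map)
  nh <- 2L * n_individuals
  set.seed(as.integer(seed))

  ## founder alleles: per-SNP frequency away from the boundaries so the
  ## realized panel frequency rarely violates the floor
  pf <- stats::runif(m, 0.5 + maf_floor, 0.95 - maf_floor / 2)
  pf <- ifelse(stats::runif(m) < 0.5, pf, 1 - pf)
  founders <- matrix(stats::rbinom(n_founders * m, 1L, rep(pf, each = n_founders)),
                     nrow = n_founders, ncol = m)

  ## switch probabilities between adjacent SNPs, zero across chromosome breaks
  same_chrom <- map$chrom[-1L] == map$chrom[-m]
  r <- pmin(0.5, diff(map$pos) * ld_decay)
  r[!same_chrom] <- 1  # independent founder start on a new chromosome

  ## founder path per haplotype, vectorised over SNPs
  path <- matrix(0L, nrow = nh, ncol = m)
  for (k in seq_len(nh)) {
    sw <- c(TRUE, stats::runif(m - 1L) < r)
    grp <- cumsum(sw)
    fid <- sample.int(n_founders, max(grp), replace = TRUE)
    path[k, ] <- fid[grp]
  }
  H <- matrix(founders[cbind(as.vector(path), rep(seq_len(m), each = nh))],
              nrow = nh, ncol = m)

  ## enforce the MAF floor by redrawing founder alleles of offending SNPs
  for (attempt in seq_len(25L)) {
    f <- colMeans(H)
    bad <- which(pmin(f, 1 - f) < maf_floor)
    if (length(bad) == 0L) break
    for (j in bad) {
      pj <- stats::runif(1, 0.35, 0.65)
      founders[, j] <- stats::rbinom(n_founders, 1L, pj)
      H[, j] <- founders[cbind(path[, j], rep(j, nh))]
    }
  }
  f <- colMeans(H)
  if (any(pmin(f, 1 - f) < maf_floor)) {
    stop("could not satisfy 'maf_floor' after 25 redraws; ",
         "lower the floor or increase the panel size", call. = FALSE)
  }

  ids <- sprintf("id%04d", seq_len(n_individuals))
  haplotype_panel(H, map, ids)
}

#' Extract one chromosome (or its complement) from a panel
#' @param panel a `haplotype_panel`.
#' @param chrom chromosome label.
#' @param invert if `TRUE`, drop the chromosome instead of keeping it.
#' @return a `haplotype_panel` restricted to the selected SNPs.
#' @export
subset_chrom <- function(panel, chrom, invert = FALSE) {
  keep <- panel$map$chrom == chrom
  if (invert) keep <- !keep
  if (!any(keep)) stop("no SNPs left after subsetting", call. = FALSE)
  haplotype_panel(panel$haplotypes[, keep, drop = FALSE],
                  panel$map[keep, , drop = FALSE], panel$ids)
}
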