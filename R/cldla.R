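## Genome scan by combined linkage-disequilibrium and linkage analysis:
## at each SNP-interval midpoint, H1 fits polygenic (LOCO-G) + locus (D_RM)
## + residual, H0 fits polygenic + residual, and the evidence is
## LRT = -2 (logL(H0) - logL(H1)).

## Fit H1 in the rotated basis, with an escalating diagonal ridge on the
## D_RM if the covariance loses positive definiteness; returns the core
## fit plus a 'bent' flag. Adding a ridge to D is equivalent in the
## rotated basis because U is orthogonal.
.fit_h1 <- function(su, Dst, vtot, init) {
  bent <- FALSE
  lam <- 1e-6 * mean(diag(Dst))
  for (attempt in 0:6) {
    core <- tryCatch(
      .reml_core_rot(su, Dst, vtot, init = init),
      error = function(e) NULL)
    if (!is.null(core)) return(c(core, list(bent = bent)))
    Dst[su$dix] <- Dst[su$dix] + lam * 10^attempt
    bent <- TRUE
  }
  NULL
}

#' Combined LD and linkage (cLDLA) genome scan
#'
#' Treats every SNP-interval midpoint as a putative causal locus. For each
#' chromosome a leave-one-chromosome-out genomic relationship matrix is
#' built and the null model (polygenic + residual) is fitted once -- its
#' likelihood does not depend on the midpoint. Then, at each admissible
#' midpoint, haplotype IBD probabilities are estimated from the
#' `window_size` surrounding SNPs ([window_ibd()]), converted to a
#' diplotype relationship matrix ([drm_from_ibd()]), and the alternative
#' model with the locus-specific random effect is fitted; the midpoint's
#' evidence is the likelihood-ratio test between the two. Midpoints whose
#' window would extend beyond the chromosome are skipped, so all scanned
#' midpoints share one window size. Fits are warm-started from the
#' neighbouring midpoint. Per-midpoint numerical failures are recorded in
#' the `flag` column and the scan continues.
#'
#' @param panel a [haplotype_panel()].
#' @param trait coded trait ([code_trait()] object or numeric vector).
#' @param covariates optional matrix/data frame of fixed covariates (an
#'   intercept is always included); age at phenotyping is the conventional
#'   covariate.
#' @param window_size even sliding-window size in SNPs (20/40/80/160 are
#'   the conventional choices).
#' @param step evaluate every `step`-th admissible midpoint (default 1 =
#'   all; larger values give a cheaper coarse scan).
#' @param chroms chromosomes to scan (default all).
#' @param ne,t_gen IBD model parameters, see [window_ibd()].
#' @param loco build the polygenic matrix excluding the scanned chromosome
#'   (default). Set `FALSE` to use the full-panel matrix -- required for
#'   single-chromosome panels, where leaving the chromosome out would leave
#'   no SNPs.
#' @param verbose print per-chromosome progress.
#' @return object of class `cldla_scan`: a data frame with one row per
#'   scanned midpoint (`chrom`, `interval`, `midpoint_bp`, `win_start_bp`,
#'   `win_end_bp`, `lrt`, `converged_h0`, `converged_h1`, `bent`), with the
#'   per-chromosome H0 fits and scan parameters as attributes.
#' @seealso [permutation_thresholds()], [significant_regions()]
#' @export
cldla_scan <- function(panel, trait, covariates = NULL, window_size = 40,
                       step = 1, chroms = NULL, ne = 100, t_gen = 10,
                       loco = TRUE, verbose = FALSE) {
  y <- if (inherits(trait, "coded_trait")) trait$values else as.numeric(trait)
  coding_id <- if (inherits(trait, "coded_trait")) trait$coding_id else NA_character_
  n <- n_individuals(panel)
  if (length(y) != n) stop("trait length must match the panel", call. = FALSE)
  X <- .design_matrix(covariates, n)
  if (window_size < 2 || window_size %% 2 != 0) {
    stop("'window_size' must be even and >= 2", call. = FALSE)
  }
  step <- max(1L, as.integer(step))
  if (is.null(chroms)) chroms <- unique(panel$map$chrom)

  rows <- list()
  h0_fits <- list()
  for (cc in chroms) {
    mc <- length(.chrom_index(panel$map, cc))
    half <- window_size / 2
    mids <- seq.int(half, mc - half, by = step)
    if (length(mids) == 0L) next
    G <- grm(panel, exclude_chrom = if (loco) cc else NULL)
    su <- .rot_setup(y, X, G)
    h0 <- .reml_core(y, X, list(G), method = "eigen", eigen_setup = su)
    h0_fits[[as.character(cc)]] <- h0[c("vc", "logL", "converged")]
    if (verbose) {
      message(sprintf("chromosome %s: %d midpoints (H0 logL %.3f)",
                      cc, length(mids), h0$logL))
    }
    vtot <- stats::var(y)
    init <- c(h0$vc[1L], 0.05 * sum(h0$vc), 0.95 * h0$vc[2L])
    for (i in mids) {
      ibd <- window_ibd(panel, cc, i, window_size, ne = ne, t_gen = t_gen)
      D <- drm_from_ibd(ibd)
      Dst <- crossprod(su$U, unclass(D) %*% su$U)
      h1 <- .fit_h1(su, Dst, vtot, init)
      if (is.null(h1)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cc, interval = i,
          midpoint_bp = attr(ibd, "midpoint_bp"),
          win_start_bp = attr(ibd, "window_bp")[1L],
          win_end_bp = attr(ibd, "window_bp")[2L],
          lrt = NA_real_, converged_h0 = h0$converged,
          converged_h1 = FALSE, bent = TRUE, stringsAsFactors = FALSE)
        next
      }
      if (h1$converged) init <- h1$vc  # warm start for the next midpoint
      lr <- max(0, -2 * (h0$logL - h1$logL))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc, interval = i,
        midpoint_bp = attr(ibd, "midpoint_bp"),
        win_start_bp = attr(ibd, "window_bp")[1L],
        win_end_bp = attr(ibd, "window_bp")[2L],
        lrt = lr, converged_h0 = h0$converged,
        converged_h1 = h1$converged, bent = h1$bent,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cldla_scan", "data.frame"),
            window_size = window_size, step = step, coding_id = coding_id,
            ne = ne, t_gen = t_gen, h0 = h0_fits)
}

.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cv <- as.matrix(as.data.frame(covariates))
  if (nrow(cv) != n) stop("covariates must have one row per individual",
                          call. = FALSE)
  X <- cbind("(Intercept)" = 1, cv)
  storage.mode(X) <- "double"
  X
}

#' @export
print.cldla_scan <- function(x, ...) {
  cat("cLDLA scan: ", nrow(x), " midpoints, window size ",
      attr(x, "window_size"), " SNPs, step ", attr(x, "step"), "\n", sep = "")
  ok <- stats::complete.cases(x$lrt)
  cat(sprintf("  max LRT %.2f at %s:%d bp\n",
              max(x$lrt[ok]), x$chrom[ok][which.max(x$lrt[ok])],
              x$midpoint_bp[ok][which.max(x$lrt[ok])]))
  if (any(!x$converged_h1)) {
    cat("  unconverged H1 fits:", sum(!x$converged_h1), "\n")
  }
  invisible(x)
}

#' @export
plot.cldla_scan <- function(x, threshold = NULL, ...) {
  chroms <- unique(x$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(cc) {
    max(x$midpoint_bp[x$chrom == cc])
  }, numeric(1))))
  gx <- x$midpoint_bp + offs[match(x$chrom, chroms)]
  cols <- rep_len(c("grey25", "steelblue"), length(chroms))
  graphics::plot(gx / 1e6, x$lrt, pch = 20, cex = 0.6,
                 col = cols[match(x$chrom, chroms)],
                 xlab = "cumulative position (Mb)", ylab = "LRT", ...)
  if (!is.null(threshold)) {
    th <- if (inherits(threshold, "perm_threshold")) threshold$threshold else threshold
    graphics::abline(h = th, col = "red")
  }
  invisible(x)
}

#' Empirical genome-wide LRT significance threshold by permutation
#'
#' For each chromosome, `n_datasets` phenotype permutations are tested at
#' `n_midpoints` random admissible SNP-interval midpoints each (sampled
#' without replacement within a permuted dataset); the null model is
#' refitted per permuted dataset, and all randomized LRT values are pooled
#' across chromosomes. The genome-wide threshold at
#' `alpha = k / (n_chrom * n_datasets * n_midpoints)` is the k-th largest
#' pooled value. In the full-size design (31 chromosome units x 100 x 100),
#' k = 15 gives alpha = 15/310,000. Covariates stay attached to the
#' individuals when the phenotype is permuted.
#'
#' @inheritParams cldla_scan
#' @param n_datasets phenotype permutations per chromosome.
#' @param n_midpoints random midpoints per permuted dataset (must not
#'   exceed the admissible midpoints of any scanned chromosome).
#' @param k order statistic defining the threshold.
#' @param seed integer seed; the permutation study is fully reproducible.
#' @return object of class `perm_threshold`: `threshold`, `alpha`, `k`,
#'   `n_total`, `values` (all randomized LRT values, retained for audit),
#'   `window_size`, `coding_id`.
#' @export
permutation_thresholds <- function(panel, trait, covariates = NULL,
                                   window_size = 40, n_datasets = 100,
                                   n_midpoints = 100, k = 15, seed = 1,
                                   chroms = NULL, ne = 100, t_gen = 10,
                                   loco = TRUE, verbose = FALSE) {
  y <- if (inherits(trait, "coded_trait")) trait$values else as.numeric(trait)
  coding_id <- if (inherits(trait, "coded_trait")) trait$coding_id else NA_character_
  n <- n_individuals(panel)
  X <- .design_matrix(covariates, n)
  if (is.null(chroms)) chroms <- unique(panel$map$chrom)
  half <- window_size / 2
  set.seed(as.integer(seed))

  values <- list()
  for (cc in chroms) {
    mc <- length(.chrom_index(panel$map, cc))
    mids_all <- seq.int(half, mc - half)
    if (n_midpoints > length(mids_all)) {
      stop("'n_midpoints' exceeds the ", length(mids_all),
           " admissible midpoints on chromosome ", cc, call. = FALSE)
    }
    G <- grm(panel, exclude_chrom = if (loco) cc else NULL)
    su <- .rot_setup(y, X, G)
    drm_cache <- new.env(parent = emptyenv())
    vals <- numeric(0)
    for (b in seq_len(n_datasets)) {
      yp <- y[sample.int(n)]
      sup <- su
      sup$yst <- crossprod(su$U, yp)
      h0 <- .reml_core(yp, X, list(G), method = "eigen", eigen_setup = sup)
      vtot <- stats::var(yp)
      init <- c(h0$vc[1L], 0.05 * sum(h0$vc), 0.95 * h0$vc[2L])
      mids <- sample(mids_all, n_midpoints)
      for (i in mids) {
        key <- as.character(i)
        Dst <- drm_cache[[key]]
        if (is.null(Dst)) {
          D <- unclass(drm_from_ibd(window_ibd(panel, cc, i, window_size,
                                               ne = ne, t_gen = t_gen)))
          Dst <- crossprod(su$U, D %*% su$U)
          drm_cache[[key]] <- Dst
        }
        h1 <- .fit_h1(sup, Dst, vtot, init)
        vals <- c(vals, if (is.null(h1)) NA_real_ else {
          max(0, -2 * (h0$logL - h1$logL))
        })
      }
    }
    if (verbose) message(sprintf("chromosome %s: %d randomized LRT values",
                                 cc, length(vals)))
    values[[as.character(cc)]] <- vals
  }
  pooled <- unlist(values, use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  structure(c(.threshold_from_pool(pooled, k),
              list(values = pooled, per_chrom = lengths(values),
                   n_datasets = n_datasets, n_midpoints = n_midpoints,
                   window_size = window_size, coding_id = coding_id,
                   seed = seed)),
            class = "perm_threshold")
}

## k-th largest of a pool of randomized LRT values; alpha = k / pool size
.threshold_from_pool <- function(values, k) {
  if (k < 1 || k > length(values)) {
    stop("'k' must lie in [1, pool size]", call. = FALSE)
  }
  list(threshold = sort(values, decreasing = TRUE)[k],
       alpha = k / length(values), k = as.integer(k),
       n_total = length(values))
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation threshold: LRT >= %.3f (k = %d of %d pooled values, alpha = %.3g)\n",
    x$threshold, x$k, x$n_total, x$alpha))
  invisible(x)
}

#' Merge significant scan midpoints into QTL regions
#'
#' Consecutive scanned midpoints whose LRT reaches `threshold` and whose
#' SNP windows overlap are merged into one region; the region span is the
#' union of the window spans. Merging is idempotent and independent of
#' chromosome processing order.
#'
#' @param scan a [cldla_scan()] result.
#' @param threshold LRT threshold (number or `perm_threshold` object).
#' @return data frame with one row per region: `chrom`, `start_bp`,
#'   `end_bp`, `n_windows` (count of overlapping significant windows),
#'   `peak_lrt`, `peak_bp`.
#' @export
significant_regions <- function(scan, threshold) {
  th <- if (inherits(threshold, "perm_threshold")) threshold$threshold else threshold
  out <- list()
  for (cc in unique(scan$chrom)) {
    s <- scan[scan$chrom == cc & !is.na(scan$lrt) & scan$lrt >= th, ,
              drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$interval), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(s$win_start_bp[-1L] >
                                     cummax(s$win_end_bp)[-nrow(s)])))
    for (g in unique(grp)) {
      sg <- s[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start_bp = min(sg$win_start_bp),
        end_bp = max(sg$win_end_bp), n_windows = nrow(sg),
        peak_lrt = max(sg$lrt),
        peak_bp = sg$midpoint_bp[which.max(sg$lrt)],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_windows = integer(),
                      peak_lrt = numeric(), peak_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
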