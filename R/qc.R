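#' Marker and sample quality control
#'
#' Replicates a standard pre-mapping QC pipeline on a genotype matrix with
#' possible missingness. Filters are applied sequentially in a fixed,
#' documented order: (1) SNPs with unknown position, (2) SNPs with a call
#' rate strictly below `marker_callrate_min`, (3) SNPs with a minor allele
#' frequency strictly below `maf_min` (computed on non-missing calls after
#' the call-rate filter), and (4) individuals whose genotype call rate is
#' not strictly above `sample_callrate_min`. Thresholds are strict
#' inequalities: a marker with call rate exactly 0.9 is kept, an individual
#' with call rate exactly 0.95 is removed.
#'
#' @param genotypes `n x m` dosage matrix (0/1/2, `NA` = missing), or a
#'   [haplotype_panel()] (which has no missingness), or a list with elements
#'   `geno`, `map` and optionally `ids`.
#' @param map genome map data frame; positions `NA` or `<= 0` are treated
#'   as unknown. Taken from `genotypes` when that is a panel or list.
#' @param maf_min,marker_callrate_min,sample_callrate_min thresholds.
#' @return list with `geno` (filtered matrix), `map`, `ids` and `report`
#'   (class `qc_report`). Removing every marker is a hard error with the
#'   report attached to the condition.
#' @examples
#' g <- matrix(rbinom(40, 2, 0.4), nrow = 4)
#' qc <- qc_filter(g, genome_map(10))
#' qc$report
#' @export
qc_filter <- function(genotypes, map = NULL, maf_min = 0.01,
                      marker_callrate_min = 0.9, sample_callrate_min = 0.95) {
  if (inherits(genotypes, "haplotype_panel")) {
    map <- genotypes$map
    ids <- genotypes$ids
    geno <- dosages(genotypes)
  } else if (is.list(genotypes) && !is.data.frame(genotypes) &&
             !is.matrix(genotypes)) {
    geno <- as.matrix(genotypes$geno)
    map <- genotypes$map
    ids <- genotypes$ids %||% rownames(geno) %||% as.character(seq_len(nrow(geno)))
  } else {
    geno <- as.matrix(genotypes)
    ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  }
  if (is.null(map)) stop("a genome map is required", call. = FALSE)
  if (nrow(map) != ncol(geno)) {
    stop("map rows and genotype columns disagree", call. = FALSE)
  }
  n0 <- nrow(geno); m0 <- ncol(geno)

  unknown <- is.na(map$pos) | map$pos <= 0
  geno <- geno[, !unknown, drop = FALSE]
  map1 <- map[!unknown, , drop = FALSE]

  callrate_m <- colMeans(!is.na(geno))
  low_cr <- callrate_m < marker_callrate_min
  geno <- geno[, !low_cr, drop = FALSE]
  map2 <- map1[!low_cr, , drop = FALSE]

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  low_maf <- maf < maf_min
  geno <- geno[, !low_maf, drop = FALSE]
  map3 <- map2[!low_maf, , drop = FALSE]

  report_counts <- c(unknown_position = sum(unknown),
                     marker_callrate = sum(low_cr),
                     maf = sum(low_maf))
  if (ncol(geno) == 0L) {
    cond <- simpleError("all markers removed by QC")
    cond$report <- report_counts
    stop(cond)
  }

  callrate_s <- rowMeans(!is.na(geno))
  low_s <- !(callrate_s > sample_callrate_min)
  geno <- geno[!low_s, , drop = FALSE]
  ids <- ids[!low_s]

  report <- structure(list(
    n_snps_in = m0, n_snps_out = ncol(geno),
    n_individuals_in = n0, n_individuals_out = nrow(geno),
    removed = c(report_counts, sample_callrate = sum(low_s)),
    thresholds = c(maf_min = maf_min,
                   marker_callrate_min = marker_callrate_min,
                   sample_callrate_min = sample_callrate_min)),
    class = "qc_report")
  rownames(map3) <- NULL
  list(geno = geno, map = map3, ids = ids, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  SNPs:        %d in -> %d out\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("  individuals: %d in -> %d out\n",
              x$n_individuals_in, x$n_individuals_out))
  cat("  removed per filter (applied in this order):\n")
  for (nm in names(x$removed)) {
    cat(sprintf("    %-18s %d\n", nm, x$removed[[nm]]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
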