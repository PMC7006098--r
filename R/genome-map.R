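#' Build a genome map for simulated panels
#'
#' A genome map is a data frame with one row per SNP and columns `chrom`
#' (chromosome label), `snp` (marker id) and `pos` (1-based bp position,
#' strictly increasing within chromosome). Positions default to an even grid,
#' which at the default 10 kb spacing gives chromosome lengths of realistic
#' magnitude for a few thousand markers per chromosome.
#'
#' @param n_snps integer vector, number of SNPs per chromosome (each >= 2).
#' @param spacing_bp distance between adjacent SNPs in bp.
#' @param chrom optional chromosome labels, defaults to `"1","2",...`.
#' @param positions optional list of bp position vectors (one per
#'   chromosome), overriding `spacing_bp`. Must be strictly increasing.
#' @return a `data.frame` with columns `chrom`, `snp`, `pos`.
#' @examples
#' map <- genome_map(c(100, 100))
#' head(map)
#' @export
genome_map <- function(n_snps, spacing_bp = 1e4, chrom = NULL,
                       positions = NULL) {
  if (!is.null(positions)) {
    n_snps <- vapply(positions, length, integer(1))
  }
  n_snps <- as.integer(n_snps)
  if (length(n_snps) < 1L || any(is.na(n_snps)) || any(n_snps < 2L)) {
    stop("each chromosome needs at least 2 SNPs", call. = FALSE)
  }
  if (is.null(chrom)) chrom <- as.character(seq_along(n_snps))
  if (length(chrom) != length(n_snps)) {
    stop("'chrom' must have one label per chromosome", call. = FALSE)
  }
  if (anyDuplicated(chrom)) stop("duplicated chromosome labels", call. = FALSE)
  if (is.null(positions)) {
    if (!is.numeric(spacing_bp) || spacing_bp <= 0) {
      stop("'spacing_bp' must be a positive number", call. = FALSE)
    }
    positions <- lapply(n_snps, function(m) as.numeric(seq_len(m)) * spacing_bp)
  }
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    if (any(p < 1) || any(diff(p) <= 0)) {
      stop("positions must be 1-based and strictly increasing within ",
           "chromosome ", chrom[i], call. = FALSE)
    }
  }
  map <- data.frame(
    chrom = rep(chrom, n_snps),
    snp = unlist(lapply(seq_along(n_snps), function(i) {
      sprintf("c%s_s%d", chrom[i], seq_len(n_snps[i]))
    })),
    pos = unlist(positions),
    stringsAsFactors = FALSE
  )
  rownames(map) <- NULL
  map
}

.check_map <- function(map) {
  if (!is.data.frame(map) || !all(c("chrom", "snp", "pos") %in% names(map))) {
    stop("a genome map needs columns 'chrom', 'snp' and 'pos'", call. = FALSE)
  }
  for (cc in unique(map$chrom)) {
    p <- map$pos[map$chrom == cc]
    if (length(p) < 2L) stop("chromosome ", cc, " has fewer than 2 SNPs",
                             call. = FALSE)
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ",
                                "chromosome ", cc, call. = FALSE)
  }
  invisible(map)
}

.chrom_index <- function(map, chrom) {
  idx <- which(map$chrom == chrom)
  if (length(idx) == 0L) stop("chromosome '", chrom, "' not in map",
                              call. = FALSE)
  idx
}
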