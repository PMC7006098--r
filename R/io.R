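## File formats: PLINK .bed/.bim/.fam, phased VCF, phenotype TSV,
## scan TSV and region BED export.

#' Write a panel as a PLINK .bed/.bim/.fam fileset
#'
#' Genotypes are written SNP-major with the standard 2-bit encoding
#' (00 = two copies of allele 1, 10 = heterozygous, 11 = zero copies,
#' 01 = missing). Allele 1 is the haplotype allele coded 1 in the panel.
#'
#' @param panel a [haplotype_panel()] or a list with `geno` (dosage matrix,
#'   `NA` = missing), `map`, `ids`.
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @param phenotypes optional phenotype data frame (column `sex` is used
#'   for the .fam sex field).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(panel, prefix, phenotypes = NULL) {
  if (inherits(panel, "haplotype_panel")) {
    geno <- dosages(panel)
    map <- panel$map
    ids <- panel$ids
  } else {
    geno <- panel$geno
    map <- panel$map
    ids <- panel$ids
  }
  n <- nrow(geno)
  m <- ncol(geno)
  bim <- data.frame(map$chrom, map$snp, 0, map$pos, "A", "G")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  sex_code <- rep(0L, n)
  if (!is.null(phenotypes) && "sex" %in% names(phenotypes)) {
    sex_code <- ifelse(phenotypes$sex == "male", 1L, 2L)
  }
  fam <- data.frame(ids, ids, 0, 0, sex_code, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## dosage (of allele 1) -> 2-bit codes: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[geno == 1L] <- 2L
  code[geno == 2L] <- 0L
  code[is.na(geno)] <- 1L
  nbytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * nbytes - n
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, pad))
    dim(cj) <- c(4L, nbytes)
    bytes <- cj[1L, ] + cj[2L, ] * 4L + cj[3L, ] * 16L + cj[4L, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' @param prefix path prefix of the fileset.
#' @return list with `geno` (dosage of allele 1, `NA` = missing), `map`
#'   and `ids`.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  map <- data.frame(chrom = bim[[1L]], snp = bim[[2L]], pos = bim[[4L]],
                    stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = "character")
  ids <- fam[[2L]]
  n <- length(ids)
  m <- nrow(map)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK .bed file", call. = FALSE)
  }
  nbytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", nbytes * m)
  v <- as.integer(raw)
  two_bits <- rbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, v %/% 64L)
  dim(two_bits) <- c(4L * nbytes, m)
  codes <- two_bits[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_integer_, n, m)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  rownames(geno) <- ids
  colnames(geno) <- map$snp
  list(geno = geno, map = map, ids = ids)
}

#' Write a panel as a phased VCF
#'
#' Minimal VCFv4.2 with phased GT fields (`0|1` etc.), REF `A`, ALT `G`
#' (allele 1 of the panel is the ALT allele). 1-based positions.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path (plain text).
#' @return the path, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  h <- panel$haplotypes
  odd <- seq(1L, nrow(h), by = 2L)
  gt <- matrix(paste0(h[odd, , drop = FALSE], "|", h[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$ids), collapse = "\t"),
    vapply(seq_len(nrow(panel$map)), function(j) {
      paste(c(panel$map$chrom[j], panel$map$pos[j], panel$map$snp[j],
              "A", "G", ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phased VCF into a haplotype panel
#'
#' Uses \pkg{vcfR} when available, otherwise a plain-text fallback reader
#' for the minimal VCFs this package writes. Only biallelic sites with
#' phased GT are accepted.
#'
#' @param path VCF file path.
#' @return a [haplotype_panel()].
#' @export
read_phased_vcf <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    map <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                      snp = as.character(v@fix[, "ID"]),
                      pos = as.numeric(v@fix[, "POS"]),
                      stringsAsFactors = FALSE)
    ids <- colnames(gt)
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "##")]
    header <- strsplit(body[1L], "\t")[[1L]]
    ids <- header[-(1:9)]
    rows <- strsplit(body[-1L], "\t")
    map <- data.frame(chrom = vapply(rows, `[`, "", 1L),
                      snp = vapply(rows, `[`, "", 3L),
                      pos = as.numeric(vapply(rows, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
    gt <- t(vapply(rows, function(r) r[-(1:9)], character(length(ids))))
    if (length(ids) == 1L) gt <- matrix(gt, ncol = 1L)
  }
  if (any(!grepl("^[01]\\|[01]$", gt))) {
    stop("VCF must contain phased biallelic GT fields ('0|1' style)",
         call. = FALSE)
  }
  m <- nrow(map)
  n <- length(ids)
  H <- matrix(0L, 2L * n, m)
  H[seq(1L, 2L * n, 2L), ] <- t(matrix(as.integer(substr(gt, 1L, 1L)), m))
  H[seq(2L, 2L * n, 2L), ] <- t(matrix(as.integer(substr(gt, 3L, 3L)), m))
  haplotype_panel(H, map, ids)
}

#' Write / read a phenotype table as TSV
#'
#' Columns `id`, `category`, `sex`, `age_days`, `polled_genotype` plus any
#' coded-trait columns.
#'
#' @param phenotypes data frame.
#' @param path TSV path.
#' @return `write_phenotypes`: the path invisibly; `read_phenotypes`: the
#'   data frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export scan results as TSV and significant regions as BED
#'
#' The scan TSV mirrors a generic Manhattan-plot layout (`chrom`, `bp`,
#' `lrt`, flags). The BED export converts the package's 1-based closed
#' region spans to BED's 0-based half-open convention (`start - 1`, `end`).
#'
#' @param scan a [cldla_scan()] result.
#' @param regions a [significant_regions()] data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  out <- data.frame(chrom = scan$chrom, bp = scan$midpoint_bp,
                    lrt = scan$lrt,
                    win_start_bp = scan$win_start_bp,
                    win_end_bp = scan$win_end_bp,
                    converged_h1 = scan$converged_h1, bent = scan$bent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_tsv
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, as.integer(regions$start_bp) - 1L,
                    as.integer(regions$end_bp),
                    sprintf("region_%d", seq_len(nrow(regions))),
                    round(regions$peak_lrt, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
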