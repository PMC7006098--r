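## Shared small mapping dataset with a strong embedded QTL
local_scan_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- simulate_panel(80, genome_map(c(300, 150)), seed = 50)
      ph <- simulate_phenotypes(panel,
        truth_record(qtl_chrom = "1", qtl_snp = 150, qtl_variance = 0.35,
                     h2_poly = 0.2, seed = 50))
      cache <<- list(panel = panel, ph = ph,
                     trait = code_trait(ph, "CC"),
                     X = cbind(age = ph$age_days))
    }
    cache
  }
})

test_that("the scan walks admissible midpoints, is deterministic, and finds the QTL", {
  d <- local_scan_data()
  sc <- cldla_scan(d$panel, d$trait, covariates = d$X, window_size = 20,
                   step = 5, chroms = "1")
  half <- 10
  expect_true(all(sc$interval >= half & sc$interval <= 300 - half))
  expect_true(all(diff(sc$midpoint_bp) > 0))
  expect_true(all(sc$lrt >= 0, na.rm = TRUE))
  ## the global peak sits near the embedded QTL (SNP 150)
  qtl_bp <- d$panel$map$pos[150]
  peak_bp <- sc$midpoint_bp[which.max(sc$lrt)]
  expect_lt(abs(peak_bp - qtl_bp), 5e5)

  sc2 <- cldla_scan(d$panel, d$trait, covariates = d$X, window_size = 20,
                    step = 5, chroms = "1")
  expect_equal(as.data.frame(sc), as.data.frame(sc2))
})

test_that("region merging handles the empty, isolated and consecutive cases", {
  ## constructed scan fixture, window span 20 SNPs at 10 kb spacing
  mk <- function(intervals, lrts, spacing = 1e4, w = 20) {
    structure(data.frame(
      chrom = "5", interval = intervals,
      midpoint_bp = intervals * spacing + spacing / 2,
      win_start_bp = (intervals - w / 2 + 1) * spacing,
      win_end_bp = (intervals + w / 2) * spacing,
      lrt = lrts, converged_h0 = TRUE, converged_h1 = TRUE, bent = FALSE),
      class = c("cldla_scan", "data.frame"), window_size = w, step = 1)
  }
  base <- mk(10:50, rep(1, 41))
  expect_equal(nrow(significant_regions(base, 14.74)), 0L)

  one <- mk(10:50, c(rep(1, 20), 20, rep(1, 20)))
  r1 <- significant_regions(one, 14.74)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_windows, 1L)
  expect_equal(r1$start_bp, one$win_start_bp[21])
  expect_equal(r1$end_bp, one$win_end_bp[21])

  ## 18 consecutive significant overlapping windows merge into one region
  lr <- rep(1, 41); lr[12:29] <- 16
  many <- mk(10:50, lr)
  r2 <- significant_regions(many, 14.74)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$n_windows, 18L)
  expect_equal(r2$start_bp, many$win_start_bp[12])
  expect_equal(r2$end_bp, many$win_end_bp[29])
  expect_equal(r2$peak_lrt, 16)

  ## two separated peaks stay two regions; merging is idempotent in the
  ## sense that re-running on the same scan gives identical regions
  lr3 <- rep(1, 41); lr3[c(5, 35)] <- 20
  two <- mk(10:50, lr3)
  r3 <- significant_regions(two, 14.74)
  expect_equal(nrow(r3), 2L)
  expect_identical(significant_regions(two, 14.74), r3)
})

test_that("region merging is independent of chromosome processing order", {
  d <- local_scan_data()
  sc <- cldla_scan(d$panel, d$trait, covariates = d$X, window_size = 20,
                   step = 10)
  th <- 3
  r_fwd <- significant_regions(sc, th)
  sc_rev <- sc[rev(seq_len(nrow(sc))), ]
  attributes(sc_rev) <- c(attributes(sc_rev),
                          attributes(sc)[c("window_size", "step")])
  r_rev <- significant_regions(sc_rev, th)
  ord <- function(r) r[order(r$chrom, r$start_bp), ]
  expect_equal(ord(r_fwd), ord(r_rev), ignore_attr = TRUE)
})

test_that("permutation thresholds implement the k-th largest rule", {
  ## order-statistic bookkeeping on a synthetic pool
  set.seed(52)
  pool <- stats::rexp(1200)
  tp <- scurmap:::.threshold_from_pool(pool, 5)
  expect_equal(tp$threshold, sort(pool, decreasing = TRUE)[5])
  expect_equal(tp$alpha, 5 / 1200)
  expect_equal(scurmap:::.threshold_from_pool(pool, 1)$threshold, max(pool))
  expect_error(scurmap:::.threshold_from_pool(pool, 0), "k")

  ## full-size bookkeeping: 31 units x 100 x 100 pooled values, k = 15
  big <- stats::rchisq(31 * 100 * 100, df = 1)
  tp15 <- scurmap:::.threshold_from_pool(big, 15)
  expect_equal(tp15$n_total, 310000L)
  expect_equal(tp15$alpha, 15 / 310000)
})

test_that("a desk-scale permutation run is reproducible and audited", {
  d <- local_scan_data()
  pt <- permutation_thresholds(d$panel, d$trait, covariates = d$X,
                               window_size = 20, n_datasets = 4,
                               n_midpoints = 5, k = 5, seed = 99)
  expect_equal(pt$n_total, 2L * 4L * 5L)  # 2 chromosomes
  expect_equal(pt$alpha, 5 / 40)
  ## threshold re-derivable from the audited values
  expect_equal(pt$threshold, sort(pt$values, decreasing = TRUE)[5])
  ## thresholds are monotone in k
  expect_gte(scurmap:::.threshold_from_pool(pt$values, 1)$threshold,
             pt$threshold)
  pt2 <- permutation_thresholds(d$panel, d$trait, covariates = d$X,
                                window_size = 20, n_datasets = 4,
                                n_midpoints = 5, k = 5, seed = 99)
  expect_equal(pt$values, pt2$values)
  expect_error(
    permutation_thresholds(d$panel, d$trait, n_midpoints = 1e5, k = 1),
    "admissible")
})

test_that("scan output and regions export to TSV/BED with coordinate conversion", {
  d <- local_scan_data()
  sc <- cldla_scan(d$panel, d$trait, covariates = d$X, window_size = 20,
                   step = 20, chroms = "1")
  tsv <- tempfile(fileext = ".tsv")
  write_scan_tsv(sc, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(sc))
  expect_equal(back$lrt, sc$lrt)

  regions <- significant_regions(sc, min(sc$lrt))  # everything significant
  bed <- tempfile(fileext = ".bed")
  write_regions_bed(regions, bed)
  bb <- utils::read.delim(bed, header = FALSE)
  expect_equal(bb[[2]], as.integer(regions$start_bp) - 1L)  # 0-based start
  expect_equal(bb[[3]], as.integer(regions$end_bp))          # half-open end
})
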