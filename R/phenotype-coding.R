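#' Liability-scale transform of ordered category counts
#'
#' Maps ordered phenotype category counts onto a standard-normal liability
#' scale. Thresholds are the N(0,1) quantiles of the exact (unrounded)
#' cumulative category frequencies, and each category's coded value is the
#' mean of a standard normal truncated to its section:
#' `m_k = (phi(t_{k-1}) - phi(t_k)) / (Phi(t_k) - Phi(t_{k-1}))`
#' with `t_0 = -Inf` and `t_K = +Inf`. For the mapping design's counts
#' 75/130/19/7/1 this reproduces thresholds (-0.46, 1.19, 1.81, 2.63) and
#' section means (-1.111, 0.292, 1.458, 2.110, ~2.94) at the printed
#' precision. Using rounded thresholds instead would distort the means
#' (e.g. 0.290 instead of 0.292 for the second category), which is why the
#' transform always works from exact quantiles.
#'
#' @param category_counts positive counts of the ordered categories
#'   (at least 2 categories, total n >= 5). Zero counts are an error: an
#'   empty section has no mean.
#' @return an object of class `liability_coding`: a list with `thresholds`
#'   (K-1 values), `section_means` (K values, strictly increasing),
#'   `frequencies` and `counts`.
#' @examples
#' liability_transform(c(75, 130, 19, 7, 1))
#' @export
liability_transform <- function(category_counts) {
  k <- length(category_counts)
  if (k < 2L) stop("need at least 2 categories", call. = FALSE)
  if (any(category_counts <= 0)) {
    stop("zero or negative category counts: an empty section has no mean",
         call. = FALSE)
  }
  n <- sum(category_counts)
  if (n < 5) stop("total count must be at least 5", call. = FALSE)
  freq <- category_counts / n
  t <- stats::qnorm(cumsum(freq)[seq_len(k - 1L)])
  tt <- c(-Inf, t, Inf)
  means <- (stats::dnorm(tt[seq_len(k)]) - stats::dnorm(tt[-1L])) /
    (stats::pnorm(tt[-1L]) - stats::pnorm(tt[seq_len(k)]))
  structure(list(thresholds = t, section_means = means, frequencies = freq,
                 counts = category_counts),
            class = "liability_coding")
}

#' @export
print.liability_coding <- function(x, ...) {
  cat("Liability-scale coding of", length(x$counts), "ordered categories\n")
  cat("  counts:       ", paste(x$counts, collapse = "/"), "\n")
  cat("  thresholds:   ", paste(format(round(x$thresholds, 3)), collapse = ", "),
      "\n")
  cat("  section means:", paste(format(round(x$section_means, 3)),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Code the 5-category horn phenotype for mapping
#'
#' Converts the ordered horn-status categories of the mapping design into a
#' numeric trait under one of four coding models:
#' \describe{
#'   \item{CC}{linear score 1..5 over the ordered categories;}
#'   \item{CCL}{liability-scale section means from [liability_transform()]
#'     applied to the observed category counts;}
#'   \item{BC1}{binary, smoothly polled (1) vs any corneous change (2) --
#'     frontal bumps are cases;}
#'   \item{BC2}{binary, smoothly polled or frontal bumps (1) vs keratinized
#'     phenotypes scabs-to-scurs (2).}
#' }
#'
#' @param phenotypes data frame with a `category` column on the mapping
#'   scale (see [mapping_categories]), or a factor/character vector of
#'   categories.
#' @param coding_id one of `"CC"`, `"CCL"`, `"BC1"`, `"BC2"`.
#' @param category_counts counts used for the CCL transform; defaults to
#'   the observed counts in `phenotypes`.
#' @return an object of class `coded_trait`: list with `coding_id`,
#'   `values`, and for CCL also `thresholds` and `section_means`.
#' @examples
#' ph <- factor(c("smoothly_polled", "scabs", "frontal_bumps"),
#'              levels = mapping_categories)
#' code_trait(ph, "BC1")$values
#' @export
code_trait <- function(phenotypes, coding_id = c("CC", "CCL", "BC1", "BC2"),
                       category_counts = NULL) {
  coding_id <- match.arg(coding_id)
  category <- if (is.data.frame(phenotypes)) phenotypes$category else phenotypes
  category <- as.character(category)
  if (!all(category %in% mapping_categories)) {
    bad <- setdiff(unique(category), mapping_categories)
    stop("unknown mapping-scale categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(category, mapping_categories)
  out <- switch(coding_id,
    CC = list(values = as.numeric(idx)),
    BC1 = list(values = ifelse(idx == 1L, 1, 2)),
    BC2 = list(values = ifelse(idx <= 2L, 1, 2)),
    CCL = {
      if (is.null(category_counts)) {
        category_counts <- as.integer(table(factor(category,
                                                   levels = mapping_categories)))
      }
      lc <- liability_transform(category_counts)
      list(values = lc$section_means[idx], thresholds = lc$thresholds,
           section_means = lc$section_means)
    })
  structure(c(list(coding_id = coding_id), out), class = "coded_trait")
}

#' @export
print.coded_trait <- function(x, ...) {
  cat("Coded trait (", x$coding_id, "), n = ", length(x$values), "\n", sep = "")
  print(table(x$values))
  invisible(x)
}

#' Select the genotyping subset of a survey-scale phenotype table
#'
#' Applies the mapping-design selection criteria to a survey-scale table:
#' (i) horn categories smoothly polled, frontal bumps or scurs; (ii) minimum
#' age for the smoothly polled and frontal bumps categories only (animals
#' with scurs are informative at any age); (iii) a single sex; and (iv) a
#' single heterozygous polled genotype. An empty result is allowed.
#'
#' @param phenotypes survey-scale data frame with columns `category`, `sex`,
#'   `age_days`, `polled_genotype`.
#' @param min_age_days minimum age for the age-filtered categories.
#' @param sex,polled required sex and polled genotype.
#' @param categories categories retained.
#' @param age_filtered_categories categories to which the age criterion
#'   applies.
#' @return the subset of `phenotypes` satisfying all criteria.
#' @export
select_mapping_subset <- function(phenotypes, min_age_days = 700,
                                  sex = "female", polled = "PF/p",
                                  categories = c("smoothly_polled",
                                                 "frontal_bumps", "scurs"),
                                  age_filtered_categories =
                                    c("smoothly_polled", "frontal_bumps")) {
  cat_chr <- as.character(phenotypes$category)
  keep <- cat_chr %in% categories &
    phenotypes$sex == sex &
    phenotypes$polled_genotype == polled &
    (!(cat_chr %in% age_filtered_categories) |
       phenotypes$age_days >= min_age_days)
  out <- phenotypes[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("mapping subset is empty")
  rownames(out) <- NULL
  out
}

#' Exclude horned and ambiguous animals from a survey-scale table
#'
#' Removes animals in the `horns` and `others` categories, which carry no
#' information about the expression of scurs in polled animals.
#'
#' @param phenotypes survey-scale data frame with a `category` column.
#' @return list with `phenotypes` (the filtered table) and `excluded_count`.
#' @export
exclusion_filter <- function(phenotypes) {
  drop <- as.character(phenotypes$category) %in% c("horns", "others")
  out <- phenotypes[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(phenotypes = out, excluded_count = sum(drop))
}

#' Exploratory contingency tests of the horn phenotype
#'
#' Runs the two exploratory tests of the survey data: a Pearson chi-squared
#' test of independence between horn category and sex, and a two-sided
#' Fisher exact test of scurs (vs not) against the heterozygous polled
#' variant carried (PF/p vs PC/p). Given a plain contingency matrix, both
#' tests are applied to it directly.
#'
#' @param x survey-scale data frame (columns `category`, `sex`,
#'   `polled_genotype`) or a contingency matrix.
#' @param pool_scabs if `TRUE` and the table is on the mapping scale, scabs
#'   are pooled with scurs for the Fisher test; the default compares scurs
#'   only.
#' @return list of class `contingency_report` with elements `sex_test`
#'   (statistic, df, p_value, table) and `polled_test` (p_value, table);
#'   for matrix input, `chisq` and `fisher` on the given table.
#' @export
contingency_tests <- function(x, pool_scabs = FALSE) {
  if (is.matrix(x) || is.table(x)) {
    if (any(dim(x) < 2) || any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      stop("degenerate contingency table (empty row or column)", call. = FALSE)
    }
    ch <- stats::chisq.test(x, correct = FALSE)
    fi <- stats::fisher.test(x)
    return(structure(list(
      chisq = list(statistic = unname(ch$statistic), df = unname(ch$parameter),
                   p_value = unname(ch$p.value)),
      fisher = list(p_value = fi$p.value),
      table = x), class = "contingency_report"))
  }
  tab_sex <- table(category = droplevels(factor(x$category)), sex = x$sex)
  if (any(dim(tab_sex) < 2)) {
    stop("degenerate phenotype-by-sex table", call. = FALSE)
  }
  ch <- stats::chisq.test(tab_sex, correct = FALSE)

  scur_cats <- if (pool_scabs) c("scurs", "scabs") else "scurs"
  het <- x$polled_genotype %in% c("PF/p", "PC/p")
  tab_pol <- table(scurs = ifelse(as.character(x$category)[het] %in% scur_cats,
                                  "scurs", "no_scurs"),
                   polled = x$polled_genotype[het])
  if (any(dim(tab_pol) < 2)) {
    stop("degenerate scurs-by-polled-variant table", call. = FALSE)
  }
  fi <- stats::fisher.test(tab_pol)
  structure(list(
    sex_test = list(statistic = unname(ch$statistic),
                    df = unname(ch$parameter),
                    p_value = unname(ch$p.value), table = tab_sex),
    polled_test = list(p_value = fi$p.value, table = tab_pol)),
    class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  cat("Exploratory contingency tests\n")
  if (!is.null(x$sex_test)) {
    cat(sprintf("  phenotype x sex: X^2 = %.3f (df = %d), p = %.3g\n",
                x$sex_test$statistic, x$sex_test$df, x$sex_test$p_value))
    cat(sprintf("  scurs x polled variant (Fisher): p = %.3g\n",
                x$polled_test$p_value))
  } else {
    cat(sprintf("  chi-squared: X^2 = %.3f, p = %.3g; Fisher p = %.3g\n",
                x$chisq$statistic, x$chisq$p_value, x$fisher$p_value))
  }
  invisible(x)
}
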