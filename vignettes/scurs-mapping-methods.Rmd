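---
title: "Mapping QTL for ordered categorical horn traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL for ordered categorical horn traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scurmap)
```

## The problem

Scurs are loose, hornlike keratinous growths that appear in the horn area
of genetically polled (hornless) cattle, attached by soft tissue rather
than fused to the skull. Their expression is variable — from smoothly
polled animals through frontal bumps and scabs up to scurs several
centimetres long — and depends on sex, age at phenotyping and the genotype
at the *polled* locus. Whether a single *scurs* locus exists, or the trait
is oligogenic, is a long-standing question. `scurmap` implements the full
variance-component mapping chain used to attack it: phenotype coding on a
liability scale, combined linkage-disequilibrium-and-linkage analysis
(cLDLA) at SNP-interval midpoints, mixed linear model association
(MLMA) with leave-one-chromosome-out (LOCO) control, GREML
SNP-heritability, empirical permutation thresholds, and a
liability-threshold power study — together with a simulator that produces
phased panels and categorical phenotypes with known architecture, so that
every stage is testable without access to proprietary cattle data.

## Coding ordered categories

A five-category ordered horn status (smoothly polled, frontal bumps,
scabs, small scurs, medium scurs) is converted into a numeric trait in
four ways:

* **CC** — linear scores 1..5;
* **CCL** — liability-scale values: with category frequencies `f_k`, the
  thresholds are `t_k = qnorm(cumsum(f)[k])` and each category's value is
  the mean of a standard normal truncated to its section,
  `m_k = (dnorm(t_{k-1}) - dnorm(t_k)) / (pnorm(t_k) - pnorm(t_{k-1}))`;
* **BC1** — binary, smoothly polled vs everything else (frontal bumps are
  cases, on the view that a bump is a precursor of a scur);
* **BC2** — binary, keratinized phenotypes (scabs and scurs) vs the rest.

```{r liability}
liability_transform(c(75, 130, 19, 7, 1))
```

Two numerical points matter. First, the transform always works from the
*exact* quantiles: rounding the thresholds to two decimals before
computing section means visibly distorts them (the second mean becomes
0.290 instead of 0.292). Second, the mean of the open upper section of a
tail category with a single observation is sensitive to the last
threshold's precision; the truncated-normal formula gives 2.9385 where
two-decimal intermediate rounding would print 2.939 — the package reports
the formula value and the tests allow 0.01 on this one cell (5e-4
elsewhere). Similarly, the third threshold is 1.8186, which rounds to
1.82 rather than the conventionally quoted 1.81; tests therefore pin the
first and fourth thresholds at two decimals and bound the others within
0.011.

## Relationship matrices

The polygenic covariance is the frequency-standardized cross-product GRM,
`G = W W' / m` with `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))` and
observed frequencies `p_j` — the standard construction in genomic
evaluation. For genome scans a LOCO version excludes the scanned
chromosome so that the locus term is not absorbed by the polygenic one.

### Haplotype IBD at SNP-interval midpoints

A chromosome with `n` SNPs has `n - 1` intervals; each interval midpoint
is treated as a putative causal locus. Identity by descent between two
haplotypes at the midpoint is estimated from the `w` surrounding SNPs
(`w/2` per side; `w` of 20, 40, 80 or 160 conventionally) with a
deterministic coalescent approximation:

* two haplotypes coalesce within `T` generations with geometric rate
  `1/(2 Ne)` (defaults `Ne = 100`, `T = 10`);
* given coalescence at generation `t`, the shared segment around the
  midpoint extends left and right by independent exponential genetic
  distances with rate `2t` per Morgan (1 cM/Mb);
* markers inside the segment agree; markers outside agree
  identically-by-state with probability `h`, the mean homozygosity of the
  window's SNPs;
* on each side the observed data are summarized by the run of consecutive
  agreeing markers outward from the midpoint, truncated at the first
  discordant marker; Bayes' rule against the no-recent-coalescence
  alternative gives the posterior IBD probability.

Because the posterior depends only on the two run lengths, the whole
`2n x 2n` matrix is filled from a `(w/2 + 1)^2` lookup table, and run
lengths are computed on the *unique* window haplotypes only. The
approximation's contract — monotone in the agreement runs, near 0 for
haplotypes discordant at both flanking SNPs, a plateau for fully
identical windows — is what the tests pin, alongside a per-pair oracle
of the formula itself; `Ne` and `T` are exposed as configuration.

The haplotype-level IBD matrix is condensed to the individual-level
diplotype relationship matrix (D_RM):
`d_ij = (P(i1,j1) + P(i1,j2) + P(i2,j1) + P(i2,j2)) / 2` off the
diagonal and `d_ii = 1 + P(i1,i2)`. D_RMs from panels with shared
haplotypes are routinely singular; `repair_psd()` bends such matrices by
the smallest diagonal ridge that restores a minimum eigenvalue of 1e-8.
Inside the scan a cheaper equivalent is used: the alternative model is
fitted directly and a ridge is added only if the covariance loses
positive definiteness, with the event recorded in the scan's `bent`
column.

## The mixed models

At every midpoint `i` the alternative model is

y = X b + u + q + e,  u ~ N(0, G s2_u),  q ~ N(0, D_RM_i s2_q),
e ~ N(0, I s2_e),

with fixed effects intercept and age at phenotyping; the null model drops
`q`. Both are fitted by REML and compared with
`LRT = -2 (logL(H0) - logL(H1))`, clamped at zero and referred to
chi-squared(1) for p-value conversion. The true null at the variance
boundary is a 50:50 mixture of a point mass at zero and chi-squared(1),
so the chi-squared(1) convention is conservative; tests check the
mixture's signature (a large point mass at zero, exceedance rates below
the chi-squared envelope).

### The REML engine

`reml_fit()` maximizes the restricted likelihood with
average-information (AI) updates, stabilized expectation-maximization
style multiplicative steps for the first iterations, step-halving, and
an active-set constraint that pins components driven negative at a floor
of `1e-8 * var(y)` (flagged as boundary solutions). Convergence requires
both `|d logL| < 1e-6` and relative parameter changes below 1e-4.
Non-convergence is a *flagged outcome*, never an exception: binary
codings of highly skewed traits are expected to misbehave, and scans must
surface the flag rather than die. Three computational paths share the
iteration driver and give identical likelihoods (verified against a dense
projection-matrix oracle to 1e-8):

* a single random term is fitted in the eigenbasis of `K`, where the
  covariance is diagonal and iterations cost O(n);
* several random terms use dense Cholesky algebra;
* the scan's two-term fits run in the eigenbasis of the chromosome's
  LOCO-G, where the polygenic matrix is diagonal, `tr(V^-1 G)` and
  `tr(V^-1)` come from `diag(V^-1) = rowSums(chol(V)^-1 ^ 2)`, and
  `tr(V^-1 D)` follows from `tr(V^-1 V) = n` — no `n x n` inverse is
  formed. Midpoint fits are warm-started from the neighbouring midpoint.

The null fit is performed once per chromosome (its likelihood does not
depend on the midpoint) and reused.

## Significance

Two conventions are provided. For single-SNP tests, Bonferroni
thresholds `0.05/N` (genome-wide) and `1/N` (suggestive). For the scan's
LRT, an empirical permutation threshold: per chromosome, `n_datasets`
phenotype permutations are evaluated at `n_midpoints` random midpoints
each (sampled without replacement within a dataset; covariates stay
attached to individuals), all randomized LRT values are pooled, and the
threshold is the k-th largest, with `alpha = k / pool size`. In the
full-size design of 31 chromosome units x 100 x 100 this is 15/310,000,
i.e. alpha = 4.84e-5. Midpoints skipped for window-boundary reasons are
excluded from both the scan and the permutation pool, keeping the null
exchangeable. Consecutive significant midpoints with overlapping windows
merge into regions whose span is the union of the window spans.

## MLMA and the congruence transform

`mlma_loco()` estimates the polygenic and residual variances once per
chromosome under LOCO-G (the standard MLMA approximation) and then tests
each SNP by generalized least squares in the whitened basis, with the
residual scale re-estimated per SNP and a Wald chi-squared(1) test. This
form makes two desirable identities exact: with an identity relationship
matrix it *is* single-SNP ordinary least squares, and it equals direct
GLS-with-estimated-scale computed through an explicit `V^-1`. To compare
the SNP-based curve with the midpoint-based scan, `-log10(p)` values are
averaged over 10 adjacent SNPs and aligned to the midpoint between the
window's central SNPs (edges truncated, not padded).

## Power of the design

`run_power()` implements the liability-threshold power study: per
replicate, `n = 232` independent liabilities are the sum of a biallelic
QTL effect explaining `fraction x h2` of the unit variance (default
`h2 = 0.6`; fractions 0.10/0.20/0.30) and an independent residual;
liabilities are discretized by the thresholds fixed from the reference
category counts; a marker in LD with the QTL at haplotype `r^2 = 0.8` is
generated by letting each marker haplotype copy the QTL allele with
probability `sqrt(r^2)` (else redrawing at the same frequency, which
makes any `r^2 <= 1` feasible at equal frequencies — the QTL frequency
defaults to 0.5 and is configurable); and the coded phenotype is
regressed on marker dosage with a Wald chi-squared(1) p-value compared to
both thresholds on shared replicates. Scenarios sharing a seed share
their latent draws, so codings are compared replicate by replicate. Tests
check size under the null, monotonicity in the QTL fraction, the
dominance of continuous codings over binary ones, and agreement with a
closed-form noncentral chi-squared approximation.

## The synthetic panel and its limits

`simulate_panel()` generates haplotypes as mosaics of 30 hidden founder
haplotypes, switching founders between adjacent SNPs with probability
`distance x ld_decay` (default 1e-6 per bp). This yields LD that decays
with distance and background relatedness among individuals sharing
founder segments — the two features the mapping machinery actually
exploits — at any panel size. Defaults were fixed once, at values a
mapping study of this kind would call realistic, and are documented here:

* SNP spacing 10 kb: desk-scale panels of a few thousand SNPs then span
  chromosome lengths of realistic magnitude (a 2,000-SNP chromosome is
  20 Mb);
* MAF floor 0.05, mimicking the ascertainment of genotyping arrays after
  QC;
* age at phenotyping uniform on [700, 3000] days with a 5% share of
  liability variance, mirroring the age-dependent penetrance of scurs;
* phenotype category frequencies 75/130/19/7/1 out of 232, the
  distribution of the motivating all-female, heterozygous-polled mapping
  design; liabilities are standardized empirically (centred, divided by
  the realized SD) so the N(0,1) quantile thresholds land exactly on the
  simulated scale.

What the generator does *not* emulate: coalescent site-frequency
spectra, recombination hotspots, pedigree structure, sex chromosomes,
selection or phenotype-dependent ascertainment beyond the category
frequencies, and phasing or imputation error (panels are phased by
construction). Passing tests therefore demonstrate that the estimators
and their calibration behave correctly under a plausible LD and
relatedness structure — not that any particular real-data result is
reproduced.

## Desk-scale profiles

The defaults used by the test suite and `run_pipeline()` are scaled-down
profiles chosen as the package's own working sizes: 2–3 chromosomes of a
few hundred to 2,000 SNPs, permutation studies of 20 x 20 rather than
100 x 100 with `k` chosen to keep alpha comparable, power runs of 2,000
replicates, and scans evaluated at every `step`-th midpoint (steps of
4–12, i.e. 40–120 kb between evaluated midpoints at the default spacing
— an order of magnitude below the 1 Mb localization tolerance the
recovery checks use). Full-size parameters remain configurable
everywhere.

## Known limitations

* Window size trades resolution against stability: longer windows broaden
  the LRT peak and leave its location essentially unchanged, but — with
  the run-length IBD estimator — they do *not* reduce the count of strict
  local maxima on simulated panels. Short windows saturate their
  agreement runs for many haplotype pairs, which yields coarse, tie-rich
  relationship matrices and locally flat LRT stretches, while long
  windows resolve run lengths finely and wiggle. Peak *morphology*
  should therefore be judged by span and stability, not by counting
  micro-maxima.
* The linear mixed model is applied to binary codings as-is (no
  threshold/probit link); that reproduces the known convergence fragility
  of binary codings, which the package surfaces via flags by design.
* The IBD approximation ignores mutation and summarizes each side of the
  midpoint by its first discordant marker; markers beyond it contribute
  only through the null hypothesis's homozygosity terms.
* `alpha = k / pool size` is the definition used for permutation
  thresholds; quoting it as 0.0005 for the 15/310,000 rule (as sometimes
  seen) is an inconsistency this package does not adopt.
* Heritability estimates on a phenotype-selected mapping subset describe
  that subset, not the population; the permutation validation guards
  against pure-noise estimates, nothing more.
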