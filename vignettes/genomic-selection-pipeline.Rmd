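---
title: "Genomic selection and genetic-gain analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection and genetic-gain analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

breedgain implements the analysis backbone of a genomic-selection (GS)
breeding program for inbred line crops such as irrigated rice: genotype
quality control, a two-stage multi-environment trial analysis, ridge-regression
BLUP genomic prediction with cross-validation, sparse-testing design
construction, and genetic-gain (era) regression — all exercised end to end on
a built-in breeding-program simulator with known truth. This vignette is the
package's own account of the models, the tunable parameters, the numerical
choices, and what the synthetic experiments do and do not demonstrate.

## The mixed-model core

Every prediction step in the package reduces to one linear mixed model with a
single random term,

$$y = X\beta + Zu + e, \qquad
  u \sim N(0, K\sigma^2_u), \qquad e \sim N(0, R\sigma^2_e),$$

with $R = \mathrm{diag}(w)$ a known diagonal weight matrix. The three
workhorse cases differ only in $Z$ and $K$:

* **Marker-effect ridge regression (rrBLUP):** $Z$ = centred SNP dosages,
  $K = I$. Genomic estimated breeding values are $\widehat{g} = M\hat u$ for
  any genotyped line, phenotyped or not.
* **Pedigree BLUP:** $Z$ = line incidence, $K = A$, the additive
  relationship matrix from the tabular method (diagonal $1+F$).
* **Genomic BLUP:** $Z$ = line incidence, $K = G$, the VanRaden method-1
  genomic relationship matrix $WW'/(2\sum_k p_k(1-p_k))$ from centred
  dosages.

`reml_solve()` estimates the variance components by REML. The restricted
likelihood is profiled down to the single ratio
$\delta = \sigma^2_e/\sigma^2_u$ and maximised by Brent search on
$\log\delta \in [-10, 10]$ (natural log, tolerance $10^{-9}$; hitting an
endpoint sets a `boundary` flag). The profile is evaluated spectrally: after
absorbing the fixed effects through an orthonormal contrast basis, one
eigendecomposition of the projected kernel gives the likelihood at every
$\delta$ for the cost of a vector update. When the number of random columns
$q$ is smaller than the residual degrees of freedom, the decomposition is
taken on the $q\times q$ cross-product instead of the $n\times n$ covariance
— so a marker model with 800 SNPs on 6,400 trial records costs an
800-dimensional eigenproblem, not a 6,400-dimensional one. The reported
log-likelihood uses the orthonormal-contrast REML convention on the
weight-transformed scale; the test suite checks it against a brute-force
dense grid over $\log_{10}\delta \in [-6, 6]$.

Two consequences of this design are load-bearing and tested:

* **Parameterisation equivalence.** The marker model ($Z = M$, $K = I$) and
  the line model ($Z$ = incidence, $K = MM'/c$) have identical restricted
  likelihood profiles up to a shift of $\log\delta$ by $\log c$, so GEBVs are
  identical for any $c > 0$; at a matched ratio they agree to machine
  precision. `fit_stage_two()` exploits this with its `dosage` argument: for
  populations with many more lines than markers the marker parameterisation
  is used internally and line gBLUPs are recovered as $M\hat u$.
* **Restricted-likelihood boundary.** When $q \ge n - \mathrm{rank}(X)$ a
  perfect fit is possible and the likelihood is flat as
  $\sigma^2_e \to 0$; the solver then reports the boundary flag and the
  residual variance is not meaningfully estimated. Tests that compare
  estimated components avoid this regime or compare at a fixed ratio.

Prediction error variances (PEV) of $u$ are returned on request
(diagonal or full matrix); they satisfy
$0 \le \mathrm{PEV}_{ii} \le \sigma^2_u K_{ii}$ and feed the generalised
heritability below.

## Genotype quality control

`qc_genotypes()` applies, in this order:

1. **Lines:** drop a line when its heterozygous proportion among
   *non-missing* calls is strictly greater than `het_max` (default 0.15).
   Missing calls carry no zygosity information, so they are excluded from
   the denominator. In F7–F9 inbred material, high apparent heterozygosity
   indicates contamination.
2. **Markers:** drop a marker when its missing fraction is strictly greater
   than `miss_max` (default 0.15) or its minor allele frequency is strictly
   below `maf_min` (default 0.05), with MAF computed from non-missing calls
   and heterozygotes counted as one copy of each allele.

Lines are filtered before markers because the marker statistics depend on
which lines remain; swapping the order can change the result, so the order
is fixed. All thresholds are strict inequalities: a line at exactly 15%
heterozygosity and a marker at exactly 0.05 MAF survive. Strict filtering is
*not* algebraically idempotent in general — removing markers changes line
heterozygosity — but at realistic noise rates (2% residual heterozygosity,
3% missingness) a second pass is a no-op, and the tests assert exactly that.

`encode_dosage()` recodes hom-ref/het/hom-alt as $-1/0/+1$ and imputes
missing cells with the per-marker mean of observed codes (imputed values are
fractional). The paper trail for the imputation choice is thin everywhere in
this literature; marker-mean is the standard neutral default and the coding
constant cancels from GEBV contrasts. Monomorphic surviving markers are kept
but flagged.

## Two-stage trial analysis

**Stage 1 (per trial).** Each trial is analysed separately by fixed-effects
least squares with genotype effects plus a blocking structure chosen by BIC:
candidates are none/replicate for RCBD and augmented designs, and
none/row/column/row+column for row-column designs. BIC uses the
maximum-likelihood log-likelihood because the candidates differ in fixed
effects; ties go to fewer parameters, and aliased or saturated candidates
are skipped with a log entry. Blocking factors enter in sum-to-zero
contrasts so each genotype coefficient is its adjusted mean (BLUE) at the
average block; in augmented designs the replicated checks estimate the
block corrections applied to unreplicated entries. Output is one BLUE and
standard error per line per trial.

**Stage 2 (across trials).** The BLUEs are modelled with environment
(year × location) as fixed and line as random with an A, G or identity
kernel. The default residual weights are the squared stage-1 standard
errors, making the stage-2 residual covariance proportional to the stage-1
error covariance; identity weights are available for sensitivity analysis.
The line predictions are the performance BLUPs (pedigree kernel) or genomic
BLUPs (G kernel) that downstream gain regression consumes.

**Two-stage versus one-stage.** On balanced, orthogonal, equal-variance
data the line-by-environment means are sufficient statistics, so stage-2
BLUPs reproduce a single joint plot-level fit *exactly* — conditional on
the variance ratio. With the ratio re-estimated at each stage the two fits
use different residual information (the joint fit sees within-plot
replication that the means level cannot), so they agree only statistically.
The acceptance test therefore checks machine-precision equality at the
joint fit's ratio (the algebraic theorem) and close agreement
(correlation > 0.999) for the fully re-estimated route. `reml_solve()` and
`fit_stage_two()` expose `lambda` for such conditional fits.

**Heritability.** Trial heritability uses the generalised (Cullis)
definition
$H^2 = 1 - \bar v_\Delta / (2\hat\sigma^2_g)$, where $\bar v_\Delta$ is the
mean prediction-error variance of a difference between two genotype BLUPs
from a genotype-random refit. This definition remains meaningful under the
unbalance of augmented designs, and in a balanced RCBD it lands on the
line-mean heritability $r h^2 / (1 + (r-1)h^2)$, which the tests verify
(plot $h^2 = 0.5$, three replicates, $H^2 \approx 0.75$). A simpler
mean-PEV shortcut (ignoring BLUP covariances) is used only when a full PEV
matrix was not requested.

## Genomic prediction workflows

* `compute_gebv()` fits the marker model on phenotyped lines and scores all
  genotyped lines. With an intercept-only fixed part and centred dosages the
  training GEBVs are centred near zero.
* `predict_unphenotyped()` estimates marker effects on a training set (for
  example, yield-tested parents) and scores a genotyped-only target set
  (their early-generation progeny), refusing to predict when the shared
  marker count falls below a floor (default 100).
* `prediction_accuracy()` is the Pearson correlation between GEBVs and
  observed values over shared lines — constant inputs are an error, never a
  silent zero.
* `cross_validate()` repeats, at each training fraction
  $f \in \{0.2, 0.3, 0.4, 0.5, 0.6, 0.8\}$ and for `n_iter` iterations
  (default 500): draw $\lfloor fn\rfloor$ lines without replacement, fit,
  predict the complement, record accuracy. The validation set is the
  complement of the training draw. Fraction 1.0 is supported as fit-to-all
  self-accuracy and flagged optimistic — it is the "100% training" point of
  a training-size curve, not a cross-validation. Each iteration derives its
  own counter-based sub-seed, so single iterations are independently
  reproducible and the whole result is deterministic given one seed.
* `relative_efficiency()` scales accuracy by heritability. Because flat
  typography makes the printed convention ambiguous in parts of this
  literature, both $r/H^2$ (default) and $r/\sqrt{H^2}$ are implemented and
  the convention used is recorded in the result.
* `select_parents()` ranks by GEBV with ties broken by line id, so selection
  is deterministic.

## Sparse testing

`build_common_share()` samples $\lfloor 0.40\,n\rfloor$ lines to be planted
at every location under the constraint that every cross is represented:
pass 1 takes one line per cross, visiting crosses in an order that prefers
sharing a parent with an already-covered cross (ties by cross id), so the
common share carries pedigree connectivity; pass 2 fills the remaining slots
uniformly. `build_sparse_design()` then deals the non-common remainder out
in draws of $\lfloor 0.25\,|\text{remainder}|\rfloor$ *without replacement*
across the four training populations, so TPs pairwise intersect exactly in
the common share and, with step fraction $1/n_{TP}$, the remainder is
exhausted and every line is tested somewhere.

Read literally, a 40% common share plus a 25%-of-the-remainder unique share
gives each TP 55% of the population — while a 60% TP share is also quoted in
descriptions of this scheme. The two statements are arithmetically
incompatible; the without-replacement reading is the only self-consistent
one and is what the package implements, with the realised TP share reported
by `design_diagnostics()` rather than silently adjusted. Leftover lines
(step fractions below $1/n_{TP}$) are likewise reported, never dropped.

## Genetic gain by era regression

`estimate_genetic_gain()` regresses per-line BLUPs (performance or genomic)
on the calendar year of evaluation; the slope is the annual genetic gain in
t/ha, reported with its standard error, t statistic, p-value, t-quantile
confidence interval, and percent gain relative to the first-year mean. Two
deliberate conventions:

* **Duplicates.** A line evaluated in several years contributes one point at
  its *first* evaluation year (cohort entry); `duplicates = "all"` keeps
  every record for sensitivity.
* **Intervals.** `confidence_interval()` provides the classic z-based mean
  interval $\bar x \pm z^{*}\sigma/\sqrt n$ — the form used to band era
  scatter plots — while the slope itself carries the regression-standard
  t-quantile interval. Both are labelled, because a z-interval of a mean is
  not a slope interval and conflating them is a common reporting slip.

A caveat the simulator makes explicit: when yearly cohorts are finite random
samples, their realised mean breeding values drift around the programmed
trend by $\sigma_{TBV}/\sqrt{n_{\text{cohort}}}$ per year. That drift is
genuine genetic signal to the OLS t-test, so testing the slope against a
*programmed* zero rejects somewhat more often than the nominal $\alpha$ —
an inflation that scales identically with cohort size in numerator and
denominator and therefore does not vanish as programs grow. The acceptance
check budgets for it explicitly (a 20-seed binomial envelope of a ~10%
per-seed rate) instead of pretending the nominal level applies.

## The simulator: what it emulates, and what it does not

`sim_config()` fixes the study conditions; the important defaults, with
units and rationale:

| parameter | default | meaning |
|---|---|---|
| `n_markers` | 800 | SNP panel size after QC attrition from a ~1k panel |
| `n_chromosomes`, `chrom_length_morgans` | 12, 1.5 | a rice-like genome |
| `maf_range` | (0.1, 0.5) | founder allele frequencies |
| `n_qtl` | min(200, markers) | markers carrying effects; effects normal, rescaled so realised TBV variance equals `var_g` exactly |
| `var_g` | 0.25 (t/ha)² | genetic SD 0.5 t/ha among lines |
| `heritability_plot` | 0.5 | $\sigma^2_g/(\sigma^2_g+\sigma^2_e)$; sets plot error |
| `gxe_ratio` | 0.1 | line×location variance as a share of `var_g` |
| `grand_mean` | 5.5 t/ha | irrigated-season yield level |
| `selfing_generations` | 6 | F7 material via rapid generation advance |
| `residual_het_rate`, `missing_rate` | 0.02, 0.03 | imperfect fixation and genotyping dropout, injected per cell after inbreeding |
| `locations` | 4 sites | multi-location testing with RCBD, 2 replicates |

Meiosis is modelled per chromosome with a Poisson crossover count (mean =
map length in Morgans), uniform positions, and no interference — enough to
generate realistic within-family linkage disequilibrium. Founders are fully
inbred, as released varieties are; one consequence worth knowing is that
VanRaden G then has diagonal near $1+F=2$ on founders (near 1 only for
Hardy–Weinberg material). Families are advanced by single-seed descent, so
per-locus heterozygosity decays as $(1/2)^g$ from the F1 before the residual
heterozygosity injection. True breeding values are exact dosage-weighted
effect sums at all times; missingness is injected only into the *observed*
genotype copy.

`run_recurrent_program()` closes the loop — cross, derive, trial, predict,
recycle top-GEBV parents — and records per-cycle mean TBV, so selection
response is measurable against ground truth. `simulate_era_program()`
instead programs a deterministic expected trend (default magnitudes 0–0.12
t/ha/yr) by shifting QTL allele frequencies in proportion to their effects,
the footprint selection leaves in a breeding program, with a fixed check set
planted every year to anchor environment effects across eras.

What passing tests on this generator do **not** show about real data: the
panel tags all causal variation (no missing heritability), G×E is
unstructured line-by-location noise (no crossover interaction, no spatial
field trend), phenotypes have no outliers or recording errors, and cohorts
are unselected random draws within each year. Accuracies on the synthetic
program (≈0.6–0.8) therefore sit above typical real-data yield accuracies;
it is the *shapes* — accuracy rising with training fraction, gain recovered
within tolerance, selection beating chance — that the tests certify, not the
levels.

## Problem sizes used in the shipped experiments

The test suite runs the solver-versus-grid sweep on 50 instances
($n \le 30$, $q \le 60$), cross-validation at $n = 500$ lines × 800 markers
with 200 iterations per fraction, era regression on 4 years × 400 lines over
20 seeds (plus 20 null seeds), and 20 paired selection-response seeds.
`scripts/acceptance.R` reruns the full pipeline at the same population sizes
with 100 CV iterations per fraction. These sizes were chosen so the whole
battery completes comfortably on a single CPU while keeping Monte Carlo
error well inside every asserted tolerance.

## Known limitations

Single-trait, additive-only analysis; one random term per fit (no spatial
AR1×AR1 adjustment, no explicit G×E covariance structures); marker-mean
imputation only; the sparse-testing constructor targets connectivity, not
optimality criteria such as CDmean; and trait-specific marker flags are
carried as metadata without any marker-assisted selection logic. These match
the package's scope: the routine GS decisions of a line-breeding program,
not a general mixed-model platform.
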