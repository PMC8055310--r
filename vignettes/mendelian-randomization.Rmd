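---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
library(dplyr)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (say, genetic liability to type 2 diabetes, or HbA1c level) on an
outcome (say, ischemic stroke) from two independent GWAS: one supplying
per-variant exposure associations $\hat\gamma_j \pm \sigma_{\gamma j}$, the
other outcome associations $\hat\Gamma_j \pm \sigma_{\Gamma j}$ for the same
genetic variants. If variant $j$ is a valid instrument — associated with the
exposure, independent of confounders, and affecting the outcome only through
the exposure — then $\Gamma_j = \beta\,\gamma_j$ and each variant yields a
Wald ratio estimate $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ of the causal
effect $\beta$.

`mrpipe` implements the whole analysis as composable tibble-in/tibble-out
steps: reading and validating summary statistics, allele harmonization,
instrument selection by significance filtering and greedy LD clumping,
variance explained on the observed and liability scales, the IVW, weighted
median, MR-Egger and simulation-based outlier-test estimators, multivariable
MR for cluster-weighted exposures, FDR control over an exposure-by-outcome
grid, bidirectional analyses, and a synthetic generator with known causal
truth that makes every one of these stages testable offline.

## Harmonization

Exposure and outcome effects must refer to the same allele on the same
strand. For each shared variant we compare allele pairs: identical pairs are
taken as-is; swapped pairs have the outcome effect negated and the allele
frequency complemented; strand-complemented pairs (A/G vs T/C) are
complemented before matching; anything else is dropped as a mismatch.
Palindromic pairs (A/T, C/G) are strand-ambiguous: under the default
`infer_by_frequency` policy a palindromic variant is kept only when both
allele frequencies fall on the same side of 0.5 and both minor allele
frequencies are below `maf_ambiguity_threshold` (default 0.42, a common
choice: at MAF above ~0.42 the frequency itself can no longer distinguish
the two strand readings). Palindromes whose frequencies disagree in side are
dropped rather than flipped — flipping on frequency evidence alone is the
more aggressive convention used by some tools, and we prefer losing a variant
to silently aligning it wrongly. A missing frequency disables inference for
that variant only, and every input variant is accounted for by exactly one
`action`, so the audit is conservation-complete.

Estimator input is conventionally oriented so all exposure effects are
non-negative (`orient_exposure_increasing()`). Ratio-based estimators are
unaffected; MR-Egger is orientation-dependent and re-orients internally, so
every estimator is invariant to which allele the input files call the effect
allele.

## Instrument selection

Candidates with $p \le$ `p_threshold` (default $5\times10^{-8}$) are clumped
greedily: rank by ascending p (ties by chromosome, position, id), keep the
best remaining variant, discard every remaining same-chromosome variant
within `window_kb` (default 10,000 kB either side) whose $r^2$ with it
exceeds `r2_max` (default 0.01), repeat. This is the de facto standard
(PLINK-style) greedy algorithm; pairs absent from the LD table count as
$r^2 = 0$. The retained set provably satisfies the pairwise constraint, and
the test suite checks the implementation against an independent step-by-step
trace oracle on random instances.

Variance explained per variant is offered in two forms for continuous
traits: `z_based` (default), $r^2 = z^2/(z^2 + n - 2)$ from the summary
statistics alone, and `freq_based`, $2p(1-p)\beta^2$ for standardized
effects. For binary traits we compute liability-scale variance explained in
the So et al. style: solve the baseline odds so that Hardy–Weinberg genotype
frequencies with multiplicative per-allele odds reproduce the population
prevalence, map the genotype penetrances to mean liabilities through the
inverse normal, and report the variance of those means (total liability
variance 1). The multiplicative allelic odds model is an explicit assumption.
Instrument strength is summarized by the mean F statistic,
$\overline{(\hat\gamma/\sigma_\gamma)^2}$.

## Estimators

* **Wald ratio**: $\hat\Gamma/\hat\gamma$, with delta-method SE. The default
  (`first_full`) keeps both first-order terms,
  $\sqrt{\sigma_\Gamma^2/\gamma^2 + \Gamma^2\sigma_\gamma^2/\gamma^4}$;
  `first_simple` drops the exposure term; `second` adds the cross term
  $\sigma_\Gamma^2\sigma_\gamma^2/\gamma^4$.
* **IVW**: the precision-weighted mean of the ratios with weights
  $\gamma_j^2/\sigma_{\Gamma j}^2$, identically weighted regression of
  $\Gamma$ on $\gamma$ through the origin. The default dispersion model is
  multiplicative random effects with the dispersion floored at 1 — the
  conventional "random-effects IVW" — so under homogeneity it coincides with
  the fixed-effect analysis and can only be more conservative otherwise; an
  additive DerSimonian–Laird variant is available. Confidence intervals are
  normal-theory.
* **Cochran Q**: $\sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$ against
  $\chi^2_{J-1}$, the heterogeneity screen for pleiotropy.
* **Weighted median**: the interpolated ratio at normalized centered
  cumulative weight 0.5; consistent while valid instruments carry more than
  half the weight. Its SE comes from a seeded parametric bootstrap
  (default 1,000 draws); `n_boot = 0` returns the point estimate alone. With
  the interpolation definition a single instrument holding just over half
  the weight pins the estimate near — not exactly at — its own ratio; exact
  equality would require the non-interpolated step definition, and we follow
  the interpolated one used in the field.
* **MR-Egger**: weighted least squares of $\Gamma$ on $\gamma$ with an
  intercept; the slope estimates $\beta$ under the InSIDE assumption and the
  intercept estimates the mean directional pleiotropic effect. Inference is
  t-based with $J-2$ degrees of freedom and multiplicative dispersion floored
  at 1.
* **Pleiotropy residual test (MR-PRESSO-style)**: the observed statistic is
  the weighted residual sum of squares about leave-one-out IVW slopes; its
  null distribution is built by parametric simulation (seeded, with +1/+1
  Monte-Carlo continuity so p-values are never 0 and have resolution
  $1/(n_{sim}+1)$). Per-variant squared residuals are compared with their own
  simulated distributions and Bonferroni-adjusted; because an outlier drags
  the observed leave-one-out slopes of *clean* variants while the simulated
  null does not (swamping), final outlier calls come from a second,
  decontaminated pass that recomputes slopes and the null without the
  first-pass flags. On clean data the second pass never triggers and the
  procedure reduces to the canonical single pass. The corrected estimate is
  by construction exactly the default IVW on the unflagged variants. Note
  the Bonferroni resolution bound: flagging anything at level $\alpha$
  requires $n_{sim} \gtrsim J/\alpha$ simulations.

For binary outcomes effects are log odds ratios throughout and are
exponentiated only at reporting time (`add_odds_scale()`); a 1-log-odds
increment corresponds to an $e \approx 2.72$-fold change in odds.

## Multivariable MR

For jointly modelled exposures — e.g. endophenotype clusters with
per-variant weights — `build_cluster_exposures()` forms one exposure column
per cluster as weight × variant effect (zero where a variant carries no
weight), optionally appending an adjustment trait (such as HbA1c) as an
extra exposure column; that realizes "adjusting for" as joint estimation
rather than effect subtraction, which we prefer because it keeps the
adjustment's own uncertainty in the design. `mr_mvmr_ivw()` then fits the
outcome effects on all exposure columns without intercept, weights
$1/\sigma_\Gamma^2$, multiplicative dispersion floored at 1, t inference with
$J-K$ degrees of freedom. With orthogonal instrument supports the fit
separates exactly into the univariable analyses.

## The analysis grid

`run_mr_grid()` executes exposure × outcome × analysis-variant cells
(variants are `primary` plus one per annotation-exclusion list, e.g.
erythrocyte-trait exclusions at `p < 0.001`, strict inequality). Cells fail
independently — an error is recorded in the `note` column and the grid
continues. Benjamini–Hochberg q-values are computed over the primary-method
(IVW) family within each analysis variant, the grouping we consider the
closest match to one reported figure or table; it is a deliberate choice the
user can override by re-running `bh_fdr()` over any other family. Tiers:
`fdr_significant` (q < 0.05), `nominal` (raw p < 0.05 but q ≥ 0.05), `null`.
Every instrument dropped anywhere (harmonization, exclusion lists, outlier
flags, zero exposure effects) appears exactly once in the attached audit
table with a reason. All randomness (median bootstrap, residual-test
simulations) derives from the single config seed through per-cell
substreams keyed by exposure, outcome, analysis and method, so a rerun is
byte-identical. Bidirectional analyses rerun the primary method with the
roles swapped, selecting reverse instruments at the relaxed
$p < 10^{-6}$ threshold conventional when the former outcome is a disease
GWAS with few genome-wide hits.

## The synthetic generator

`simulate_summary_stats()` draws, per variant: an allele frequency uniform on
`eaf_range`; a true exposure effect $\gamma \sim N(0, \tau)$; a direct
(pleiotropic) outcome effect $\alpha$ per model — none, balanced
($N(0,\psi)$), directional ($N(\mu_\alpha,\psi)$, InSIDE holding),
InSIDE-violating ($\alpha$ correlated with $\gamma$), or sparse outliers (a
fraction receiving an offset of `offset` × their outcome SE). Standard errors
scale as $1/\sqrt{2p(1-p)n}$; observed effects are normal draws about their
truths; the exposure and outcome samples are independent (two-sample
assumption, no overlap). Pleiotropic effects are defined in the
exposure-increasing orientation — the only frame where "directional" is
meaningful, since allele labelling is arbitrary — and applied with the sign
of the true exposure effect. Instrument ascertainment (`ascertain_p`) draws
the observed exposure effect from its marginal
$N(0,\sqrt{\tau^2+\sigma^2})$ truncated to the significance region and the
true effect from its exact conditional, which reproduces winner's curse
without rejection sampling. What the generator does **not** emulate: linkage
between instruments (LD enters only through the separate
`simulate_ld_block()` fixtures), sample overlap, population stratification,
liability-scale case/control sampling (binary traits are generated directly
on the log-odds scale), and heavy-tailed effect-size architectures. Passing
tests therefore demonstrate correctness of the estimators under their stated
sampling models, not robustness to those further features of real data.

## The study-shaped fixture

`study_shaped_fixture()` assembles a bundle shaped like a two-exposure ×
five-outcome diabetes–stroke MR study: a binary exposure with 289
significance-ascertained instruments at the effective sample size of a
74,124-case/824,006-control GWAS, a continuous exposure with 333 instruments
at n = 421,923, and binary outcomes at the case/control scales of large
stroke consortia (60,341/451,210 down to 1,545/1,481). True log odds ratios
per cell are fixed in the bundle's `truth` table. The exposure effect scales
were calibrated once, against the generator's ascertainment model, so the
selected instruments explain ≈12.7% of liability variance (binary exposure,
prevalence 8.5%) and ≈2.6% of trait variance (continuous exposure):
$\tau_{binary} = 0.0593$ log-odds, $\tau_{continuous} = 0.0022$ SD.

One instructive consequence is faithfully retained rather than engineered
away: 333 instruments explaining 2.6% at n = 421,923 implies a mean F
statistic near 33, barely above the genome-wide selection threshold
($z = 5.45$, F ≈ 30). Under a Gaussian effect-size prior most such
"significant" associations are substantially luck, so the fixture's
continuous-exposure IVW estimates are winner's-curse attenuated (about
0.55 on the log-OR scale), while the strongly instrumented binary exposure
(mean F ≈ 460) recovers its true effects essentially unbiased. This is a
real hazard of weakly instrumented two-sample MR, and the fixture makes it
visible.

## Numerical choices and degenerate inputs

Reported p-values are floored at 1e-320 so they satisfy the (0, 1] contract
through FDR. Variants with an exposure effect of exactly zero are excluded
(with a warning) before ratio estimation. A single instrument degrades IVW
to the Wald ratio with a note in the method label; fewer instruments than a
method's minimum (2 for IVW, 3 for median/Egger, 4 for the residual test)
yields a flagged empty grid cell. Clumping tie-breaks are fully
deterministic (p, chromosome, position, id), making selection
permutation-invariant. The liability solver uses `uniroot` on the baseline
log-odds over ±40 with tolerance 1e-12 and reports its inputs on failure.
Problem sizes used by the test suite and the acceptance script (e.g. 10,000
null replicates at J = 10 for calibration; 500 replicates per pleiotropy
regime at J = 100; 200 planted-outlier replicates at J = 20; brute-force
clumping checks at up to 12 variants) were chosen to keep Monte-Carlo error
well below the tolerances being asserted while the whole suite runs in
minutes.

## Known limitations

No proxy-variant lookup, genome-build liftover, or VCF parsing (delimited
text only); no LD computation from genotype panels; no mode-based,
MR-RAPS or Steiger-filtered estimators; no conditional F statistics for
multivariable MR; no sample-overlap correction. The residual-test outlier
procedure makes no claim of numerical identity with any published
implementation — it is validated by calibration and planted-truth recovery.
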