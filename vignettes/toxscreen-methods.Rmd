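---
title: "Methods: from well responses to hazard ranking, grouping, and margin of exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from well responses to hazard ranking, grouping, and margin of exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`toxscreen` implements a complete analysis path for multi-cell-type in vitro
hazard screening: plate-normalized concentration-response profiling with
one-standard-deviation benchmark points of departure (POD), ToxPi-style
integration into per-cell-type and overall prioritization scores,
unsupervised chemical grouping scored against a reference classing with the
Fowlkes-Mallows (FM) index, supervised chemical-class prediction under
repeated cross-validation, and margin-of-exposure (MoE) screening after
in vitro-to-in vivo dose conversion. A synthetic screen generator with known
ground truth accompanies every stage so the whole pipeline can be validated
without external data.

This vignette explains the models, the tunable parameters, and the design
choices made where more than one defensible option existed.

## The concentration-response model and the POD

Every chemical x phenotype series (all replicate wells, no pre-averaging) is
fit with the four-parameter Hill (logistic) model

$$ r(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
   {1 + (\mathrm{EC}_{50} / c)^{h}} $$

on log10 concentration, by bounded Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`). Bounds are EC50 in [1e-4, 1e4] uM and Hill slope in
[0.3, 8]; three starts seed the EC50 at the minimum, median and maximum
tested concentration and the lowest residual sum of squares wins. The fitted
curve is monotone by construction, so the benchmark crossing below is unique
when it exists.

Responses are expressed in percent of the plate-matched vehicle-control mean
(`normalize_to_vehicle()`), so the baseline is 100 and the vehicle standard
deviation $\sigma_v$ is on the same scale. The POD is the lowest
concentration at which the fitted curve departs from the baseline by one
vehicle standard deviation:

$$ \mathrm{POD} = \min \{ c : |r(c) - 100| = \sigma_v \}. $$

`derive_pod()` locates the crossing numerically (600-point log-grid scan
plus `uniroot()` refinement); the synthetic module's `analytic_pod()` inverts
the Hill function in closed form and serves as an independent oracle in the
tests. $\sigma_v$ is the *plate-matched, per-phenotype* vehicle SD: the
benchmark inherits exactly the normalization scope. A plate whose vehicle
wells are all identical ($\sigma_v = 0$) cannot define a benchmark and is
rejected rather than silently passed through.

Censoring and extrapolation rules:

* No crossing within the tested range: the POD is censored at the maximum
  tested concentration (100 uM by default), recorded, and later scored as 0
  bioactivity -- censored chemicals are never dropped.
* Extrapolation below the lowest tested concentration is allowed one decade
  (down to 1e-3 uM); a crossing below that floor is reported as
  "< lowest tested" (censored low) rather than an extrapolated number.
* If the optimizer fails on every start, the fit is flagged non-converged
  and the POD falls back to linear interpolation of concentration-wise mean
  responses in log10 concentration.

### The activity call

A fitted curve is only interrogated for a POD if the Hill model is
statistically supported over a flat (intercept-only) model by an F-test
(`hit_alpha = 0.01` by default in `fit_pod_table()`). Without this gate,
roughly one in seven truly flat series acquires a spurious benchmark
crossing at 10% well noise -- the bounded optimizer will happily trace noise
-- and those false calls land at arbitrary concentrations, contaminating
every downstream profile. The gate is the same practice as hit-calling in
large screening pipelines; setting `hit_alpha = 1` disables it. The test
suite verifies a false-call rate below 5% and that the gate costs little
power: weakly active curves whose asymptote barely clears the benchmark are
the ones censored, and their PODs would sit at the censoring bound anyway.

## Assay quality control

`qc_assay()` evaluates five plate-quality parameters per plate x phenotype:
CV% of each of two negative controls (vehicle and medium-only wells;
pass <= 15%), a Welch t-test for a difference between the two controls
(pass when *not* significant at alpha = 0.05), intra-plate replicate
correlation and inter-plate correlation (pass >= 0.8), and the EC50 of a
positive control inside a user-declared window. All thresholds are
configurable. A check whose data are absent (no medium wells, a single
plate, no positive-control expectations) is reported `NA` -- not-evaluable
is never converted to a silent pass.

## ToxPi integration

PODs are inversely scaled per phenotype onto [0, 1]: the lowest POD (highest
bioactivity) maps to 1, the highest to 0. Interpolation is done on the log10
scale by default (`scale_mode = "log10"`) because the tested concentrations
span five decades; linear mode is retained for sensitivity analysis. PODs
censored at the maximum tested concentration score exactly 0. A phenotype
with fewer than two distinct observed PODs cannot anchor a scale and is
scored all-0 with a warning.

Each cell type forms one ToxPi slice; the slice score is the unweighted mean
of its member phenotype scores, and the overall score is the equally
weighted mean of the five slice scores (weights configurable). Chemicals are
ranked by descending overall score with lexicographic tie-breaking, so the
ranking is reproducible. Useful invariants, all tested: scores stay in
[0, 1]; multiplying a phenotype's PODs by a constant leaves log10-mode
scores unchanged; lowering any single POD never lowers that chemical's
overall score.

## Grouping and the Fowlkes-Mallows index

`cluster_chemicals()` clusters chemicals from any chemicals x features
matrix -- scaled bioactivity profiles from this pipeline, external assay
matrices, or fingerprint bits -- using correlation distance ($1 - r$,
range [0, 2], deliberately not clipped) or Euclidean distance, with average
or Ward linkage. A constant feature vector has no defined correlation and
receives the maximal dissimilarity of 1 with a warning. The default cut is
k = 5, matching the number of reference classes, but k is free.

Correspondence between a k-group cut and the reference classing is the FM
index. With contingency counts $m_{ij}$, row sums $a_i$, column sums $b_j$
and $n$ chemicals:

$$ T_k = \sum m_{ij}^2 - n, \quad P_k = \sum a_i^2 - n, \quad
   Q_k = \sum b_j^2 - n, \quad B = T_k / \sqrt{P_k Q_k}, $$

so $B = 1$ exactly for identical partitions and 0 when no co-clustered pair
is shared. Under the null of uniform random relabeling,
$E[T_k] = P_k Q_k / (n(n-1))$, and the variance follows the closed-form
moments of the pair-count statistic; the one-sided p comes from the normal
approximation. Because closed-form higher moments are easy to transcribe
wrongly, the analytic mode is validated in the test suite against a
permutation oracle: the permutation-null mean of $B$ must sit within three
standard errors of the analytic expectation, and analytic and permutation z
statistics must agree within 15% for n >= 20. Permutation mode (relabel one
partition uniformly, `n_perm >= 999`,
$p = (1 + \#\{B_{perm} \ge B_{obs}\})/(n_{perm}+1)$) is the default in
`run_pipeline()` and is enforced for n <= 3 where the analytic moments
degenerate.

## Supervised class prediction

`repeated_cv_classify()` trains a random forest (500 trees, sqrt(p) features
per split -- the conventional defaults) under 5-fold cross-validation
repeated over 50 random splits. Folds are stratified per class when the
class has at least 5 members; smaller classes (the two phthalates) are
assigned to distinct random folds, which guarantees at least one training
instance everywhere -- a size-2 class cannot be stratified over 5 folds.
Predictions are made only on held-out folds and confusion counts are summed
over repeats, so each chemical contributes one prediction per repeat.
A class with a single member is an error with instructions to merge or drop.

`permutation_baseline()` re-runs the full cross-validation under uniformly
permuted labels to produce a null accuracy distribution and an exceedance p.
`feature_importance()` measures, for every feature, the mean drop in
held-out accuracy when that feature is shuffled within the test fold --
an out-of-sample, model-agnostic permutation importance (the in-training
impurity importance would not be comparable across feature types). Constant
features score exactly 0; ties rank lexicographically.

## Margin-of-exposure screening

The per-chemical surrogate POD is the most sensitive (minimum) POD over the
phenotypes in scope -- one cell type or all cell types combined; the
all-cell-types surrogate is by construction never larger than any
single-cell-type surrogate. Censoring propagates: an all-censored chemical
yields a censored surrogate that downstream stages treat as a lower bound.

Dose conversion assumes linear toxicokinetics: with a supplied
steady-state-concentration factor $C_{ss}$ (uM per 1 mg/kg/day, typically an
upper-95th-percentile variability value), the administered equivalent dose
is $\mathrm{AED} = \mathrm{POD}_{\mu M} / C_{ss}$. The factors are an input
table: the package consumes precomputed toxicokinetic outputs and does not
model toxicokinetics itself. A packaged table
(`synthetic_tk_table()`, 16 chemicals) carries order-of-magnitude plausible
*synthetic* values so the risk stage is exercisable offline; it is labeled
synthetic in both filename and documentation and supports no substantive
conclusion.

$\mathrm{MoE} = \mathrm{AED}/\mathrm{exposure}$, with "potential concern"
flagged strictly below the benchmark of 100 (an MoE of exactly 100 is not
flagged); zero exposure gives an infinite, unflagged MoE. For censored
surrogates the MoE is a lower bound; the default conservative mode still
flags a bound below 100, and `conservative = FALSE` defers instead.
`conservatism_comparison()` summarizes NAM-vs-in-vivo POD ratios on the
log10 scale with the fraction unconservative (NAM strictly above in vivo)
and, among those, the fraction within 10-fold. Units are declared
(`mg/kg/day` everywhere on the dose scale, uM on the concentration scale)
and a mismatch raises rather than guesses. Chemicals missing any required
field are excluded pairwise per comparison, with a message reporting counts.

## The synthetic screen generator

`simulate_screen()` emulates the screen the analysis assumes: 42 chemicals
in five classes, five cell types carrying 41 phenotypes (5 hepatocyte, 10
neuron, 9 cardiomyocyte, 8 endothelial, 9 HUVEC -- the per-cell-type assay
lists), five log-spaced concentrations (100, 10, 1, 0.1, 0.01 uM), three
treated replicates, and 16 vehicle plus 16 medium control wells per plate
and phenotype (medium wells included by default so all five QC parameters
are evaluable; set `n_medium_wells = 0` to disable). Treated wells are Hill
responses plus independent Gaussian noise (default `noise_sd = 10`% of
control); control wells are N(100, noise_sd). Potencies are drawn on log10
EC50 -- the tested range spans five decades, so a normal on the log scale is
the natural family. Per-chemical and per-stage random substreams are derived
from one master seed by counter-based mixing, so any subset of the screen is
reproducible on its own.

The default class signatures are deliberately well separated, because their
job is to provide ground truth that downstream stages should recover almost
perfectly; failure to do so then indicates a pipeline defect rather than an
ambiguous simulation:

* inorganic substances: active in every cell type with a graded potency
  pattern (hepatocytes strongest, mean log10 EC50 -2.0, down to
  cardiomyocytes at +0.8) so class members share a profile *shape* --
  a uniformly flat profile would carry no signal under correlation distance;
* pesticides: cardiomyocyte-selective (mean log10 EC50 -1.0 there, 5%
  background activity elsewhere);
* PAHs: hepatocyte- and neuron-active;
* other industrial chemicals: endothelial-selective;
* phthalates: HUVEC-selective.

Within-class spread is sd 0.2-0.3 in log10 EC50 per phenotype plus a
chemical-level potency shift of sd 0.15 shared across all of a chemical's
phenotypes. Efficacies are uniform on 35-65% of control, Hill slopes uniform
on 0.8-3, and 70-85% of responding phenotypes decrease rather than increase.

What the generator does *not* emulate -- and therefore what passing tests do
not establish about real screens: correlated noise within plates or between
related phenotypes, edge effects and other spatial plate artifacts,
non-monotone (e.g. hormetic) responses, cytotoxicity-driven signal loss in
functional channels, solubility or volatility failures at high
concentration, and real chemicals' potencies. Results on synthetic data
validate the *arithmetic and statistical machinery*, not the biology.

## Problem sizes and numerical choices

The validation suite runs the full default screen (42 chemicals x 41
phenotypes, 10% noise) end to end for the planted-recovery checks, with the
supervised stage at 5 folds x 50 repeats for the observed accuracy and a
99-permutation label null computed under a lighter 5-repeat scheme -- the
null mean is unaffected by the repeat count and its slightly wider spread
only makes the exceedance check harder to pass. POD oracle equivalence is
checked on 1000 random curves at 1e-3 relative tolerance; FM pair-counting
is checked exactly against brute-force pair enumeration for n <= 12.
Root-finding uses a 600-point log grid with `uniroot()` refinement
(tolerance 1e-10); linkage ties follow `stats::hclust`'s deterministic
ordering; ranking and importance ties break lexicographically. All tables
are comma-delimited UTF-8 with dot decimals; concentrations are always uM
and doses always mg/kg/day.

## Known limitations

* The 1-SD benchmark ties the POD to plate noise: cleaner plates give lower
  PODs for the same curve. That is inherent to the definition, and it is why
  the vehicle SD is always reported alongside the POD.
* The activity gate trades a small loss of sensitivity near the benchmark
  for a large specificity gain; with very few replicates (< 2 per
  concentration) the F-test loses power and `hit_alpha` may warrant
  loosening.
* Analytic FM moments use a normal approximation; for small n or extremely
  unbalanced partitions use the permutation mode (the pipeline default).
* The linear dose-to-Css assumption ignores saturable kinetics; it is the
  standard screening-level simplification and the conversion factors are
  inputs, so any better factor set can be supplied.
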