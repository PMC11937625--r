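---
title: "Measuring the replicability of differential abundance methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the replicability of differential abundance methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daareplic)
```

## The evaluation model

Differential abundance analysis (DAA) asks, taxon by taxon, whether
abundance differs between two groups of microbiome samples. Because
sequencing counts are compositional, zero-heavy and overdispersed, methods
disagree substantially, and real data offer no ground truth to arbitrate.
This package evaluates methods by *internal consistency* instead. Two
protocols are implemented:

* **Split-data** (`evaluate_split()`): a dataset is split at random into
  two equal halves, stratified by group; one half generates hypotheses
  (exploratory), the other re-tests them (validation). Any systematic
  disagreement between halves is attributable to the method, since both
  halves sample the same population.
* **Separate-study** (`evaluate_cross()`): datasets from different studies
  of the same condition serve as exploratory and validation sets. Here
  disagreement mixes method error with genuine between-study differences,
  so these results characterize expected replicability in practice rather
  than method correctness.

A taxon is a **candidate** when its FDR-adjusted q-value falls below the
nominal level α in the exploratory dataset and it survives prevalence
filtering in the validation dataset. Candidates classify as *replicated*
(validation P < .05, same nonzero direction), *conflicting* (validation
P < .05, opposite direction), or *not validated*. Directions are signs of
the effect estimate, positive meaning more abundant in cases. All pooled
percentages sum numerators and denominators across exploratory/validation
pairs before dividing; averaging per-pair percentages would weight a
two-candidate pair as heavily as an eighty-candidate pair and is
deliberately not done.

### The ideal Conflict% bound

In split-data evaluation a conflicting result requires a false result in
one of the halves. Under FDR control at level α, at most a fraction α of
candidates are false discoveries in expectation. A false (null) candidate
is significant in the independent validation half with probability 0.05
(the unadjusted cutoff) and, being null, lands on the opposite direction
with probability 0.50. Multiplying gives the approximate upper limit

> ideal Conflict% ≤ α × 0.50 × 0.05,

i.e. 0.025%, 0.125%, 0.25% and 0.50% at α = 0.01, 0.05, 0.10 and 0.20
(`ideal_conflict_bound()`). Note the factor α presumes that most
candidates are *true* positives. On global-null data every candidate is a
false discovery, so the conflict rate among candidates converges to the
conditional factor 0.50 × 0.05 = 2.5% rather than to the bound itself; the
test suite therefore checks the bound's *derivation* on null data (the
2.5% conditional rate, via a binomial bound on the observed conflict
count) rather than naively comparing a near-empty candidate set against
α × 0.125%.

### Confidence-interval overlap

Two independent (1−γ) Wald intervals for the same normally-estimated
quantity with equal standard errors overlap when |z₁ − z₂| ≤ 2·z(γ/2),
and (z₁ − z₂)/√2 is standard normal, so 83.4% intervals overlap with
probability ≈95% (`ci_overlap_normal_mc()` verifies this by simulation).
CI% is the observed overlap fraction over candidates with at least 10%
prevalence in both experimental groups; intervals are treated as closed,
so touching endpoints count as overlap (a measure-zero convention fixed
for exactness on discrete grids). Unequal standard errors make overlap
*more* likely, so 95% is effectively a floor for well-behaved estimators.

### Pooled estimate correlation

Per pair, the Spearman correlation between exploratory and validation
estimates is computed over all shared (filtered) taxa — not candidates
only, which would condition on significance; a candidates-only variant is
available by subsetting the result tables. Correlations are pooled on the
Fisher z scale, tanh(mean(atanh(ρ))); magnitudes of exactly 1 are clipped
to 1 − 10⁻¹² before the transform, and pairs with fewer than three shared
taxa are skipped with a message.

## The elementary methods

All methods receive the prevalence-filtered dataset; normalization is
recomputed on the retained taxa (proportions over the filtered
composition). Filtering removes taxa with prevalence strictly below the
threshold — a taxon at exactly 10% is retained.

* **`orm`** — proportional-odds (cumulative logit) regression treating
  each distinct TSS proportion as an ordered category, ties sharing a
  category. Its score test for the two-group comparison is exactly the
  Wilcoxon rank-sum test (with tie correction); the package reports Wald
  inference, which tracks the large-sample Wilcoxon P-value within about
  10% relative difference for P > 10⁻⁴ and within about a quarter order
  of magnitude in the far tail. The effect estimate is the group log odds
  ratio.
* **`linear_logtss`** — OLS of log(proportion + pseudocount) on group and
  covariates; exactly the pooled-variance t-test with no covariates. The
  default pseudocount is half the smallest nonzero proportion in the
  matrix (the convention of the MaAsLin2-style analysis this mirrors);
  per-sample and fixed-constant policies are selectable. The estimate is
  the log fold-change of relative abundance.
* **`logr`** — logistic regression of presence (count > 0) on group and
  covariates; the estimate is the log odds ratio of presence.
* **`nb_glm`** — per-taxon negative binomial regression on raw counts
  with log library-size offset. This is a deliberately naive foil:
  unmoderated per-taxon NB regression is anti-conservative on microbiome
  data (its null P < .05 rate runs above 5% in the package's own
  calibration checks), which makes it a useful contrast for the
  consistency metrics. Its output is reported, never asserted as correct.

### Numerical choices in the ordinal fitter

The number of ordinal categories approaches the sample size, a regime
where generic ordinal-regression fitters that quasi-Newton over all
thresholds are slow or unstable. The package fits the cumulative-logit
likelihood by full Newton–Raphson with analytic gradient and Hessian
accumulated in vectorized form (the threshold block of the Hessian is
tridiagonal), starting from the empirical cumulative logits with a zero
slope, with step halving whenever a step would leave the ordered-threshold
region or decrease the likelihood. Convergence is declared on a relative
log-likelihood change below 10⁻⁸ (30 halvings, 50 iterations maximum).
Under complete separation the group-effect MLE is infinite; the likelihood
plateaus, the fit stops at a large finite estimate with a large standard
error, and the sign — the quantity the protocols use — is correct. The
fitter agrees with `MASS::polr` to at least four decimals on
moderate-category problems (it is cross-checked against it in the test
suite), while remaining fast at one category per sample.

### Degenerate cases

A taxon with all-tied values (e.g. absent everywhere) is reported with
status `degenerate`, estimate 0, P = 1, and never counts as replicated or
conflicting. For `logr`, a taxon present in every sample, absent in every
sample, or with 0%/100% presence within a group (separation of the
likelihood) is degenerate rather than Firth-corrected — keeping the method
elementary; such taxa are rare after prevalence filtering. Non-converged
fits are `failed` and excluded downstream with the counts logged.
Estimates at floating-point noise (|estimate| < 10⁻¹⁰) get direction 0.

## The synthetic-data generator

Real benchmark collections are large and external; the generator supplies
their statistical shape with a known truth. Baseline mean relative
abundances are Dirichlet (normalized gamma) with shape 0.2, giving the
heavy-tailed few-dominant-taxa profile of gut profiles; a fraction of taxa
(default 10%) receives a case-group multiplier exp(±effect) with random
sign, after which the composition is renormalized — so the planted truth
is a *relative*-abundance effect, and `truth$true_rel_log_fc` records the
realized log fold-change including the shared renormalization offset.
Library sizes are uniform on 2,000–20,000 reads and counts are
gamma-Poisson with dispersion 4 (variance μ + 4μ²). Under the defaults a
100-taxon, 100-sample dataset has roughly half its entries zero, median
taxon prevalence near 0.6, and ~80–90 taxa surviving the 10% filter —
inside the 36–276 post-filter taxon range of typical curated human gut
collections. Zero inflation is implicit (low means plus overdispersion); a
`dropout_prob` adds explicit dropout for prevalence stress tests.
Covariates act multiplicatively on the log scale on a random subset of
taxa and can be correlated with the group to induce confounding.

What the generator does **not** emulate: taxon-wise measurement bias of
sequencing workflows, 16S-versus-shotgun platform differences, absolute
abundance shifts (the data are strictly compositional by construction),
and real phylogenetic correlation structure. Passing the package's checks
on these conditions therefore demonstrates internal correctness and
calibration of the machinery — not that any method is robust to those
real-data phenomena.

## Test conditions and their rationale

The suite's stochastic checks fix seeds and use the following problem
sizes, chosen to give tight Monte Carlo error at desk scale:

* *Null calibration*: 200 global-null datasets of 100 taxa, 50+50 samples;
  each elementary method's pooled unadjusted P < .05 rate must fall in
  4–6%. Split-data conflicts on 60 null datasets are bounded by a 99.9%
  binomial envelope at the 2.5% conditional conflict rate discussed above.
* *Ordinal/Wilcoxon correspondence*: ≥100 taxa simulated with low
  dispersion and deep libraries so all proportions are distinct — the
  condition under which the score test is exactly the rank test.
* *CI overlap*: 100,000 simulated normal pairs at the 83.4% level.
* *Effect recovery*: sign recovery of planted effects (magnitude 1.5 log
  units, 100+100 samples) under the default zero-heavy conditions;
  interval coverage (95% ± 3 points) under abundant-taxon, low-dispersion
  conditions where the log-linear estimand equals the planted
  relative-abundance effect. Under zero-heavy conditions the pseudocount
  floor attenuates estimates of low-prevalence taxa toward zero, and
  coverage of the planted value degrades accordingly (to roughly 75–80%
  pooled over all differential taxa in internal measurements) — a known
  limitation of pseudocount-based log-linear analysis, not of the interval
  construction.

## Other design decisions

* Splits are stratified by group; with odd group sizes the extra sample
  goes to the exploratory half. The minimum of 10 subjects per group per
  half is enforced, refusing to split rather than silently producing
  underpowered halves.
* In multi-validation (separate-study) pairs, a candidate counts as
  replicated if it replicates in ≥1 validation dataset and conflicting if
  it conflicts in ≥1; a candidate doing both increments both numerators
  over a single-candidate denominator and is reported in `n_double`. A
  first-validation-wins alternative is available via `aggregation`.
* Validation significance uses unadjusted P < .05 by default; a BH
  variant over the candidate set is behind `validation_adjust = "bh"`.
* `calibrate_alpha_for_nhits()` searches the grid of observed q-values
  (where NHits steps), so an exact target hit count is attained whenever
  the grid allows — enabling equal-sensitivity comparisons of methods.
* All randomness flows from explicit seed arguments (restored afterwards
  via `withr`); pipeline stages derive fixed offsets from the single
  configured seed, recorded in the run manifest.

## Limitations

Only the two-group design with optional covariates is supported; ordinal
or continuous exposures are not. The elementary methods are fit per taxon
with no information sharing, so they are slower and less powerful than
moderated frameworks at very small n. The separate-study pairing assumes
condition labels are comparable across studies; no attempt is made to
harmonize taxonomies beyond exact taxon-id matching.
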