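---
title: "Methods: TAI grading, synthetic cohorts, and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TAI grading, synthetic cohorts, and model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(taigrade)
```

## The problem

MRI detects traumatic axonal injury (TAI) that CT misses, and the anatomical
distribution of TAI — which region, which subregion, unilateral or bilateral,
and on which pulse-sequence family it is conspicuous — predicts long-term
functional outcome in critically ill TBI patients. Several rule-based grading
systems condense a patient's lesion pattern into an ordinal grade. `taigrade`
implements four of them, a simulator of cohorts with the published marginal
structure, and the statistical machinery used to derive and compare such
systems against the core clinical predictors (age, admission GCS, pupillary
light responsiveness) and the Rotterdam CT score, with the dichotomized
Glasgow Outcome Scale (unfavorable = GOS 1–3) as the outcome.

## Lesion representation

A lesion observation is a binary indicator at a *site*: (region, subregion,
laterality, sequence family). Seven regions are modelled — basal ganglia,
corpus callosum (trunk / splenium / genu-rostrum), posterior limb of the
internal capsule, midbrain (tegmentum / tectum / cerebral peduncles /
unspecified), pons (ventral / dorsal / unspecified), subcortical white
matter, and thalamus — crossed with three sequence families: DWI, FLAIR, and
the susceptibility-sensitive family pooling SWI and T2\*GRE. The corpus
callosum is midline, so its laterality is `not_applicable`; 75 valid sites
result. Lesions are present/absent only: no volumes, no signal intensities.

## The grading engines

All four systems are evaluated across the three sequence families; on
disagreement the most severe grade wins, grades are mutually exclusive, and
additional qualifying lesions within a grade never change it. Patients
matching no rule receive grade 0 (Adams, Firsching, Abu Hamdeh), while the
Stockholm system's grade I is the exhaustive fallback — it covers both
lesion-free patients and those with TAI only in regions its grades II–IV do
not name (e.g. basal ganglia).

Design choices where the published rules leave room:

* **Substantia nigra** is not a separate site; Abu Hamdeh grade IV accepts
  any midbrain-tegmentum lesion on the susceptibility family. Anatomically
  the substantia nigra lies in the tegmentum, and the available region
  checklist resolves no finer.
* **Age exactly 30** for the Abu Hamdeh strata ("<30" vs ">30" leaves 30
  unassigned) falls in stratum *b*.
* **Pontine subregions** (ventral/dorsal) are ignored by every grading rule —
  only laterality matters — but retained for the severity table.
* **Adams "hemispheric"** is interpreted as subcortical/lobar white matter,
  basal ganglia, internal capsule, and thalamus: the MRI adaptation of a
  histopathological system groups deep grey lesions nowhere else.
* **Firsching on an empty lesion map** returns 0, not I: "supratentorial
  lesions only" presupposes at least one lesion.
* **`swi_available`** is kept in the Abu Hamdeh interface for fidelity, but
  since SWI and T2\*GRE are pooled into one susceptibility family it does not
  alter the result.

The engines are validated two ways: exhaustively over all one- and two-site
lesion maps (monotonicity — adding a lesion never lowers any grade — and
equivalence with an independent declarative rule-table interpreter), and on
2,000 random multi-site maps.

## The synthetic cohort generator

The generator is calibrated once to the published tables and its defaults are
the package's study conditions.

**Latent severity.** Each patient carries a scalar z ~ N(0, σ²), σ = 1.6 by
default. One latent factor is the most parsimonious mechanism that reproduces
the published phenomenology — multifocal co-occurring lesions and covariates
that worsen monotonically with lesion grade — given that no lesion
correlation matrix is published.

**Lesions.** Site s is present with probability logit⁻¹(aₛ + δ + z). The
intercepts aₛ are solved by quadrature so each site's marginal prevalence
matches the published per-sequence lesion counts (n/351); rows reported by
subregion and laterality separately are split 70/30 unilateral/bilateral. The
shared offset δ is then solved so that P(at least one lesion) equals the TAI
prevalence target (default 0.73, the published detection rate). With σ = 1.6
these two calibrations also reproduce the published overall unfavorable
fraction (183/351 ≈ 0.52) without further adjustment.

**Covariates.** Gaussian copulas tie the covariates to standardized severity:
GCS (marginal over 3–15 with median 4, IQR 3–7; ρ = 0.60 toward low scores),
pupillary response (70.8 / 9.9 / 19.2% responsive / unilaterally /
bilaterally unresponsive; ρ = 0.60), Rotterdam CT score (1–6, unimodal
marginal chosen as typical for an ICU TBI population since the source prints
no margin; ρ = 0.55). Age is truncated normal (mean 43.8, SD 18.6, range
15–82) with a mild negative severity coupling (ρ = −0.35): high-energy
trauma skews younger, and a weakly predictable age is also what makes
regression imputation meaningfully testable. Scan delay is log-normal
(median 7 days, IQR ≈ 4–13), truncated to 0–28 days.

**Outcome.** The Stockholm grade is computed from the generated lesions, and
unfavorable outcome is drawn Bernoulli with the published grade-conditional
probabilities (28/40/74/97% for I–IV) — these are the generator's ground
truth; the per-site severity percentages serve only as a qualitative check,
since the joint lesion distribution is not published. GOS levels are then
assigned within the unfavorable (1:2:3 = 38:9:136) and favorable (4:5 =
106:62) strata, matching the published outcome distribution; only the
dichotomy matters downstream.

**Detectability decay.** Non-hemorrhagic TAI fade from MRI as the injury
ages. `apply_detectability_decay()` retains each lesion with probability
exp(−rate · delay), with default daily rates 0.08 (DWI) > 0.04 (FLAIR) >
0.01 (susceptibility). The generator's base rates already describe *observed*
lesions (the published counts are post-delay), so decay is a separate
transformation, not part of `generate_cohort()`; whether delay interacted
with outcome in the real cohort is unreported, and here decay affects
detection only.

**Missingness** is masked completely at random, covariates only (default
4%), because the source does not characterize its missingness mechanism.

What the generator does *not* emulate: lesion volumes, inter-site correlation
beyond one factor, direct covariate–outcome effects (outcome depends on
covariates only through severity via the grade), selection into MRI referral,
or the real cohort's effect magnitudes. Tests passing on synthetic data
therefore demonstrate pipeline correctness and directional behavior, not
real-data performance numbers.

## Derivation: GA and random forest

The cohort is split 2/3–1/3 stratified by outcome. Feature selection runs a
generational genetic algorithm over binary inclusion vectors: tournament
selection (size 3), uniform crossover (rate 0.8), per-bit mutation (1/L),
elitism (2), population 50 × 40 generations by default — standard GA practice,
config-exposed, since the original hyperparameters are not published. The
population is seeded with the empty and all-features chromosomes, so the
best-ever result is bounded below by both, and elitism makes the best fitness
non-decreasing (asserted exactly in tests).

Fitness is the desirability D = √(d_auc · d_size) of a 5-fold stratified
cross-validated logistic-regression AUC: d_auc = max(0, (AUC − 0.5)/0.5),
d_size = exp(−λk), λ = 0.1. The functional form is this package's
construction (the original is described but not specified): geometric mean of
two [0, 1] desirabilities, zero at chance discrimination, strictly increasing
in AUC and decreasing in model size. Logistic CV fitness — rather than
refitting the random forest each generation — keeps the selection objective
smooth and desk-scale fast, and matches the published separation between GA
selection and RF validation. CV folds are fixed once per run, so fitness is a
deterministic function of the chromosome and can be cached; `ga_select()` is
fully reproducible given its seed, and `exhaustive_select()` with the same
seed evaluates all 2^L subsets under identical folds, giving an exact
optimality benchmark for L ≤ ~12.

`rf_validate()` trains two forests (core + selected TAI features; core only)
on the training partition and compares held-out AUC; Gini importances come
from the full forest. The judgment step by which thalamic TAI was added to
the published system post-GA is not modelled; pass any forced features
directly to `rf_validate()`.

## Evaluation battery

Fifteen logistic models are fitted (each system alone; core; Rotterdam;
core + system; core + Rotterdam; core + Rotterdam + system), reporting
Nagelkerke pseudo-R², AIC, and AUC, plus likelihood-ratio tests of each
system's addition to core + Rotterdam and pairwise DeLong tests among the
four single-system models.

Choices where the published analysis is silent:

* **Grades enter as one ordinal integer** (0–IV) per system — the published
  battery adds one predictor per system and treats grades as an escalating
  scale; dummy coding is available via `grade_coding = "factor"`.
* **Rotterdam CT score** enters as ordinal, for the same reason.
* **DeLong comparisons** use the univariate system models (the alternative —
  full multivariate models — is a config switch away, by fitting those models
  and calling `delong_test()` directly).
* **Two-sided tests** throughout; ties in the AUC receive half-credit.
* **Perfect separation** in a logistic fit is flagged with a warning rather
  than silently reported; coefficients from a separated fit are unstable but
  fitted probabilities and the log-likelihood remain usable for AUC/LRT.
* No multiple-testing correction across the DeLong matrix (none was applied
  in the source analysis).

The DeLong variance uses midrank placements; when both score vectors are
identical the variance degenerates and the test returns p = 1 with a
warning. The implementation is verified against an explicit ψ-matrix
evaluation, against `pROC`'s DeLong test (z, p, and single-curve variance),
and against a 20,000-replicate stratified-bootstrap AUC-difference oracle.
The Cochran–Armitage trend statistic is checked against both
`stats::prop.trend.test` and a 50,000-replicate permutation oracle; the
likelihood-ratio test's type-I error is verified to sit in [0.04, 0.06] over
2,000 null replicates at n = 300.

## Imputation

`impute_chained()` is a deliberately lightweight chained-equations imputer:
random-draw initialization from each covariate's observed values, then ten
cycles in which every incomplete covariate is regressed on the other
covariates plus the dichotomized outcome — linear for continuous/ordinal
(age; GCS and Rotterdam rounded and clipped to range), one-vs-rest logistic
for categorical (pupils) — with missing cells replaced by the model
prediction. Predictive-mean updates (no posterior draws, no predictive-mean
matching) make the completed data deterministic given the seed and minimize
cell-level error, which is the relevant property here: imputation is
peripheral plumbing, not an inferential step, and single-imputation variance
understatement does not affect the package's claims. Observed cells are
never modified.

## Numerical choices

* Latent-severity integrals (site intercepts, prevalence offset) use a
  241-point probability-weighted grid over ±6σ with `uniroot` to 1e-9.
* All randomness flows from one seed; pipeline stages draw from named
  substreams (`derive_seed(seed, stage)`), and every generator restores the
  caller's RNG state.
* Degenerate configurations short-circuit: prevalence target 0 yields
  lesion-free grade-I cohorts; zero decay rates are the identity; rate-0
  missingness returns the input unchanged.

## Problem sizes

The test suite and acceptance script run at sizes chosen for a desk-scale
reproduction: 20,000 draws per grade for outcome calibration, 10,000-patient
cohorts for prevalence margins, n = 3510 (ten times the reference cohort)
for the direction of the headline model comparisons, n = 400–1,000 with 6–8
candidate features for GA-vs-exhaustive benchmarks, and 2,000–50,000
replicates for the simulation oracles.

## Limitations

The published real-data magnitudes (AUC 0.72, pseudo-R² 0.21, the Table-5
cells) are not reproducible from this package because the patient data are
not deposited; the synthetic cohort reproduces directions and calibration
targets, not effect sizes. The latent-factor lesion model is our
construction; the true joint lesion distribution, the exact region checklist,
and the original GA hyperparameters are unavailable. Grading assumes a single
expert reading per patient — inter-rater variability is out of scope.
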