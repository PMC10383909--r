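---
title: "QSPR modeling and Pareto screening of heavy-metal chemosensor ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSPR modeling and Pareto screening of heavy-metal chemosensor ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsprscreen)
library(dplyr)
```

## The problem

Fluorescent chemosensors and ion-selective membranes detect heavy-metal
ions (Cd²⁺, Cu²⁺, Pb²⁺) in water through metal–ligand complexation. Two
experimental quantities summarize how useful a ligand is as a sensor
component: the **stability constant** of the 1:1 complex, modeled on the
log10 scale as logβ = log₁₀([ML]/([M][L])), and the **potentiometric
sensitivity** (PS, mV per decade of ion concentration), the slope of the
electrode calibration curve. Measuring either requires synthesis and
potentiometric characterization, so quantitative structure–property
relationship (QSPR) models that predict both from computed molecular
descriptors make virtual screening of candidate ligands possible.

This package implements that modeling workflow end to end: descriptor
cleaning, multiple linear regression (MLR) with genetic-algorithm (GA)
descriptor selection under the QUIK collinearity rule, a full
internal/external validation battery, a leverage applicability domain,
a bank of six published predictive equations (one per metal × property),
AdaBoost.R2 and simple nonlinear alternatives with a pluggable adapter
for external regressors, and Pareto-consensus screening of enumerated
candidate libraries.

## Data model

Everything tabular is an ordinary tibble with a light column contract:
`compound_id` (unique), optional `smiles`, optional `split`
(`"train"`/`"test"`), one numeric response column named by the caller,
and numeric descriptor columns everywhere else. Descriptor names are
opaque labels — Dragon-style names such as `H_D/Dt` or `B06[C-O]` pass
through untouched, and the pipeline never interprets their chemistry.
Fitted models, validation reports, GA runs and domain assessments are
small S3 objects with `tidy()`/`glance()`/`autoplot()` methods, so the
whole workflow composes with dplyr pipes.

## Preprocessing

Descriptor matrices computed from structure generators are wide and
redundant, so cleaning precedes everything:

* `remove_near_constant()` drops columns with sample standard deviation
  strictly below 0.1 (the threshold is a strict inequality; a column at
  exactly 0.1 survives).
* `remove_correlated()` drops, scanning pairs in table order, the later
  column of any pair with |Pearson r| strictly above 0.95. Published
  descriptions of this cleaning protocol are silent on which member of
  a correlated pair to discard; the order-based rule is our choice,
  made for determinism, and documented here rather than hidden. Correlation with
  the response is deliberately not consulted, which keeps the filter
  unsupervised and leakage-free.
* `fit_scaler()` / `apply_scaler()` implement standard scaling
  x = (X − X̄)/s with the sample (n−1) standard deviation. Scalers are
  fitted on the training split only and applied with those training
  statistics to any other table — scaling the test set by its own
  statistics would leak information.
* `split_dataset()` assigns train/test labels by simple random sampling;
  the test size is n·fraction rounded half away from zero (a rule had to
  be picked; this one is symmetric and documented).

Both filters are idempotent, and running the near-constant filter first
guarantees the correlation filter never meets an undefined correlation.

## The regression core

Models are ordinary least squares with intercept,
Y = α₀ + α₁X₁ + … + αₚXₚ, solved by rank-revealing QR (relative rank
tolerance 1e-10) rather than the normal equations; rank deficiency is an
error that names the collinear columns rather than a silent dropped
term. Leverages h_i = x_iᵀ(XᵀX)⁻¹x_i are computed through the same QR
factor with the descriptor vector augmented by a leading 1, which makes
the applicability-domain threshold h* = 3p′/n (p′ = number of model
variables + 1) internally consistent: the mean training leverage is
exactly p′/n.

### The published equation bank

`published_models()` loads six transcribed equations — logβ and PS
models for each of Cd²⁺, Cu²⁺ and Pb²⁺ with 6, 11, 5, 7, 6 and 7
descriptors respectively. Two transcription decisions matter:

* The printed source carries typesetting damage in four descriptor
  names (trailing "?" characters); they are stored under the standard
  Dragon block names `B06[C-O]`, `DLS_01`, `LLS_01` and `Eta_F_A`.
* The original training scaling statistics (per-descriptor means and
  standard deviations) were never published, so the bank's contract is
  that **inputs are already standard-scaled**. Evaluating any bank model
  at the all-zero vector — the training centroid in that space — returns
  its printed intercept. Whether the printed coefficients apply to
  scaled or raw descriptors is not stated explicitly in the source; we
  adopt the scaled reading because the source normalizes its data before
  training, and we record it as an assumption.

## GA descriptor selection and the QUIK rule

`ga_select()` evolves descriptor-membership bitmasks: tournament
selection of size 2, uniform crossover (rate 0.8), per-gene bit-flip
mutation (rate 0.05), elitism of 1, population 100, at most 500
generations. These mechanics are not prescribed by the source workflow
(which names only "crossover, mutation"); they are standard,
reproducible choices. Fitness is Q²LOO by default (adjusted R² is
available). Two feasibility rules apply, and infeasible chromosomes
score −∞ rather than being repaired:

* **Size rule**: 5·|subset| ≤ n_train, the usual
  observations-per-variable guard against overfitting.
* **QUIK rule**: the model is rejected when K_XY − K_XX < δK
  (default δK = 0.05). K is Todeschini's multivariate correlation index
  — with λ_j the eigenvalues of the column correlation matrix,
  K = Σ|λ_j/Σλ − 1/p| / (2(p−1)/p) ∈ [0, 1] — computed for the
  descriptor block alone (K_XX) and the block augmented with the
  response (K_XY). The source names the rule but not the K formula; the
  eigenvalue form implemented here is the one used throughout the
  QSARINS lineage of QSAR software.

Evolution stops when at least 90% of a generation shares the best
fitness (mirroring the convergence behaviour the source reports) or
when generations are exhausted. The source also reports ">10⁵
iterations" without defining the unit; we deliberately stop on
convergence, not on an iteration count. After evolution, the top
subsets undergo deterministic backward elimination: a member is dropped
whenever removal does not lower the fitness (compared at 1e-10), so
redundant descriptors that ride along with a perfectly fitting core are
trimmed and ties resolve towards parsimony. The whole run is a pure
function of its seed.

## The validation battery

For a model on a split dataset, `validate_model()` assembles:

* **Fit**: R², adjusted R², the Friedman lack-of-fit score
  LOF = (SSE/N)/(1 − λ(c + d·p)/N)² with safety factor λ = 1 and
  smoothing parameter d = 1 (both configurable). The printed form of
  this equation in the source is typographically corrupted; the
  implementation is the standard Friedman form, the closest well-formed
  reading of the printed symbols.
* **Significance**: the source calls for an "F-test of the LOF" without
  defining one (a classical lack-of-fit ANOVA needs replicate design
  points, which descriptor data do not have). We report the global
  regression F-test, F = (SSR/p)/(SSE/(N−p−1)) with its p-value,
  alongside the LOF score, and note the divergence here. The source's
  printed p-values are not treated as reproduction targets for the same
  reason.
* **Internal**: Q²LOO by the PRESS shortcut e_i/(1−h_i), algebraically
  identical to n explicit refits (and tested against them); Q²LMO with
  70% retained over 2000 iterations by default, where each iteration's
  denominator uses the retained-subset mean — the conservative choice,
  stated because the source is silent; Y-randomization over 2000
  permutations by default, refitting the fixed descriptor subset
  against scrambled responses and recording R², Q²LOO and K_XY per
  permutation (identity permutation excluded).
* **External**: Q²F1 (training-mean reference), Q²F2 (test-mean
  reference), Q²F3 (per-observation variance ratio). Q²F2 ≤ Q²F1
  always, with equality exactly when the test mean equals the training
  mean; a single-valued test response makes Q²F2 undefined and it is
  reported as `NA` while the others remain.

All resampling is bit-reproducible given (seed, iterations); the LMO
and Y-randomization streams are derived from separate seeds so the two
procedures are independent.

## Applicability domain

`assess_domain()` classifies compounds on the Williams plane: leverage
above h* = 3p′/n makes an X-outlier; a standardized residual beyond ±3
makes a Y-outlier. The source does not define the denominator of its
"standard residual"; we standardize by the training RMSE, the simplest
Williams-plot convention. Screening candidates have no measured
response and are therefore gated on leverage only, matching how the
source checks its designed compounds. `autoplot()` draws the Williams
plot.

## Ensemble layer

`adaboost_fit()` implements AdaBoost.R2 — the canonical regression
AdaBoost — because the source names an "AdaBoost regressor MLR" without
specifying the boosting variant. Base learners are fitted by weighted
least squares rather than weighted bootstrap resampling, which makes
the procedure deterministic and gives the exact reduction of a single
round to plain OLS; a residual spread at numerical-noise level
terminates boosting as a perfect fit. Prediction is the weighted median
with weights log(1/β). The three nonlinear forms (polynomial,
logarithmic, exponential) are least squares in a transformed space with
explicit domain checks. All other regressors the source compares
(Gaussian processes, SVR, random forests, gradient boosting, k-NN,
MLP) are *not* re-implemented: they enter through
`register_regressor()`, whose registration self-test rejects adapters
that are not deterministic under a fixed seed. The tuned
hyperparameters originally used for those models were never published,
so the adapter defaults here are independent choices.

## Screening

`enumerate_library()` substitutes fragment lists into `[R1]`-style
placeholders of a core SMILES template — a purely syntactic Cartesian
product with deterministic order and string deduplication; optional
canonicalization via ChemmineOB tightens deduplication when chemistry
support is available. The package does not compute structural
descriptors: candidate descriptor tables are supplied externally or
generated synthetically.

`predict_candidates()` evaluates all six bank models (or any model set)
per candidate and applies the leverage gate per model where training
tables are supplied. `pareto_select()` then runs non-dominated sorting
per metal on (logβ maximized, PS in the configured direction) and flags
the **consensus** set: candidates on the first front for every metal,
ordered by normalized distance to the ideal point. Two decisions here
deserve note:

* The source's screening treats *low* PS as desirable (trading off
  against high logβ via 1/PS), while its introduction describes a high
  PS as indicating a wider response range. We default to minimizing PS
  to match the screening usage and expose `ps_direction = "max"` rather
  than silently resolving the contradiction.
* Negative predicted PS makes 1/PS non-monotone, so ranking always uses
  the signed PS value with the configured direction, never the
  reciprocal.

## Synthetic data

`make_regression_dataset()` draws descriptors from a block-equicorrelated
Gaussian (mean 0, std 1 — the scaled space), with within-block
correlation ρ ∈ [0, 1) in blocks of 5 by default, a sparse linear truth
with coefficients drawn from ±5 unless supplied, homoscedastic Gaussian
noise (the minimal error model, since the source states none), and
optional near-constant (std ≈ 0.01) and duplicate columns for the
cleaning filters. `make_published_dataset()` draws standard-normal
values for one bank model's descriptors and generates the response from
the printed equation plus noise, so refitting recovers the printed
coefficients exactly at σ = 0.

What the generators deliberately do **not** emulate: the marginal
distributions of real Dragon descriptors (heavy-tailed, discrete,
bounded blocks), inter-property correlation between logβ and PS for the
same ligand, and measurement error structure in potentiometric data.
Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under the stated assumptions, not predictive
validity on new experimental chemistry.

## Numerical choices and problem sizes

Rank decisions use a relative tolerance of 1e-10 in every QR; the
correlation and std filters compare at strict printed thresholds;
GA fitness ties are resolved at 1e-10 towards smaller subsets and then
lexicographic subset order; JSON model serialization writes full
decimal precision so round-trips are exact. Degenerate inputs error
early with the offending row/column named: constant responses, constant
columns in correlation/K computations, single-row scalers, empty test
splits, fractions outside (0, 1).

The test-suite and acceptance-script simulations use moderate sizes
chosen to make the statistical assertions sharp but quick: n = 30–120
compounds, 100 replicate seeds for unbiasedness checks, 500 permutations
for Y-randomization behaviour, exhaustive search over all 3-subsets of a
15-descriptor pool as the GA oracle. The published protocol sizes (2000
LMO iterations, 2000 permutations) remain the package defaults.

## A compact worked run

```{r example, eval = FALSE}
library(qsprscreen)

# simulate a Cd2+ logB dataset from the published equation, clean + split
sim <- make_published_dataset("Cd_logB", n = 100, sigma = 0.3, seed = 1)
d <- split_dataset(sim$data, test_fraction = 0.2, seed = 2)

# fit and validate
report <- validate_model(d, "logB", lmo_iterations = 500,
                         yrand_iterations = 500, seed = 3)
glance(report)
autoplot(report)

# applicability domain
ad <- assess_domain(report$model, d, response = "logB")
autoplot(ad)

# screen a candidate library with the published bank
bank <- published_models()
all_desc <- unique(unlist(lapply(bank, function(m) names(m$coefficients))))
cands <- tibble::as_tibble(matrix(rnorm(120 * length(all_desc), sd = 0.8),
                                  120, dimnames = list(NULL, all_desc)))
cands$compound_id <- sprintf("cand%03d", 1:120)
sel <- pareto_select(predict_candidates(cands, bank))
head(sel)
```

## Known limitations

* The bank operates only in its (unpublished) training scaling space;
  absolute predictions for raw descriptor values are impossible without
  those statistics, and the package does not pretend otherwise.
* The GA explores stochastically; on noisy data with many correlated
  descriptors different seeds can return different near-tied subsets.
  The ranking is deterministic per seed, and the QUIK and size rules
  bound, but do not eliminate, selection instability.
* Enumeration is string-based; without canonicalization, chemically
  identical SMILES written differently are counted as distinct.
* The applicability domain is leverage-only; density- or
  distance-based domains can disagree near the training hull.
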