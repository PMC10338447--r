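---
title: "Methods: penalized ensembles and psychometric networks for correlated outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized ensembles and psychometric networks for correlated outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis in one paragraph

`aggpsynet` implements a two-stage analysis of the relationship between
proneness to aggression and general psychopathology in community youth
cohorts. Stage one asks *whether* the two outcomes share predictive
information: each outcome is predicted from a few hundred survey items by a
repeated-subsampling LASSO ensemble, features that are stably selected
across repeats are retained, and the averaged models are exchanged across
outcomes (cross-prediction) on a holdout sample. Stage two asks *which*
characteristics link the outcomes: the features selected by *both* models
are reduced to oblique factors, and a Gaussian graphical model (GGM) over
the factor scores and the two outcomes exposes the conditional-dependence
structure, with bootstrap analyses quantifying how stable its edges and
centralities are.

The package ships a synthetic-cohort generator so that every stage runs,
and can be verified against ground truth, at desk scale. Real cohorts can
be supplied as a CSV plus a data dictionary (`read_cohort()`).

## Outcomes

**General psychopathology (p-factor).** The first principal component of
the eight symptom-scale totals, computed on the correlation matrix
(z-scored inputs). Symptom scales have heterogeneous ranges, and the
pipeline standardizes all numeric variables, so correlation-matrix PCA is
the consistent choice. The component is oriented so the loading sum is
positive: with positively keyed symptom scales a one-dimensional symptom
structure then loads all scales positively and a higher score means more
symptoms. The component is fitted on the discovery sample only and holdout
participants are *projected* onto it (`project_general_psychopathology()`),
so the holdout never influences any fitted quantity.

**Proneness to aggression.** The sum of the 12 aggression-questionnaire
items; the four subfactors (physical aggression, verbal aggression, anger,
hostility; three items each) are kept for the descriptive correlation grid.
Subfactor-by-symptom-scale Pearson correlations are adjusted by
Benjamini–Hochberg FDR with the whole grid treated as one family — the
natural reading of "controlling for multiple comparisons" across a single
displayed heat map.

## Preprocessing rules

* Items with **strictly more than 25%** missing values are removed, as are
  free-text (string) items.
* Participants with any missing outcome, age or sex item, or **strictly
  more than 5%** missingness over the remaining items, are excluded.
* Nominal items are expanded to a **full indicator set** (one 0/1 column
  per category, not reference coding); the L1 penalty handles the induced
  collinearity, and full sets keep every category's coefficient
  interpretable. Categories unseen in training map to all-zero dummies.
* Zero-variance training columns are dropped; all remaining columns and
  the outcomes are centered and scaled with training statistics.
* Missing cells are imputed by the unweighted mean of the `k = 20` nearest
  training rows. Distances are Euclidean over mutually observed
  standardized features, rescaled by the fraction of observed coordinates
  (so rows with different missingness patterns are comparable); ties are
  broken by row index for determinism; a cell's neighbours are restricted
  to rows that observe that column. Imputation runs on standardized
  features: scaling precedes imputation in the pipeline ordering. The
  order is a design choice — scaling statistics are computed from observed
  entries only, so the two orders differ only by the imputed values
  themselves, and imputing in standardized space makes the distance metric
  scale-free.
* Every statistic above is fitted on the training rows of the split at
  hand and carried forward; the test suite includes an explicit leakage
  audit (perturbing holdout rows changes no fitted transform, penalty
  choice, or coefficient).

**Splits.** One fixed discovery (3/4) / holdout (1/4) partition, and 100
independent train (3/4) / test (1/4) partitions of the discovery set. The
smaller block takes the floor of its fraction, which reproduces the
2184 → 1638/546 partition exactly. All index sets derive from one seed.

## The penalized ensemble

Per repeat: preprocessing is fitted on the inner-train block, the LASSO
penalty is tuned by mean out-of-fold RMSE over a 10-fold CV on a geometric
grid of 100 points spanning exactly $[10^{-10}, 1]$ (ties go to the
stronger penalty), the model is refitted at the tuned penalty, and the
standardized coefficients plus inner-test metrics (r, R², RMSE, MAE — all
on the standardized-outcome scale) are recorded. Coefficients are indexed
by design-column name; a column absent from a repeat's design (unseen
category, zero variance in that subsample) counts as a zero coefficient.

After 100 repeats, each feature gets a **percentile** 95% interval
(2.5th/97.5th percentiles of its 100 coefficients). Percentile intervals
are distribution-free and match the zero-crossing rule directly; a feature
whose interval excludes zero is *significant*, all others are zeroed, and
the significant coefficients are averaged. This rule is a stability
heuristic, not a calibrated test — under a global null its per-feature
false-flag rate is below 10% empirically (tested), because the tuned
penalty pushes null coefficients to exactly zero in most repeats.

Holdout prediction uses `X %*% mean_significant_beta` plus the mean
intercept (outcomes are standardized, so the intercept is ≈ 0; it is kept
for exactness). **Cross-prediction** applies one outcome's averaged model
to the holdout features and scores it against the *other* outcome. The
"overlap models" are zero-restrictions of the averaged models to the
intersection of the two significance masks — a restriction, not a refit,
so the same averaged-coefficient object is reused throughout. An Elastic
Net variant (`penalty = "elastic_net"`, mixing grid searched in the same
CV) is available as a sensitivity analysis and reproduces the LASSO at
mixing 1.

## Factor reduction

Overlap features are reduced on the complete-case subset (participants
without any missing feature value), where no imputation noise enters the
network stage.

* **Parallel analysis** compares factor-model eigenvalues (reduced
  correlation matrix with squared multiple correlations on the diagonal)
  of the observed data against eigenvalues of 100 same-shape
  standard-normal datasets. The retained count is the number of *leading
  consecutive* observed eigenvalues above the reference: the tail of a
  reduced correlation matrix is negative on both sides, where plain
  counting picks up meaningless exceedances. The reference is the random
  **mean** by default, with the 95th percentile exposed
  (`criterion = "q95"`); the mean is the more common convention, the
  percentile is stricter on noise.
* **Minres extraction** minimizes the sum of squared off-diagonal
  residuals of the correlation matrix over the uniquenesses (L-BFGS-B,
  communality-iteration start, bounds $[0.005, 1]$).
* **Oblimin rotation** with $\gamma = 0$ (direct quartimin) by gradient
  projection; oblique rotation is required because the downstream network
  conditions factors on one another. Factors are ordered by explained
  variance and signed so each factor's dominant loading is positive.
* **Regression (Thurstone) scores** $Z R^{-1} \Lambda \Phi$ carry
  participants into the network; they are the standard choice when scores
  feed a further covariance-based model, and a ridge-stabilized inverse
  (with a warning) guards against near-singular correlation matrices.

## Automatic normalization

The GGM assumes Gaussian inputs, so every node variable (factor scores and
both outcomes) is transformed by the candidate family: identity,
Yeo–Johnson (MLE λ), Box–Cox (MLE λ, positive data only), log10(x + a),
√(x + a) (both with a = max(ε, ε − min x), ε = 10⁻³), arcsinh, and ordered
quantile normalization. The winner minimizes the Pearson chi-square
normality statistic on the transformed training values, computed with
⌈2·n^0.4⌉ equiprobable standard-normal classes and divided by the class
count (the classical Pearson-test binning; a standard-normal sample scores
≈ 1). Ties go to the earlier-listed, simpler transform. The ordered
quantile map uses plotting positions (r − 0.5)/n with mid-ranks for ties;
new values interpolate linearly and extrapolate along the end segments,
keeping the map strictly monotone. All candidates are monotone, so ranks —
and hence Spearman correlations — are preserved exactly.

## The Gaussian graphical model

Edges are partial correlations: $w_{ij} = -\kappa_{ij} / \sqrt{\kappa_{ii}
\kappa_{jj}}$ from the precision matrix $K$. With n in the thousands and
around twenty nodes, regularization costs more bias than it saves
variance, so the model is selected *unregularized*:

1. A 100-point graphical-lasso path (penalties geometric from the largest
   absolute off-diagonal correlation down to 1% of it) proposes candidate
   structures; each distinct structure is refitted by constrained maximum
   likelihood and scored by EBIC with $\gamma = 0$ (i.e. the BIC;
   $\gamma$ is exposed in `ggm_config()`).
2. From the best seed, a stepwise search evaluates **every** single-edge
   addition and removal per sweep by exact refit, accepts the best
   strictly improving change (ties broken by lexicographic edge order for
   determinism), and stops at a local optimum.

The constrained ML fit iteratively matches the implied covariance to the
sample covariance on the structural entries (regression/IPF-style column
updates, tolerance 10⁻⁸); the saturated structure reproduces $S^{-1}$
exactly and the empty structure the diagonal model. On four-node problems
the stepwise optimum agrees with exhaustive enumeration over all 64
structures in ≥ 95% of simulated datasets (tested), and on a 15-node
sparse benchmark with partial correlations around 0.25 edge sensitivity
and specificity both exceed 0.9 at n = 5000 (tested).

**Flow diagrams** list, for a chosen source node, its neighbours with edge
weights (layer 1) and the remaining nodes via their edges into layer 1.

## Stability analysis

* **Edge bootstrap**: rows resampled with replacement, full model-selection
  refit per resample, percentile 95% intervals per edge (absent edges
  count as weight 0); the default 1000 resamples follows the common
  psychometric-network tooling. The summary table reports, per edge:
  sample weight, bootstrapped mean, bootstrapped 95% CI.
* **Expected influence**: the signed sum of a node's edge weights (equal to
  strength centrality when all edges are positive).
* **Case-drop CS coefficient**: at each drop proportion d in
  {0.05, …, 0.75}, subsample (1 − d)·n rows without replacement, refit,
  and correlate subsample expected influence with the full-sample values;
  CS is the largest d at which ≥ 95% of correlations reach 0.7. The grid
  ceiling of 0.75 is the convention of the reference tooling — a CS
  printed above 0.75 is not representable on such a grid, so this
  implementation never reports one. Degenerate refits (no edges, constant
  centrality) count as correlation 0 rather than being dropped.

## What the synthetic generator emulates — and what it does not

Items follow a single-common-factor-per-scale model
$x = \lambda z + \sqrt{1-\lambda^2}\,\varepsilon$ with loadings uniform on
[0.4, 0.8], 300 items in 29 scales (sizes 10–11), 2184 participants, and
12 latent factors. Each outcome draws on 4 factors through a normalized
sum; a configurable fraction of those factors is shared. Defaults (3 of 4
factors shared, outcome-item noise SD 1.8) place the p-factor/aggression
correlation near 0.56, the regime the analysis is designed for;
`tune_overlap_for_target_r()` re-calibrates the shared fraction and noise
to any attainable target. The first two items play age
(≈ N(20, 2.8), matching the cohort's age distribution) and sex (41%/59%
binary split); a configurable minority of items is nominal (3–5
equiprobable categories by thresholding a latent normal — enough to
exercise dummy coding without inventing item semantics).

Missingness is MCAR at a 0.15% cell rate, with ~70 items at a 35% rate (so
the 25% item filter removes them, emulating the 300 → 230 attrition) and a
random 5% of participants boosted by 15 percentage points (so the 5%
participant filter has work to do). Outcome items use a tenth of the
feature rate, keeping outcome-driven exclusions a small minority. The MCAR
choice matches the kNN-imputation assumption and keeps recovery tests
interpretable.

Not emulated: realistic item wording or content; informative (MAR/MNAR)
missingness; ordinal/Likert response scales for the outcome items
(generated continuous); longitudinal structure; cross-loadings and local
item dependence. Consequently, passing tests demonstrate that the
*machinery* is correct under the stated statistical structure — they do
not certify behaviour under informative missingness or strong measurement
non-invariance in real surveys.

## Numerical choices and degenerate inputs

* Penalty grid endpoints are exactly 10⁻¹⁰ and 1; at penalty 1 with
  standardized data every coefficient is zero and the prediction collapses
  to the training mean.
* Constant/never-observed design columns are dropped at fit time; constant
  outcome vectors are rejected.
* Correlation cells involving constant columns are flagged `NA` and
  excluded from the FDR family rather than silently set to zero.
* All-zero averaged models give a constant prediction; correlation metrics
  are then flagged degenerate (`NA`) instead of erroring.
* Ensemble repeats that fail are logged and skipped; fewer than 90%
  successes aborts. Bootstrap refits may fail in up to 10% of resamples.
* Every stochastic stage derives its seed deterministically from one
  master seed, so a pipeline run is reproducible end to end (tested
  byte-identically).

## Problem sizes used by the shipped checks

The test suite exercises the machinery at reduced sizes chosen to keep a
full run comfortably interactive while leaving all statistical margins
wide: GGM oracle equivalence on 4 nodes at n = 2000 over 20 seeds;
15-node structure recovery at n = 5000 over 10 seeds; ensemble recovery
with one planted effect among 50 noise features at n = 1500 with 50
repeats over 20 seeds; cross-prediction transfer across shared-factor
fractions {0, ¼, ½, ¾, 1} at n = 1600 with 15 repeats; case-drop
stability on the 15-node benchmark at n = 20000. The acceptance script
runs the full default cohort (2184 × 300) with the full 100-repeat
ensembles, a 100-resample edge bootstrap and 10 case-drop subsamples per
level; these sizes are the package's choices for a reproducible
desk-scale recomputation and are configurable upward.

## Known limitations

* The CI-based selection rule controls nothing formally; it is a stability
  filter and is documented and tested as such.
* Minres uses numerical gradients; on hundreds of features a fit takes
  tens of seconds. The stepwise GGM search refits exactly per candidate
  edge, which is the method's cost for exactness; the graphical-lasso seed
  keeps the number of sweeps small.
* Polychoric correlations are out of scope: network inputs are continuous
  factor scores and outcomes.
* `casedrop_cs` reports at the 0.75 grid ceiling even when the network
  would survive harsher subsampling.
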