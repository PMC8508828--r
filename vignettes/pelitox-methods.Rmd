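---
title: "Quantitative toxicogenomic profiling with pelitox: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative toxicogenomic profiling with pelitox: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelitox)
```

# The assay and its quantification model

pelitox analyses plate experiments in which a library of GFP-fused yeast
reporter strains — one strain per stress-response protein (ORF), each
assigned to exactly one of five stress categories (general, chemical, DNA,
oxidative, protein) — is exposed to a test material across a concentration
series while a plate reader records OD600 and GFP every 5 minutes over a
2 hour window. The analysis proceeds in fixed stages; every stage is an
exported function, so the numbered scripts under `analysis/` and
`run_pipeline()` are thin orchestration over the same code the tests
exercise.

## Normalization and induction factors

Per well, expression is GFP normalized by biomass with blank correction:

$$P(t) = \frac{\mathrm{GFP}(t) - \mathrm{GFP}_{blank}(t)}
              {\max(\mathrm{OD}(t) - \mathrm{OD}_{blank}(t),\ \mathrm{od\_floor})}$$

Blank wells contain exposure medium and test material but no yeast, so
subtracting the per-condition mean blank removes the material's
autofluorescence and absorbance. Nanomaterial suspensions scatter and
fluoresce appreciably at tens of mg/L, which is why the blank is matched to
the (compound, concentration) condition rather than shared plate-wide.

The log induction factor against the vehicle control of the same strain is

$$\ln I(t) = \ln \frac{P_{treated}(t)}{P_{vehicle}(t)}$$

Replicate wells are combined by averaging $\ln I$ (not by pooling raw
signal), so a single aberrant well perturbs the trajectory linearly rather
than through the ratio. When drift correction is on (default), the
housekeeping reporter's (PGK1) $\ln I$ under the same condition is
subtracted pointwise; PGK1 expression is assumed stress-insensitive, so any
apparent induction there is plate-level drift.

Numerical guards: `od_floor = 0.01` AU and `p_floor = 1e-6` AU. Instrument
noise can push blank-corrected values to or below zero; flooring keeps
$\ln I$ finite, and the number of floored points is reported as a warning so
a plate with pervasive flooring is conspicuous. Signed $\ln I$ is retained
throughout (downregulation is informative); the $\pm 2$ clipping that
heatmap displays use (`clip_for_display()`) is never applied before
endpoint computation.

## The protein expression level index (PELI)

The single-biomarker index is the exponential of the time-averaged absolute
log induction:

$$\mathrm{PELI}_{ORF} = \exp\!\left(\frac{1}{T}\int_0^T |\ln I(t)|\,dt\right)$$

with trapezoidal integration on the measurement grid and $T = 120$ min.
This form has three properties that anchor the rest of the analysis: a
no-effect condition gives exactly 1; the positivity threshold
$\mathrm{PELI} > 1.5$ (strict) corresponds to a 50% average fold
alteration; and the index is monotone in pointwise $|\ln I|$. The absolute
value treats repression as toxicity signal on the same footing as
induction. The function is passed around as a strategy (`peli_fun`
argument), so an alternative index — say, a rectified-positive variant —
can be substituted in one place without touching any downstream stage.

Category and total indices are geometric means of member-ORF PELIs,
equivalently the exponential of the mean integrated $|\ln I|$ — the only
aggregation consistent with the exponential single-ORF form. An
arithmetic-mean option exists (`method = "arithmetic"`). The 1.5 threshold
applies identically at ORF, category, and total levels.

## Concentration-response, PELI1.5, and censoring

Category-level and total PELI values across the concentration series are
fit with the increasing four-parameter logistic

$$y(x) = A + \frac{D - A}{1 + (C/x)^B}$$

by bounded least squares (L-BFGS-B on $(A, B, \log C, D-A)$), with
$A \in [1, 3]$, $B \in [0.1, 10]$, $C \in [c_{min}/10,\ 10\,c_{max}]$, and
$D \ge A$ enforced by parameterizing the plateau rise. Initialization is a
deterministic multi-start grid — four log-spaced midpoint guesses crossed
with two slope guesses, best SSE kept — rather than randomly jittered
starts: the grid covers the same basin diversity and makes fits exactly
reproducible without consuming RNG state. A plateau rise below 0.05 is
flagged `degenerate` (flat response).

`peli15()` inverts the fitted curve analytically at the threshold:
$x^* = C\,[(D-A)/(1.5-A) - 1]^{-1/B}$. The endpoint is censored rather
than extrapolated: `above_range` (rendered "N/A") when the curve has not
reached 1.5 at the highest studied concentration, and `below_range`
(rendered "<0.031" under the default range) when the response already
exceeds 1.5 at the lowest. A fitted baseline $A \ge 1.5$ is flagged as an
invalid fit by `peli15()` itself; the pipeline maps that condition to
`below_range`, since a baseline above threshold means the response exceeds
1.5 throughout the studied range — the same conclusion the censoring rule
draws, reached from the fit's floor rather than its evaluation at
$c_{min}$.

## Toxic equivalents

Toxic equivalents express a sample's category-level response as the dose of
a reference standard producing the same response: mitomycin C (DNA
category) for genotoxic equivalents, H2O2 (oxidative category) for
oxidative ones. The arithmetic is one consistent reading of
"equivalents at PELI1.5", isolated behind `compute_teq()` so an alternative
convention is a one-function change: evaluate the sample's category curve
at the sample's *total-level* PELI1.5 concentration to obtain a response
$p^*$, then invert the reference compound's same-category curve at $p^*$.
Censoring propagates — a below-range PELI1.5 evaluates at $c_{min}$ and
reports a ">" bound; an above-range PELI1.5 yields no equivalent; a $p^*$
outside the reference's own studied response range is bounded at the
corresponding range limit. Reference response tables are supplied as input
(or generated synthetically); no literature dose-response values are baked
in.

## Enrichment

**Category GSEA.** All library ORFs are ranked by PELI (descending; ties
broken by a seeded shuffle recorded through the seed), and the weighted
Kolmogorov-Smirnov running sum of the category's members is computed with
weights $|\mathrm{PELI} - 1|$ (exponent 1). The null is empirical: random
member sets of the same size drawn from the library,
$p = (1 + \#\{ES_{null} \ge ES_{obs}\})/(1 + n_{perm})$, 1000 permutations
by default. Gene-label permutation is the only feasible choice at $n = 3$
replicates per condition; condition permutation would have a support of a
handful of arrangements. With all member weights zero (every PELI exactly
1) the unweighted statistic is used, and an `exhaustive` mode enumerates
every subset when the library is small. One caveat stated rather than
hidden: because the weights are $|\mathrm{PELI}-1|$, p-values are exactly
invariant to order-preserving *rescalings* of the deviations (weights are
normalized) but not to arbitrary monotone transforms of PELI; the tests
check the invariance in the exact form.

**Ontology enrichment.** Activated ORFs ($\mathrm{PELI}_{ORF} > 1.5$,
typically at the top concentration) are tested per ontology term with the
hypergeometric upper tail, using the reporter library itself as the
reference population — the correct background, since the library is a
curated, stress-biased panel, not a genome sample. Terms are flat sets (no
ancestor propagation; precompute closure into the term map if wanted).
Significance is $p < 0.05$ uncorrected by default, matching the
screening-style usage of small fixed term collections; Benjamini-Hochberg
is available by option.

## Multivariate structure

Profiles (biomarker-by-condition mean $\ln I$) are clustered with
dissimilarity $1 - r$ (Pearson) and average linkage. "Average" is the
default because it is the operative choice for expression profiles of this
kind; complete linkage is selectable. Clustering uses unclipped values even
where a heatmap would clip at $\pm 2$. PCA treats conditions as
observations in biomarker space: column-mean-centered SVD, variance
fractions summing to 1, and a fixed sign convention (largest-magnitude
loading per component positive) so output is reproducible across BLAS
implementations.

## Phenotypic anchoring

ROS induction is summarized as a fold change of trapezoidal AUC over the
2 h window — AUC rather than a single timepoint because DCFDA kinetics are
cumulative and the plateau time varies by condition (a final-timepoint
option exists): blank-medium and chemical (dye + material, no yeast)
controls subtract the dye and material backgrounds, the stained control
provides the baseline denominator. H2O2-equivalent doses come from monotone
piecewise-linear inversion of a measured standard curve, with out-of-range
folds reported as censored bounds. Comet % Tail DNA uses a one-sided Welch
t-test for an increase over the untreated control (positive at $p < 0.05$);
Welch because treatment groups routinely have inflated variance. Molecular
and phenotypic endpoints are correlated with Pearson's $r$ and the
two-sided t-transform p on $n - 2$ degrees of freedom, with $n$ reported —
the pairing (which concentrations enter) is whatever the user supplies.

# The synthetic generator: what it emulates and what it does not

The generator (`synthetic_truth()`, `simulate_plate()`) reproduces the
study design as its defaults: 74 biomarkers, 5 compounds, six
concentrations 0.031-32 mg/L in a four-fold series, triplicates, 0-120 min
at 5-minute spacing, blank/vehicle/PGK1 controls. Its statistical choices:

* **Growth** is logistic from OD 0.2 with rate 0.006 min$^{-1}$ and
  capacity 1.0 — a modestly growing culture over 2 h.
* **Induction** of a responsive ORF follows a Hill curve in dose,
  $\mathrm{eff}(c) = \max\ln I \cdot d^h/(ec_{50}^h + d^h)$ with
  $d = c \times$ compound potency, and ramps linearly in time from 0 to
  that plateau. The linear ramp is deliberate: the time-averaged
  $|\ln I|$ is then exactly $|\mathrm{eff}|/2$, giving closed-form oracles
  for every downstream endpoint.
* **Effect sizes** default to 60% of ORFs responsive with
  $|\max\ln I| \sim U(0.6, 2.5)$ (15% repressed): the library is a curated
  stress panel, magnitudes beyond $\pm 2$ do occur, and at saturating dose
  category indices then cross the 1.5 threshold — so synthetic runs produce
  the realistic mixture of interval, "N/A", and "<0.031" endpoints.
  Compound potencies are graded, with the last compound strongly potent, to
  emulate a panel whose strongest member saturates near the bottom of the
  range.
* **Material optical interference** is a concentration-proportional
  additive background on both channels, identical in blank wells — so
  blank subtraction is *exactly* sufficient, which is precisely the design
  assumption the normalization stage encodes, and the noise-free pipeline
  recovers programmed $\ln I$ to machine precision.
* **Noise** is multiplicative lognormal with unit mean at 5% CV by default
  (a typical plate-reader replicate CV).
* **Phenotypes** are affine functions of the programmed oxidative / DNA
  effect sizes plus Gaussian noise with a programmed correlation $r$, so
  correlation-recovery tests have a known target.

What it does **not** emulate: growth inhibition by the material
(concentrations are taken as subcytotoxic by design), reporter maturation
delays, spatial plate effects (edge wells), carry-over between timepoints,
or any mechanistic stress biology — effects are phenomenological. Passing
tests on synthetic data therefore demonstrate that the estimators recover
what the model family programs, not that the model family captures every
failure mode of real plates.

# Validation problem sizes

The test suite and the acceptance script run at sizes chosen to make every
check exact or statistically decisive at desk scale: enumeration oracles on
libraries up to $N = 20$; 4PL recovery on 50 datasets at 3% CV across the
six study concentrations; linkage comparison against a naive $O(n^3)$
reference on 20 random 5-item matrices; null calibration on a full
74-biomarker, 5-compound null plate at 5% CV plus 1000 simulated comet
nulls; determinism on two complete study-design runs (GSEA at 199
permutations in that fixture's config). The one-ORF end-to-end oracle
checks $\mathrm{PELI} = e^{0.5}$ because a unit ramp's time-averaged
magnitude is exactly 0.5.

# Known limitations

* The PELI functional form and the TEQ arithmetic are each one defensible
  convention among several; both are strategy seams, and conclusions that
  depend on their exact form should be checked under the alternatives.
* Censored endpoints carry direction but no likelihood-based uncertainty;
  no confidence intervals are produced for PELI1.5 or TEQ.
* GSEA p-values at 1000 permutations have a floor of about 0.001; raise
  `n_perm` where smaller p-values matter.
* The shipped 74-entry library is a synthetic stand-in with plausible yeast
  stress genes; substitute the real strain list via `read_library()` for
  any real experiment.
* Correlation-based clustering requires nonzero variance per item; a
  completely uniform compound (every biomarker identical) is rejected by
  design rather than silently dropped.
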