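---
title: "Normative modelling of male total testosterone across the lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of male total testosterone across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttnorm)
```

## The problem

Diagnosing male hypogonadism presumes that the normal range of serum total
testosterone (TT) is known at every age, yet reference intervals in routine
use are rarely age-indexed. ttnorm builds an age-related *normative model*:
a mean TT curve over the lifespan together with an age-dependent spread, from
which centile curves, reference tables and individual z-scores follow. The
headline scientific content the package encodes is that mean TT peaks around
age 19, settles by age 40 and does **not** decline thereafter in the average
case, while the population *variance* keeps rising with age — so a fixed
cut-off misclassifies an increasing share of older men at both tails.

## The model

Observed TT (nmol/L) is transformed to the log-adjusted scale
$y = \log_{10}(\mathrm{TT} + 1)$. The unit offset keeps zero concentrations
at zero (important because artificial zero anchors at the age origin are part
of the fit) and stabilises a spread that grows with the hormone level. On
this scale the normative distribution at age $x$ is taken to be Gaussian,

$$ y \mid x \;\sim\; \mathcal{N}\!\left(\mu(x),\, \sigma^2(x)\right), \qquad
   \mu(x) = \frac{a + cx + ex^2 + gx^3}{1 + bx + dx^2 + fx^3}, $$

a cubic-over-cubic rational polynomial with seven free parameters (the
denominator constant is fixed at 1). Rational polynomials emerged as the best
family in a broad model screen of this dataset, and seven parameters is the
complexity that 5-fold cross-validation selects (see below). The log base is
10: with the published coefficients this form reproduces the tabulated median
column (0.4 / 13.0 / 13.2 nmol/L at ages 3 / 40 / 88), which a natural-log
reading misses by an order of magnitude — this reconstruction check is the
first test in the suite and everything else builds on it.

```{r}
m <- tt_reference_model()
round(predict_tt(m, c(3, 19, 40, 88)), 2)
peak_age(m)
```

The $p$-th centile at age $x$ is $10^{\mu(x) + z_p\,\sigma(x)} - 1$, clipped
below at zero; an individual's z-score is
$z = (y - \mu(x)) / \sigma(x)$.

## Data model and harmonization

The model is meant for pooled cross-sectional data digitized from published
scatterplots of thirteen studies (total n = 10,360; ages 0–101). Pooling
requires three harmonization rules, all implemented in `harmonize()`:

* **Units.** 1 ng/dL = 0.0347 nmol/L, applied before anything else.
* **Assay scale.** Platform immunoassays (DPC, DSL, Centaur, Roche, RIA) are
  mapped to LC-MS/MS equivalents through published conversion formulae —
  linear for the platform assays, a power law $x = 0.706\,y^{1.077}$
  (inverted to $y = (x/0.706)^{1/1.077}$) for the RIA. Conversions operate
  on nmol/L, are strictly increasing on positives, and the assay tag is
  rewritten afterwards so a conversion can never be applied twice. Linear
  conversions with negative intercepts can map values near zero slightly
  negative; these are clipped at 0 (concentrations are non-negative).
* **Age censoring.** Points below age 3 are dropped (extractions below that
  age could not be matched to their published summary statistics). The
  boundary is inclusive (`age >= 3` is kept) so the youngest tabulated
  reference age stays in-domain.

Finally, artificial zero-TT *anchors* are appended at the age origin — the
only exactly known level at any age — to force candidate curves through it.
The count defaults to 1% of the censored dataset (the anchoring strength is
not prescribed anywhere authoritative, so it is configurable), the anchor age
defaults to 0 years (source ages are postnatal; "conception" would sit at
−0.75, but the model is only reported from age 3 and the choice is
configurable). Anchors enter the least-squares loss at unit weight and are
excluded from every error statistic, r², residual analysis and SD estimate.

## Fitting and numerical choices

`fit_rational()` minimises squared error on the log-adjusted scale with
Levenberg–Marquardt (via minpack.lm), tolerances `ftol = ptol = 1e-9`
(convergence to nine significant figures). Specific choices:

* **Initialisation.** A linearised rational least-squares solve
  (regress $y$ on $[x^0..x^p, -yx^1..-yx^q]$), with a plain polynomial fit
  and up to 20 seeded random perturbations as fallbacks. On noise-free data
  from a cubic/cubic truth this initialisation already lands on the curve;
  LM then polishes to machine precision.
* **Pole rejection.** A candidate whose denominator is not strictly positive
  on a 0.1-year grid over [0, 105] is rejected and refit from a new start;
  a rational curve with a pole inside the age domain is not a usable
  normative curve, whatever its r².
* **Degenerate targets.** r² is defined as 0 when the response has zero
  variance, avoiding 0/0 and flagging such fits as uninformative.
* **Iteration cap.** The optimiser's hard maximum (1024) is used; with the
  1e-9 tolerances every fit in the test suite converges in well under 100
  iterations, so the cap is never active.
* **Degree allocation.** A candidate with $n$ parameters uses numerator
  degree $\lceil (n-1)/2 \rceil$ and denominator degree
  $\lfloor (n-1)/2 \rfloor$, so $n = 7$ is cubic/cubic, the validated
  model's shape; the allocation for other $n$ is a package choice (no
  authoritative prescription exists).

## Model-complexity selection

`cross_validate()` splits the data into 5 random, near-equal folds (anchors
distributed like ordinary points), trains rational polynomials with 3–11
parameters on each set of four folds and evaluates mean squared error on the
held-out fold, anchors excluded on both sides. High training *and* test error
signals underfit; low training but high test error signals overfit.
`select_optimal()` takes the complexity with minimal mean test error, ties
broken by parsimony — the natural operationalisation of "optimal trade-off
between overfit and underfit" (a one-SE-style rule would be an equally
defensible reading; minimal test error is adopted and documented here).
A candidate whose fit fails in any fold (usually pole rejection at high
degrees) is excluded from selection rather than compared on a subset of
folds, which would not be a like-for-like comparison.

On synthetic pooled cohorts generated from the seven-parameter reference
truth with log-scale noise $\sigma = 0.15$, five-fold cross-validation
selects seven parameters, and seven is the modal selection across
replicates — the test suite runs ten replicates at half the pooled sample
size (roughly 5,000 points, chosen to keep the default test run fast while
leaving the selection signal intact).

## Residual validation and the LOESS comparator

`residual_analysis()` reports the proportions of log-scale residuals within
1/2/3 SD (ideal Gaussian: 68.3 / 95.4 / 99.7%) and the r² of a
moment-matched Gaussian density against the residual histogram.
Freedman–Diaconis binning is used (robust bin widths for heavy-ish tails; no
authoritative binning rule exists for this diagnostic). `residuals_by_decade()`
repeats the analysis in the reporting bands 3–11, 12–19, then decades to
80–89. `loess_r2()` fits locally weighted regressions (span grid 0.2–0.75,
degree 1–2) as the "ensemble of local models" alternative; on synthetic data
from the rational truth the selected global fit outperforms the best LOESS
in r², mirroring the ordering reported for the real data (0.41 vs 0.32 —
numbers that are *not* reproducible here because the digitized source data
are not redistributable; only the ordering is asserted).

## Age-dependent spread and centiles

How the age-dependent SD was estimated for the published table is not
recorded anywhere authoritative, so `estimate_sd_profile()` offers three
mechanisms: a Gaussian-kernel-weighted SD centred at each query age (default,
bandwidth 5 years — narrow enough to resolve the post-40 variance rise,
wide enough to smooth decade-scale noise), binned SDs with interpolation, and
a global constant. The default profile shipped with the reference model
(`tt_reference_sd()`) anchors $\sigma$ at 0.151 / 0.137 / 0.173 at ages
19 / 40 / 88 — values obtained by inverting the published 2.5–97.5 normative
bands at those ages under the Gaussian-in-log model — and interpolates
linearly, constant outside. The rising tail encodes the increased variance
after age 40.

`normative_table()` produces the 86 × 13 reference grid (ages 3–88,
percentiles 1–99), exported rounded to one decimal. Two caveats are
deliberate:

* Below the pubertal rise the lower centiles clip at exactly 0 nmol/L; a
  clipped centile is not invertible, so score/centile round-trip identities
  hold only where the curve is positive.
* The extreme (1st/99th) columns of the published table are detectably
  asymmetric around the Gaussian prediction at old ages, suggesting the
  original tails were not pure z-scores; an `mode = "empirical"` option uses
  standardised-residual quantiles instead. Exact reproduction of those two
  columns is a non-goal. The related published "95% prediction limit"
  statement (18.7 → 24.5 nmol/L from age 40 to 88) does not correspond to
  any column under the Gaussian reading and is left unreproduced.

```{r}
tab <- normative_table(tt_reference_model(), tt_reference_sd())
tab[tab$age %in% c(19, 40, 88), c("age", "2.5", "50", "97.5")]
score_individual(6.6, 40, tt_reference_model(), tt_reference_sd())
```

## The synthetic cohort generator

`simulate_cohort()` emulates the pooled dataset so the whole pipeline is
testable without source data. Per study it draws ages from a scaled Beta
distribution on the study's age range with the concentration fixed at 5 and
the shape solved so the median matches the study's published median (bounded,
skewable, and exactly satisfies the two available targets — the true
within-study age distributions are unknown, so this is a stand-in, not an
inference). Log-adjusted TT is Gaussian around the ground-truth curve,
back-transformed, clipped at 0, and mapped onto the study's native assay
scale with the inverse conversion. One integer seed drives per-study
substreams; the caller's RNG state is untouched.

What the generator does *not* emulate: digitization error, longitudinal
structure collapsed to cross-section, convenience-sample selection effects,
and between-study level offsets beyond the assay conversions. Passing tests
on synthetic data therefore demonstrate the pipeline's correctness and the
selection behaviour of the validation machinery, not the epidemiological
accuracy of any refit to real data.

## Problem sizes used by the test suite

The default test run fits cohorts of roughly 10,000 points for the main
cross-validation check (a few seconds per LM fit), ten half-size replicates
for selection consistency, and a one-million-draw Gaussian sample for the
residual-proportion check; the full suite completes in about two minutes on
one core.

## Known limitations

* The reference coefficients are printed to 4–5 significant figures; the
  peak height is reproducible only to about 1% (15.30 vs the published
  15.4 nmol/L).
* Only rational-polynomial and plain polynomial families are implemented —
  a configurable subset of the commercial 330-model screening library the
  original analysis used.
* Model uncertainty (confidence bands on $\mu$ or the centiles) is not
  propagated; the printed standard errors of the coefficients are not used.
* The normative table is reported for ages 3–88 even though source data
  reach 101; outside that range the model extrapolates and the SD profile is
  held constant.
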