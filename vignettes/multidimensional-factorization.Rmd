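---
title: "Multidimensional Rasch-like measurement by matrix factorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional Rasch-like measurement by matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschmf)
```

## The model

`raschmf` treats a persons-by-items response matrix **X** (N × I, with
arbitrary missing cells) as a noisy image of a low-rank "true" matrix:

$$X = R\,C + \varepsilon, \qquad E = R\,C, \qquad
  E_{ni} = \sum_{d=1}^{D} R_{nd} C_{id}.$$

Each person and each item is a point in a common D-dimensional space; a
cell estimate is the dot product of the two coordinate vectors.  The model
assumes (i) every item is sensitive to the *same* D dimensions and to no
others (a "common space", the multidimensional analogue of the Rasch
unidimensionality requirement); (ii) noise is Gaussian with a
*characteristic scale per row and per column* (people are consistently
careful or careless; items are consistently clean or noisy); and (iii) the
observed metric of every column can be brought to an approximately linear,
unbounded scale.

When these assumptions hold at the correct D, least-squares solutions have
the *specific objectivity* property: the coordinates of a person can be
computed from any sufficiently large subset of their item responses with
the same result (exactly so at zero noise, approximately under noise).
This is what licenses item banking — scoring a new person from previously
calibrated item coordinates — and common-item equating of forms.

## Estimation

Calibration is unregularized alternating least squares on the non-missing
cells only.  C is initialized (see below), then row coordinates are solved
per person by OLS against C over the person's observed cells, R is
orthonormalized by QR (only the orthonormal factor is kept; the triangular
factor is re-absorbed when C is refit in the next half-step), and column
coordinates are solved per item.  Iteration stops when the RMS change of
the estimates over observed cells falls below `tol`.  The observed-cell RMS
residual is non-increasing across iterations by construction, and rows of R
end orthonormal to 1e-8.  No ridge or lasso penalty is used anywhere;
overfitting is controlled by dimensionality selection and by fit analysis,
not by shrinkage.  Rank-deficient solves fall back to the minimum-norm
solution with a warning reporting the condition number.

**Initialization.**  The default start is deterministic: the leading right
singular vectors of the column-mean-imputed matrix.  We chose this after
observing that purely random starts converge to local minima on roughly
three quarters of seeds when the missingness is *blocked* (whole item
ranges unseen by whole age groups) — and those stuck runs do not escape
with more iterations, while the spectral start converged on every matrix we
tried, typically in under 20 iterations.  A seeded random start
(`init = "random"`) remains available and is what multi-seed workflows use
when they keep the best of several runs; on well-fitting data the *product*
E is invariant to the seed even though R and C individually are not (the
axis orientation of the space is arbitrary and is never interpreted).

**Defaults.**  `tol = 1e-6` (RMS change of E, pseudo-logit units),
`max_iter = 50` — convergence on well-conditioned data usually needs fewer
than 20 iterations; exactness-critical runs in the test suite tighten these
to `1e-9`–`1e-10` and 150–200 iterations.  Rows or columns with ≤ D
observed cells are excluded from calibration with a warning rather than
failing the run.

## Column metrics and the pseudo-logit scale

OLS needs all columns on one unbounded linear metric.  Each column is
converted by a strictly increasing, invertible "plausible logit" map:
dichotomous 0/1 → logits of probabilities 0.25/0.75 (±1.0986); polytomous
category k of K → logit((k + 0.5)/K); interval → column z-score; ratio
(hard floor at zero, e.g. timings) → z-score of the natural log.  The
fitted location/scale parameters are stored so the raw metric can be
recovered and so new responses are normalized identically at scoring time.
The constants are a design choice — symmetric, bounded away from infinite
logits, order-preserving; nothing downstream depends on their exact values
because the factorization absorbs per-column affine changes.

Construct estimates from least squares are shrunk by measurement noise, so
before building the reporting scale they pass through a variance-restoring
"semi-true" rescale `g (x − mean) + mean` with
`g = sqrt(1 + RMSE²/var(x))`, RMSE the root mean square of the person
standard errors.  The reporting scale (DRS) is then an affine map fitted so
the 1st and 99th percentiles of the calibration sample land on 10 and 90 —
robust to tail outliers and keeping scores inside 0–100 without hard
clipping.  All four numbers (g, center, slope, intercept) persist in the
bank, so calibration and scoring reproduce identical values.

## Dimensionality

D is the most important unknown.  Too low misses real variation; too high
reproduces noise and destroys cross-sample reproducibility.  Three
statistics are computed per candidate d:

* **accuracy** — hide a seeded 10% of observed cells ("pseudo-missing"),
  refit, and correlate hidden observations with their estimates.  The 10%
  default is large enough for a stable correlation and small enough to
  preserve solvability (hiding never reduces a row or column below d + 1
  observations).
* **stability** — calibrate R separately from the odd and even item
  columns, align the second solution to the first by orthogonal Procrustes
  rotation (independent runs differ by an arbitrary rotation; a shared
  anchor frame would understate independent-calibration variance), and
  correlate corresponding entries.
* **objectivity** = √(accuracy · stability), with negative inputs clamped
  to zero.  The best d maximizes objectivity; exact ties go to the smaller
  d.

On simulated data the accuracy curve plateaus at the true D while
stability declines beyond it, so objectivity peaks at D; the test suite
verifies recovery of D ∈ {2, 3, 6} in at least 4 of 5 replicates at
moderate noise (150 × 60 matrices, unit base noise, 25% random missing,
d_max = 10, 3 seeds per d).  When an age column is supplied, the search
runs on the age-residualized matrix and the final dimensionality is the
residual optimum plus one.

## The error model

Three levels of error are distinguished: raw residuals `Res = X − E`
(observed cells only); **EAR**, the expected absolute residual, i.e. the
characteristic scale of `|X − E|` per cell; and **SE**, the expected
distance between the *estimate* and the unobserved *true* value.

EAR comes from decomposing the squared-residual matrix itself: square,
floor, log (the hard zero floor makes squared residuals a ratio scale; the
log converts it to an interval scale, and the row-times-column structure
becomes additive, which one extra dimension absorbs — hence ALS at
dimensionality 2), exponentiate the fitted values, map them back onto the
raw squared residuals by a per-column degree-1 polynomial fit, floor, and
take the square root.  Numerical floors: squared residuals are floored at
`eps = 1e-12` before the log so exact-fit cells stay finite; the polynomial
fit can dip negative, and its output is floored at
`max(eps, 0.05 × median column squared residual)` — column-relative, so
exact-fit columns still bottom out near `sqrt(eps)` while noisy columns can
never produce a near-zero EAR that would explode standardized misfits.

The cell standard error is

$$SE_{ni} = \frac{2\,EAR_{ni}\,\sqrt{d}}{\left[(r_n - d)(c_i - d)\right]^{1/4}},$$

with r and c the observed-cell counts of the row and column, so missingness
is folded into the standard error automatically.  As r → d or c → d the
fit interpolates the data and SE diverges, which this denominator (unlike
the (r−1)(c−1) variant, available as an option) reproduces; in the
one-facet, one-dimension reduction the formula collapses to the classical
`scale/√(n−1)`.  A second decomposition of the SE matrix (same pipeline)
yields smooth expected standard errors and a portable 2-dimensional
coordinate pair per person and item, letting person-level error statistics
be recomputed from a bank and a single response vector.

On heteroscedastic simulations with known truth (300 × 80, true D = 6,
unit base noise, lognormal row/column noise spreads of 0.5 — a clearly
heteroscedastic regime), the median of `|E − T| / SE` falls within
[0.4, 2.0] and SE correlates positively (Spearman > 0.2) with the realized
error.  The formula is conservative at small noise; as noise grows the
bias moves toward underestimation, and the test suite asserts exactly that
directional pattern.  In our simulations the ratio never actually crosses
1 before extreme noise collapses it again — the formula stayed
conservative throughout — so the strict "underestimates at very large
noise" half of the claim is checked only as a direction, not a crossing.

Cell misfit is `(X − E)/EAR`; person and item *outfit* are root mean
square misfits.  A person with outfit ≥ 2 occupies an indeterminate
position in the space and their score is flagged uninterpretable (the
threshold is configurable; on conforming simulations fewer than 15% of
persons are flagged).

## Age anchoring

To keep age out of the construct dimensions, calibration anchors
standardized (centered, unit-norm) log-age as the first person coordinate,
solves each column's age loading, and factorizes the residual matrix for
the remaining dimensions.  By the normal equations every residual column is
orthogonal to the age vector over its observed cells.  The literal
merge-and-one-pass finish turned out to be insufficient under blocked
missingness: the per-column age solves leak age variance into the residual
matrix (the age vector correlates with the other dimensions on each
column's observed subset), so the residual matrix has one more dimension
than the residual factorization models.  The package therefore runs an
anchored refinement — ALS iterations with the age dimension held fixed —
before the final pass that solves C from R and then R from C, persons
last, so person measures reflect the best attainable fit.  At zero noise
this restores exact recovery of the generating matrix.  The final R is the
best-fit solution given C and is deliberately not re-orthonormalized.
Because the calibrated item coordinates carry the age loadings, scoring a
new person does not require their age.

## Equating, banking, scoring

Form B is equated to a reference bank by fixing the C coordinates of the
common items at their bank values, solving each Form-B person from the
common items in one pass, and then solving the new items' coordinates.
The package requires more than D common items (hard) and recommends 2D
(warning below), a margin against noise in the link.  The per-common-item
RMS residual certifies the link; equating is transitive at zero noise.
Item drift between group-wise calibrations in a shared frame is reported
per item, per dimension, and pooled, since the field reports all three.

The bank is one JSON document: item estimate coordinates, EAR/SE column
coordinates with their polyfit maps and floors, observed-column counts,
fitted column metrics, construct coordinates, the scale transform, cut
scores, and provenance.  Scoring solves the new person's coordinates from
the banked item coordinates (needing > D matched responses, 2D
recommended), takes the dot product with the construct coordinates, and
applies the banked transform.  The person's standard error propagates the
cell SEs through the least-squares solve,
`V = (AAᵀ)⁻¹ A diag(SE²) Aᵀ (AAᵀ)⁻¹` for the matched item coordinates A,
then `se_DRS = slope · g · sqrt(wᵀVw)` for construct coordinates w.

## The simulator

`simulate_dataset()` draws standard-normal R_true and C_true, forms
T = R_true C_true, adds Gaussian noise with cell sd
`noise_base · row_sd · col_sd` (lognormal multipliers — every row and
column has its own characteristic noise scale), and deletes cells randomly
or in age-form blocks.  `simulate_instrument()` adds the instrument
structure: ages log-uniform over 7–82, centered unit-norm log-age as the
first true dimension, a constant second dimension carrying per-item
difficulty offsets, child/teen/adult forms (< 10, 10–15, ≥ 16 years) whose
item visibility produces ≈ 25% blocked missingness, a fraction of items
dichotomized at their median, positive "timing" columns whose loadings are
the negated loadings of a paired dichotomous item (so observed pairs
correlate negatively), and a 0–10 rating formed by adding noise
(sd = 0.3 × projection sd) to a weighted projection of R_true and cutting
at sample quantiles into 11 categories.

Default conditions, chosen once to mirror the calibration study's shape at
desk scale: 300 persons × 120 items, D = 6, `noise_base = 1` (cell noise
sd ≈ 1 against a cell signal sd of ≈ √6), row/column noise spreads 0.3,
25% blocked missingness, 11 rating categories.  Exactness-critical tests
use noise-free variants at 200–250 × 80–100.

What passing tests do *not* show about real data: the simulator's noise is
exactly Gaussian with exactly multiplicative row/column scales, its items
load on exactly D common dimensions, and its rating is exactly a noisy
linear projection.  Real instruments violate all three to some degree —
the method's own misfit statistics, not these tests, are the check that a
given dataset conforms.  Dichotomization also discards information the
model treats as present, so pseudo-logit estimates for dichotomous columns
are approximations whose quality the error model, not the factorization,
must absorb.

## Known limitations

* Two facets only (persons × items); no rater facet.
* One construct-rating column per calibration call (multiple constructs can
  be banked, but panels/consensus machinery is out of scope).
* The plausible-logit constants and the semi-true rescale are principled
  choices, not estimates; alternative "true logit" recovery schemes exist.
* The column-centering of interval/ratio metrics leaves any globally
  constant person dimension only weakly identified; difficulty-like
  offsets are best modeled, as here, through the metric transform rather
  than recovered as a dimension.
* Standard-error calibration degrades when the dimensionality is
  misspecified; the SE formula is only claimed valid at the optimum D.
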