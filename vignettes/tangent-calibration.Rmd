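---
title: "Tangent-line calibration of spherical AFM tips: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tangent-line calibration of spherical AFM tips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmtangent)
```

## The problem

AFM nanoindentation of soft biological samples is usually done with a
spherical glass bead glued to the cantilever, because spheres are gentle on
cells, gels and tissues. Converting a force–indentation curve into a Young's
modulus requires the bead radius $R$, and $R$ is conventionally measured in a
separate calibration step (SEM imaging or scanning a sharp calibration
grating) that must be repeated for every new probe. `afmtangent` implements a
calibration that removes that step: both the tip radius and the Young's
modulus are recovered from a *single* force–indentation curve, with no prior
knowledge of either.

## Contact models

For a rigid sphere of radius $R$ on an incompressible elastic half-space the
exact (Sneddon) solution is parametric in the contact radius $r_c$:

$$F = \frac{E}{2(1-\nu^2)}\Big[(r_c^2+R^2)\ln\frac{R+r_c}{R-r_c} - 2r_cR\Big],
\qquad h = \frac{r_c}{2}\ln\frac{R+r_c}{R-r_c}.$$

`sneddon_force()` evaluates this pair, inverting the depth relation by a
bracketed root search on $r_c/R \in [0,1)$ (Brent's method, tolerance
$10^{-12}$; the mapping is strictly monotone, so bracketing is safe).

A closed-form force–depth law follows from expanding
$r_c/R = c_1 (h/R)^{1/2} + c_2 (h/R) + \dots + c_N (h/R)^{N-1}$ and
integrating the contact stiffness $dF/dh = 2E^* r_c$
(with $E^* = E/(1-\nu^2)$):

$$F = 2E^*\Big[\tfrac{2}{3}c_1R^{1/2}h^{3/2} + \tfrac{1}{2}c_2h^2 +
\tfrac{1}{3}c_3R^{-1}h^3 + \dots + \tfrac{1}{N}c_NR^{2-N}h^N\Big].$$

Two coefficient sets are built in (`afm_coefs()`): a three-term set
$\{1.022, -0.1133, -0.0742\}$ valid for $h_{max}/R \le 1.32$ — the common
experimental regime — and a six-term set valid to $h_{max}/R \le 4.9512$,
i.e. essentially any depth. `fit_coefficient_set()` regenerates such sets
from the parametric solution (2000 evenly spaced contact-radius samples,
unweighted least squares on the $\{u^{1/2}, u, \dots, u^{N-1}\}$ basis);
the refit reproduces the built-in constants to well under 2%. The built-in
printed values remain the authoritative defaults; refitting exists for
validation and custom domains. Note an intrinsic accuracy limit: the
three-term expansion cannot represent the parametric relation better than a
few $10^{-3}$ in $r_c/R$ near its domain edge, whatever the fitting grid;
the six-term expansion stays below $10^{-3}$.

The Hertz law $F = \frac{4}{3}E^*R^{1/2}h^{3/2}$ is the small-depth limit.
Using it at $h = R$ underestimates the modulus by about 10% — one of the two
reasons to prefer the polynomial law (the other being the calibration
below).

## The tangent-line method

Write the tangent to the force–indentation curve at maximum depth as
$F = S h + b$, with $S = dF/dh|_{h_{max}}$. Two intercepts matter:

* the **indentation-axis intercept** $h_{com} = -b/S$, whose ratio to
  $h_{max}$ depends *only* on $u = h_{max}/R$:
  $$\frac{h_{com}}{h_{max}} =
  \frac{\frac{1}{3}c_1u^{3/2} + \frac{1}{2}c_2u^2 + \frac{2}{3}c_3u^3 +
        \dots + \frac{N-1}{N}c_Nu^N}
       {u\,(c_1u^{1/2} + c_2u + \dots + c_Nu^{N-1})};$$
  the modulus cancels, so inverting this strictly decreasing function
  (`solve_radius()`) yields $R$ without knowing $E$;
* the **force-axis intercept** $b = 2E^*R^2\,\tilde b(u)$ with
  $\tilde b(u) = -[\frac{1}{3}c_1u^{3/2} + \dots + \frac{N-1}{N}c_Nu^N]$,
  which then yields $E$ (`solve_modulus()`).

The ratio $h_{com}/h_{max}$ runs from $1/3$ (the Hertz limit $u \to 0$) down
to $\approx 0.10$ at $u = 5$; in the deep limit $h_{com}/R \to 0.5$ and
$b/(2E^*R^2) \to -0.5$.

In practice the curve is first fitted to
$F = a h^{3/2} + b h^2 + c h^3$ (`fit_force_curve()`; unweighted,
unconstrained linear least squares — the model is linear in $a,b,c$), the
tangent is formed analytically (`tangent_from_polyfit()`), and
`afm_calibrate()` chains the steps into a classed model object with the
usual `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
methods.

A caution the package makes testable: the *individual* fit coefficients
$a, b, c$ also map to $(E, R)$ in closed form, but the three basis functions
are nearly collinear, so many $(a,b,c)$ combinations describe the same
curve and that "naive" route is wildly unstable on noisy data. The tangent
functionals $S$ and $b$ are far better determined; this is why the method
works where the coefficient map does not.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `v` | 0.5 | Poisson ratio; 0.5 (incompressible) suits hydrated gels/cells |
| `coefs` | `"auto"` | solve with the six-term set, re-solve with the three-term set when the recovered $h_{max}/R \le 1.32$ (the routine regime) |
| `degeneracy_threshold` | 0.005 | flag the Hertz regime when $h_{com}/h_{max} > 1/3 - 0.005$; near small ratios the mapping changes by only $\sim 5\times10^{-4}$ per 0.01 of $u$, so closer ratios carry no usable radius information |
| `precontact_degree` | 1 | baseline polynomial for contact-point detection (0–3); degree 1 absorbs a tilted baseline |

All lengths are SI metres internally; `units = "nm"` converts nm/nN at the
I/O boundary only.

## Degenerate (Hertz) regime

When $h_{max} \ll R$ the curve obeys the Hertz law, for which
$h_{com} = h_{max}/3$ *identically* — the tangent intercept carries no
radius information. `solve_radius()` and `afm_calibrate()` flag such curves
`degenerate` and return `NA` rather than an arbitrary radius; the
command-line tool exits with status 2 so batch drivers can count them.

## Contact-point detection

For raw piezo/deflection records, every admissible sample is tried as the
contact point: a baseline polynomial is fitted before it and the
$\{h^{3/2},h^2,h^3\}$ contact basis after it, and the index with the lowest
total sum of squared residuals wins (every index is scanned up to 5000
samples, every second one beyond). On noiseless curves this recovers the
exact junction. Under white force noise of 1% of $F_{max}$ the detected
index is unbiased to a few samples but spreads over roughly ±10–20 samples
(of 400): near contact the force is below the noise floor, so that
ambiguity is intrinsic, not an implementation artifact. Radius recovery is
correspondingly sensitive — a ±3-sample mislocation on the standard
synthetic curve moves $R$ by up to ~8% (worse when baseline points are
absorbed into the contact side, because the inversion amplifies
intercept-ratio error by an order of magnitude at routine depth ratios).

## Synthetic data: what it does and does not emulate

`simulate_curve()`, `simulate_raw_curve()` and `simulate_batch()` generate
curves from any of the forward models on an evenly spaced depth grid, with
additive Gaussian force noise (sd a fixed fraction of $F_{max}$), optional
tilted pre-contact baselines and cantilever kinematics ($z = h + F/k$), all
deterministic under a seed (batches use child seeds `seed + i`). Defaults —
200 points per curve, 200 baseline points, moduli drawn from 102–174 kPa
with a fixed 0.92 µm radius at 432 nm depth — mirror a soft agarose-gel
experiment with a nominal 1 µm borosilicate sphere.

What the generator does *not* emulate: adhesion, viscoelastic rate
dependence, plastic deformation, thermal drift, and — importantly —
*smooth model misfit*. Real soft-sample curves deviate from the elastic
model in a correlated way; white noise is harsher on the tangent
functionals than correlated misfit of equal amplitude. Consequently white
noise at 2% of $F_{max}$ yields a broad, skewed radius distribution
(sd/mean near unity at 200 points per curve), whereas at instrument-realistic
0.2% the batch mean is accurate to well under 1% with ~10% spread. Passing
tests therefore demonstrate correctness and modulus-insensitivity of the
inversion, not that any particular real-world spread will be achieved.

## Numerical choices

* Root searches (`sneddon_contact_radius()`, `solve_radius()`):
  `stats::uniroot` on a guaranteed bracket, tolerance $10^{-12}$.
* The dimensionless intercept relations accept $u$ up to 1% beyond the
  six-term set's fitted bound 4.9512, because the standard tabulation and
  limit values are quoted at $u = 5.00$; force and stiffness evaluation
  stay strict.
* Lookup tables round half-even to 4 decimals (R's `round()`), matching the
  customary table precision. Regenerating the tables exposes two 1-ulp
  inconsistencies in the published tabulations: the value at $u=0.25$ is
  0.3215 (not 0.3216) and at $u=1.00$ is 0.2803 (not 0.2802).
* `fit_inverse_quartic()` provides the popular quartic shortcut
  $h_{max}/R \approx p_4x^4+\dots+p_0$, $x = h_{com}/h_{max}$, regenerated
  from the exact relation on each call. Its coefficient of determination
  rounds to 1.0000 on the sub-unity domain, but the four terms nearly
  cancel: *rounded* coefficients are useless (published 4-significant-digit
  versions of $p_i$ mispredict by several $10^{-3}$), the map's pointwise
  error is a few $10^{-3}$, and it must not be extrapolated outside its
  fitted range (at $x = 1/3$ it returns a small negative value rather
  than 0). `solve_radius()` is the accurate route; the quartic exists for
  desk estimates only.
* Fit signs ($a>0, b<0, c<0$) are flagged, never constrained, preserving
  plain least-squares reproducibility. Hertz-likeness is decided by a
  nested-model F test against the pure $h^{3/2}$ law (individual t values
  are misleading because the basis is nearly collinear).
* Deflection noise makes the converted $h$ locally non-monotone; points are
  ordered by depth rather than rejected. A strictly decreasing piezo ramp
  (a retract segment), by contrast, is an error.

## A worked consistency note

The package reproduces the published worked example end to end: the printed
cubic fit $(a, b, c) = (281, -23340, -1.019\times10^{10})$ at
$h_{max} = 432$ nm gives $S \approx 0.251$ N/m and
$h_{com} \approx 1.35\times10^{-7}$ m; the printed tangent values
($S = 0.2505$, $b = -3.363\times10^{-8}$) give
$h_{com} = 1.342\times10^{-7}$ m and $R = 0.921$ µm. One printed number
does not check out: substituting those same tangent values, $R$ and
$\nu = 0.5$ into the modulus equation yields $E \approx 162$ kPa, not the
132.5 kPa quoted alongside. The implementation follows the equation
verbatim; the discrepancy is recorded here rather than reconciled, and no
test asserts the 132.5 kPa figure.

## Known limitations

* Elastic, adhesionless, axisymmetric spherical contact on a half-space
  only; no substrate-thickness correction, no JKR/DMT adhesion, no
  viscoelasticity (use a very small indentation rate and carry the
  recovered $R$ into rate-dependent analyses).
* The radius inversion amplifies intercept noise; single noisy curves give
  noisy radii. Averaging over a batch of curves is the intended use.
* Instrument-side calibration (deflection sensitivity, spring constant) is
  out of scope; deflection is assumed already in metres and $k$ known.
* Proprietary vendor file formats are not parsed; input is delimited text.
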