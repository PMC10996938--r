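---
title: "A spatiotemporal chromatic contrast sensitivity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spatiotemporal chromatic contrast sensitivity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaCSF)
```

## What the model computes

chromaCSF predicts the smallest detectable contrast of a simple stimulus — a
Gabor patch or a disc — on a uniform adapting background, as a function of
six stimulus properties: the colour direction of the modulation, stimulus
area, spatial frequency, temporal frequency, mean luminance, and retinal
eccentricity. Sensitivity is reported as the inverse of RMS cone contrast at
threshold,

$$ C = \sqrt{\tfrac13\left[(\Delta L/L_0)^2 + (\Delta M/M_0)^2 +
(\Delta S/S_0)^2\right]}, \qquad S = 1/C_\text{thr}. $$

A stimulus is encoded as a background cone-excitation triplet
$(L_0, M_0, S_0)$ and a modulation direction $(\Delta L, \Delta M,
\Delta S)$. Cone excitations use a scale in which $L + M$ equals luminance
in cd/m². The direction is mapped to opponent increments (achromatic,
red–green, yellow–violet) by a fixed matrix,

$$ \begin{pmatrix}\Delta A\\\Delta R\\\Delta V\end{pmatrix} =
\begin{pmatrix}1 & 1 & 0\\ 1 & -2.3112 & 0\\ -1 & -1 & 50.9875\end{pmatrix}
\begin{pmatrix}\Delta L\\\Delta M\\\Delta S\end{pmatrix}, $$

and divided by background luminance $Y = L_0 + M_0$ to give opponent
contrasts. The matrix is a constant derived for a grey (daylight-white)
background and is deliberately **not** re-derived per background: a
luminance modulation on an unusual background may leak into the chromatic
rows, and the model treats that as signal, not as an error to correct.

Each opponent contrast is weighted by a mechanism sensitivity
$S_c(\rho, \omega, Y, a, e)$ and pooled into a detection energy with a
Euclidean norm,

$$ E = \Big[\textstyle\sum_{c}\big(S_c\,\Delta C_c\big)^2\Big]^{1/2} . $$

Detection is assumed at $E = 1$. Because $E$ is homogeneous of degree one
in the modulation direction, the threshold is found analytically by
rescaling the direction by $1/E$; the reported sensitivity is the inverse
cone contrast of that rescaled increment, and it is invariant to the
magnitude of the direction vector the user supplies. The test suite checks
this inversion against a bisection oracle that knows nothing about
homogeneity.

One note on the pooling: written without the square root, the energy would
not be homogeneous and the analytic threshold factorisation would fail.
The root-sum-square form is the only pooling under which "threshold at
$E = 1$ by rescaling" is self-consistent, so that is what the package
implements.

## Mechanism structure

Each mechanism sensitivity is a separable product (with one sum):

* **Temporal channels.** All three mechanisms have a sustained (low-pass)
  channel $R_S(\omega) = \exp(-\omega^{\beta}/\sigma)$. Only the
  achromatic mechanism adds a transient (band-pass) channel
  $R_T(\omega, Y) = \exp\!\big(-(\omega^{\beta_T} -
  \omega_0^{\beta_T})^2/\sigma_T\big)$ whose peak follows
  $\omega_0(Y) = m_\omega \log_{10} Y + c_\omega$ Hz, shifting to higher
  flicker rates at higher luminance. Both achromatic branches are always
  evaluated, including at 0 Hz — "static" is not special-cased; the
  transient contribution at 0 Hz is whatever the filter yields. The peak
  line is clamped below at 0.1 Hz because it is linear in $\log Y$ and
  would otherwise go negative far below the fitted luminance range.
* **Spatial envelope.** A log-parabola
  $10^{-(\log_{10}\rho - \log_{10}\rho_m)^2/2^{k_b}}$, truncated on the
  low-frequency side: achromatic channels plateau at $1 - k_a$ (lateral
  inhibition leaves a finite low-frequency loss), chromatic channels
  level off at 1 (no inhibition; low-pass). The bandwidth denominator is
  taken as $2^{k_b}$, which is strictly positive for any real $k_b$; the
  alternative parameterisation $2 k_b^2$ is available via
  `options$bandwidth_mode = "sq"` for comparison.
* **Spatial summation.** Sensitivity grows with area up to a critical
  area $a_x(\rho) = a_0 / (1 + (\rho/\rho_0)^2)$, via
  $S_\text{area} = \rho\sqrt{a_x/(1 + a_x/a)}$ (in cycles), saturating at
  the critical number of cycles $\rho\sqrt{a_x}$. Area acts independently
  of luminance and eccentricity, a separability the tests assert.
* **Luminance gain.** Achromatic sustained:
  $k_{s1}(1 + k_{s2}/Y)^{-k_{s3}}\big(1 - (1 + k_{s4}/Y)^{-k_{s5}}\big)$ —
  a DeVries–Rose rise, a Weber plateau, and a decline at very high
  luminance. Chromatic: the same without the declining factor. Achromatic
  transient: a power law $k_{s2} Y^{k_{s1}}$. The $k/Y$ placement inside
  these gain laws is the one that reproduces the three regimes (rise,
  plateau, decline) over realistic luminance ranges, which is why it was
  adopted.
* **Peak-frequency shift.** The achromatic sustained log-parabola peak
  rises with luminance, $\rho_m(Y) = k_{\rho 1}(1 +
  k_{\rho 2}/Y)^{-k_{\rho 3}}$; the transient and chromatic peaks are
  constants.
* **Eccentricity.** $S_\text{ecc} = 10^{-(\hat k_{e1}\rho e +
  \hat k_{e2} e)}$, log-linear in eccentricity and steeper at high spatial
  frequency. The coefficients blend nasal and non-nasal values with
  $\alpha = \min(1, |\theta - 180|/90)$ (right-eye convention, $\theta =
  0$ temporal, $180$ nasal). The absolute value in $|\theta - 180|$ is
  essential: it is the only form that keeps $\alpha \in [0, 1]$ on both
  sides of the nasal meridian, so it is made explicit here.

Gabor stimuli with a nominal spatial frequency of 0 (Gaussian blobs) are
evaluated as half-cycle Gabors, $\rho = 0.5/(2\sqrt{a/\pi})$, with a hard
floor of $10^{-4}$ cpd.

### Disc stimuli

A disc forms a circular edge, and edge detection is carried by the most
sensitive spatial channel. The disc sensitivity per mechanism is

$$ S^\text{disc}_c = (2\pi a)^{1/\beta}\,\max_\rho S_c(\rho, \omega, Y,
a_\text{disc}, e), $$

with fixed (never fitted) $\beta = 3.01142$ and $a_\text{disc} = 2.42437$
deg². The $(2\pi a)$ base is taken literally as $2\pi \times$ area; the
alternative circumference-based form $2\sqrt{\pi a}$ changes only the
effective $\beta$ scale of fixed constants and was not adopted. The
$\rho$-maximum is taken on a fixed log grid, $2^{-6}$ to $2^{6}$ cpd with
257 points; the maximand is smooth and unimodal for sensible parameters,
so grid error is far below fitting error and no iterative refinement is
done. Because the grid is evaluated at the fixed reference area, the
implementation deduplicates disc rows that share $(\omega, Y, e, \theta)$
when predicting tables — an exact optimisation, not an approximation.

## Default parameters

The shipped parameter set (`default_params()`, also in
`inst/extdata/default_params.txt`) is a hand-set, plausible configuration —
not a fit to published data, which would require the original consolidated
tables. Values were chosen once so the model exhibits the expected
qualitative behaviour: an achromatic static CSF peaking at a few cpd with
band-pass shape; chromatic envelopes peaking below 1 cpd and low-pass;
red–green the most responsive mechanism in this cone-contrast scale;
critical areas saturating near 0.5 cpd (achromatic sustained) and well
below that for chromatic channels; transient peak moving from ~1 Hz at
0.02 cd/m² to ~15 Hz at 10,000 cd/m². All parameters carry their units in
the documentation of the component functions. The parameter file format is
a flat `key value` map (`ach.sustained.k_b` etc.); a missing key is a hard
error — there are no silent defaults when reading files.

The truncation depths $k_a$ of the sustained and transient achromatic
channels are exposed as separate parameters (the alternative of tying them
is a one-line constraint in user code); nothing in the model requires them
to be equal.

## Spectral input

Spectral radiance input is a convenience path: measurement tables are
cone-native, so nothing downstream depends on it. Cone excitations are
trapezoidal integrals of the spectrum against 2° cone fundamentals
(linearly interpolated onto the spectrum's native grid), scaled by
0.689903, 0.348322 and 0.0371597 so that $L + M$ equals the
luminous-efficiency integral, i.e. luminance. The shipped fundamental and
daylight-white tables are **constructed analytic stand-ins** — split
log-Gaussian cone lobes peaking at 570/543/442 nm and a 6504 K Planckian
radiator — labelled `_synthetic` in their filenames. They preserve every
property the package relies on (positivity, unit-peak normalisation, the
$L + M$ = luminance identity, a fixed chromaticity for the grey
background) but are not colorimetric standards; users with measured
tables can substitute them via `options(chromaCSF.cone_fundamentals=)`.

## Fitting and evaluation

Consolidated measurement tables (one row per threshold, cone-native
columns, per-condition means over observers) are fitted jointly: all
mechanism parameters plus one multiplicative sensitivity shift $s_d$ per
dataset, with the reference dataset pinned at $s_d = 1$. The loss is

$$ \mathcal{L} = \sum_d \sum_i \big(\log_{10} S_{i,d} -
\log_{10}(s_d \tilde S_{i,d})\big)^2 + \lambda \sum_d (\log_{10} s_d)^2,
\qquad \lambda = 0.01 . $$

The penalty is read as a plain $\lambda\,\Sigma$ (no $1/D$ factor); the
per-dataset scaling is available as `lambda_scale = "per_dataset"`. Rows
with sensitivity below 1 are removed before fitting (they encode contrast
thresholds above 1). Optimisation is quasi-Newton (BFGS) in a transformed
space: $\log_{10}$ for positivity-constrained parameters and shifts, logit
for the $(0,1)$-boxed truncation depths, untransformed for the
transient-peak line coefficients, which may take either sign. To avoid
local minima, the optimiser multistarts from the supplied initialisation
plus seeded jitters of about ±0.1 log-units; the first start is always the
unjittered initialisation and the best run is returned. Everything is
deterministic given the seed.

Evaluation uses $k$-fold cross-validation **within** each dataset (default
five folds by seeded shuffle): each fold's model and shifts are fitted on
the training rows and the error on the held-out rows is reported in dB,
$20\,\mathrm{RMSE}(\log_{10} S)$. Shifts learned on the training rows are
reused for the same dataset's test rows: they are dataset-level nuisance
parameters describing a lab's procedure, not data-dependent predictions,
so reusing them does not leak test information. (Refitting shifts per
fold versus carrying full-data shifts is a genuinely open choice; the
package refits them with each training fold.)

## The synthetic generator

`synthetic_design()` / `generate_measurements()` emulate the structure of
consolidated threshold data: four sparse, non-overlapping dataset families
(an HDR-like wide-luminance reference family, a low-frequency chromatic
family, a peripheral disc family, and a joint spatial×temporal family),
per-dataset multiplicative shifts, and log-domain Gaussian noise with a
default of 3 dB standard deviation — the middle of the 2.5–6.7 dB
interobserver spread typical of such data. Noise is multiplicative in
sensitivity (additive in dB) to match both the error metric and the way
interobserver variability is reported for this kind of data.

The reference family includes red–green and yellow–violet modulations
alongside achromatic ones, as its real-world counterpart does. This
matters for identifiability: if the reference dataset (the one with
$s_d \equiv 1$) carried no chromatic content, the chromatic gain
parameters and the chromatic datasets' shifts would form a nearly flat
direction of the loss, restrained only by the weak $\lambda$ penalty, and
recovered shifts would drift.

What the generator does *not* emulate: psychometric-function sampling or
staircase procedures, observer-level variability (rows are per-condition
means), aperture idiosyncrasies, or calibration error. Passing the
generate→fit→evaluate loop therefore demonstrates the internal consistency
of the pipeline under the model's own assumptions — it does not by itself
validate the model against human data.

## Problem sizes and tolerances

The test suite and the acceptance script use: 1000 randomized stimuli for
the oracle-equivalence check (tolerance $10^{-6}$ relative); $10^{-9}$ for
the unit-energy identity and direction-magnitude invariance; about 400
synthetic points across the four families with 3 dB noise and one true
shift of 1.5 for the recovery loop, with a reduced multistart (2 for the
full fit, 1 per cross-validation fold) — sizes chosen to exercise every
model dimension while keeping a full run in the minutes range on one CPU.
The recovery loop passes when the cross-validated error lands within
[0.8, 1.25]× the injected noise and the recovered shift within ±10% of
truth.

## Known limitations

* No chromatic transient channels, no third temporal channel, no
  orientation tuning, no critical-flicker-fusion prediction, and no
  binocular summation: deliberately out of scope.
* The disc extension does not saturate the summation along the
  circumference and is not expected to extend to flickering discs.
* Cone fundamentals are standard-observer style (no age, macular pigment,
  or observer-specific corrections), and the shipped tables are analytic
  stand-ins (see above).
* At fixed stimulus area every CSF, chromatic included, must fall to zero
  as $\rho \to 0$ (the summation factor is proportional to $\rho$); the
  "low-pass" character of chromatic channels refers to their envelopes and
  to the experimentally probed frequency range.
* The default parameters are plausible, not fitted; quantitative
  comparisons against measured thresholds require fitting to real
  consolidated tables via `csf_fit()`.
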