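# chromaCSF

An R package for modelling human **contrast sensitivity** — the inverse of
the smallest detectable contrast — as an analytic function of six stimulus
properties: the **c**olour direction of modulation, stimulus **a**rea,
**s**patial and **t**emporal frequency, mean **l**uminance, and retinal
**e**ccentricity. It is aimed at vision scientists consolidating threshold
measurements from multiple studies, and at display/graphics engineers who
need a single callable detection model across a wide stimulus space
(HDR and wide-gamut displays, foveated AR/VR rendering, visibility
metrics).

## The model

A stimulus is a background in cone excitations $(L_0, M_0, S_0)$ (scaled so
$L+M$ is luminance in cd/m²) and a modulation direction
$(\Delta L, \Delta M, \Delta S)$. The direction is mapped to opponent
increments by a fixed matrix,

$$
\begin{pmatrix}\Delta A\\ \Delta R\\ \Delta V\end{pmatrix}
= \begin{pmatrix}1 & 1 & 0\\ 1 & -2.3112 & 0\\ -1 & -1 & 50.9875\end{pmatrix}
\begin{pmatrix}\Delta L\\ \Delta M\\ \Delta S\end{pmatrix},
$$

divided by luminance $Y = L_0 + M_0$ to give opponent contrasts
$\Delta C_c$, weighted by per-mechanism sensitivities and pooled into a
detection energy

$$
E = \sqrt{\sum_{c \in \{A, R, V\}} \big(S_c(\rho,\omega,Y,a,e)\,
\Delta C_c\big)^2},
$$

with detection at $E = 1$. Each mechanism sensitivity combines sustained
(low-pass) and — for the achromatic mechanism — transient (band-pass)
temporal channels with a luminance-dependent transient peak, truncated
log-parabola spatial tuning (band-pass achromatic, low-pass chromatic),
spatial summation up to a frequency-dependent critical area
($S_\text{area} = \rho\sqrt{a_x/(1+a_x/a)}$,
$a_x = a_0/(1+(\rho/\rho_0)^2)$), luminance-dependent gain
(DeVries–Rose rise, Weber plateau, high-luminance decline), and
log-linear eccentricity attenuation with nasal/temporal blending. Disc
stimuli are handled by an edge-detection extension,
$S^\text{disc}_c = (2\pi a)^{1/\beta}\max_\rho S_c(\rho,\omega,Y,
a_\text{disc},e)$ with fixed $\beta = 3.01142$, $a_\text{disc} = 2.42437$
deg². Reported sensitivity is the inverse RMS cone contrast at threshold
and is invariant to the magnitude of the direction vector.

The package also provides: a flat delimited schema for consolidated
threshold tables (`read_measurements()` / `write_measurements()`,
aperture standardisation, the sensitivity-below-1 filter), joint fitting
of all model parameters plus per-dataset multiplicative shifts $s_d$
(`csf_fit()`, quasi-Newton with seeded multistart, reference dataset
pinned at $s_d = 1$, shift regularisation $\lambda = 0.01$), five-fold
within-dataset cross-validation reported in dB
(`cross_validate()`, $20 \cdot \mathrm{RMSE}(\log_{10} S)$), a synthetic
measurement generator emulating the sparse multi-study structure
(`generate_measurements()`), and a command line (`inst/cli/csf`).

See the methods vignette
(`vignettes/contrast-sensitivity-model.Rmd`) for assumptions, parameter
semantics, numerical choices, and known limitations. The shipped
parameter set and the spectral tables under `inst/extdata/` labelled
`_synthetic` are constructed, plausible stand-ins, not fits to published
data — see the vignette before using them quantitatively.

## Worked example

```r
library(chromaCSF)

bg <- d65_background(30)                      # grey background, 30 cd/m^2
st <- csf_stimulus(bg = bg, dir = c(bg[["L"]], bg[["M"]], 0),  # luminance mod.
                   rho = 4, omega = 0, area = pi)              # 4 cpd Gabor
csf_detect(st, default_params())
#> <csf_detection> energy = 136.667, sensitivity = 167.383
```

The energy of 136.7 means the (arbitrary-magnitude) probe direction is
136.7 times above threshold; scaled down by that factor it sits exactly at
threshold, where its inverse cone contrast — the sensitivity — is 167.4.
A threshold Michelson-like cone contrast of 1/167.4 ≈ 0.6% at 4 cpd and
30 cd/m² is the familiar magnitude for foveal achromatic vision. Chromatic
and peripheral stimuli work the same way:

```r
csf_sensitivity(csf_stimulus(bg = bg, dir = c(1, -1, 0),   # red-green
                             rho = 0.5, area = pi), default_params())
#> [1] 1031.83
csf_sensitivity(csf_stimulus(bg = 100, dir = c(0, 0, 1),   # violet disc,
                             area = 3.14, ecc = 20,        # 20 deg nasal
                             theta = 180, shape = "disc"), default_params())
#> [1] 140.5569
```

Or from a shell:

```sh
inst/cli/csf sensitivity --lum 30 --dir-lms 20.49,9.51,0 --rho 4 --area 3.14
# sensitivity: 167.382645
inst/cli/csf simulate --out sim.csv --seed 5 --noise-db 3
inst/cli/csf fit --data sim.csv --out-params fit.txt --out-shifts shifts.csv
inst/cli/csf eval --data sim.csv --out report.txt --folds 5
inst/cli/csf plot --out csf.png --x rho --family lum --dir ach
```

## Measurement schema

Comma-separated, header required, cone-native:

```
dataset_id, L0, M0, S0, dL, dM, dS, rho_cpd, omega_hz, area_deg2,
ecc_deg, theta_deg, shape, sensitivity
```

`shape` is `gabor` or `disc` (disc rows leave `rho_cpd` empty); `theta_deg`
uses the right-eye convention (0 = temporal, 180 = nasal) and is 0 by
convention for foveal rows; sensitivities are per-condition means over
observers, in inverse cone contrast. A small example fixture is at
`inst/extdata/example_measurements.csv`. Apertures that are not Gaussian
envelopes are standardised with `standardize_aperture()` (circular
diameter $d \to \pi(d/2)^2$; rectangular area kept; Gaussian
$\sigma \to \pi\sigma^2$).

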