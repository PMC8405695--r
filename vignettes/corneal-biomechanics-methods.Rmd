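---
title: "Methods: corneal elastography, extensometry and their synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corneal elastography, extensometry and their synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CorneaBiomech)
```

This vignette explains the models implemented in **CorneaBiomech**, the
assumptions behind them, the numerical choices made where the methods
literature leaves room, and what the synthetic-data tests do and do not
demonstrate about real measurements.

## Phase-difference elastography

### Model

A spectral-domain OCT system records a complex-valued B-scan
$B(z, x)$ whose phase is sensitive to sub-wavelength axial displacement.
Under a small quasi-static load (here an ambient pressure reduction of
3 mmHg applied to the intact globe), a displacement field $u_z(z, x)$
shifts the phase of the deformed scan by
$\phi = 4\pi n\, u_z / \lambda$. The complex cross-correlation
$R(z,x) = B_\mathrm{ref}\cdot B_\mathrm{def}^{*}$ carries this phase,
and differencing it between adjacent depth pixels gives the axial
strain:

$$\Delta\varepsilon =
  \frac{\lambda \cdot \angle\!\left(R_s(z,x)\, R_s^{*}(z+1,x)\right)}
       {4\pi\, n\, \mathrm{asu}}.$$

Assumptions: the load is small enough that speckle does not decorrelate
(pure axial phase encoding, no lateral or out-of-plane motion), and the
per-pixel phase step stays inside $(-\pi, \pi]$, i.e.
$|\varepsilon| < \lambda / (4 n \cdot \mathrm{asu}) \approx 35.6$ ‰ at
the defaults. The observed corneal strains (≈ 5 ‰) sit comfortably
inside this range, which is why no explicit phase unwrapping is needed;
pixels at the saturation boundary are flagged invalid in the strain
mask rather than unwrapped.

### Averaging order: a deliberate choice

Two orders of operations produce formally similar estimators:

1. smooth $R$ spatially, then take the angle of the depth-adjacent
   product of the smoothed field;
2. form the depth-adjacent product of the raw correlation, then
   vector-average the product (complex phasors) and take the angle.

For a uniform strain, every raw product pixel carries *exactly* the
phase step $4\pi n \varepsilon\, \mathrm{asu}/\lambda$, so order (2) is
exact at any window size on noiseless data. Order (1) is not: the
smoothing window's shared-pixel terms enter the product with canceling
phase and bias the estimate toward zero — about 1–2 % at 5 ‰ strain
with the default window, growing with the phase step. The package
therefore uses order (2). The `CorrelationField` object still carries
the smoothed field (useful for inspection and for amplitude-based
masking); the strain estimator consumes the raw product and applies the
same window to it. This choice is what makes the noiseless round-trip
tests exact rather than "close".

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `wavelength` | 878 | nm | system centre wavelength |
| `asu` | 4.48 | μm/px | axial sampling unit (see below) |
| `refractiveIndex` | 1.375 | – | corneal stroma |
| `lateralPitch` | 12.5 | μm/px | lateral A-scan spacing |
| `window` | 5 × 9 | px | ≈ 22 μm × 112 μm strain resolution |
| `deltaP` | −3 | mmHg | pressure modulation; 133.322 Pa/mmHg |
| `radius` | 1.5 | mm | corneal curvature for Laplace stress |
| ROI | 0.5 mm zone | – | central averaging region |

The axial sampling unit is defined as the **physical depth per pixel in
tissue**. This is the only convention under which the strain equation
above recovers the imposed strain in a round trip, and it makes
thickness extraction a plain pixel count times `asu` with no further
refractive-index correction. (Treating `asu` as an in-air optical-path
increment would double-count $n$: the phase step would become
$4\pi\varepsilon\,\mathrm{asu}/\lambda$ and the equation would return
$\varepsilon/n$.)

The nominal 6 px axial window implied by the stated 26 μm axial strain
resolution is even; boxcar windows must be odd to be centred, so the
default is 5 px (22.4 μm), the nearest odd size.

Both reported ROI conventions are implemented: a physical 0.5 mm
central zone through the whole thickness (default) and a fixed 21 × 21
pixel box. The two stated descriptions of the pixel ROI (21 × 21 px vs
68 × 63 μm) are mutually inconsistent at the stated sampling; the
package implements both modes, records which was used, and does not
attempt to resolve the inconsistency.

### Segmentation

The corneal interfaces are found per A-scan by thresholding the
log-intensity midway between the 5th and 99.5th percentile levels
(background vs tissue), followed by a lateral running-median filter
(9 columns) to reject speckle dropouts. Thickness is the median
boundary separation over the central 0.5 mm, in pixels, times `asu`.
Featureless images (log-contrast below half a decade) raise an error
rather than returning a spurious thickness. The tissue mask handed to
the strain average is eroded axially by the correlation half-window
plus one pixel, so no averaged pixel mixes tissue and background phase.

### Modulus and sign convention

The Laplace stress $\Delta\sigma = \Delta p \cdot R / (2\,cct)$ is
signed like $\Delta p$; compression under a pressure decrease makes the
mean strain negative. The modulus is the ratio of magnitudes,
$E = |\Delta\sigma| / |\bar\varepsilon|$, so the physically expected
configuration yields a positive modulus. A zero mean strain is an
error, not an infinite modulus.

Group-level modulus summaries depend on whether one averages per-eye
ratios or divides group means; the published group values are not
reproducible from group-mean stress and strain alone, so the package
evaluates recovery per eye (ratio first, then averaging) and validates
against round trips rather than against the irreproducible aggregate.

## 2D extensometry

### Stress, strain, protocol

A corneal button clamped over a 1.6 mm aperture and loaded axially by a
hemispherical indenter deforms into a spherical cap. The tensile stress
is $\sigma = F/(2\pi R\, cct)$ and the strain is the arc-over-chord
stretch of the cap,
$\varepsilon = (r/R)\arcsin(R/r) - 1$, $r = (\Delta l^2+R^2)/(2\Delta l)$,
which is zero at zero travel, strictly increasing up to
$\Delta l = R$, and asymptotically $(2/3)(\Delta l/R)^2$ for small
travel. The as-published variant with $\sin$ in place of $\arcsin$ goes
negative for small travel and is not a physical stretch; it is kept
behind `form = "printed"` for comparison only.

Two radii appear in the geometry: the corneal curvature (1.5 mm, used
by the Laplace stress) and the holder aperture radius (0.8 mm). For
extensometry the deforming structure is the clamped aperture, so the
aperture radius is the default in stress and strain conversion; it is
configurable and recorded in every output.

The three-phase protocol is segmented from the trace shape. During
stress relaxation the *displacement* is held, so the discriminating
signature is a plateau of constant indenter travel (the force decays);
the splitter takes the longest constant-travel run of at least 5 s as
the relaxation segment, everything before as pre-conditioning, and
everything after as the rupture ramp. The relaxation clock re-zeroes at
the plateau start, defining $\sigma(t_0)$ for the reduction statistic
$100\,(\sigma(t_0)-\sigma(t_0{+}100\,\mathrm{s}))/\sigma(t_0)$.
Traces without a plateau still support ramp analyses; relaxation
analyses refuse explicitly. Rupture is an instantaneous force drop
exceeding 50 % of the running maximum; "premature" means the 10–15 %
strain window was not completed, in which case the eye is flagged and
no modulus is reported.

### Prony fitting

The relaxation modulus $E(t) = E_\infty + \sum_i E_i e^{-t/\tau_i}$
(3 terms) is fit to $\sigma(t) = \varepsilon_0 E(t)$ by constrained
least squares. Exponential-sum fitting is notoriously ill-conditioned,
so the implementation uses variable projection: for fixed time
constants the moduli enter linearly and are solved by non-negative
least squares; Nelder–Mead searches over $\log\tau$ from multi-start
initialisations spanning log-spaced decades (including the
$\{1, 10, 100\}$ s permutations); a bounded Levenberg–Marquardt polish
of all seven parameters follows, and is only accepted if it does not
worsen the residual. Ties are broken by sorting terms by ascending
$\tau$. Degenerate inputs behave sensibly: a constant trace fits as
$E_\infty = \bar\sigma/\varepsilon_0$ with vanishing decaying terms
(the NNLS step falls back to a single active-set pass when the design
is collinear).

**Identifiability.** On a 120 s window, a noiseless trace determines
all seven parameters: the round trips recover the wild-type constants
exactly and the Col5a1 constants — whose $\tau_2 = 56$ s and
$\tau_3 = 57$ s are nearly degenerate — to within 2 % on $\tau_3$. With
noise the slow tail is a different matter: at 1 % noise the Fisher
information gives relative standard errors above 100 % for $E_\infty$
and several hundred percent for $\tau_3$ (the long-term modulus trades
off against an ever-slower exponential that the window cannot
distinguish). The noisy-recovery tests therefore assert the
identifiable quantities — the fast term $(E_1, \tau_1)$, the
instantaneous modulus $E(0)$, the fitted relaxation function inside the
window, and the 100 s statistic — rather than pretending the tail
parameters are measurable at that noise level.

### Synthetic ramp construction

The synthetic rupture ramp embodies a target stress–strain slope: the
strain is ramped linearly to 0.5 over the nominal programme duration
(12 s at the default 0.3 N/s), stress follows the linear law anchored
at the preload, and travel is obtained by numerically inverting the
arc-chord relation (monotone bisection to $10^{-12}$). The full
0.4–4.0 N force range is *not* reproduced: with tens-of-kPa window
slopes, a linear stress–strain law cannot span MPa-scale aperture
stresses inside the invertible strain range ($\varepsilon < \pi/2 - 1$).
This mirrors a real inconsistency of scales between the aperture stress
at the preload (hundreds of kPa) and the reported window moduli
(tens of kPa); the generated ramp carries exactly the quantity the
analysis measures. For the same reason the ramp noise level is
specified relative to the force span of the ramp rather than the
preload, which would otherwise bury the slope signal entirely.

## Synthetic data: what it emulates, and what it does not

The phantom generator produces fully developed speckle (circular
Gaussian complex reflectivity) inside a circular-arc shell of apex
thickness `cct` and curvature radius 1.5 mm, zero outside, with an
imposed uniform axial strain encoded as a depth-cumulative phase ramp
and additive complex white Gaussian noise at a chosen SNR. Relaxation
traces are forward evaluations of a Prony model at constant strain
(default $\varepsilon_0 = 0.18$, the strain at which a 0.4 N preload on
a 148 μm cornea meets the reference instantaneous modulus) plus
Gaussian noise; cohorts are per-eye normal draws at the group means and
SDs. All generators are bit-reproducible under a fixed seed. The
per-eye phase noise of the real instrument is not reported anywhere, so
the SNR default (30 dB in the emulation configuration) is a documented
free parameter, not an inferred one.

Passing round trips therefore demonstrate that the *estimators* are
correct and stable under the stated noise — they do not validate the
forward models against real tissue. In particular the phantoms contain
no speckle decorrelation, no motion, no depth-dependent signal
roll-off, and no strain heterogeneity; real strain maps are noisier
than phantom maps at equal SNR, and real relaxation curves need not be
a 3-term Prony series.

## Cohort statistics

Each variable is compared with the Shapiro–Wilk-gated two-sample
workflow: Student's t-test (two-tailed, pooled variance) when **both**
groups pass normality at $\alpha = 0.05$, otherwise the Mann–Whitney U
test. Requiring both groups to pass is the conservative reading of the
gate. Zero-variance groups cannot be Shapiro–Wilk-tested and route to
the rank path; completely tied samples report $p = 1$. No
multiple-testing correction is applied, matching the reported workflow;
summary SDs are sample SDs ($n-1$), and between-group ratios are ratios
of means (larger over smaller) rounded to one decimal.

## Problem sizes

The test suite and the acceptance script use phantoms of 101–201
A-scans (the 0.5 mm central analysis zone spans 40 columns at the
12.5 μm pitch, so these widths leave a wide margin), 10 Hz × 120 s
relaxation traces, 15-seed noisy-fit replicates and 100–200-seed
statistical simulations. These sizes were chosen so the full
verification runs in about a minute while every assertion retains its
statistical meaning; the study emulation accepts larger sizes through
its configuration.

## Known limitations

* The strain estimator assumes pure axial displacement; it has no
  decorrelation handling and will degrade on data with lateral motion.
* Segmentation assumes exactly one bright layer per A-scan; multi-layer
  or detached-tissue images are out of scope.
* The Prony fit reports, but cannot overcome, the identifiability limit
  of time constants comparable to or exceeding the observation window.
* The interface between pipeline stages assumes SI-consistent units as
  documented per function (μm, mm, mmHg, Pa); there is no unit-carrying
  type system.
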