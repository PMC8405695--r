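# CorneaBiomech

Corneal biomechanical characterization for murine eyes from two
complementary measurement modalities, built for researchers quantifying
corneal stiffness and viscoelasticity — e.g. when comparing a
collagen-V-haploinsufficient (Col5a1+/-, Ehlers–Danlos model) cohort
against wild-type littermates:

1. **Quasi-static optical coherence elastography (OCE).** A reference
   complex B-scan at ambient pressure and a deformed B-scan after a small
   pressure modulation (Δp = −3 mmHg) are combined through the complex
   cross-correlation R(z,x) = B_ref · B_def\*. The axial strain follows
   from the depth-adjacent phase difference,

       Δε = λ · ∠( R_s(z,x) · R_s*(z+1,x) ) / (4π · n · asu),

   with λ the centre wavelength (878 nm), n the corneal refractive index
   (1.375) and asu the axial sampling unit (4.48 μm). Central corneal
   thickness (cct) is segmented from the structural image, the membrane
   stress follows Laplace's thin-shell law Δσ = Δp·R / (2·cct) with
   R = 1.5 mm the corneal curvature radius, and the elastic modulus is
   E_oct = Δσ / Δε.

2. **2D extensometry.** Force/indenter-travel traces from a clamped
   corneal button (aperture radius 0.8 mm) are converted to tensile
   stress σ = F / (2π·R·cct) and arc-chord strain
   ε = (r/R)·arcsin(R/r) − 1 with r = (Δl² + R²)/(2Δl). The three-phase
   protocol (pre-conditioning cycles, 120 s stress relaxation at a 0.4 N
   preload, rupture ramp to 4 N) is segmented automatically; the
   relaxation segment yields the percent stress reduction at 100 s and a
   constrained 3-term Prony fit E(t) = E∞ + Σ Eᵢ·exp(−t/τᵢ); the ramp
   yields the mean stress–strain slope between 10 and 15 % strain
   (E_ext).

3. **Synthetic data and cohort statistics.** Every input the pipeline
   consumes can be generated with known ground truth — speckle B-scan
   phantoms with an imposed axial strain, Prony-model relaxation and ramp
   traces, and two-group per-eye cohorts — so each stage is verifiable by
   parameter recovery. Group comparisons follow a normality-gated
   workflow (Shapiro–Wilk, then Student's t-test or Mann–Whitney U).

## Worked example

Simulate a Col5a1+/--like eye (thin cornea, stiff in OCE) and analyse it
end to end:

```r
library(CorneaBiomech)

pair <- simulateScanPair(cct = 125, imposedStrain = -4.74e-3,
                         nAscans = 201, snrDb = 30, deltaP = -3, seed = 42)
out <- analyzeScanPair(pair)
#> cct = 125.4 um | strain = -4.74 permil | stress = -2391 Pa | E = 505 kPa
```

The recovered thickness matches the phantom's ground truth to within one
axial pixel, the mean central strain reproduces the imposed −4.74 ‰, and
the modulus (505 kPa) recovers the value implied by the injected stress
and strain.

Fit the reference wild-type Prony constants from a synthetic relaxation
trace:

```r
wt <- mouseCorneaPronyConstants("wt")
tr <- simulateRelaxationTrace(wt, eps0 = 0.18,
                              geometry = LoadingGeometry(148, 0.8))
sigma <- stressFromForce(traceForce(tr), traceGeometry(tr))
fitProny(sigma, traceTime(tr), eps0 = 0.18)
#> RelaxationResult: 45.2% stress reduction; fit RSS 1.78e-18 Pa^2
#> PronyModel: E_inf = 1.18 MPa, 3 terms
#>   E_1 = 0.43 MPa, tau_1 = 3.1 s
#>   E_2 = 0.51 MPa, tau_2 = 51 s
#>   E_3 = 0.88 MPa, tau_3 = 124 s
```

All generating constants (E∞ = 1.18 MPa, τ₃ = 124 s, …) are recovered
exactly, and the reported 45.2 % reduction is the closed-form relaxation
of the fitted model at 100 s.

A full two-group study emulation — phantoms and traces per eye, analysis,
summary table and gated comparisons — runs with
`runStudyEmulation(defaultRunConfig(seed = 1), outDir = "study_run")`.

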