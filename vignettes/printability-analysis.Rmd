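---
title: "Printability analysis for microvalve droplet bioprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Printability analysis for microvalve droplet bioprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvejet)
```

## The problem

Microvalve-based bioprinting (MBB) ejects a cylindrical liquid ligament each
time a solenoid valve opens for a dwell time (typically 1000 µs) under back
pressure; the ligament pinches off into one or more droplets. Whether a
bioink prints cleanly — one droplet per pulse, no satellites, no splashing on
impact — is governed by the balance of inertial, viscous, capillary and
gravitational forces, which this package quantifies with the standard
dimensionless groups:

* Weber number, We = ρv²D/σ — inertia vs surface tension,
* Reynolds number, Re = ρvD/μ — inertia vs viscous dissipation,
* Ohnesorge number, Oh = μ/√(ρσD) = √We/Re, and Z = 1/Oh,
* Froude number, Fr = v/√(gD) — inertia vs gravity,
* splash parameter K = Oh·Re^1.25 — impact spreading vs deposition,
* Bond number Bo = We/Fr² = ρgD²/σ.

The characteristic length is the nozzle orifice diameter D (250 µm for the
hardware these defaults describe) and the characteristic velocity the
measured ligament velocity. These two choices are not arbitrary: with D as
the length scale, Oh computed from printed (We, Re) pairs agrees with
independently printed Oh values across every bioink family we checked, which
pins down the convention.

The canonical drop-on-demand result is that stable single-droplet jetting
occupies roughly 1 ⩽ Z ⩽ 10: below Z = 1 the ink is too viscous (or the
impulse too weak) for clean detachment, above Z = 10 rapid capillary
thinning makes satellites likely. `classify_z()` applies these bands with
closed boundaries (Z = 1 and Z = 10 count as printable).

## Rheology: the power-law viscosity model

Bioinks are shear-thinning; over the shear-rate window of a rotational
rheometer sweep (0.1–1000 1/s) their apparent viscosity is well described by

μ(γ̇) = K γ̇ⁿ⁻¹,

with consistency index K (Pa·sⁿ) and flow index n (n = 1 Newtonian, n < 1
shear-thinning). `fit_power_law()` estimates (K, n) by damped
(Levenberg–Marquardt) least squares on the objective

Σᵢ wᵢ (μᵢ − K γ̇ᵢⁿ⁻¹)², with wᵢ = 1/μᵢ² by default.

Inverse-square weighting makes the objective the sum of squared *relative*
residuals. This matters because a flow curve spans several decades of
viscosity: unweighted least squares would be dominated entirely by the
low-shear, high-viscosity points and fit the high-shear decade — the decade
that actually controls nozzle flow — poorly.

Numerical choices, all configurable:

* **Starting point.** Ordinary log–log regression of μ on γ̇; for power-law
  data this is near the global optimum, and the damped solver then refines
  in linear space under the chosen weights.
* **Parameterisation.** K is optimised as log K, so the positivity
  constraint is built in and the step scaling is sane across decades.
* **Bounds.** K ∈ (10⁻⁸, 10⁴) Pa·sⁿ, n ∈ (0.05, 1.5); fits pinned at a
  bound are flagged (`at_bounds`) rather than silently returned. Observed
  bioink fits live well inside, typically 0.15 < n ⩽ 1.
* **Shear-rate floor.** Cleaning drops rows with γ̇ ⩽ 10⁻³ 1/s (a rheometer
  sweep nominally starts at zero, where apparent viscosity is undefined);
  evaluation regularises with `apparent_viscosity(fit, γ̇, floor)`,
  returning K·max(γ̇, floor)ⁿ⁻¹ so the n < 1 zero-shear singularity becomes
  a high but finite plateau. The default floor is 10⁻² 1/s.
* **Sweep direction.** Up- and down-sweeps are fitted separately; no
  thixotropy model is attempted.
* **No automatic outlier rejection.** Replicate scatter (batch-to-batch
  variation) is reported through residual diagnostics, not silently
  trimmed.

Oscillatory amplitude sweeps are summarised by `summarize_moduli()`: mean
G′, mean G″ and tan δ over the user-declared linear viscoelastic strain
window. Nothing is fitted; the window must be chosen by inspection.

## Ligament metrology

`calibrate_drop_volume()` implements gravimetric calibration: a burst of
(by default) 1000 droplets is dispensed into a pre-weighed tube, and the
per-drop volume is mass/(drops × ρ). A calibration session is **accepted**
only if both

* the coefficient of variation over ⩾ 3 replicate bursts at the operating
  dwell is ⩽ 5%, and
* volume versus dwell time over ⩾ 3 bracketing dwell times is linear with
  R² ⩾ 0.99.

Both thresholds are inclusive, and the conjunction is exact: failing either
gate fails the session. With fewer than three distinct dwell times the R² is
undefined and the session cannot be accepted. One numerical wrinkle: an
exactly linear — including exactly constant — volume–dwell relation has zero
residual *and* possibly zero total variance, where the textbook R² is 0/0;
we report R² = 1 when the residual sum of squares vanishes at the scale of
the measurement, since a constant response to dwell is a perfect line.

Jet velocity comes from `estimate_velocity()`: the OLS slope of leading-edge
displacement against time over a stroboscopic sweep (50 µs frame steps), with
a Theil–Sen option for sweeps with occasional mis-tracked frames. The
estimate is invariant to time- and position-origin shifts. Geometric
descriptors are `aspect_ratio()` (L_ar = L_l/D) and `equivalent_diameter()`
(d_eq = (6V/π)^⅓). Ligament volume and per-drop volume name the same
gravimetric quantity here. Cell density is carried as a covariate only — no
viscosity correction for cell loading is applied, because measured volumes
across 0.5–3 × 10⁶ cells/mL stay within a narrow band.

## Nozzle flow

During the ~1 ms dwell the flow inside the short cylindrical nozzle
(radius 0.125 mm, length 0.84 mm) is steady, laminar and — assuming fully
developed conditions — has an exact solution for a power-law fluid:

u(r) = (Q/πR²)·((3n+1)/(n+1))·(1 − (r/R)^((n+1)/n)),
γ̇_w = ((3n+1)/(4n))·4Q/(πR³), γ̇(r) = γ̇_w (r/R)^(1/n),

with Q = V_lig/dwell from the gravimetric calibration. At n = 1 this is
classical Poiseuille flow (parabolic velocity, linear shear rate); for
shear-thinning inks the profile is flatter (centreline-to-mean ratio
(3n+1)/(n+1), e.g. ≈ 1.36 at n = 0.22 versus 2.0 Newtonian) and the shear
rate concentrates at the wall. We chose the analytic solution deliberately:
for this geometry and these boundary conditions it *is* the converged
target of an axisymmetric finite-element solve of the same problem, so a
mesh, stabilisation and solver add cost without adding information.
Entrance-length effects over the 0.84 mm are neglected, consistent with the
fully developed assumption. The apparent-viscosity profile reuses the same
shear-rate floor as the rheology module at the centreline, where γ̇ → 0.

For a typical 60 nl ligament per 1 ms dwell, γ̇_w ≈ 3.9 × 10⁴ 1/s at n = 1
and higher for shear-thinning indices — squarely in the 10⁴–10⁵ 1/s band
where wall shear exposure is the relevant concern for encapsulated cells.
(A shear-dose/viability model is a documented extension, not implemented.)

## Regimes, frequency bands and maps

`classify_regimes()` attaches three labels to each condition: the Z band,
the splash class, and an actuation-frequency band, with a text trace of
every threshold applied.

* **Splash threshold.** K = Oh·Re^1.25 above K_c means splash, at or below
  means deposition. The default K_c = 57.7 is the classical
  deposition/splash limit from the droplet-impact literature — it is an
  external default, not a value measured by this workflow, and should be
  overridden per substrate.
* **Frequency bands.** The jetting frequency must leave time for pinch-off:
  t_p ≈ τ_c(1 + α·Oh) with τ_c = √(ρR³/σ) (a few tenths of a millisecond
  for a 250 µm nozzle, so tens to a few hundred Hz are workable). The
  viscous-factor coefficient α defaults to 2.0; the scaling is standard, the
  coefficient is a package default, and both are configurable. The
  recommended operating bands are a data table (`default_frequency_bands()`),
  not code: Z < 1 → 20–50 Hz; 1 ⩽ Z < 5 → 50–150 Hz; 5 ⩽ Z ⩽ 30 →
  100–200 Hz; Z > 30 → 20–100 Hz, all clipped to the valve's 20–200 Hz
  window. The top band for very high Z encodes the practical rule that
  extremely low-viscosity inks need throttling to suppress satellites, even
  though their pinch-off time would permit faster jetting; moderately
  high-Z inks (Z up to ~30) eject cleanly at the top of the window. Where
  published guidance and figure-caption zone names disagree on this point,
  the package follows the in-text guidance.

`build_map()` projects classified conditions onto six planes — L_ar–Oh,
We–Fr, We–Oh, We–Re, Oh–Re and Oh–frequency — together with the Z = 1 and
Z = 10 boundary loci expressed in each plane's coordinates (in We–Re space
the curves Re = √We·Z; in Oh-indexed planes the lines Oh = 1/Z; on Oh–f the
operating-window edges). Maps never relabel: a point's stored regime always
equals the regime recomputed from its coordinates. The zone shading is
advisory — these maps are a semi-quantitative screening tool, not a
predictive model of breakup.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, deterministically
from a seed:

* `gen_flow_curve()` — power-law viscosity on a log-spaced grid spanning
  0.1–1000 1/s (the rheometer sweep range), with multiplicative lognormal
  noise; 1% relative SD emulates a well-behaved instrument, 10% a noisy
  one.
* `gen_displacement()` — linear leading-edge displacement at 50 µs frame
  steps with Gaussian position jitter (10 µm is a realistic edge-detection
  uncertainty at this magnification).
* `gen_drop_masses()` — burst masses linear in dwell with a stated
  coefficient of variation, at the operating dwell plus bracketing dwells.

These fixtures exercise the estimators under the noise models the
estimators assume. They do **not** emulate thixotropy, viscoelastic recoil,
ligament necking dynamics, satellite formation, or any imaging artefact —
so green tests certify the numerics (recovery, invariances, conservation
laws, boundary behaviour), not the fidelity of the power-law model to any
particular real bioink. Test problem sizes (30-point curves, 200–500 seeds
for stochastic-recovery checks, 10³ draws for round-trip properties) were
chosen as the smallest sizes at which the asserted statistics are stable.

## Using published summary tables

Raw rheometry is not always available. `read_dimensionless_table()` ingests
a per-condition summary (We, Re, Oh, Fr, ligament geometry per formulation,
with or without surfactant), fills missing Oh from √We/Re, and feeds the
classification and mapping machinery directly. The package ships such a
table (`inst/extdata/dimensionless_conditions.csv`) transcribed from
published per-condition measurements of six bioink families (fibrinogen,
collagen I, Matrigel, alginate, agarose, GelMA) on a 250 µm microvalve
nozzle; partially reported rows carry NA and are skipped where a map or
classification needs the missing coordinate.

```{r example, eval = FALSE}
tab <- read_dimensionless_table(
  system.file("extdata", "dimensionless_conditions.csv",
              package = "valvejet"))
lab <- classify_regimes(tab[!is.na(tab$z) & !is.na(tab$k_splash), ])
autoplot(build_map(lab[!is.na(lab$we) & !is.na(lab$re), ], "We_Re"))
```

## Known limitations

* The power-law model has no zero-shear plateau and no yield stress; inks
  better described by Carreau, Cross or Herschel–Bulkley laws will show
  structured residuals (reported, not corrected).
* The characteristic viscosity entering Re and Oh is a modelling choice.
  The package supports a directly measured high-shear viscosity or a
  power-law fit evaluated at γ̇ = v/D, logs which path was used, and leaves
  the choice to the user; back-solving published fibrinogen numbers gives
  ≈ 1 mPa·s, i.e. a high-shear value, which motivates the v/D default.
* Nozzle flow is fully developed and single-phase: no valve-opening
  transient, no free-surface jet, no entrance region.
* Regime boundaries (Z bands, K_c, frequency bands) are literature
  conventions plus practitioner guidance, exposed as configuration — they
  are screening thresholds, not fitted decision boundaries.
* Contact angles are stored metadata; the package does not compute them
  from images, and no image analysis of any kind is included.
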