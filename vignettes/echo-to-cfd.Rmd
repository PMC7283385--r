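---
title: "From Doppler echocardiography to CFD boundary conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From Doppler echocardiography to CFD boundary conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coaflow)
```

## The problem

Coarctation of the aorta (CoA) is a congenital narrowing of the aorta,
usually at the isthmus. The clinical severity marker is the peak-systolic
pressure difference across the stenosis; repair is generally indicated above
20 mmHg. Patient-specific computational fluid dynamics (CFD) can refine that
estimate and let clinicians explore repairs *in silico*, but in settings
where phase-contrast MRI is unavailable the boundary conditions must come
from Doppler transthoracic echocardiography: velocity–time envelopes at the
aortic inlet, the three supra-aortic branches (innominate, left common
carotid, left subclavian), the coarctation itself, and the descending aorta.

`coaflow` implements the preprocessing between those digitized envelopes and
a ready-to-run incompressible-flow case: waveform cleaning, normalization to
a common cardiac period, conversion to volumetric flow, mass-consistent flow
splitting under three data-availability regimes, severity metrics from
cross-section geometry, OpenFOAM dictionary generation, and a
grid-independence report for the resulting simulations.

## Waveform model and processing

A `velocity_waveform` holds one cardiac cycle of the Doppler envelope
magnitude: strictly increasing times, non-negative velocities, at least
three samples. Extracting a single beat from a multi-beat recording is the
operator's job; the reader validates but does not segment.

Processing applies, in order:

1. **Smoothing** (`smooth_waveform`): each sample is replaced by the value
   of a least-squares quadratic fitted over a centered window (default 7
   samples). A local polynomial preserves pulse peaks far better than a
   moving average, which matters because every downstream quantity is
   peak-based. Near the ends the window shrinks symmetrically (so the fit
   stays centered and the endpoints are returned unchanged), and fitted
   values are clamped at zero because an envelope magnitude cannot be
   negative.
2. **Period normalization** (`normalize_period`): the time axis is linearly
   rescaled to 0.5 s (a 120 bpm reference), leaving velocities untouched, so
   traces recorded at different instantaneous heart rates can be combined.
   This deliberately ignores the physiological reshaping of the waveform at
   different rates; it is a comparability device, not a model.
3. **Peak extraction** (`peak_of`): the maximum sampled value, earliest
   occurrence winning ties — peak systole is the *first* systolic event.

The simplified Bernoulli relation converts a peak velocity to a clinical
pressure difference, $\Delta P = 4 v^2$ (mmHg from m/s). The coefficient 4
is the clinical rounding of the dynamic-pressure conversion
$\tfrac12 \rho \times 0.00750062$; with $\rho = 1060\,$kg/m$^3$ and the
Pa→mmHg factor 0.00750062 the exact value is 3.9753, a 0.62 % difference
the test suite pins. Frictional losses and the proximal velocity are neglected, which is
why CFD-derived pressure differences typically come out below the echo
estimate in stenotic flow.

Volumetric flow uses $Q = A_{patch}\, v_{ave}$. Doppler records the maximum
velocity in the beam, so at outlet patches the average is taken equal to the
maximum, while at the inlet the average is taken as half the maximum as for
a parabolic profile. Patch areas come from echo diameters under a circular
cross-section assumption, $A = \pi (d/2000)^2$ with $d$ in mm.

## Flow-split regimes

Boundary conditions must conserve mass (rigid walls), but independently
measured site flows never do. Three regimes cover decreasing data
availability; the tunable factors live in a `split_factors` object.

* **Full data** (`conserve_mass_scale`): every outlet flow is multiplied by
  the single factor that makes the peak of the summed outlet flows equal the
  peak inlet flow. The factor is a data-quality diagnostic in its own right
  (values near 1 mean consistent measurements).
* **Partial post-repair data** (`derive_case2_outlets`): when only the inlet
  and innominate were measured, the innominate inherits the full-data
  scaling, the carotid and subclavian are imputed from the full-data
  peak-flow ratios relative to the innominate, and the descending aorta —
  which shows essentially no diastolic flow through a repaired stenosis —
  reuses the inlet waveform shape scaled by a factor $s$ solved so the
  peak of the summed outlets matches the peak inlet flow. Because the peak
  of a sum is not linear in $s$ when site waveforms are phase-lagged, $s$
  is found by bisection on $(0, 2]$ to $10^{-10}$.
* **Hypothetical healthy** (`derive_case3_outlets`): with no data at all, a
  fixed fraction of the inlet flow (default 0.70, the accepted healthy
  descending-aorta share, configurable within (0, 1)) leaves distally and
  the remainder splits across the branches by patch-area ratio. This split
  conserves mass pointwise by construction and is invariant under uniform
  rescaling of the areas.

Steady boundary values are read at $t^\*$, the first time of the inlet-flow
maximum, by linear interpolation of each outlet (`extract_steady_bcs`). The
inlet boundary value is then *defined* as the sum of the outlet steady
values — not the raw inlet peak — so every `boundary_spec` satisfies the
conservation contract $Q_{in} = \sum Q_{out}$ to $10^{-9}$ relative by
construction. Phase-lagged outlets therefore contribute less than their own
peaks, and the written inlet value can differ from the measured inlet peak;
the discrepancy is reported, not hidden. An alternative sometimes used —
phase-shifting the outlet waveforms so their peaks align with the inlet —
is available as an explicit comparison strategy but is off by default.

### Numerical conventions

Summation of outlet waveforms happens on a common uniform 1000-point grid
(`resample_uniform`). Both the inlet peak and the summed-outlet peak are
read off that same grid: mixing a native-sample peak with an interpolated
one biases the solved factors by the interpolation deficit at the pulse
peak (order $10^{-4}$ relative for typical sampling), which matters at the
tolerances the construct-then-recover tests enforce. Degenerate inputs —
zero summed peak, a zero innominate reference, no admissible $s$ — raise
typed errors rather than returning factors outside $(0, 2]$.

## Geometry metrics

Severity grading uses hydraulic diameters, $D_h = 4A/P$, which equal
geometric diameters for circular lumens and are the definition the severity
table values satisfy. Contours (mm) are measured by the shoelace formula
with an explicit simple-polygon check; direct (area, perimeter) pairs are
accepted as well. The coarctation ratio is the coarctation $D_h$ over the
descending-aorta $D_h$ at the diaphragm. Outlet patches are extruded by ten
hydraulic diameters (configurable) to keep recirculation away from the
outlet plane. A minimal STL reader and plane-cut utility
(`plane_cut_contour`, `min_hydraulic_diameter`) can sweep user-supplied
planes along a stenosis and report the narrowest section; since the
narrowest-plane search strategy is not standardized, the user chooses the
planes and the package reports the minimum found.

## OpenFOAM case generation

`write_openfoam_case` emits `0/U`, `0/p`, `constant/transportProperties`,
`system/fvSchemes` and `system/fvSolution` in the version-6 keyword set:
`flowRateInletVelocity` at the inlet, `flowRateOutletVelocity` with positive
magnitudes at each outlet (the built-in conditions handle direction),
`noSlip` at the wall, Newtonian transport with $\nu = 3.78\times10^{-6}\,$
m$^2$/s and $\rho = 1060\,$kg/m$^3$, a `backward` time scheme and a bounded
second-order `linearUpwind` convective scheme. The exact convective scheme
name is a declared default — "higher-order and bounded" is the requirement,
not a specific stencil. Pressure treatment is `zeroGradient` on all patches
with an internal reference (cell 0, value 0) by default; the simplified
zero-pressure-outlet variant used for grid studies is behind the
`zero_pressure_outlets` flag. Writers are deterministic (numbers are
printed with the shortest decimal representation that round-trips the
double), so regenerating a case from the same spec is byte-identical, and
the bundled reader recovers every flow value exactly. Solvers, meshing and
decomposition are out of scope.

Solver output sampled along assessment lines (inlet, arch,
proximal/local/distal stenosis, outlets) is read back by
`read_sampled_lines`; pressures are kept kinematic (m$^2$/s$^2$) and
converted with `kinematic_pressure_to_mmHg` only for display.

## Grid-independence assessment

For each pair of successive mesh resolutions (coarsest first, e.g. 0.5M →
2M → 4M cells) and each shared station, `assess_grid_independence` compares
the trapezoidal station-mean pressure (relative change, finer mesh as
reference) and the velocity profile (relative $L_2$ and max norms of the
coarse profile interpolated onto the fine positions over their overlap).
The study passes when **every** metric is at or below the threshold
(default 5 %). Applying the criterion to both pressure and velocity is the
conservative reading of "flow parameters independent within 5 %"; adjacent
pairs rather than all pairs mirror standard refinement practice. A
relative norm against an identically zero reference profile is undefined
and raises an error.

## The synthetic patient generator

Real envelopes are unavailable in a test environment, so `gen_waveform`
draws from a parametric family: a raised-cosine systolic pulse (systolic
fraction 0.35 of the cycle), an optional exponential diastolic tail whose
amplitude fraction models the clinically important continuation of flow
through a stenosis during diastole (time constant one period by default),
a cyclic site phase lag, and additive Gaussian sampling noise clamped at
zero (envelopes are non-negative). The clean envelope is rescaled so its
sampled maximum equals the requested peak exactly, making peak-based
oracles sharp. Defaults: 120 bpm, 201 samples per cycle — a dense but
plausible digitization of a printed trace.

`gen_patient` assembles site sets with reference peak velocities and
diameters at clinically representative magnitudes (ascending aorta 1.3 m/s
/ 13.0 mm, coarctation jet 3.49 m/s pre-repair, and so on), then
*calibrates* amplitudes so the ground-truth split factors stored with the
patient are recovered exactly by the noise-free pipeline: outlet envelopes
are scaled so the mass-conservation factor is exactly the stored
`outlet_scale` (default 0.8243), and in the partial scenario the innominate
amplitude is set so the solved descending factor is exactly the stored
`descending_inlet_scale` (default 0.5101). Noise is added *after*
calibration, so noisy recovery is genuinely approximate. Waveforms are
bit-reproducible for a fixed seed and the generator never touches the
caller's RNG stream.

What the generator does **not** emulate: spectral broadening, beam-angle
dependence, acoustic-window dropouts, beat-to-beat variability, or
waveform reshaping with heart rate. Passing recovery tests therefore show
the pipeline's arithmetic is faithful, not that clinical digitization error
behaves like iid Gaussian noise.

### A known sensitivity

The split factors are ratios of sampled maxima. After window-7 quadratic
smoothing, additive envelope noise of standard deviation $\sigma$ retains
roughly $\sigma\sqrt{3/7}$ near the peak, and the maximum over the samples
competing in the flat top of a raised-cosine pulse sits a further factor
above that. For branch-vessel envelopes below about 1 m/s this makes
peak-based factor recovery degrade roughly in proportion to
$\sigma / v_{peak}$, and the relative error of the solved case-2 factor is
amplified by $(1-s)/s$. Users adding realistic noise should expect
factor-recovery errors of a few percent per 0.05 m/s of envelope noise at
these amplitudes; averaging over several digitized beats, not a different
estimator, is the practical remedy.

## Problem sizes and test design

The test suite builds every fixture in code: 201-sample cycles, 1000-point
summation grids, 20-replicate seeded recovery loops, 96×40-facet synthetic
tubes for the plane-cut checks, and hand-written sampled-line files for the
grid assessment. Independent oracles are used wherever a closed form exists
(parabola reproduction for the smoother, inscribed-polygon limits for
contour metrics, trapezoid sums recomputed by brute force, Savitzky–Golay
interior-point agreement for the local quadratic fit).

## Limitations

* One cycle in, one cycle out: no beat detection, ECG parsing, or
  multi-beat averaging.
* The healthy-split branch areas come from whatever geometry source the
  user supplies; with only echo diameters, the circular assumption feeds
  the area ratios directly.
* The imputation regime inherits full-data branch ratios unchanged; any
  post-repair redistribution of supra-aortic flow is invisible to it.
* Case files are skeletons: mesh, solver invocation and convergence control
  remain the user's responsibility.
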