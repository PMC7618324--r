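---
title: "Models and methods: creep rheology, pressurized-tube mechanics and tissue-shape quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotube)
```

## The scientific problem

During early vertebrate development the brain inflates dramatically while
the spinal cord keeps its narrow shape, even though both are part of one
continuous epithelial tube pressurized by the same lumen fluid (tens of
pascals, rising from roughly 15 Pa at the onset of expansion to roughly
25 Pa later). The divergence can be explained mechanically if the dorsal
hindbrain tissue is more *fluid* — creeps more under sustained stress —
than the dorsal spinal cord, so that the same pressure thins the hindbrain
roof while the spinal cord resists. This package implements the three
quantitative pillars of that argument so they can be exercised end to end
on synthetic data with known ground truth:

1. **AFM creep rheology** — extracting a fluidity exponent and an
   instantaneous stiffness from indentation creep experiments;
2. **pressurized-tube mechanics** — a Maxwell viscoelastic thin-shell
   tube with a mechanically distinct dorsal sector, plus the
   ferrofluid-droplet forward model used to infer tissue viscosity;
3. **tissue-shape quantification** — circumferential thickness profiles,
   dorsal roof metrics, apical intensity binning, and the accompanying
   small-cohort statistics.

## Power-law creep rheology of AFM indentation

A spherical bead (diameter 89.3 um) is pressed into the dorsal tissue at
10 um/s until the force reaches 50 or 75 nN, then the force is held for
3 s while the indentation keeps creeping. The analysis is two-stage.

**Stage 1 — the force ramp.** The force trace is fit by the piecewise
model

$$F(t) = F_C \cdot \begin{cases} 0 & t < t_C\\
((t-t_C)/\Delta t_A)^\alpha & t_C \le t < t_C + \Delta t_A\\
1 & t \ge t_C + \Delta t_A,\end{cases}$$

with the ramp-shape exponent $\alpha$ constrained to $[1,2]$ by the
bounded optimiser itself ($\alpha = 1$ is a linear ramp, $\alpha \to 2$
polynomial). `fit_force_ramp()` uses bounded least squares with three
starts in $\alpha$; the model is non-smooth in $t_C$, so a line-search
abort at the kink is accepted as converged only when a restart makes no
further progress. One wording note: descriptions of this protocol
sometimes swap the roles of $t_C$ and $\Delta t_A$ in prose; the piecewise
form above ($t_C$ = ramp onset, $\Delta t_A$ = ramp duration) is the
definition used throughout.

**Stage 2 — the creep response.** The tissue is modelled as a power-law
viscoelastic half-space with creep compliance
$J(t) = (1/k_0)(t/t_0)^\beta$, where $k_0$ (Pa) is the reduced
instantaneous elastic stiffness (the analogue of $E_0/(1-\nu^2)$) and
$\beta \in [0,1]$ is the fluidity: 0 for an elastic solid, 1 for a
viscous fluid. For the monotonically non-decreasing ramp-then-hold load,
the Lee–Radok hereditary integral

$$\delta^{3/2}(t) = \frac{3}{4\sqrt{R}}\int_0^t J(t-t')\,
\frac{dF}{dt'}\,dt'$$

evaluates in closed form to

$$\delta(t) = \left[\frac{3}{4 k_0 \sqrt{R}}\, F_C\, \alpha\,
\frac{(t-t_C)^{\alpha+\beta}}{\Delta t_A^{\alpha}\, t_0^{\beta}}\,
B\!\left(\min\!\left(\tfrac{\Delta t_A}{t-t_C},1\right);
\alpha,\beta+1\right)\right]^{2/3},$$

with $B(x;a,b)$ the (non-regularised) incomplete beta function. We
re-derived this form from the hereditary integral rather than trusting
any transcription, and the package carries the numerical integral itself
(`hereditary_creep_oracle()`, Gauss–Legendre quadrature of the
convolution) as the contractual ground truth: the closed form is required
to agree with it to better than 1% over $(\alpha,\beta) \in
[1,2]\times[0,0.8]$ on the hold phase, and in practice agrees to ~1e-6.
The synthetic generator deliberately produces indentation through the
oracle, never through the closed form, so round-trip tests cannot be
self-fulfilling.

`fit_creep_powerlaw()` then solves a bounded least-squares problem in
$(k_0, \beta)$ on the hold phase (three starts in $\beta$, ties broken by
residual). Choices worth knowing:

* **$t_0 = 1$ s.** The reference time is not identifiable separately from
  $k_0$ (any other choice rescales $k_0$ by $t_0^\beta$); fixing 1 s
  defines $k_0$ as the stiffness at 1 s. Configurable.
* **Hold-only fitting** is the default (`fit_phase = "all"` includes the
  ramp); the hold phase is where creep is cleanly expressed.
* **Elastic check.** `fit_hertz_instantaneous()` fits the Hertz model
  $F = \tfrac43 K \sqrt{R}\,\delta^{3/2}$ to the approach data; for
  weakly creeping tissue $K$ lands close to $k_0$ (within ~15% at
  $\beta = 0.1$), reproducing the internal consistency check of the
  original analysis.

Group comparison (`paired_group_compare()`) follows the study's recipe:
two-sided t tests, paired for within-embryo designs, Shapiro–Wilk
normality per group, 0.05 threshold reported rather than silently
applied.

## The pressurized Maxwell tube

The tube cross-section is a circular lumen of radius $R$ in a thin
incompressible shell of thickness $h$, discretised into angular segments
with a dorsal sector (60 degrees by default) that can be assigned its own
Maxwell parameters. The wall load is the thin-shell Laplace (hoop)
stress $\sigma = PR/h$ — force proportional to both pressure and radius,
which is the geometric heart of the hindbrain/spinal-cord difference.
Each segment obeys the Maxwell law
$\dot\varepsilon = \sigma/\eta + \dot\sigma/E$; arc length grows with
strain, thickness follows from exact per-segment conservation of
$l \times h$ (so the conservation invariant holds to machine precision by
construction), and $R$ is recomputed from the total circumference.

Numerics: explicit first-order stepping with an adaptive step targeting a
strain increment of 5e-4 (1e-3 in the droplet forward model), rejection
with halving (a step that would produce non-positive thickness or an
excessive increment is retried as two half steps; 20 nested halvings
abort with the offending state attached), and a damped fixed-point
solve for the instantaneous elastic response before viscous stepping
begins. Strains are re-referenced each step (hypoelastic convention).
Halving the step changes trajectories by < 0.2%.

Three guards truncate a trajectory with an explicit reason instead of
failing: radius beyond 10x initial; wall thinned below 2% of initial
(the finite-time collapse inherent to a Maxwell shell without growth);
and hoop stress exceeding $0.45E$ — a pressure-controlled shell loses
elastic equilibrium at $\sigma \sim E/2$ (limit-point instability), and
the explicit scheme is honest about approaching it. The elevated-pressure
(BDX-like, 1.3x) hindbrain run genuinely reaches this limit at ~18 h;
comparisons against baseline are made at the last common time.

Default parameters (all configurable, chosen as plausible embryo-scale
values, not published measurements): hindbrain $R_0 = 100$ um vs spinal
cord $R_0 = 30$ um with $h_0 = 40$ um walls; $E = 1$ kPa;
$\eta_{dorsal} = 10^7$ Pa·s and $\eta_{rest} = 5\times10^8$ Pa·s (a 50x
dorsal fluidisation, within the 10–100x range the model is meant to
explore). With the 15-to-25 Pa schedule over 20 h these give a hindbrain
dorsal thickness ratio of ~0.49 — the "approximately halved" roof — with
the rest of the wall at ~0.95 and the spinal cord dorsal ratio at ~0.88.
We first tried $\eta_{dorsal} = 5\times10^6$ Pa·s, which collapses the
roof entirely before 20 h; the default sits comfortably inside the
stable-yet-thinning regime, and the package's qualitative claims
(orderings across region, pressure and viscosity) hold across a wide
band around it. The spinal cord's higher dorsal *curvature* enters only
through its smaller radius; bending stiffness is neglected (a known
limitation of the thin-shell picture).

## Ferrofluid droplet mechanics

A droplet whose volume exceeds the largest sphere that fits the lumen is
squeezed into a capsule: a cylinder capped by two hemispheres of the
lumen radius. Its caps carry the Laplace pressure $\Delta P = 2\gamma/r$
(single principal curvature from a cross-section contour; axisymmetry
assumed), which loads the wall under the droplet. The wall creeps, the
local radius grows, and volume conservation shortens the capsule, so the
aspect ratio relaxes toward 1 on the slow tissue timescale — hours,
orders of magnitude beyond the droplet's own surface-tension/viscosity
timescale — which is exactly what makes the rounding dynamics a
viscometer for the surrounding tissue. Loading stops once the droplet
fits as a sphere. Experimental volume presets: 4 nl in the hindbrain
lumen, 1 nl in the spinal cord lumen. The droplet-site geometry presets
use pre-expansion radii (hindbrain 60 um, spinal cord 30 um): at the
expanded hindbrain radius the 4 nl droplet would already fit as a sphere
and exert no load, which is also why droplet injections are done early.

The interfacial tension $\gamma$ is a configuration input with default
1 mN/m. The choice matters: the wall stress under the droplet is
$2\gamma/h$ independent of radius, and at 5 mN/m with kPa-scale tissue
moduli the load crosses the elastic stability limit instantly; 1 mN/m
places the model in the slow, hours-scale rounding regime the
measurements describe.

`estimate_viscosity_from_droplet()` inverts an observed aspect-ratio
series by simulation-based least squares over a single effective wall
viscosity (all other parameters fixed). Implementation: model aspect
curves are precomputed on a 33-point grid spanning two decades of
$\log_{10}\eta$ either side of the prior; each fit is a grid search with
parabolic refinement, the point estimate is polished by a narrow
continuous search, and a bootstrap over frame residuals (pivoted on the
grid estimate so its small offset cancels) gives the confidence
interval. A flat series is reported as unidentifiable (a lower bound on
$\eta$) instead of a point estimate. `fit_rounding_timescale()` provides
the simple exponential summary $A(t) = A_\infty + (A_0 -
A_\infty)e^{-t/\tau}$ used to initialise and sanity-check the full
inversion.

## Tissue-shape quantification

`thickness_profile()` formalises the manual measurement: at equally
spaced arc positions along the inner (lumenal) contour, thickness is the
distance to the outer contour along the local inner normal (nearest
intersection wins; samples whose normal misses are dropped, and a
profile with >10% losses is refused). Positions are normalised so the
dorsal midpoint is 0 and the ventral midpoint 1 on each side.
`normalise_and_average()` pools resampled profiles (both sides pooled
rather than averaged first) and fits a 4th-degree polynomial as the
group-average profile. `roof_metrics()` reports the mean thickness of
the first 100 or 300 um of roof and the single-cell-thick roof length —
the threshold for "single-cell thick" is not a published number; the
default is 10 um and the metric is monotone in it, so sensitivity is
easy to check. Roof length is measured per side as the arc position of
the last contiguous sample at or below threshold, summed over sides.
`apical_intensity_bins()` bins max-normalised intensity into 2 or 3
equal-arc windows from the dorsal-most position using
arc-length-weighted (trapezoidal) means, which makes the linear-ramp
case analytic (0.25/0.75 for two bins). `cap_curvature()` fits a circle
(Kasa algebraic fit) to the 25% of contour length centred on the tip of
the droplet; a half-perimeter window would drag straight-side points
into the fit and bias the radius by tens of percent, so the tight window
is the operative definition.

## The synthetic-data generators

Every input the pipeline consumes can be generated with known ground
truth: creep records (force from the piecewise ramp, indentation from
the hereditary oracle, additive Gaussian noise), paired cohorts with
group fluidity effects drawn from truncated normals (defaults 0.35 vs
0.15, sd 0.05, the hindbrain/spinal-cord contrast scale; n down to 2),
cross-sections (annulus, eccentric annulus, dorsally thinned, arbitrary
thickness laws for dimpled roofs), droplet series (forward model plus
contour noise, with the observed aspect re-measured from the noisy
contours through the same code path real contours would take), and
apical intensity traces. All generators are pure functions of their
arguments and a seed; identical seeds give bit-identical output.

What the generators deliberately do *not* emulate: segmentation error
structure of real microscopy (noise is i.i.d. Gaussian on coordinates),
tissue growth and proliferation (no growth term in the tube model —
trajectories describe redistribution, not volume increase), axial
3-D mechanics, and the osmotic machinery that generates lumen pressure.
Passing tests therefore validate the computational chain, not these
biological simplifications; noise magnitudes are free parameters, not
calibrated instrument values.

## Problem sizes used in validation

The shipped test-suite and acceptance runs use: 100 Hz creep sampling
(1 kHz for the linear-ramp worked example), a 3x3 (k0, beta) recovery
grid with 100 noise seeds per cell at 5% signal noise, 16–24 angular
segments, 13-frame droplet series with 20 seed replicates and 40
bootstrap draws, and 1000 null cohorts at n = 9 for the type-I-error
calibration of the paired test. These sizes were chosen so the full
validation completes in minutes on one core while keeping Monte-Carlo
bands well inside the asserted tolerances.

## Known limitations

* Thin-shell, circular-lumen, quasi-static: no bending stiffness, so
  dorsal curvature differences act only through the radius.
* The Maxwell wall flows forever; without a growth/remodelling term the
  model has a finite-time collapse, and runs near it are truncated with
  a reason rather than extrapolated.
* The droplet inversion returns one effective viscosity; with dorsal
  and rest compartments differing it reports a geometry-weighted
  effective value, not the compartment values.
* Absolute viscosities are model-scale quantities; only orderings and
  ratios are asserted anywhere in the validation.
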