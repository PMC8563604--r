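---
title: "Methods: DoE optimization and RTD analysis of structured-bed enzyme flow reactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DoE optimization and RTD analysis of structured-bed enzyme flow reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowdoe)
```

# Scope

`flowdoe` models the software side of an automated continuous-flow
biocatalysis platform: 3D-printed ceramic structured inserts (honeycomb
"HC" with straight hexagonal channels, cubic-lattice "CL"), coated with an
immobilized decarboxylase and run as small packed columns. The package
covers four layers:

1. **Residence-time distribution (RTD) analysis** of dual-point
   step-tracer experiments, producing inlet-corrected moments, the
   Bodenstein number under the open-open axial dispersion model, the
   axial dispersion coefficient and the Reynolds number per insert and
   flowrate.
2. **A two-iteration fractional spherical central composite design
   (CCD)** over flowrate, temperature and dilution ratio, selecting the
   space-time-yield (STY) optimum.
3. **Process metrics**: dosing by pump-flow dilution, inline UV-Vis
   quantification, conversion/yield, residence time, STY, immobilization
   yield, activity units and steady-state detection.
4. **A virtual reactor** (tanks-in-series cascade with Michaelis-Menten
   kinetics and a temperature-peaked activity profile) plus a synthetic
   tracer-step generator, so that every estimator can be exercised and
   validated against known ground truth without hardware.

# RTD estimation

## Model

A step change of tracer concentration is recorded by two photometric flow
cells, one at the column inlet and one at the outlet. After normalization
the records are cumulative RTDs, $F(t) \in [0,1]$; the exit-age density is
$E = \mathrm{d}F/\mathrm{d}t$. The extent of axial dispersion is
summarized by the Bodenstein number $Bo = uL/D_{ax}$ (plug flow for large
$Bo$, stirred-tank behavior for small $Bo$). Under the open-open boundary
conditions of the axial dispersion model the dimensionless variance obeys

$$\sigma_\theta^2 = \frac{2}{Bo} + \frac{8}{Bo^2},$$

with the closed-form inverse $Bo = 8/(\sqrt{1+8\sigma_\theta^2}-1)$
(`bodenstein_from_variance()`). One subtlety matters in practice: in the
open-open model the *measured* mean residence time exceeds the space time
$\tau$, $\bar t = \tau(1 + 2/Bo)$, while the variance relation above is
normalized by $\tau$. `analyze_rtd()` therefore inverts the observable
ratio $r = \sigma^2/\bar t^{\,2} = (2/Bo + 8/Bo^2)/(1+2/Bo)^2$, which is a
quadratic in $1/Bo$ with a closed-form positive root
(`bodenstein_from_measured()`). Ignoring the mean bias would overestimate
$Bo$ by more than 60% at $Bo = 5$.

The feed capillary contributes its own dispersion. Because RTD moments
are additive for devices in series, subtracting the inlet-cell moments
from the outlet-cell moments (`correct_moments()`) removes the
contribution of everything upstream of the column.

## Moment estimation from noisy records

The textbook route — differentiate $F$ to $E$, then integrate $tE$ and
$(t-\bar t)^2E$ — is available (`f_to_e()`, `rtd_moments()`) and is exact
on clean curves, but numerical differentiation amplifies detector noise
catastrophically in the variance integral. `analyze_rtd()` instead
integrates the step response directly,

$$\bar t = \int (1-F)\,\mathrm{d}t, \qquad
  \sigma^2 = 2\int t\,(1-F)\,\mathrm{d}t - \bar t^{\,2},$$

with three refinements, each addressing a distinct noise pathway:

* the integrals are truncated at the detected plateau onset (found on a
  widely smoothed curve), because beyond it the true integrand is zero
  and the record contributes pure noise with weight $t$;
* baseline and plateau levels are re-estimated as means over their full
  flat regions rather than the edge-window medians — a plateau-level
  error rescales the whole curve and is otherwise the dominant error
  term;
* the integrand uses the *unclipped* normalized signal, because clipping
  to $[0,1]$ rectifies zero-mean plateau noise into a bias.

The reported F-curves remain clipped to $[0,1]$ (they are distribution
functions); only the internal moment integrals use the raw rescaled
signal. With 2000 samples and 0.5% multiplicative detector noise, the
median relative error of the recovered $Bo$ is 2–4% for
$Bo \in \{5, 20, 80\}$ (the package's tests recompute this over 20 seeds
per level); without these refinements the same pipeline shows errors of
tens of percent. A corrected variance of zero (e.g. identical inlet and
outlet records) flags the fit as `above_range` instead of failing:
dispersion below the measurement resolution is not an error.

Degenerate inputs are rejected early: non-monotone time axes, flat
signals (step height below five baseline spreads), records of fewer than
five samples, and outlet means smaller than inlet means.

# The design engine

## Geometry

Three factors are varied: total flowrate (0.2–2 mL/min), temperature
(25–35 °C) and the dilution ratio $D$ (4–40), the solvent-to-substrate
pump-flow ratio that sets the feed concentration $c_0 =
c_\mathrm{stock}/(1+D)$. The first iteration screens a centered subregion
spanning 70% of each axis; the second spans 40% of the first, centered on
the measured first-iteration best point (which is not re-run). With
$k = 3$ factors one iteration holds $1 + 2k = 7$ center/axial points plus
a half fraction (defining relation $I = ABC$, so sign product $+1$) of
the factorial corners, $2^{k-1} = 4$, for 11 runs; the second iteration
re-uses its center, so the campaign totals $11 + 10 = 21$ runs.

The design is *spherical*: the axial points sit on the subregion faces
(coded $\pm 1$) and the factorial corners at $\pm 1/\sqrt{3}$ per axis,
so every non-center point lies on the same coded sphere. In the textbook
scaling, where corners are written $(\pm 1, \pm 1, \pm 1)$, that common
radial distance is $\alpha = \sqrt{k} = \sqrt{3}$. This placement is
deliberate: the coordinates it generates (e.g. first-iteration corner
$30 - 3.5/\sqrt{3} \approx 28.0$ °C, $1.1 + 0.63/\sqrt{3} \approx
1.464$ mL/min, dilution $22 - 12.6/\sqrt{3} \approx 14.7$; dilution axial
point 9.4; second-iteration dilution extreme $9.4 - 5.04 = 4.36$) are
exactly the run conditions a campaign on this design space produces, and
the containment guarantee below depends on the axial points sitting on
the faces.

Because axial points reach the subregion faces, a second region centered
on any first-region point extends at most $0.4 \times 0.7/2 = 14\%$ of
the axis beyond each first-region edge: per axis the scheme can reach
$0.7 \times (1 + 0.4) = 98\%$ of the design space
(`coverage_fraction()`), and no generated point can ever leave it. For
non-default fractions that could overflow, the second region is
translated inward with its span preserved, keeping the CCD geometry
intact.

Selection is greedy: the single highest-STY run wins (ties broken by run
order), and the second iteration zooms on it alone. This mirrors the
automated platform's behavior and is a known limitation discussed below.

# Process metrics

All scalar formulas use bench units at the interface (mm³, mL/min, °C,
mM) and convert internally: residence time $\tau = V_i/FR$;
$STY = c_\mathrm{prod} \cdot FR / V_i$ in g/(L·h) with $c_\mathrm{prod}$
in g/L (vinylphenol molar mass 120.15 g/mol for the mM conversion);
conversion $X = (c_0 - c_S)/c_0$ and yield $Y = c_P/c_0$ on a mole basis
(the decarboxylation is 1:1, so $Y \le X$ whenever no product appears
from nowhere); immobilization yield $Y_i = (A_b - A_a)/A_b \times 100$;
activity $U = (C_0 - C_t)V_\mathrm{assay}/t$ in µmol/min. Inline UV-Vis
quantification averages the absorbance over a species window (product
263–269 nm, substrate 325–328 nm, where the product does not absorb) and
divides by a linear calibration slope; negative concentrations from
baseline noise are clipped to zero with a warning. Steady state is
declared at the earliest window whose relative range is below a
tolerance (default 2%), and the window mean is the steady value.

# The virtual reactor

The generator stands in for the physical rig, with ground truth known by
construction:

* **Hydrodynamics.** Tanks-in-series with $n$ equal tanks; $n$ defaults
  to the count whose variance matches a Bodenstein number of 20
  ($1/n \approx 2/Bo + 8/Bo^2$, giving $n = 8$), consistent with the
  strongly backmixed behavior such inserts show.
* **Kinetics.** Michaelis-Menten with $K_m = 0.5$ mM and a Gaussian
  temperature-activity profile peaking at 30 °C (width 6 °C), the
  interior optimum reported for this enzyme class. Each tank's steady
  state has a closed-form outlet (positive quadratic root), so the
  cascade solves exactly and mass balance holds to machine precision.
* **Flow maldistribution.** A pure Michaelis-Menten bed makes STY
  monotone non-decreasing in flowrate, which contradicts the observed
  preference for *medium* flowrates on these inserts. Real structured
  beds lose effective catalytic contact at higher rates (channeling and
  maldistribution, visible in their RTDs), so the maximal rate carries
  an effectiveness factor $\eta(FR) = \exp(-(FR/1.7\,\mathrm{mL/min})^2/2)$.
  With the defaults the noise-free STY optimum sits at a medium flowrate
  (~0.8 mL/min), the lowest dilution and 30 °C — the qualitative optimum
  structure the platform is meant to find.
* **Noise.** Multiplicative Gaussian noise (default 1% relative) on the
  measured concentrations, seeded per run index so campaigns are
  bit-reproducible while distinct runs get independent draws.
* **Tracer steps.** The inlet cell sees a nearly ideal step that has
  passed a short, weakly dispersed capillary (space time 2 s,
  $Bo = 150$); the outlet is that signal convolved with the column's
  open-open density. Records start with a pre-step hold (15% of the
  record) so baseline estimation has a clean window, and run ~6 standard
  deviations past the mean arrival so the plateau is established.
  Signals are reported as raw detector counts (baseline 40, span 980,
  emulating a 10-bit ADC) with multiplicative noise (default 0.5%).

What the generator does *not* emulate: enzyme deactivation over time,
CO₂ gas effects, solvent property changes, pump pulsation, and drift in
the detector baseline. Passing tests on synthetic data therefore
demonstrate estimator correctness under the stated noise model, not
robustness to every artifact of real records.

# Validation choices and problem sizes

The test suite freezes closed-form oracles wherever one exists (circle /
square / hexagon hydraulic diameters, the open-open variance relation
and its inverse, first-order CSTR and plug-flow limits of the cascade,
the STY/yield/residence-time identity) and uses parameter recovery
elsewhere. Problem sizes were chosen so the full suite runs in seconds:
tracer records use 2000 samples; Bodenstein recovery uses 20 seeds per
level; optimizer recovery uses 20 random kinetic configurations
(temperature optimum uniform over the interior 70% of the axis, maximal
rate log-uniform 0.03–0.3 mM/s, $K_m$ 0.2–2 mM, width 3–8 °C, 4–20
tanks, maldistribution scale 1.4–2.2 mL/min); oracle grids use 21 points
per axis.

# Known limitations

* **Greedy zoom.** The campaign refines around the single best
  first-iteration point. When the true optimum combines extremes on two
  or more axes (an off-center temperature optimum *and* the lowest
  dilution), the zoom cannot reach that combination, and the final best
  can fall 10–40% short of the exhaustive-grid optimum over the
  nominally reachable region. Under the nominal study conditions — the
  temperature optimum at the design center, which is how such campaigns
  are set up in practice — the two-stage design recovers 94% or more of
  the oracle STY at every tested noise seed, and the final temperature
  lands within one axial step of the true optimum in all tested noisy
  configurations. A multi-start or response-surface-fitting extension
  would lift the greedy limitation but is out of scope.
* **Design resolution.** Eleven points cannot pin a sharp response
  surface: temperature-activity widths near 3 °C approach the 3.5 °C
  axial spacing and are at the edge of what the screen can resolve.
* **Moment truncation.** The robust moment estimator assumes the record
  extends well into the plateau; severely truncated records fall back to
  the plain edge-median normalization.
* **Open-open only.** Closed-closed or mixed boundary conditions, and
  full deconvolution of the inlet signal, are not implemented; the
  moment-additivity correction is the supported inlet compensation.
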