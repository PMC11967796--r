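---
title: "Modelling centrifugal step emulsification and designing droplet digital assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling centrifugal step emulsification and designing droplet digital assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepemul)
```

## The physical model

In a centrifugal step emulsifier an aqueous sample is spun through shallow
rectangular microchannels that open abruptly into a deep oil-filled
reservoir. At the step, confinement is released, a balloon-shaped droplet
inflates at the nozzle, and a thin liquid neck (the *connection tube*)
between channel and balloon eventually collapses by Rayleigh–Plateau
instability, pinching off a droplet. At low Weber number this repeats with
remarkable regularity (*periodic dripping*, monodisperse droplets); at high
Weber number the neck never collapses cleanly and the flow jets (*dripping
faucet*, polydisperse).

Everything upstream of the nozzle is classical laminar hydraulics in a
rotating frame. For a rotor spinning at angular velocity $\omega$ with the
aqueous free surface at radius $R_1$ and the nozzles at radius $R_1 + R_2$:

* driving pressure of the liquid column,
  $P_{\mathrm{aqu}} = \tfrac12 \rho\,\omega^2\left[(R_1+R_2)^2 - R_1^2\right]$
  (the integral of $\rho\,\omega^2 r$ across the column);
* capillary pressure of the advancing meniscus in a $w \times h$
  rectangular channel,
  $P_{\mathrm{cap}} = 2\gamma\cos\theta\,(1/w + 1/h)$, negative for the
  hydrophobically treated walls ($\theta > 90^\circ$) such devices need;
* hydraulic resistance of the rectangular duct,
  $R_{\mathrm{hyd}} = \dfrac{12\,\mu\,l}{w h^3\left[1 -
  \frac{192 h}{\pi^5 w}\sum_{i=1,3,5,\dots}\frac{1}{i^5}
  \tanh\!\left(\frac{i\pi w}{2h}\right)\right]}$;
* mean inlet velocity
  $V_{\mathrm{in}} = (P_{\mathrm{aqu}} + P_{\mathrm{cap}})/(R_{\mathrm{hyd}}\,w\,h)$.

The duct series is evaluated with the smaller cross-section dimension in
the role of $h$; the printed form of the formula only converges in that
convention, the resistance is physically symmetric under $w \leftrightarrow
h$, and the convention reproduces the classical square-duct constant
($12/0.4217 \approx 28.5$). Terms are truncated when a term's relative
contribution drops below $10^{-12}$ (about 50 odd terms at worst); terms
decay as $i^{-5}$, so this is far below any physical uncertainty.

The nozzle-radius centrifugal acceleration $a = \omega^2 (R_1+R_2)$,
the channel dimension, and $V_{\mathrm{in}}$ are the three parameters that
dominate droplet size.

### Regime classification

The package uses the Weber number
$We = \rho V_{\mathrm{in}}^2 D_h / \gamma$ with hydraulic diameter
$D_h = 2wh/(w+h)$ and a configurable threshold defaulting to 1. No sharp
experimental boundary is established for this geometry; order one is where
inertial and capillary stresses cross, and the default should be treated as
a heuristic. A Weber number exactly at the threshold is classified as
dripping faucet (the unsafe side). Only periodic-dripping conditions enter
the predictive model.

## The resistance-factor predictive model

The droplet diameter $D$ sets the Laplace pressure difference that drives
liquid through the connection tube,
$P_{\mathrm{channel}} - P_{\mathrm{drop}} = 2\gamma(1/w + 1/h - 2/D)$.
Lumping the tube's geometry into a single *resistance factor* linking this
pressure difference to the inlet flow rate gives

$$R_f = \frac{2\gamma\,(1/w + 1/h - 2/D)}{V_{\mathrm{in}}},$$

where the tube flow rate is approximated by the inlet velocity (adopted
verbatim; no correction term). Empirically, at a fixed centrifugal
acceleration the resistance factors of different channels and flow rates
collapse onto a single decaying exponential in $D$:

$$R_f = \alpha\, e^{-\beta D},$$

with $\alpha$ and $\beta$ constant per acceleration. Setting the two
expressions equal yields one equation whose root is the predicted diameter.
On $D \in (D_h, \infty)$ the left side rises strictly from zero and the
right side decays and stays positive, so the root is unique whenever it
exists. The solver certifies the bracket $(D_h(1+10^{-6}),\ 1\,\mathrm{mm}]$
before calling a bracketed root finder, then polishes with Newton steps to a
relative residual below $10^{-10}$ — diameters are reproducible to well
under a nanometre, which matters only because it makes round-trip and
oracle tests exact.

Generation frequency follows from volume conservation:
$f = 6whV_{\mathrm{in}}/(\pi D^3)$ per channel.

### Fitting choices

The laws are fitted by ordinary least squares on $\ln R_f$ versus $D$
rather than nonlinear least squares on $R_f$. The resistance factors span
orders of magnitude across a diameter window, so log-space fitting
stabilises the variance and gives a deterministic closed-form answer;
whether residuals should be minimised in $R_f$ or $\ln R_f$ is genuinely
open, and log space was chosen and documented. Observations are grouped by
acceleration with a 1% relative tolerance (absorbing floating-point jitter
from rpm-based ingest); each group needs at least three periodic-dripping
observations. Predictions at accelerations with no fitted law are a hard
error by default, because the law family is per-acceleration; an optional
interpolation mode (piecewise-linear $\ln\alpha$ and $\beta$ in $a$) is
available and candidates produced through it are flagged.

```{r fit-example}
grid <- generate_condition_grid()
obs <- generate_observations(grid, synthetic_truth(), seed = 1)
model <- fit_droplet_model(obs)
model
```

Model quality is assessed by a seeded train/validate split, stratified by
acceleration (defaulting to 2/3 : 1/3), reporting the mean absolute
relative diameter error over the validation set:

```{r evaluate-example}
evaluate_model(obs, seed = 1)
```

## Reservoir depletion

With no-dead-volume emulsification the free surface recedes as the sample
drains, the column shortens, and $V_{\mathrm{in}}$ declines. The reservoir
is modelled as a column of constant free-surface area $A$ whose surface
recedes radially outward ($R_2 = V/A$, $R_1 = R_{\mathrm{noz}} - R_2$); the
actual reservoir geometry of any particular chip is not modelled. The
volume balance $dV/dt = -n\,w\,h\,V_{\mathrm{in}}(V)$ is integrated by a
fixed-step classical Runge–Kutta scheme (default 2000 steps per
characteristic drain time) with the step count doubled until the end
velocity changes by less than 0.1%. Capillary pressure and hydraulic
resistance are constants of a run, so each flux evaluation is a closed
form.

Numerical details worth knowing: integration stops at
$V \le 10^{-4} V_0$, avoiding division noise at the empty limit, and the
final point is pinned to that terminal volume by interpolation so that the
reported end velocity is independent of step size. For hydrophobic
channels the no-flow state ($P_{\mathrm{aqu}} + P_{\mathrm{cap}} \le 0$) is
an *asymptote* of the balance, so a run is also terminated once the flux
falls below $10^{-6}$ of its initial value; the small residual volume the
capillary barrier protects then legitimately remains undispensed, and the
flux integral accounts for everything that left. A condition that cannot
flow at the initial volume is an error ("condition does not emulsify");
zero channels is a degenerate guard returning a constant trace.

Note one modelling consequence: because the driving pressure here is
entirely the receding column's, any full drainage run ends with the
velocity near zero. Statements about "negligible decline" apply to the
portion of a run in which only a small fraction of the column height has
receded, not to complete drainage.

## Droplet pre-design

Pre-design inverts the model: given assay constraints, find the diameter
window, then search generation conditions that land in it.

* **Area budget.** In a monolayer, each droplet of diameter $D$ occupies a
  $D \times D$ square footprint of which the inscribed circle is droplet
  area, so a reservoir of area $A_r$ offers $A_r(1-\rho_{\mathrm{res}})\pi/4$
  of accumulated circle area, with $\rho_{\mathrm{res}}$ an optional
  headroom fraction for rapid tiling. Alternative packings (hexagonal) are
  deliberately excluded: the square-minus-circle spacing rule is the
  design convention being modelled. An explicit budget override is
  accepted, since published designs sometimes quote a rounded budget
  (e.g. 208 mm²) rather than the rule's exact value (206.2 mm² for a
  350 mm² reservoir with one quarter reserved).
* **Diameter window.** The accumulated circle area of the whole sample is
  $A(D) = N \pi D^2/4 = 1.5\,V/D$, decreasing in $D$, so the budget binds
  from below: $D_{\min} = 1.5\,V/A_{\mathrm{budget}}$. The droplet count
  $N(D) = 6V/(\pi D^3)$ binds from above:
  $D_{\max} = (6V/\pi N_{\min})^{1/3}$. Each bound carries a label naming
  its binding constraint, and an infeasible window ($D_{\min} > D_{\max}$)
  is flagged rather than clipped. All returned values are unrounded;
  display rounding is the caller's choice.
* **Occupancy.** Expected entities per droplet at bulk concentration $c$
  is $\lambda = c\,\pi D^3/6$, the Poisson mean behind digital
  quantification.
* **Reverse engineering.** A grid search over a channel catalogue and a
  rotational-speed grid (default 500–6000 rpm in 100 rpm steps, a lab
  centrifuge's range) evaluates each condition through the hydraulics and
  the fitted model, returning in-window periodic-dripping candidates
  sorted by distance from the window midpoint, with per-condition
  rejection reasons for everything else.

```{r design-example}
w <- diameter_window(20e-9, 1e4, 208e-6)
w
droplet_count(20e-9, 145e-6)
```

## Digital-assay statistics

Downstream of emulsification, analytes are randomly discretised across
droplets, so occupancy is Poisson and the positive fraction $p$ returns
the concentration through $C = -\ln(1-p)/V$. A saturated assay ($p = 1$)
carries no finite estimate and is treated as an error, not clamped. An
optional Wilson interval on $p$ can be propagated through the same
transform; it is an extension beyond the point estimate.

Classification uses two rules:

* **Global threshold**: mean of negative-control intensities plus three
  sample SDs; "exceeds" is strict, so a droplet exactly at the threshold
  is negative.
* **Local rule**: stitched scans carry periodic baseline fluctuations
  (focus and illumination vary across tiles), so each droplet is re-tested
  against the mean of its ten nearest provisionally negative neighbours in
  scan order (five on each side where available) plus five of their SDs.
  Scan order stands in for geometry, which is not otherwise specified. The
  provisional negative pool — everything below the global threshold — is
  truncated near drift peaks, which biases local baselines low, so the
  re-test is iterated with the updated labels until they stabilise (at
  most ten sweeps). On drift-free data the first sweep reproduces the
  global labels and iteration changes nothing. A neighbourhood with zero
  SD falls back to the global threshold for that droplet; fewer than ten
  provisional negatives in the whole population falls back to global
  thresholding outright, with a warning flag.

The limit of detection is the lowest concentration whose replicates are
all positive; the minimum inhibitory concentration is the lowest tested
antibiotic concentration with droplet-level survival at or below 10%
(cutoff configurable). Dilution linearity is ordinary least squares in
log10–log10 space.

## What the synthetic data emulate — and what they do not

The generators exist so every routine is testable without measured data.

`generate_condition_grid()` builds the default study: square channels of
20, 30 and 40 µm crossed with 20 rotor settings — five accelerations
(1500–8000 m s⁻², including the worked value 6579.7 m s⁻²), each realised
by four rotor geometries ($R_1$ = 12–21 mm, $R_2$ = 6 mm, $\omega$ chosen
to hit the acceleration). Sixty conditions; the high-acceleration 40 µm
corner legitimately crosses into the dripping-faucet regime and is
excluded from fitting, as such conditions are in practice. The default
fluid system (density 1000 kg m⁻³, viscosity 1 mPa s, interfacial tension
5 mN m⁻¹, contact angle 120°) is a plausible synthetic water-in-oil system
with hydrophobic treatment — chosen values, not measured ones, since the
liquid-parameter table of any particular device is its own calibration.

The synthetic truth laws ($\ln\alpha$ falling linearly with $a$, $\beta
\approx 2\times10^4\,\mathrm{m^{-1}}$ with a mild trend) were calibrated
once so the grid's diameters span the 80–400 µm envelope of centrifugal
step emulsifiers and the 20 µm channel at 6579.7 m s⁻² lands near 145 µm,
then frozen. They are documented as synthetic calibration values.

`generate_observations()` applies the configured diameter CV (default 1%,
monodispersity in this technique reaches CVs below 1%) at two levels: a
condition-level lognormal perturbation of the mean diameter, emulating
model mismatch and assembly-to-assembly variability — this is the
component that limits prediction accuracy, giving validation errors of
order one percent — and droplet-level polydispersity across 1000 draws,
setting the emitted empirical CV.

`generate_droplet_population()` emulates a scanned droplet array: Poisson
occupancy, Gaussian intensity noise (SD 2 a.u. on a baseline of 100), a
sinusoidal stitching drift (period 500 droplets, amplitude 10% of the
100 a.u. positive–negative separation), and retained true labels.

What passing tests therefore show: the hydraulics match their closed
forms and quadrature oracles; fitting recovers known laws exactly and
degrades gracefully under noise; the solver agrees with brute-force grid
scans; pre-design numbers invert their defining constraints; and the assay
chain recovers known concentrations within 0.05 dex over its usable
decades. What they cannot show: that the exponential law holds for any
particular real device, that the default Weber threshold separates the
regimes of a given chip, or that real stitching artefacts are sinusoidal.
Those are calibration questions for measured data, which travel through
the same CSV interfaces.

Problem sizes used throughout the examples and tests — 60-condition grids,
1000-droplet diameter draws, populations of 3000–12 500 droplets, a
10⁴-point oracle grid — match the scale of one real study and keep any
check comfortably fast.

## Known limitations

* The regime threshold is a heuristic; near $We \approx 1$ the label
  should not be trusted either way.
* The resistance-factor law is fitted per acceleration; interpolation
  between accelerations is an explicitly flagged extension, not part of
  the law family.
* The depletion model's reservoir is a constant-area column; chips with
  stepped or conical reservoirs need their own $R_2(V)$ map.
* Saturation: with 145 µm droplets (1.6 nL), concentrations above a few
  thousand copies µL⁻¹ occupy essentially every droplet and cannot be
  quantified; the package errors rather than extrapolating.
* No image processing: intensities arrive pre-extracted, and the
  position index is whatever order the extraction produced.
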