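---
title: "Modelling bypass-graft flow and the uncertainty of TTFM patency metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bypass-graft flow and the uncertainty of TTFM patency metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftflow)
```

## What the package models

Intraoperative transit-time flow measurement (TTFM) summarises a bypass
graft's flow waveform in a handful of patency metrics: mean flow rate
$Q_\mathrm{mean}$, pulsatility index
$\mathrm{PI} = (Q_\max - Q_\min)/Q_\mathrm{mean}$, the diastolic/systolic
delivered-volume ratio $\mathrm{D/S} = |V_\mathrm{dia}|/|V_\mathrm{sys}|$,
the diastolic filling percentage
$\mathrm{DF\%} = 100\,\mathrm{D/S}/(1+\mathrm{D/S})$, and the diastolic
resistance index
$\mathrm{DRI} = (\bar p_\mathrm{dia}/|\bar Q|_\mathrm{dia}) /
(\bar p_\mathrm{sys}/|\bar Q|_\mathrm{sys})$.
All delivered volumes and phase-mean flows use the absolute flow rate, so
$\mathrm{DF\%}$ and the DRI identity
$\mathrm{DRI} = (\bar p_\mathrm{dia}/\bar p_\mathrm{sys})
(T_\mathrm{dia}/T_\mathrm{sys})/\mathrm{D/S}$ hold exactly, beat by beat —
the test suite asserts both to $10^{-9}$.

These metrics are confounded by everything that shapes the waveform:
heart rate, peripheral resistance, arterial compliance, microvascular
state.  The package quantifies those confounders for a
left-internal-thoracic-artery (LITA) style graft with a configurable
stenosis, using a closed-loop lumped-parameter (0D) circulation model
that is fast enough (tens of milliseconds per ten-beat run) for global
sensitivity analysis and polynomial-chaos uncertainty quantification.

## The 0D circulation model

The network couples two time-varying-elastance ventricles, pressure-gated
valves, systemic and pulmonary arterial/venous compartments (resistance,
compliance, inertance), and one intramyocardial perfusion bed supplied
through the graft branch.  Atrial contraction is omitted: the atria are
lumped into the venous compartments, which is sufficient because none of
the assessed metrics depends on the atrial kick.

**Chamber activation.**  Elastance follows a rise–plateau–fall shape: a
half-cosine rise over the first 40% of systole, a hold at exactly
$E_\max$ until 75%, and a half-cosine relaxation over the remainder; the
waveform is $C^1$-continuous and its peak is independent of the cardiac
period.  The plateau matters: a single half-cosine peaking at
mid-systole compresses ejection into roughly 0.1 s and produces grossly
unphysiologic aortic flow.  Systole duration comes from an affine
diastole-duration relation $T_\mathrm{dia} = a\,T + b$; the shipped
coefficients ($a = 0.8$, $b = -0.19$ s) are placeholders calibrated to a
diastolic time fraction of ~0.56 at $T = 0.8$ s that increases with the
period, and should be replaced when a fitted relation is available.

**Intramyocardial bed.**  Three wall layers (sub-epicardial, mid-wall,
sub-endocardial) at mid-depth fractions 1/6, 1/2, 5/6 of the wall, each
with an arterial-side and a venous-side compliance.  The contraction-
generated tissue pressure added to both compartments increases linearly
with depth, $p_\mathrm{im} = d\, p_\mathrm{lv}$, and the arterial and
middle resistances depend on vascular volume through the inverse-square
law $R = R_0 (V_0/V)^2$; layer compliances are fixed.  Layer shares
derive from the subendocardial/subepicardial reference-volume ratio
(mid-wall takes the mean share), with total reference volume conserved
and reference resistances scaled inversely so the registry values remain
the bed's parallel equivalents.

**Graft branch.**  From the systemic arterial node: lumped graft
resistance and inertance, then a small proximal compliance at the probe
site, the optional stenosis element, and a distal epicardial node
compliance feeding the three layers.  The two graft-branch compliances
(0.002 and 0.001 mL/mmHg, fixed network constants) represent the wall
storage of the graft and epicardial segment.  They are essential to the
physics this package exists to reproduce: the proximal store receives
capacitive inflow during systole, so as a stenosis decouples the probe
site from the bed the measured waveform loses diastolic dominance — D/S
collapses from ~2.8 (patent) to below 1 at severe stenosis and PI blows
up, while mean flow is barely affected below ~50% diameter reduction.

**Stenosis element.**  The empirical pressure drop
$$\Delta p_s = \frac{4 K_v \mu}{\pi D_0^3} Q
  + \frac{\rho K_t}{2 A_0^2}\Big(\frac{A_0}{A_s}-1\Big)^2 Q|Q|
  + \frac{\rho K_u l_s}{A_0}\frac{dQ}{dt},$$
with $K_v = 32\,(0.83\,l_s + 1.64\,D_s)/D_0\,(A_0/A_s)^2$, $K_t = 1.52$,
$K_u = 1.2$, evaluated in CGS units and converted to mmHg at the
interface.  The quadratic term uses $Q|Q|$ (odd extension) so the element
is antisymmetric under flow reversal.  Inside the network the through-flow
is obtained algebraically by inverting the quadratic law between the two
graft-branch nodes, which keeps the stiffest severe-stenosis mode out of
the ODE system; the element's inertial term is lumped into the graft
inertance.  A *disabled* element merges the two nodes (exactly zero
pressure drop), which differs from a 0% stenosis by the viscous term.
The vena contracta defaults to the stenosed lumen diameter and the
effective length to 0.3 cm; both are configuration keys because the
source literature does not fix them.

**Numerics.**  Fixed-step classical Runge–Kutta in compiled code; the
default step is $\min(T/2000, 0.4\ \mathrm{ms})$, with two further caps:
the cap at 0.4 ms keeps the fastest inertial mode ($L_{sa}/R_{svb}$)
inside the explicit stability region at the long-period, low-inertance
corners that global screening visits, and a stenosis-dependent cap keeps
the algebraic-resistor coupling of the graft-branch compliances stable.
Valves are pressure-gated resistances smoothed over 0.1 mmHg with a form
that is exactly zero under reverse bias (no leak), so integrated backward
valve flow is identically zero.  Because compartment rates are assembled
pairwise, total blood volume is conserved to rounding error ($<10^{-10}$
relative over ten beats).  A run is flagged converged when the last two
beats agree to a relative $L^2$ residual below $10^{-3}$ on aortic
pressure and graft flow; defaults converge in 8–9 beats.

**Parameters.**  All 39 tunable constants (stenosis percentage included)
live in `param_registry()` with units and screening distributions.  The
referenced appendix-level values of the source models are not available,
so the defaults are literature-guided and validated only against broad
sanity bands — with the shipped defaults a ten-beat run gives aortic
pressure 121/79 mmHg, cardiac output 5.5 L/min, graft mean flow
39.5 mL/min, D/S 2.8 and DRI 0.82 at $T = 0.8$ s.

## Morris screening

`morris_trajectories()` builds one-at-a-time trajectories on a $p = 4$
level grid with the standard step $\Delta = p/(2(p-1))$, mapping the unit
cube to physical values by each parameter's inverse CDF (renormalised
truncated normals, not clipped — clipping would pile probability on the
bounds and bias the effects).  Spread maximisation generates an
oversampled candidate pool (default 200) and keeps the $r$ trajectories
with greedily maximised minimum pairwise distance, where the
trajectory-pair distance is the root-sum-of-squares of all point-pair
Euclidean distances; this is a deliberate approximation, with the same
goal, of published selection strategies, and it reduces to a closed form
in per-trajectory sums.  Elementary effects are summarised per parameter
by $\mu^*$ (mean absolute effect), $\sigma$ (effect spread) and the
combined score $\sqrt{\mu^{*2}+\sigma^2}$; failed model runs are dropped
pairwise and counted, never imputed.  `converge_r()` implements the
stopping rule of growing $r$ in steps of 10 until the top-3 ranking
stabilises.  Distributions default to truncated normals at mean ± 2 sd
with sd = 25% of the mean where no literature value is recorded; the
stenosis percentage (uniform on [0, 75]%) and the endo–epi volume ratio
(uniform on [0.8, 1.6]) are the two uniform entries, and an all-uniform
mode supports the ranking-robustness check.

## Polynomial chaos and Sobol indices

The nine-parameter UQ set couples the stenosis percentage (uniform) with
eight physiological parameters truncated at ±1.96 sd.  Four entries are
0D surrogates for distributed-model geometry: systemic arterial
compliance and characteristic resistance for the systemic artery's
cross-section and wave speed, graft lumped resistance and inertance for
the graft's.  Surrogate spreads are mapped through the physics rather
than copied: graft resistance carries a 50%-of-mean sd because
$R \propto A^{-2}$ doubles relative variance, while the lumped arterial
compliance carries 15% because the surrogated quantity is one segment's
cross-section and that segment holds only part of the compliance the
lumped element aggregates.

The expansion is least-squares regression on a total-degree orthonormal
Legendre basis over each input's bounded range.  For the truncated
normals this accepts a weight-orthogonality mismatch: truncated-normal
orthogonal polynomials have no standard closed form, and regression does
not require exact weight orthogonality for fitting.  Only the Sobol
extraction assumes it, so the coefficient-based indices are additionally
cross-checked in the test suite by Monte-Carlo pick-freeze estimation on
the fitted surrogate.  Order selection is 10-fold cross-validation over
degrees 1..2 (candidates limited to degrees fittable on every training
fold; ties break to the lower degree).  Runs whose aortic-pressure
maximum over the last beat falls in diastole are removed as unphysical
before fitting, and the stage aborts if more than half the runs are lost.

With the shipped defaults at the full 110-sample design, the stenosis
percentage carries the largest Sobol index for DRI, while mean flow is
dominated by the peripheral resistance.  For the D/S-ratio the peripheral
resistance ranks first and the stenosis percentage second-to-third: in a
fully lumped systemic circulation, $R_{svb}$ (with $C_{sa}$) sets the
diastolic aortic decay constant that the D/S integral rides on, a pathway
a distributed arterial tree dilutes.  This is a known structural
limitation of the 0D analogue, not a sampling artefact — it persists
across seeds and sample sizes.

## Autoregulation

`tune_autoregulation()` emulates microvascular autoregulation with two
multiplicative knobs — an overall scale on the three layer reference
resistances and a transmural endo/epi tilt (realised through the
layer-share mechanism) — adjusted by a damped fixed-point iteration
(damping 0.5 on log-scale updates) until the stenosed run recovers the
un-stenosed beat-median mean graft flow and endo–epi flow ratio within
1%.  A two-knob scheme is the minimal mechanism matching the two
physiological targets; tuning three per-layer resistances independently
would leave the system under-determined.  Across 20–60% stenosis the
dilation knob falls monotonically (to 0.64 at 60%), mean flow is held at
reference, and the diastolic-dominance metrics move less than they do
without tuning — though not by as little as 5% of the untuned values at
50–60% severity, because restoring mean flow through the stenosis raises
the quadratic pressure loss while the dilated bed boosts diastolic
suction, and in this lumped analogue the two effects cancel only
partially.

## The synthetic cohort

`generate_cohort()` emulates the record structure of an intraoperative
verification study: per patient it draws a physiology (cardiac period,
peripheral resistance, maximal elastance, arterial compliance, blood
volume) from the screening distributions; per graft it draws a patency
class (patent < 50%, questionable 50–74%, failed ≥ 75% true diameter
reduction — a configurable convention) and a stenosis percentage within
the class range, runs the 0D model, and emits a flow waveform (mL/min)
with additive Gaussian noise (sd 2 mL/min), a peripheral pressure
waveform, and ECG-like beat markers jittered by 10 ms.  The peripheral
waveform is produced by a second-order resonant low-pass (5.5 Hz,
damping 0.25) plus a 60 ms delay applied to the central pressure — pure
fixture machinery, since only the inverse direction (central-pressure
estimation by the $N$-point moving average, default window $T/4$) is
methodologically specified.  The generator reproduces the study *shape*
(123 grafts in 41 patients by default) but not, by construction,
inter-patient covariance, graft-type heterogeneity, competitive flow, or
measurement artefacts beyond additive noise and marker jitter — so
passing cohort tests demonstrate pipeline correctness on this model
family, not clinical performance.

Cohort analysis mirrors the clinical methods: marker-based beat
segmentation, per-record across-beat medians, median/IQR per class,
MAD/median variability of the hemodynamic parameters, Wilcoxon rank
tests between classes (through `stats::wilcox.test`; the exact small-n
enumeration is reimplemented independently in the tests as the oracle),
and monotone-trend directions of the class medians.  On default cohorts
the D/S-ratio and mean-flow class medians decrease with severity class
and DRI increases, the qualitative pattern the pipeline is meant to
expose.

## Reproducibility and problem sizes

Each pipeline stage derives its own seed from the master seed by a
stable string hash, so stages are independently reproducible and reruns
are bit-identical.  The test suite and the acceptance script use the
sizes the package defaults to: ten-beat runs, the full 2000-point
screening design (design only; elementary-effect examples use 5–7
dimensional closed-form responses), 60–110 simulation UQ designs, four
autoregulation severities, and cohorts of 4–123 records.  A full
acceptance pass — a 110-run UQ stage, the autoregulation experiment and
a 123-record cohort — takes about a minute on one core.

## Known limitations

* A single lumped systemic compartment exaggerates the influence of
  peripheral resistance and arterial compliance on diastolic aortic
  decay, and with it their share of the D/S-ratio variance.
* The diastole-duration coefficients are placeholders; the elastance
  plateau fractions (40%/75%) are fixed shape constants.
* Probe-position effects (proximal vs distal along the graft) are not
  representable in a lumped branch.
* The patency-class ↔ percentage mapping is a convention, and the
  peripheral-pressure transform is a modelling convenience, not a fitted
  arterial transfer function.
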