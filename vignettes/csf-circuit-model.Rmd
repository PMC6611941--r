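---
title: "An electrical-analog model of CSF dynamics and hydrocephalus shunting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An electrical-analog model of CSF dynamics and hydrocephalus shunting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfshunt)
```

## The physiological model

Cerebrospinal fluid (CSF) is secreted by the choroid plexus from capillary
blood, circulates through the ventricles and subarachnoid space, and is
absorbed through the arachnoid granulations into the superior sagittal
sinus. Communicating hydrocephalus is an impairment of that absorption:
the resistance to CSF outflow rises, CSF accumulates, and intracranial
pressure (ICP) climbs. The standard treatment is a shunt — a catheter with
a one-way valve that drains excess CSF to another body cavity, providing a
low-resistance path in parallel with the failing natural one.

`csfshunt` models this system as a lumped-parameter electrical network, in
the tradition of the Marmarou and Ursino models of CSF pressure–volume
compensation. The analogy maps pressure to voltage (1 Pa = 1 V), volumetric
flow to current, hydraulic resistance to electrical resistance and
compliance to capacitance. One-way valves — the arachnoid granulations and
the shunt valve, neither of which permits backflow — are ideal diodes.

The network has four pressure nodes:

* `P_a` — arterial, fed from the pulsatile source through the series
  resistance `R1` (the current through `R1` is the cerebral blood flow,
  CBF);
* `P_c` — capillary, linked to `P_a` by the arterial resistance `R2` and
  to `P_v` by the capillary resistance `R3`;
* `P_v` — venous, draining to the reference through `R4`;
* `P_ic` — intracranial (the ICP), receiving CSF formation through
  `Rf` + valve from the capillary node and losing it through the arachnoid
  branch `Ro` + valve and, when fitted, the shunt branch
  `Rshunt` + valve, both terminating at the sagittal-sinus reference
  pressure `P_vs` (0 Pa by default).

Three compliances couple the compartments: `Cai` (arterial–intracranial),
`Cvi` (venous–intracranial) and `Ctiss` (tissue, intracranial to
reference). Their pressure differences are the three state variables
`u_ai = P_a - P_ic`, `u_vi = P_v - P_ic`, `u_ic = P_ic`; the capillary
node carries no compliance, so `P_c` is algebraic.

The driving pressure is the difference of two sinusoids at the cardiac
fundamental and its first harmonic,

```
P_src(t) = 17 sin(2*pi*t - pi/2) - 12.5 sin(4*pi*t) + 16000   [Pa]
```

which gives the dicrotic shape of an arterial waveform. The ripple
amplitudes are small against the 16 kPa offset; they belong to the
reference parameter set of the circuit and are deliberately left as they
are — the steady-state pressure distribution, which is what the scenario
metrics read out, is set by the offset and the resistances.

## Governing equations

Kirchhoff current balances at the arterial and venous nodes, and the
closed-cranium volume constraint (the Monro–Kellie doctrine: arterial,
venous, tissue and CSF volume rates sum to zero) at the intracranial node,
give

```
Cai du_ai/dt = (P_src - P_a)/R1 - (P_a - P_c)/R2
Cvi du_vi/dt = (P_c - P_v)/R3 - P_v/R4
Ctiss du_ic/dt = Cai du_ai/dt + Cvi du_vi/dt + q_f - q_o - q_sh
```

with the valve-gated CSF flows

```
q_f  = max(P_c - P_ic, 0) / Rf          (formation)
q_o  = max(P_ic - P_vs, 0) / Ro         (arachnoid absorption)
q_sh = max(P_ic - P_vs, 0) / Rshunt(t)  (shunt drainage, 0 if absent)
```

`P_c` solves the algebraic balance
`(P_a - P_c)/R2 = (P_c - P_v)/R3 + f_df (P_c - P_ic)/Rf`, where the
formation-valve flag `f_df` is resolved by a two-case fixed point (the two
branches agree at the switching pressure, so `P_c` is continuous in the
state).

### Where the drainage branch ends

A genuinely open design question in a lumped CSF circuit is whether
absorbed CSF should be returned into the venous node or taken to the
reference. Physiologically the fluid does enter the sagittal sinus, but
the sinus is a low-resistance, pressure-clamped structure that is already
lumped into the reference of the drainage branch (`P_vs` is defined as the
villi-to-sinus pressure difference). We resolved the question numerically:
with the branch terminated at the reference, the DC solution reproduces
the published steady ICPs of this circuit (709 Pa normal, 2.50/3.65 kPa
for moderate/severe hydrocephalus, 779 Pa for the 1.25-ohm shunt) to
within 0.5%; re-injecting the drained current into `P_v` instead raises
the normal-scenario ICP to about 861 Pa, more than 20% off. The package
therefore terminates both drainage branches at `P_vs`, which remains a
configurable parameter.

### Valves

The valves are ideal: flow `max(dP, 0)/R`, zero forward drop, zero
reverse leakage, and exactly zero flow at zero pressure difference. No
published diode parameters exist for this circuit; ideal valves reproduce
the reference ICPs within 0.5%, and the residual offset of a few tenths of
a percent (706 simulated vs 709 reported in the normal scenario) is
consistent with a non-ideal diode forward drop in the original
implementation. We made no attempt to reverse-engineer such parameters.

## Parameters

Defaults of `model_parameters()` (ohm-analog resistances, farad-analog
compliances):

| symbol | meaning | default |
|---|---|---|
| `R1` | source series ("tuning") resistance; CBF flows through it | 6 |
| `R2` | arterial resistance | 2.5 |
| `R3` | capillary resistance | 3.25 |
| `R4` | venous resistance | 3 |
| `Rf` | capillary-to-choroid-plexus formation resistance | 5 |
| `Ro` | arachnoid outflow resistance (1 healthy, 5 moderate, 10 severe) | 1 |
| `Cai`, `Cvi`, `Ctiss` | compartment compliances | 0.1 each |
| `P_vs` | drainage reference pressure | 0 Pa |

`R1` has no direct physiological gloss; it is treated purely as the source
series resistance. The compliances are quoted as "100 mF" in the source
element table and interpreted as 0.1 F-analog; the resulting RC time
constants fall in the 0.1–1 s range, consistent with a 1 Hz cardiac drive
and transients that settle within seconds.

Two conversion constants tie the analog scales to clinical units:
1 ohm-analog is about 8 mmHg/ml/min of outflow resistance (placing the
healthy `Ro` inside the normal clinical 6–10 mmHg/ml/min range), and
133.322 Pa/mmHg converts pressures — the value implied exactly by the
reference pressure pairs such as 2496 Pa = 18.72 mmHg.

The shunt (`shunt_spec()`) is either absent, a constant resistance, or the
time-varying malfunction model `R(t) = 15 exp(-0.3 t) (1.2 + sin t)` ohm,
whose sine argument is time in seconds (angular frequency 1 rad/s). The
offset must exceed 1 so the resistance stays positive at finite time; the
decaying envelope drives it to zero, i.e. eventual over-drainage.

## Numerics

* **Integrator.** `deSolve::lsoda`, relative tolerance `1e-8`, absolute
  `1e-10`. The valve nonlinearity is continuous piecewise-linear, so no
  root-finding events are required; `lsoda` switches stiffness regimes on
  its own.
* **Problem size.** Scenarios run 60 s of model time on a 0.01 s output
  grid (6001 samples); each run takes a fraction of a second. The
  time-varying-shunt experiment uses a 15 s horizon, which covers the
  whole closed/open/over-draining episode of the decaying resistance.
* **ICP readout.** The scalar "ICP" of a run is the arithmetic mean of
  `P_ic` over the final 10 s — at least ten times the largest RC time
  constant, so transients have decayed, and an integer number of cardiac
  cycles, so the ripple averages out. The window is an argument of
  `mean_icp()`.
* **Initial conditions.** Runs start from the reference state (all
  pressures zero) by default. The time-varying-shunt experiment starts
  from the untreated severe steady state instead: it represents a patient
  whose ICP is already elevated when the shunt begins to act.
* **DC oracle.** `dc_steady_state()` solves the four-node linear system
  with the source at its offset and all valves conducting, checks the
  conducting assumption on its own solution, and refuses parameter sets
  that violate it. With pulsatile amplitudes set to zero the transient
  simulator converges onto this analytic solution — an independent check
  exercised in the test suite.
* **Tie-break.** Flow through a valve at exactly zero pressure difference
  is exactly zero.
* **Derivatives for volume rates.** `volume_rates()` uses central finite
  differences on the output grid (one-sided at the two endpoints, which
  are first-order and excluded from conservation checks).

## Scenarios and metrics

`run_scenario()` covers: `normal` (`Ro = 1`), `moderate` (`Ro = 5`),
`severe` (`Ro = 10`), `shunt_fixed` (severe + constant shunt, default
1.11111 ohm — the value whose parallel combination with `Ro = 10` restores
the healthy 1 ohm), `shunt_blocked` (severe + 100 ohm occluded shunt) and
`shunt_timevarying`. Percent increase is always computed against a fresh
normal-scenario run under identical solver settings, never against a
stored constant, so discretisation error cancels between numerator and
denominator.

Shunt efficiency is

```
efficiency = (1 - (ICP_after - ICP_healthy) / ICP_before) * 100
```

with `ICP_healthy` from the normal run, `ICP_before` from the
same-pathology no-shunt run, and `ICP_after` from the shunted run. One
internal inconsistency of the reference results is worth noting: the
1.25-ohm shunt is labelled "90% efficient" there, but applying the
efficiency formula to the accompanying ICP values gives about 98%. The
package keeps the resistance and the ICP as anchors and does not assert
the 90% label anywhere.

`resistance_for_efficiency()` inverts the map from shunt resistance to
efficiency (monotone decreasing, hence a unique root): it brackets the
root with the analytic DC solution, then refines on the full pulsatile
simulation until the achieved efficiency is within 0.1 percentage points
of the target. `poiseuille_resistance()` maps catheter geometry to
hydraulic resistance via `R = 8 mu l / (pi r^4)`; beyond the 1 ohm ≈
8 mmHg/ml/min correspondence no finer calibration to the analog scale is
attempted, since no CSF viscosity or catheter dimensions accompany the
reference circuit.

## What the model does and does not capture

The simulator reproduces the steady pressure distribution of the
reference circuit and its response to outflow pathology and shunting. It
is still a four-node caricature of CSF physiology:

* no spinal compartment compliance and no lymphatic absorption pathway
  (both acknowledged omissions of the reference model);
* no cerebral autoregulation, posture or brain-size dependence;
* the pulsatile source amplitudes are far below a physiological pulse
  pressure, so waveform morphology should not be over-interpreted — the
  model's quantitative claims concern time-averaged pressures;
* ideal valves: a real shunt valve has an opening pressure, which would
  shift low-flow operating points.

Passing the package's tests shows the network mathematics and its
steady-state calibration are right; it does not validate the circuit
against patient data.
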