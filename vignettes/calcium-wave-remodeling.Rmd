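---
title: "Centripetal calcium waves in remodeled atrial myocytes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centripetal calcium waves in remodeled atrial myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Atrial cardiomyocytes of most species lack a developed transverse-tubule
system. Calcium entering through L-type channels therefore accumulates only
at the cell periphery, where it triggers calcium-induced calcium release
from the outermost calcium release units (CRUs). Activation of the interior
proceeds as a regenerative *fire–diffuse–fire* wave: each firing CRU raises
the local calcium seen by its neighbour until that neighbour fires in turn,
producing the centripetal wave visible in line-scan images. Sustained rapid
pacing — an experimental surrogate for atrial fibrillation — remodels the
expression and behaviour of the calcium-handling machinery, and remodeled
rabbit atrial cells show *calcium silencing*: the triggered wave no longer
propagates to the cell centre. `atriawave` implements a spatially
discretized rabbit atrial myocyte in which these phenomena can be produced
and dissected: a calibrated population of model variants stands in for
natural cell-to-cell variability, remodeling is imposed as multiplicative
parameter scalings, and every simulated cell is classified into one of five
calcium-wave phenotypes (normal, alternans, silencing, alternans with
silencing, other).

## Spatial architecture

The cell cross-section is segmented into 18 serially coupled transversal
domains with reflecting ends. Every domain contains cytosol, a
sarcoplasmic-reticulum (SR) compartment, and a small sub-SR space (SRS)
hosting one effective, deterministic mean-field CRU. The first and last
domains face the sarcolemma: they carry all membrane currents and two
additional restricted volumes, a sub-sarcolemmal (SL) space sensed by the
electrogenic calcium transporters, and a junctional space into which the
L-type current empties. Interior domains have no direct contact with the
membrane, so everything they receive arrives by diffusion.

Two diffusion pathways couple neighbouring domains, both linear in the
concentration difference (`compute_diffusion()` exposes the cytosolic
operator):

* a cytosolic pathway (default coupling 0.8 /ms), which equilibrates
  diastolic gradients between beats, and
* a sub-SR network pathway (default 0.4 /ms) along which *released* calcium
  spreads laterally at high local concentration. This second pathway carries
  the regenerative wave: bulk cytosolic free calcium (peaks of a few hundred
  nanomolar) never approaches the CRU activation range, whereas the release
  microdomains do. It is the compartment-model counterpart of the sub-micron
  spark–spark coupling that a mean-field 18-domain discretization cannot
  resolve explicitly.

## Ionic model

The action potential is carried by standard Hodgkin–Huxley formulations:
fast sodium current (Luo–Rudy kinetics), transient outward and rapid/slow
delayed-rectifier potassium currents (Courtemanche-type kinetics), inward
rectifier, T-type calcium current, and background sodium, calcium and
chloride currents, plus the sodium–potassium pump, the sodium–calcium
exchanger (NCX, forward and reverse mode, with a partition coefficient of
0.2 and an allosteric calcium activation site at 40 nM), and a plasmalemmal
calcium pump. The L-type current uses voltage-dependent activation and
inactivation plus instantaneous calcium-dependent inactivation sensed in
the junctional space. Conductance magnitudes were parameterized once so the
baseline cell reproduces a rabbit-atrial phenotype at 1 Hz: APD90 ≈ 88 ms,
resting potential ≈ −78 mV, membrane calcium-transient amplitude ≈ 0.29 µM,
diastolic calcium ≈ 0.10 µM, and a per-beat sarcolemmal calcium budget that
closes to ≈ 10⁻⁶ mM per beat.

The user-facing parameters (`cell_parameters()`) are dimensionless scales
on these reference magnitudes, so a sampled model is fully described by its
multipliers. `Jmaxup` (mM/ms) is the maximal SERCA rate of a reversible
Hill pump; `RyR_P` and `NRyRs` enter as ratios to their baseline values.

## Calcium release and its gating

Each domain's CRU is a deterministic three-state (closed/open/refractory)
scheme. Opening requires two permissive signals multiplicatively: a steep
(Hill-4) activation by sub-SR calcium with half-point 22 µM, and a steep
(Hill-4) SR-load gate with half-point 0.32 mM, which makes release
collapse when the SR is unloaded. Open CRUs inactivate with a
calcium-dependent rate and recover on a ~200 ms time scale, providing
beat-to-beat refractoriness; a small calcium-dependent closed-to-refractory
pathway reduces availability when diastolic calcium is elevated. Release
flux is the open fraction times the SR-to-SRS gradient, scaled by the
release-unit density (`NRyRs`, `RyR_P[11]`). `RyR_P[5]` scales the opening
rate (so the low-calcium steady-state open probability is proportional to
it), `RyR_P[1]` the open dwell time, and `RyR_P[0]` the passive SR leak.

Two numerical properties of this gating were design constraints rather than
accidents. First, the quiescent state must be the *only* attractor at
diastolic calcium for SR loads up to at least 0.75 mM: early variants with
lower activation thresholds latched into a self-sustaining leaky state
after the first beat (release keeping sub-SR calcium high enough to keep
the CRU open). The shipped constants were selected on a clamped subsystem
scan for clean ignition, clean termination, and no latch. Second, the
membrane trigger operates deliberately close to its ignition threshold:
the baseline cell fires robustly, but reducing the L-type conductance to
about 0.8 of baseline already fails to ignite. This sharp threshold is what
makes L-type down-regulation silence the entire population, because
calibration only admits candidates whose trigger clears the threshold at
their own sampled conductance, and a 0.4× scaling then puts every member
far below it.

## Buffering

All compartments use the rapid-buffering (instantaneous equilibrium)
approximation: the net free-calcium rate is multiplied by an attenuation
factor in (0, 1] (`apply_buffering()`). The cytosolic and SL spaces carry a
fixed high-affinity buffer (50 µM sites, Kd 0.6 µM) plus a scalable
low-affinity buffer (50 µM sites, Kd 25 µM) whose dissociation constant is
multiplied by `Buff_factor`. Because the working calcium range lies well
below 25 µM, *decreasing* `Buff_factor` below 1 strictly strengthens
buffering — the convention is inverse, and deliberately so: a factor of
0.15 means markedly stronger buffering, and with the fixed buffer dominating
the working range its net effect is a modest (~15 %) reduction of the free
transient without touching the sub-SR wave pathway. That is why increased
buffering strength leaves propagation intact while visibly shrinking the
transient.

## Simulation

`run_paced()` integrates the 108-state system under square-pulse field
stimulation. The production integrator is a fixed-step operator-split
scheme: Rush–Larsen exponential updates for the eleven Hodgkin–Huxley
gates and forward Euler for voltage, concentrations and CRU states, at
`dt = 0.02` ms. An adaptive stiff solver (`method = "lsoda"`, relative
tolerance 1e-6, absolute 1e-9) is available as a cross-check; the tests
require both to agree on APD90 to within about a millisecond and on the
transient amplitude within a few percent, and halving the fixed step changes APD90 by well
under 1 ms. The split scheme is the default because population screening
is two orders of magnitude cheaper there, and the model's stiffest
components (sub-millisecond transfer between restricted spaces) are stable
at the chosen step.

A note on time scales: intracellular sodium equilibrates over minutes in a
real cell. The model uses a restricted effective sodium pool (8 % of the
cytosolic volume) so that sodium reaches quasi-steady state within a
practical pre-pacing window; studies therefore use 60 unrecorded
conditioning beats followed by 10 recorded beats. The SR/calsequestrin pool
is likewise a slow reservoir, so remodeling scenarios are compared under
this fixed, identical protocol rather than at their (computationally
remote) asymptotic states.

## Population calibration

`sample_candidates()` draws log-uniform multipliers in [0.5, 2] on the
eight maximum conductances (GCaL, GNa, Gto1, GKr, GKs, GK1, ImaxNCX,
ImaxNaK); calcium-handling parameters stay at baseline. `calibrate()`
accepts exactly the candidates that show full regenerative propagation
(beat-averaged CaT ratio ≥ 0.5), no alternans, no afterdepolarizations, and
APD90 ∈ [70, 122] ms, resting potential ∈ [−82, −74] mV, membrane CaT
amplitude ∈ [0.19, 0.47] µM — the published control phenotype mean ± 2 SD.
The default study accepts the first 16 passers from a pool of up to 300
candidates; roughly one candidate in four to eight passes, depending on the seed, the leading causes of
rejection being trigger failure (low effective L-type conductance) and
out-of-window APD90.

## Remodeling scenarios

`builtin_scenarios()` encodes the eight remodeled populations as
multiplicative scalings applied to each model's own values: (1) GCaL × 0.4;
(2) ImaxNCX × 2.5; (3) ImaxNaK × 0.5; (4) Jmaxup × 0.7; (5) RyR_P[0],
RyR_P[1], RyR_P[5] × 2; (6) RyR_P[11] and NRyRs × 0.25; (7) Buff_factor
× 0.15; (8) the union of 1–7. Applying 1–7 sequentially is exactly
equivalent to applying 8.

## Classification

For each model the classifier uses the last 10 recorded beats. Alternans:
any consecutive-beat difference in membrane CaT amplitude exceeding 5 %,
normalized by the larger of the pair (the symmetric, bounded choice;
mean-normalization is available). Silencing: central-to-membrane amplitude
ratio ≤ 0.10 on *every* beat, boundary inclusive. Validity flags take
precedence and route a model to "other": repolarization failure (diastolic
potential more than 15 mV above the pre-run resting level), irregular
dynamics (amplitude sequence neither period-1 nor period-2 within 5 %,
assessed relative to at least 0.02 µM so numerically tiny transients are
not flagged), or outright solver failure. A failed simulation is classified
"other" rather than aborting the population.

## The synthetic line-scan generator

`gen_linescan()` emulates what the study measures — per-domain calcium
traces with a centripetal activation delay, toward-centre amplitude
attenuation, even/odd-beat alternation and additive Gaussian noise — using
a difference-of-exponentials beat waveform (rise 5 ms, decay 60 ms). It
exists so the biomarker and classifier layers are testable against known
ground truth without the differential-equation model: noise-free specs
round-trip through the biomarkers to better than 0.5 %, and a seeded grid
of specs spanning all five phenotypes classifies diagonally. What it does
*not* emulate: stochastic spark statistics, wave-front curvature, motion
artefacts, or photobleaching — so classifier performance on it bounds only
the rule logic, not robustness to real imaging noise.

## Design choices where the design was open

* **Pacing rate.** 1 Hz cycle length by default; rapid-pacing remodeling is
  represented purely by parameter scalings, never by fast pacing.
* **Scaling base.** Scenario multipliers act on each model's own sampled
  values, not on the global baseline — the same remodeling applied to
  distinct cells.
* **RMP definition.** Diastolic minimum over the final 50 ms before each
  stimulus (configurable to the mean).
* **CD50.** Measured relative to the per-beat diastolic baseline at
  diastolic + 50 % of amplitude, with linear interpolation.
* **CaTm / CaTc.** Means of the two membrane and the two centremost
  domains' cytosolic traces.
* **NRyRs semantics.** A dimensionless release-magnitude scale; only the
  ratio to the baseline count matters.
* **Trigger sublinearity.** With calcium-dependent inactivation, the
  junctional trigger grows roughly like the square root of GCaL; the sharp
  ignition threshold, not the trigger's linearity, provides the all-or-none
  population response.

## Known limitations

* The CRUs are deterministic mean fields: spark statistics, stochastic
  wave initiation, and spatially discordant alternans are out of scope.
* Under Na/K-pump down-regulation the model reproduces sodium accumulation,
  resting-potential depolarization and a degraded central-to-membrane
  ratio, but the increased SR load *strengthens* the deterministic wave, so
  complete silencing under this scenario arises in fewer models than in
  stochastic formulations where elevated diastolic calcium erodes the spark
  safety margin.
* A single transversal slice is modeled; longitudinal propagation and
  multi-slice interactions are not.
* Temperature dependence and contraction are not modeled.

## Problem sizes used by the shipped analyses

The analysis scripts and the acceptance workflow use a control population
of 8–16 models accepted from a pool of at most 300 candidates, 60
conditioning plus 10 recorded beats at 1 Hz, and the fixed-step integrator
at 0.02 ms. The classifier validation sweeps 45 synthetic line scans and
1,000 randomized amplitude/ratio sequences.
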