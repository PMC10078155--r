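---
title: "An amygdala-modulated model of the GnRH pulse generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An amygdala-modulated model of the GnRH pulse generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Kisspeptin neurons of the arcuate nucleus (the KNDy population, co-expressing
kisspeptin, neurokinin B and dynorphin) generate the episodic GnRH release
that drives pulsatile luteinising hormone (LH) secretion. A kisspeptin
population in the posterodorsal medial amygdala (MePD) modulates the
frequency of this pulse generator: sustained low-frequency optogenetic
stimulation of MePD Kiss1 neurons speeds LH pulses, GABA-A antagonism in the
MePD during stimulation slows them, GABA-B antagonism merely cancels the
speed-up, and ionotropic glutamate antagonism during stimulation can stop
pulsatility altogether. `mepdsim` implements a mean-field model of this
circuitry, a synthetic LH blood-sampling generator, and the pulse-detection /
interpulse-interval (IPI) pipeline used to analyse such experiments, so the
whole qualitative pattern can be reproduced and stress-tested in silico.

## The KNDy core

The arcuate population is reduced to three dimensionless activities:
dynorphin `D`, NKB `N`, and population firing `v`, with Hill-type couplings
(`H(x; K, n) = x^n / (K^n + x^n)`):

\[
\begin{aligned}
\tau_D \dot D &= k_D H(v; K_{vD}, n_{vD}) - D\\
\tau_N \dot N &= k_N H(v; K_{vN}, n_{vN}) \big/
  \left[1 + (D/K_{DN})^{n_{DN}}\right] - N\\
\tau_v \dot v &= v_{max} H(u; K_{uv}, n_{uv}) - v, \qquad
u = \max\!\big(0,\; w_{Nv} H(N; K_{Nv}, n_{Nv}) + I_0 + I_{exc} -
I_{inh}\big)
\end{aligned}
\]

NKB excites firing, closing a fast positive loop (`v -> N -> v`), while
dynorphin accumulates slowly and divisively suppresses NKB secretion, closing
a slow negative loop. For intermediate net drive the fast subsystem is
bistable and the slow dynorphin variable sweeps it around a relaxation
cycle. Net drive `J = I_0 + I_{exc} - I_{inh}` is the bifurcation parameter:

* below a lower threshold (~0.235 with the defaults) the network is
  **silent**;
* inside the band the network is **pulsatile**, with period falling
  monotonically from ~45 min near the lower threshold to ~13 min near the
  upper one;
* above an upper threshold (~0.485) the oscillation terminates and the
  network sits in a depolarised, high-activity **quiescent** state.

`scan_input()` exposes this structure directly, and the test suite confirms
the band ordering, the monotone frequency, and (by an independent
root-finder) that the silent and quiescent states are true fixed points.

Defaults were calibrated by grid search and are committed in
`kndy_params()`: time constants `tau_D = 13`, `tau_N = 2`, `tau_v = 1` min
set the period scale; the half-activations place the bistable range so that
the basal drive `I0 = 0.392` pulses at ~15.5-min intervals at zero external
input, and at 25-30-min intervals under the basal amygdala tone. Two firing
gain parameters (`K_uv`, `n_uv`) shape how directly external input drives
firing; they were essential for making the above-threshold quiescent state
strongly attracting, so that crossing the upper threshold silences the
oscillator within tens of minutes rather than hours.

## The MePD circuit

Four lumped firing-rate populations relax (with `tau_m = 1` min) towards
rectified-saturating (`S(x) = max(0, tanh(slope (x - threshold)))`) functions
of their net input: the Kiss1 population `K` (driven to `kappa_opt` while the
light is on; basal activity `kappa0 = 0` in ovariectomised animals without
steroid replacement), a GABA interneuron population `G1 = S(w_{KG1} K)`, a
glutamatergic population `E = S(w_{KE} K + e_0)`, and the GABAergic efferent
projection `G2`, which receives the basal drive `g_0`, intranuclear
glutamatergic excitation `(1-\beta_{glu}) w_{EG2} E`, and GABA-GABA
inhibition `((1-\beta_A) w_A + (1-\beta_B) w_B) G1`. The circuit output onto
the arcuate core is `I_exc = w_{Eout} E` (glutamatergic projection) and
`I_inh = w_{G2out} G2` (GABAergic efferents).

The exact rectification of the gain function (exactly zero at and below
threshold, rather than an asymptote) makes basal quiescence literal: with the
light off and `kappa0 = 0`, `K = G1 = E = 0`, so every receptor-blockade
condition produces *identical* output — drugs alone are null by construction,
as observed in vivo.

### How the six arms arise

All arms share the control tone `I_inh = w_{G2out} S(g_0)`, which holds the
coupled system at `J_ctrl = 0.265` (~27-min IPI). During stimulation:

* **light only** — `G2` is disinhibited slightly below its basal level and
  `E` turns on, raising `J` to 0.445: faster pulses.
* **GABA-B blocked + light** — the weights were solved so that the extra
  `G2` recovered by removing the `w_B` component exactly cancels the
  stimulatory gain: `J` returns to `J_ctrl` and the IPI is unchanged.
* **GABA-A blocked + light** — glutamatergic excitation of `G2` is now
  nearly unopposed; the inhibitory output overshoots its basal level and
  `J` falls to 0.21, below the lower threshold: the treatment window
  carries at most one event and censors at the 90-min ceiling (a net
  inhibitory MePD output, as the experiments show).
* **glutamate blocked + light** — the intranuclear synapse onto `G2` is cut
  while the GABA-GABA inhibition is fully engaged, so `G2 -> 0` and the
  unopposed glutamatergic projection pushes `J` to 0.57, beyond the upper
  threshold: after at most a couple of transient events the oscillator sits
  in the depolarised quiescent state.

The GABA-A : GABA-B weight split that satisfies these four constraints
simultaneously is `w_A : w_B ~ 1.44 : 1`. A much more lopsided split cannot
make GABA-B blockade exactly cancel the stimulatory gain while GABA-A
blockade reverses it, because both blockades act through the same saturating
`G2` gain; the committed values are the exact solution of the steady-state
operating points and are exposed in `mepd_params()` for sensitivity
analysis.

Design choices left open by the biology, and how they were resolved:
interneuron and projection glutamate are merged into one population `E`
feeding both `G2` and the arcuate projection; the antagonist cocktail blocks
only the intranuclear synapse (`E -> G2`), because infused drugs act on MePD
receptors only; antagonist action is a step to full blockade at the bolus
time (50 min) held through the continuous infusion; the 5-Hz optical drive is
abstracted to a constant increment `kappa_opt` while the light is on;
unilateral stimulation is ignored (single lumped circuit).

## Regime classification and events

`classify_regime()` applies committed thresholds to the firing activity over
a window of at least 30 min: *silent* if `max(v) < 0.10 v_max`;
*quiescent-high* if activity stays at or above that level with
peak-to-trough variation under `0.05 v_max`; otherwise *pulsatile*.
`pulse_times_from_activity()` marks one event per cycle at the upward
crossing of `0.5 max(v)`. `run_arm()` starts the core on its
control-condition limit cycle (`control_cycle_state()`), so control-window
statistics are stationary, and summarises both windows with the same
censoring rule as the in-vivo pipeline: fewer than two events in a window
yields the 90-min ceiling value.

## Synthetic LH sampling

`generate_cohort()` emulates tail-tip sampling: pulse onsets follow a gamma
renewal process (mean `mu_ipi`, CV `cv_ipi = 0.2` by default — the minimal
standard choice for quasi-periodic pulses given that only group means and
SEMs are reported); each pulse deposits a lognormal amplitude (mean 2 ng/ml,
CV 0.3) that decays exponentially (`tau_clear = 15` min) over a 0.5 ng/ml
baseline; the series is sampled every 5 min for 2.5 h, with the interval
statistics switching from the pre- to the post-treatment setting at 60 min;
finally each measurement is multiplied by lognormal noise with mean 1 and CV
4.6%, the intra-assay variation of the LH ELISA. Amplitude, baseline and
clearance defaults are plausible placeholders chosen to make representative
traces look like published mouse LH profiles — they are not biological
estimates, and the recovery tests are insensitive to them within reason. The
10.2% inter-assay variation is available but off by default (one experiment
= one assay run).

What the generator does *not* emulate: assay censoring at the detection
limit, secretion kinetics (pulses are instantaneous), within-window trends,
and any coupling between amplitude and interval. Passing recovery tests
therefore show that the pipeline is consistent with its own generative
model, not that it would match DynPeak call-for-call on real data.

## Pulse detection and statistics

`detect_pulses()` is a deliberately simple two-threshold rise detector (the
published DynPeak algorithm is cited by the experimental design but its
parameterisation is not reproducible from the text): a local maximum is a
call when its rise above the preceding nadir exceeds
`max(min_rise_frac, k_sigma * assay_cv) * nadir`, with a refractory spacing
between calls. The defaults (`min_rise_frac = 0.2`, `k_sigma = 3`,
`refractory_min = 10`) were tuned on synthetic cohorts to >= 90% sensitivity
with <= 0.1 false calls per hour at the default noise level; the suite
verifies both, plus exact (±1 sample) recovery on noise-free series and
grid-shift equivariance.

`compute_ipi()` averages successive call times inside left-open,
right-closed windows (a call exactly at 60 min belongs to the control
window; a window starting at 0 includes 0), censoring at 90 min when fewer
than two calls are present — the zero-pulse convention of the in-vivo
analysis, extended to the one-call case, which likewise yields no interval.
Censored values enter group means as 90 with their flags propagated.
`compare_windows()` delegates the two-way repeated-measures analysis (time
within animal × arm between animals) to `stats::aov()` with an
`Error(animal/time)` stratum and reports F, degrees of freedom and p per
effect; the simulation suite checks that the interaction test holds its
nominal 5% size under the null and detects a 15-min post-window shift at
n = 7 in most replicates.

## Numerical choices

Integration uses the explicit adaptive Dormand-Prince 4(5) pair from
**deSolve** with `atol = 1e-8`, `rtol = 1e-6`, resampled to 0.1-min output;
the integrator is restarted at every protocol discontinuity (bolus, light
on/off) so adaptive steps never straddle a jump. The contracts are tested
rather than assumed: identical calls are bit-identical, halving tolerances
changes the firing trace by < 1e-4 relative and the measured period by
< 0.5%, finite differences of the flow reproduce the derivative field to
O(h), and an independent root-finder confirms every non-pulsatile regime
label. Event times are linearly interpolated between output samples.
`scan_input()` measures cycle frequency from mid-level crossings rather than
the event threshold, because oscillation amplitude shrinks continuously as
the upper bifurcation is approached and a fixed fraction of the peak stops
intersecting every cycle there.

Problem sizes committed in the test and acceptance suites: 50 cohorts of 7
animals for each interval-recovery target; 10,000 replicate measurements for
the noise calibration; a 21-point input scan; 400 null replicates for the
test size and 150 for power; 6 random ±10% weight-perturbation draws for the
direction-table robustness property (each draw costs four coupled
simulations).

## Known limitations

* The model is a lumped firing-rate caricature: no spiking, no conductances,
  no spatial structure, no estrogen feedback (the animals are
  ovariectomised), and no pharmacokinetics beyond a step blockade.
* The calibrated operating points are one consistent solution, not an
  identified fit; only the qualitative six-arm pattern and the bifurcation
  structure are claimed, and a robustness property guards the signed arms
  under ±10% weight perturbations.
* Under GABA-A blockade with stimulation the committed calibration silences
  the treatment window (censored at 90 min) rather than slowing it to a
  finite interval; both are "increase" outcomes under the censoring
  convention, and the wide reported spread of post-treatment intervals is
  compatible with a mixture containing censored windows.
* One to two pulse-generator events right after light onset are unavoidable
  in the glutamate-blockade arm (the drive ramps through the fast-pulsing
  band before crossing the upper threshold); termination is asserted on the
  final hour of the protocol.
* The detector is not DynPeak; agreement with published DynPeak outputs on
  real data is not claimed.
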