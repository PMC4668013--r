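---
title: "Rate and time coding of synchronized Purkinje-neuron pauses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate and time coding of synchronized Purkinje-neuron pauses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausecode)
```

## The scientific question

Cerebellar nucleus (CN) neurons receive convergent inhibition from on the
order of 200 Purkinje neurons (PNs) together with mossy-fiber excitation.
PN simple-spike trains are not Poisson: they alternate highly regular
inter-spike intervals (ISIs) with intermittent *pauses* — unusually long
ISIs.  When pauses coincide across the presynaptic population, the CN
neuron is transiently released from inhibition.  pausecode implements an
in-silico pipeline for asking how that release is read out downstream:
as a *rate code* (a firing-rate increase during the synchronous pause) or
as a *time code* (a reproducible first-spike latency after pause onset,
quantified by circular vector strength).

The pipeline has four stages, mirroring the package's modules:

1. **PN synthesis** (`generate_template_train()`, `segment_isis()`,
   `synthesize_train()`): gamma-renewal spike trains whose ISIs split into
   regular patterns and pauses.
2. **Pause synchrony** (`synchrony_spec()`, `align_pauses()`,
   `force_prepause_rate()`): imposing pause-beginning, pause-ending,
   overlapping or mixed synchronization on a selected fraction of trains.
3. **CN neuron simulation** (`cn_config()`, `simulate_trial()`,
   `run_control_pair()`): a conductance-based two-compartment model driven
   by 200 depressing GABAergic synapses and 100 mossy-fiber AMPA/NMDA
   synapses.
4. **Analysis** (`rate_increase()`, `first_spike_latency()`,
   `vector_strength()`, `latency_variability()`, `rebound_analysis()`):
   trial-level statistics against matched controls.

## Synthetic PN spike trains

Templates emulate spontaneous simple-spike recordings at 50 Hz in which
half of the ISIs are pauses.  Each ISI is labelled a pause with
probability `pause_fraction` (default 0.5); regular ISIs are drawn from a
high-order gamma (order 8, making the local coefficient of variation
about 0.35) and pause ISIs from a low-order gamma (order 1.5, mean 30 ms).
The regular mean ISI is solved so the overall rate matches `rate_hz`.
These defaults express the study conditions — 50 Hz spontaneous rate and
half of the ISIs contributed by pauses — and stay fixed throughout.

Segmentation classifies an ISI as a pause when it is at least
`pause_floor_ms` (20 ms by default, the shorter of the two pause
thresholds used downstream) *and* locally irregular: the larger CV2 of
its two adjacent ISI pairs exceeds `cv2_threshold` (default 0.2, the
regular-pattern criterion from the literature the CV2 measure comes
from).  CV2 is `2|b - a| / (a + b)`, bounded on `[0, 2]` and insensitive
to slow rate drift.  Neither constant is printed in the study this
package reimplements, so both are exposed as arguments.

Synthesis regenerates a template segment by segment with fresh gamma
draws, preserving every segment's ISI count.  By default the gamma
statistics are estimated at the train level: pause ISIs by
truncated-gamma maximum likelihood above the floor, regular ISIs by a
two-component gamma mixture fitted by EM.  The mixture matters: the
regular class pools genuinely regular intervals with short irregular
ones, and across regular patterns the effective gamma order itself
varies, so a single gamma visibly underfits at the sample sizes a 120 s
train provides (~6000 ISIs).  Validation is a two-sample
Kolmogorov–Smirnov test on the ISI distributions (`ks_validate()`,
pass means p > 0.01); with these defaults the pass rate over 100
template/synthetic pairs is at ceiling.

One design trade-off deserves emphasis.  A marginal-faithful synthesis
must reproduce the template's small population of long-but-regular ISIs,
which means a redrawn "regular pattern" occasionally contains an ISI
above the pause floor, and re-segmenting the synthetic train then finds a
slightly different pause-segment count.  A structure-preserving synthesis
(`preserve_classes = TRUE`) instead truncates every draw to its class
range — pauses stay above the floor, regular draws below it — so the
segment structure survives a round trip, at the cost of clipping that
tail.  The default is marginal fidelity; switch it when segment-count
stability matters more than distributional exactness.

What the generator does *not* emulate: complex spikes and the pauses they
trigger (not simulated at all), slow non-stationary rate modulation, and
inter-train rate heterogeneity.  Tests passing on these synthetic trains
therefore speak to the pause-synchrony mechanism, not to every statistic
of real recordings.

## Imposing pause synchrony

A synchrony event is described by `synchrony_spec()`: type, participating
fraction (round-half-up of `fraction * n` trains), pause-eligibility
threshold (20 or 40 ms), optional one-sided jitter, and the anchor time.
In each participating train an eligible pause (ISI longer than the
threshold, plus the jitter allowance for beginning alignment) is chosen
uniformly at random and moved onto the anchor by *circular rotation* of
the whole train: every ISI is preserved except the one seam interval
created at the wrap point, spike count is conserved exactly, and the
firing statistics before and after the pause remain those of the original
gamma process.  (A rigid local shift with compressed flanking ISIs was
considered and rejected: with pauses selected uniformly over a 3 s trial
the displacement is of order seconds, and any local compression would
distort flank firing rates by large factors.)

Alignment targets per type, for window `W = [event, event + threshold]`:
`beginning` puts the pause-opening spike at the anchor (after its jitter
draw from `Uniform[0, J]` — one-sided, delaying, since the analyses of
jittered inputs measure first spikes after the jitter period);
`ending` puts the pause-closing spike at the end of `W`; `overlapping`
places the pause to strictly contain `W` with the overhang split
uniformly, so no spike is aligned; `mixed` assigns participants to the
three mechanisms in equal proportion.  One event is placed per 3 s trial,
at 1.5 s — at least 500 ms after trial start and 1 s before its end so a
1 s rebound window always fits.

`force_prepause_rate()` additionally conditions the selection on the
100 ms of spiking preceding the pause containing `round(f_pn / 10)`
spikes (±1).  Because alignment rotates the train rigidly, the pre-pause
spiking travels with the pause automatically.  When no pause with the
requested history exists the function falls back to an unconditioned
eligible pause and records the miss (`fallback_rate` attribute).

## The CN neuron model

The original study drove a morphologically detailed CN neuron model whose
channel equations are not reproduced here; pausecode uses a calibrated
two-compartment stand-in that expresses the two mechanisms the study's
conclusions rest on — release-from-inhibition ramps bounded by the
chloride reversal potential, and hyperpolarization-gated recovery of
rebound conductances.  The soma carries fast Na and delayed-rectifier K
(Wang–Buzsáki kinetics), leak, and persistent Na (NaP) with slow
inactivation (half-inactivation −80 mV, τ 300 ms) acting as the
subthreshold pacemaker; the lumped dendrite carries leak, HCN, and
low-voltage-activated Ca (CaLVA) with an inactivation gate (half −80 mV,
τ 80 ms), plus all synapses.  Integration is exponential-Euler at a fixed
0.025 ms step; halving the step changes the spike count of a 2 s trial by
at most one.

Inhibition: 200 PN synapses, maximal conductance 11.7 nS each, reversal
−75 mV, double-exponential kinetics (rise 0.5 ms, decay 2.5 ms at 37 °C,
Q10 = 2 corrected to the model's 32 °C, giving ~0.71/3.54 ms).  Release
depresses with presynaptic frequency `r` (Hz) according to

* steady state: `Rss(r) = 0.08 + 0.60 exp(-2.84 r) + 0.32 exp(-0.02 r)`
* time constant: `tau(r) = 2 + 2500 exp(-0.274 r) + 100 exp(-0.022 r)` ms

with per-synapse state relaxing exactly (event-driven closed form)
between spikes, `r` taken from the most recent ISI and initialized at
each train's mean rate.  At 50 Hz drive the release scale settles near
0.20, so the effective unitary IPSG is about 2.3 nS at unit gain.

Excitation: 100 mossy fibers, independent 5 Hz Poisson processes, each
synapse expressing AMPA plus fast and slow NMDA components; NMDA
conductances are scaled by the sigmoid `f(V) = 1/(1 + s1 exp(-s2 V))`,
weakly voltage-dependent for the fast component (s1 0.42, s2 0.015) and
strongly for the slow one (s1 0.28, s2 0.062).  The AMPA/NMDA peak
conductances and `s1, s2` are calibration parameters of the stand-in
(their experimental values are not printed in the text this work is
based on).

The `gain_condition` scales synaptic maximal conductances: inhibitory
10/70/150% and excitatory 7/12/24% for low/medium/high.  Calibration
targets, in order of priority: a regular intrinsic pacemaker when all
synapses are silenced (74 Hz, ISI CV < 0.001); mean rate in the
37–38 Hz in-vivo band under the high-gain condition (achieved at the
printed gains; the medium condition sits near 47 Hz at its printed gains
and reaches the band through `tune_gains()`, which bisects the excitatory
gain at fixed inhibitory gain — the stand-in cannot make all three
printed excitatory percentages and the band simultaneously consistent,
and the low condition remains well above it); ISI irregularity strictly
increasing with gain (CV ≈ 0.08/0.70/0.81); and a membrane floor at the
chloride reversal: with excitation blocked and saturating inhibition the
voltage stays above −75.5 mV.  The three rebound variants m1/m2/m3 share
this calibration and differ only in their (HCN, CaLVA, NaP) density
triples; `block_rebound = TRUE` zeroes all three, the in-silico analogue
of pharmacological blockade.

Every synchronized trial is paired with a control simulation using the
identical mossy-fiber realization and the unmodified PN population
(`run_control_pair()`), so any difference is attributable to the imposed
synchrony alone.

## Analysis conventions

* **Rate increase**: spike-count difference between synchronized and
  control runs inside a window, divided by window length, in Hz;
  **reliability** is the percentage of trials with a positive increase.
* **First-spike latency**: time from pause onset to the first CN spike
  inside the pause; trials with no in-pause spike are censored and
  reported as a count, not silently dropped into the statistics.
* **Latency variability**: the SD if the latency sample (and any sample
  it is compared against) passes a Lilliefors normality test at the 99%
  confidence level, otherwise the MAD (scaled consistently with the SD).
* **Vector strength**: latencies are mapped onto a circle whose full turn
  is the pause duration; `R` is the resultant length of the unit phasors,
  `Z = n R²`, and significance uses the finite-sample corrected Rayleigh
  approximation.  The correction matters at the calibration point used
  throughout (n = 100, α = 0.01): the critical values are R = 0.2139 and
  Z = 4.575, where the uncorrected exponential form would give 4.605.
  For sample sizes so small that no resultant can reach significance the
  threshold is reported as `NA`.
* **Comparisons** between conditions use a percentile bootstrap of the
  mean difference (10⁴ resamples) or a one-tailed Welch t-test at the 95%
  confidence level.
* **Rebound**: the 1 s rate increase from pause onset, correlated
  (Pearson) across trials with the forced pre-pause PN rate, alongside
  the mean CaLVA and NaP inactivation gates over the 100 ms before
  onset.

## Reproducing the experiment designs

`reproduce()` wraps the condition sweeps (`gain_cv`, `rate_modulation`,
`blockade`, `timelocking`, `jitter`, `rebound`) with full seed
provenance; `scale_factor` shrinks the 100-trial cells for desk-scale
runs (0.25 by default; 1.0 reproduces full cells).  Trials are 3 s with
the synchronous event at 1.5 s; the analysis windows are the pause window
itself and the 1 s rebound window.  The test suite runs the designs at
reduced trial counts (30–100 trials per cell) so the whole suite stays
within ordinary desk budgets; the acceptance script
(`scripts/acceptance.R`) runs the full 100-trial time-locking condition.

## Numerical choices and degenerate inputs

Gamma sampling uses inverse-CDF draws for truncated classes; synthesized
ISIs are clamped to a 1 ns floor so spike times stay strictly
increasing.  Template trains that happen to lack an eligible pause are
redrawn from a deterministically bumped seed (`ensure_pause_ms`).
`align_pauses()` is idempotent: re-applying an identical spec is a
no-op.  All randomness flows through per-call seeds derived from one
master seed, and the global RNG state of the session is never disturbed.

## Known limitations

The CN model is a calibrated stand-in, not a reconstruction: absolute
rate-increase magnitudes inherit its calibration, which is why the
package's quantitative anchors are the analytic Rayleigh calibration, the
synthesis fidelity, orderings between conditions, and the significance
and monotonicity of time-locking, rather than exact rate values.  The
low-gain condition fires well above the in-vivo band at its printed
gains.  Complex spikes, spillover-mediated GABA-B effects,
zebrin-structured connectivity and multi-event trials are out of scope.
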