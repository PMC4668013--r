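# pausecode

Purkinje neurons (PNs) fire highly regular simple spikes interrupted by
pauses, and neighbouring PNs often pause together.  The cerebellar nucleus
(CN) neurons they converge on — about 200 inhibitory PN synapses per CN
neuron, plus mossy-fiber excitation — must read this structure out.
pausecode is an R package for studying, in silico, how synchronized PN
pauses are encoded downstream: as a **rate code** (firing-rate increase
during the synchronous pause, against a matched control simulation) and as
a **time code** (reproducible first-spike latency after pause onset,
quantified by circular vector strength with a Rayleigh significance test).

The package provides the full pipeline:

* **Synthetic PN trains** — gamma-renewal processes whose inter-spike
  intervals (ISIs) alternate regular patterns (high-order gamma) and pauses
  (low-order gamma); CV2-based segmentation
  (`CV2 = 2|b−a|/(a+b)`); synthesis of matched trains validated by
  two-sample Kolmogorov–Smirnov tests.
* **Pause synchrony** — align selected pauses across a population by their
  beginning spike, ending spike, or pure overlap (or a mix), at 25–100%
  participation, with optional spike jitter and forced pre-pause firing
  rates (fPN).
* **A conductance-based CN neuron** — two compartments, fast Na/K spiking,
  persistent-Na pacemaking, rebound conductances (HCN, T-type Ca,
  persistent Na) in three variants, 200 frequency-dependently depressing
  GABA synapses (`Rss(r) = 0.08 + 0.60 e^{−2.84 r} + 0.32 e^{−0.02 r}`,
  `τ(r) = 2 + 2500 e^{−0.274 r} + 100 e^{−0.022 r}` ms) and 100 mossy-fiber
  AMPA/NMDA synapses with sigmoid NMDA voltage dependence
  `f(V) = 1/(1 + s1 e^{−s2 V})`, integrated in C++ at a 0.025 ms step.
* **Analysis** — windowed rate increases and their reliability, first-spike
  latency variability with a Lilliefors normality gate (SD vs MAD), PSTHs,
  vector strength `R = |Σ e^{iθ}|/n` with the finite-sample corrected
  Rayleigh test (`Z = nR²`), Pearson correlation, bootstrap / one-tailed
  t-test comparisons, and rebound analysis against pre-pause PN rates.

## A worked example

Ten trials of the strongest time-locking condition: every one of the 200
PN trains pauses at 1500 ms for at least 20 ms, with pause-beginning
spikes aligned, at high input gain.

```r
library(pausecode)

cfg   <- cn_config(gain_condition = "high")
pairs <- run_trials(10, cfg, sync_type = "beginning", fraction = 1,
                    pause_threshold_ms = 20, seed = 42)

lat <- first_spike_latency(pairs, onset_ms = 1500, pause_ms = 20)
lat
#> <latency_sample> 10/10 trials in-pause (median 15.60 ms), 0 censored

vector_strength(lat)
#> <vector_strength> R = 0.7379 (threshold 0.6552), Z = 5.445, p = 0.00221, n = 10

ri <- vapply(pairs, rate_increase, numeric(1), window = c(1500, 1520))
round(c(mean = mean(ri), sd = sd(ri)), 1)
#> mean   sd 
#> 35.0 41.2
```

Most trials' first spikes land in a narrow band near 16 ms after pause
onset: the synchronized pause-beginning spikes clamp the membrane at the
chloride reversal (−75 mV), and the release-from-inhibition ramp is then
almost deterministic, so the resultant vector strength (0.74 at these ten
trials; ~0.86 at the 100-trial design the acceptance script runs) exceeds
its significance threshold.  The mean in-pause firing-rate increase of
35 Hz over the matched controls is the rate-code side of the same
event.  `reproduce("timelocking", ...)`, `reproduce("jitter", ...)`
and friends run the full condition sweeps.

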