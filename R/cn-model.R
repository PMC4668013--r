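#' Synapse kinetics helpers
#'
#' Double-exponential synaptic conductance and its supporting quantities.
#' The conductance after a single presynaptic spike is
#' `g(t) = gmax * N * (exp(-t/tau_decay) - exp(-t/tau_rise))`, where the
#' normalization `N` makes the peak equal `gmax`.
#'
#' @param t_since_spike time since the presynaptic spike, ms (>= 0).
#' @param g_max peak conductance, nS.
#' @param tau_rise,tau_decay rise and decay time constants, ms
#'   (`0 < tau_rise < tau_decay`).
#' @return conductance in nS; 0 at `t = 0`, exactly `g_max` at the peak time
#'   `t* = tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)`.
#' @export
double_exp_conductance <- function(t_since_spike, g_max, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need 0 < tau_rise < tau_decay")
  if (any(t_since_spike < 0)) stop("t_since_spike must be >= 0")
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  N <- 1 / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
  g_max * N * (exp(-t_since_spike / tau_decay) - exp(-t_since_spike / tau_rise))
}

#' Frequency-dependent depression of the PN-to-CN synapse
#'
#' Steady-state release probability and depression time constant as
#' functions of the instantaneous presynaptic frequency `r` (Hz):
#' `Rss(r) = 0.08 + 0.60 exp(-2.84 r) + 0.32 exp(-0.02 r)` and
#' `tau(r) = 2 + 2500 exp(-0.274 r) + 100 exp(-0.022 r)` ms.  Both are
#' monotone decreasing, with asymptotes 0.08 and 2 ms.
#'
#' @param r instantaneous presynaptic frequency, Hz (>= 0); vectorized.
#' @return `steady_state_release()`: release probability in `(0, 1]`;
#'   `depression_tau()`: time constant in ms.
#' @export
steady_state_release <- function(r) {
  if (any(r < 0)) stop("r must be >= 0")
  0.08 + 0.60 * exp(-2.84 * r) + 0.32 * exp(-0.02 * r)
}

#' @rdname steady_state_release
#' @export
depression_tau <- function(r) {
  if (any(r < 0)) stop("r must be >= 0")
  2 + 2500 * exp(-0.274 * r) + 100 * exp(-0.022 * r)
}

#' Relax the release state toward its steady state
#'
#' First-order relaxation of a synapse's release state toward
#' [steady_state_release()] at rate `1/`[depression_tau()], for a constant
#' instantaneous frequency `r` held over `dt` ms.  The update is the exact
#' solution of the linear ODE, so a single call over `dt` equals the
#' composition of any partition of `dt`.
#'
#' @param release_state current release state in `(0, 1]`.
#' @param r instantaneous presynaptic frequency, Hz.
#' @param dt elapsed time, ms (> 0).
#' @return updated release state.
#' @export
update_release <- function(release_state, r, dt) {
  if (any(dt <= 0)) stop("dt must be > 0")
  rs <- steady_state_release(r)
  rs + (release_state - rs) * exp(-dt / depression_tau(r))
}

#' NMDA receptor voltage dependence
#'
#' Sigmoidal relief of the NMDA conductance block,
#' `f(V) = 1 / (1 + s1 * exp(-s2 * V))`, in `(0, 1)` and increasing in `V`.
#'
#' @param v_m membrane potential, mV; vectorized.
#' @param s1,s2 fit parameters (`s1 > 0`, `s2 > 0`).
#' @return unitless factor in `(0, 1)`.
#' @export
nmda_factor <- function(v_m, s1, s2) {
  1 / (1 + s1 * exp(-s2 * v_m))
}

#' Q10 temperature scaling of a time constant
#'
#' `tau_ref * q10^((t_ref - t_target) / 10)`: time constants shorten when
#' warming and lengthen when cooling.
#'
#' @param tau_ref time constant at the reference temperature, ms.
#' @param t_ref_c,t_target_c reference and target temperatures, deg C.
#' @param q10 temperature coefficient (2 for synaptic current kinetics).
#' @return scaled time constant, ms.
#' @export
q10_scale <- function(tau_ref, t_ref_c, t_target_c, q10 = 2) {
  if (any(tau_ref <= 0)) stop("tau_ref must be > 0")
  tau_ref * q10^((t_ref_c - t_target_c) / 10)
}

# (HCN, CaLVA, NaP) density triples, nS.  The three presets express the
# qualitative rebound phenotypes: m1 burst + pause + prolonged rebound,
# m2 burst + pause + strong prolonged rebound, m3 burst merging into the
# prolonged rebound without a pause.  NaP is kept common so the variants
# share the same spontaneous rate; they differ in the fast (CaLVA) and slow
# (HCN) rebound components.
.rebound_presets <- list(
  m1 = c(hcn = 10, calva = 220, nap = 100),
  m2 = c(hcn = 10, calva = 300, nap = 100),
  m3 = c(hcn = 25, calva = 160, nap = 100)
)

# inhibitory / excitatory gain pairs (fractions of maximal conductance)
.gain_conditions <- list(
  low = c(inh = 0.10, exc = 0.07),
  medium = c(inh = 0.70, exc = 0.12),
  high = c(inh = 1.50, exc = 0.24)
)

#' Configure the CN neuron model
#'
#' Builds the full parameter set of the two-compartment CN neuron: passive
#' properties, spiking and rebound conductances (selected by
#' `rebound_variant` m1/m2/m3, which differ only in their HCN, CaLVA and NaP
#' densities), and the synaptic populations — 200 inhibitory PN synapses
#' (GABA-A, maximal conductance 11.7 nS, reversal -75 mV, depressing) and
#' 100 mossy-fiber synapses (AMPA + fast/slow NMDA) firing as independent
#' 5 Hz Poisson processes.  The `gain_condition` scales every synaptic
#' maximal conductance: inhibitory gains 10/70/150% and excitatory gains
#' 7/12/24% for low/medium/high.  Synaptic time constants are specified at
#' the recording temperature of 37 C and Q10-corrected (Q10 = 2) to the
#' model temperature of 32 C.
#'
#' @param gain_condition `"low"`, `"medium"` or `"high"`.
#' @param rebound_variant `"m1"`, `"m2"` or `"m3"`.
#' @param block_rebound if `TRUE`, zero the HCN, CaLVA and NaP conductances
#'   (pharmacological blockade in silico).
#' @param inh_gain,exc_gain explicit gain overrides (fractions, not %).
#' @param dt integration step, ms.
#' @param ... overrides for any engine parameter (advanced use).
#' @return object of class `cn_config`: named list of engine parameters plus
#'   bookkeeping fields.
#' @export
cn_config <- function(gain_condition = c("high", "medium", "low"),
                      rebound_variant = c("m2", "m1", "m3"),
                      block_rebound = FALSE,
                      inh_gain = NULL, exc_gain = NULL,
                      dt = 0.025, ...) {
  gain_condition <- match.arg(gain_condition)
  rebound_variant <- match.arg(rebound_variant)
  g <- .gain_conditions[[gain_condition]]
  reb <- .rebound_presets[[rebound_variant]]
  if (block_rebound) reb[] <- 0
  t_model <- 32; t_exp <- 37
  p <- list(
    # passive / intrinsic (calibration parameters, see vignette)
    c_soma = 300, c_dend = 600, g_couple = 100,
    g_na = 12000, g_kdr = 4000, g_leak_soma = 15, g_leak_dend = 25,
    e_leak = -67.5, e_na = 50, e_k = -90, e_ca = 120, e_hcn = -30,
    g_hcn = unname(reb["hcn"]), g_calva = unname(reb["calva"]),
    g_nap = unname(reb["nap"]),
    nap_tau_h = 300, calva_tau_h = 80, hcn_tau_m = 300,
    # synapses
    e_gaba = -75, e_exc = 0,
    gaba_gmax = 11.7,
    gaba_tau_rise = q10_scale(0.5, t_exp, t_model),
    gaba_tau_decay = q10_scale(2.5, t_exp, t_model),
    ampa_gmax = 27,
    ampa_tau_rise = q10_scale(0.3, t_exp, t_model),
    ampa_tau_decay = q10_scale(1.8, t_exp, t_model),
    nmdaf_gmax = 10.7, nmdaf_s1 = 0.42, nmdaf_s2 = 0.015,
    nmdaf_tau_rise = q10_scale(1, t_exp, t_model),
    nmdaf_tau_decay = q10_scale(13, t_exp, t_model),
    nmdas_gmax = 3.75, nmdas_s1 = 0.28, nmdas_s2 = 0.062,
    nmdas_tau_rise = q10_scale(8, t_exp, t_model),
    nmdas_tau_decay = q10_scale(150, t_exp, t_model),
    inh_gain = if (is.null(inh_gain)) unname(g["inh"]) else inh_gain,
    exc_gain = if (is.null(exc_gain)) unname(g["exc"]) else exc_gain,
    spike_threshold = -20, refractory = 1.5
  )
  dots <- list(...)
  p[names(dots)] <- dots
  structure(c(p, list(gain_condition = gain_condition,
                      rebound_variant = rebound_variant,
                      block_rebound = block_rebound,
                      n_pn_synapses = 200L, n_mf_synapses = 100L,
                      mf_rate_hz = 5, temperature_c = t_model, dt = dt)),
            class = "cn_config")
}

#' @export
print.cn_config <- function(x, ...) {
  cat(sprintf(
    "<cn_config> %s gain (inh %.0f%%, exc %.0f%%), variant %s%s, dt %g ms\n",
    x$gain_condition, 100 * x$inh_gain, 100 * x$exc_gain,
    x$rebound_variant, if (x$block_rebound) " (rebound blocked)" else "",
    x$dt))
  invisible(x)
}

# Pooled mossy-fiber Poisson events over [0, duration): n_fibers independent
# 5 Hz processes are equivalent to one pooled process for conductance
# purposes (no per-synapse state on the excitatory pathway).
mf_poisson_events <- function(n_fibers, rate_hz, duration_ms, seed) {
  with_seed(seed, {
    rate_ms <- n_fibers * rate_hz / 1000
    n_guess <- ceiling(rate_ms * duration_ms + 4 * sqrt(rate_ms * duration_ms)) + 10
    tt <- cumsum(stats::rexp(n_guess, rate_ms))
    while (length(tt) && tt[length(tt)] < duration_ms)
      tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n_guess, rate_ms)))
    tt[tt < duration_ms]
  })
}

#' Simulate one trial of the CN neuron
#'
#' Drives the two-compartment CN model with a population of (typically 200)
#' PN spike trains through depressing GABA-A synapses and a seeded
#' mossy-fiber Poisson barrage through AMPA/NMDA synapses, and integrates
#' the membrane equations at fixed step `config$dt`.  The result is
#' deterministic given `(config, pn_trains, mf_seed)`.
#'
#' @param config a [cn_config()].
#' @param pn_trains list of [spike_train()]s, one per PN synapse (length
#'   must equal `config$n_pn_synapses` unless `relax_n = TRUE`).
#' @param mf_seed integer seed for the mossy-fiber realization.
#' @param duration_ms simulated time; defaults to the PN train duration.
#' @param record if `TRUE`, keep voltage and gating traces sampled every
#'   `record_dt_ms`.
#' @param record_dt_ms trace sampling interval, ms.
#' @param relax_n allow PN populations of any size (testing).
#' @return object of class `cn_trial`: list with `spikes` (ms),
#'   optional `trace` (data.frame `t`, `v_soma`, `v_dend`, `h_calva`,
#'   `h_nap`, `g_inh`), `duration_ms`, `mf_seed` and the config.
#' @export
simulate_trial <- function(config, pn_trains, mf_seed = 1L,
                           duration_ms = NULL, record = FALSE,
                           record_dt_ms = 0.5, relax_n = FALSE) {
  stopifnot(inherits(config, "cn_config"))
  if (!relax_n && length(pn_trains) != config$n_pn_synapses)
    stop("expected ", config$n_pn_synapses, " PN trains, got ",
         length(pn_trains))
  if (is.null(duration_ms))
    duration_ms <- max(vapply(pn_trains, train_duration, numeric(1)))
  times <- lapply(pn_trains, as.numeric)
  n_sp <- lengths(times)
  pn_t <- unlist(times, use.names = FALSE)
  pn_syn <- rep.int(seq_along(times), n_sp) - 1L
  ord <- order(pn_t)
  pn_t <- pn_t[ord]; pn_syn <- pn_syn[ord]
  pn_rate <- 1000 * n_sp / vapply(pn_trains, train_duration, numeric(1))
  mf_t <- mf_poisson_events(config$n_mf_synapses, config$mf_rate_hz,
                            duration_ms, mf_seed)
  res <- .cn_engine(unclass(config), pn_t, as.integer(pn_syn), pn_rate,
                    mf_t, duration_ms, config$dt, record, record_dt_ms)
  structure(list(spikes = res$spikes, trace = res$trace,
                 duration_ms = duration_ms, mf_seed = mf_seed,
                 config = config),
            class = "cn_trial")
}

#' @export
print.cn_trial <- function(x, ...) {
  cat(sprintf("<cn_trial> %d CN spikes over %g ms (%.1f Hz)%s\n",
              length(x$spikes), x$duration_ms,
              1000 * length(x$spikes) / x$duration_ms,
              if (!is.null(x$trace)) ", traces recorded" else ""))
  invisible(x)
}

#' Run a synchronized trial and its matched control
#'
#' Simulates the CN neuron twice with the identical mossy-fiber realization
#' and integration settings: once with the synchronized PN population and
#' once with the unmodified population the synchronization was applied to.
#' Differences between the two runs are therefore attributable to the
#' synchronous pause alone.
#'
#' @inheritParams simulate_trial
#' @param synced_trains,control_trains PN populations differing only by the
#'   synchronization transform.
#' @return list of class `cn_trial_pair`: `synced` and `control`
#'   [simulate_trial()] results plus the `sync_info` of the synced set.
#' @export
run_control_pair <- function(config, synced_trains, control_trains,
                             mf_seed = 1L, duration_ms = NULL,
                             record = FALSE, record_dt_ms = 0.5) {
  if (length(synced_trains) != length(control_trains))
    stop("synced and control populations must have the same size")
  syn <- simulate_trial(config, synced_trains, mf_seed, duration_ms,
                        record, record_dt_ms)
  ctl <- simulate_trial(config, control_trains, mf_seed, duration_ms,
                        record, record_dt_ms)
  structure(list(synced = syn, control = ctl,
                 sync_info = attr(synced_trains, "sync_info")),
            class = "cn_trial_pair")
}
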