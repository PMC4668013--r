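#' Run a batch of synchronized trials with matched controls
#'
#' The per-trial pipeline used throughout the experiment designs: generate a
#' fresh synthetic PN population (template generation, CV2 segmentation,
#' gamma synthesis), impose the requested pause synchrony, and simulate the
#' CN neuron on the synchronized and the unmodified population with the same
#' mossy-fiber realization.  Every trial derives its own seeds from `seed`.
#'
#' @param n_trials number of trials.
#' @param config a [cn_config()].
#' @param sync_type,fraction,pause_threshold_ms,jitter_ms,event_time_ms
#'   forwarded to [synchrony_spec()] per trial.
#' @param duration_ms trial length, ms.
#' @param seed master seed for the batch.
#' @param f_pn optional forced pre-pause rate (Hz): scalar or one value per
#'   trial; switches alignment to [force_prepause_rate()].
#' @param record record voltage/gating traces.
#' @param n_trains PN population size.
#' @return list of [run_control_pair()] results, with the per-trial
#'   synchrony spec attached to each element.
#' @export
run_trials <- function(n_trials, config,
                       sync_type = "beginning", fraction = 1,
                       pause_threshold_ms = 20, jitter_ms = 0,
                       event_time_ms = 1500, duration_ms = 3000,
                       seed = 1L, f_pn = NULL, record = FALSE,
                       n_trains = config$n_pn_synapses) {
  seeds <- matrix(derive_seeds(seed, 3L * n_trials), ncol = 3L)
  if (!is.null(f_pn) && length(f_pn) == 1L) f_pn <- rep(f_pn, n_trials)
  lapply(seq_len(n_trials), function(i) {
    pop <- generate_pn_population(n_trains = n_trains,
                                  duration_ms = duration_ms,
                                  seed = seeds[i, 1L],
                                  ensure_pause_ms = pause_threshold_ms +
                                    jitter_ms)
    spec <- synchrony_spec(sync_type, fraction, pause_threshold_ms,
                           jitter_ms, event_time_ms, seed = seeds[i, 2L])
    synced <- synchronize_population(pop, spec,
                                     f_pn = if (is.null(f_pn)) NULL
                                            else f_pn[i])
    pair <- run_control_pair(config, synced, pop, mf_seed = seeds[i, 3L],
                             duration_ms = duration_ms, record = record)
    pair$spec <- spec
    pair
  })
}

#' Tune the excitatory gain to a target firing-rate band
#'
#' With the inhibitory gain fixed at its condition value, bisects the
#' excitatory gain until the mean CN firing rate over an unsynchronized
#' simulation falls inside `target_band` (defaults to the 37-38 Hz in-vivo
#' band) or `max_iter` is reached.
#'
#' @param config a [cn_config()]; its `exc_gain` is the quantity tuned.
#' @param target_band numeric `(lo, hi)` in Hz.
#' @param duration_ms length of the tuning simulation.
#' @param seed seed for the PN population and mossy fibers.
#' @param max_iter bisection iterations.
#' @param gain_range search interval for the excitatory gain (fraction).
#' @return list `(exc_gain, rate_hz, iterations)`.
#' @export
tune_gains <- function(config, target_band = c(37, 38),
                       duration_ms = 10000, seed = 1L, max_iter = 20,
                       gain_range = c(0, 2)) {
  seeds <- derive_seeds(seed, 2L)
  pop <- generate_pn_population(n_trains = config$n_pn_synapses,
                                duration_ms = duration_ms, seed = seeds[1])
  rate_at <- function(g) {
    cfg <- config; cfg$exc_gain <- g
    tr <- simulate_trial(cfg, pop, mf_seed = seeds[2],
                         duration_ms = duration_ms)
    1000 * length(tr$spikes) / duration_ms
  }
  r0 <- rate_at(config$exc_gain)
  if (r0 >= target_band[1] && r0 <= target_band[2])
    return(list(exc_gain = config$exc_gain, rate_hz = r0, iterations = 0L))
  lo <- gain_range[1]; hi <- gain_range[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo > target_band[2] || r_hi < target_band[1])
    stop(sprintf("target band unreachable for gain in [%g, %g] (rates %.1f-%.1f Hz)",
                 lo, hi, r_lo, r_hi))
  g <- config$exc_gain; r <- r0
  for (it in seq_len(max_iter)) {
    g <- (lo + hi) / 2
    r <- rate_at(g)
    if (r >= target_band[1] && r <= target_band[2])
      return(list(exc_gain = g, rate_hz = r, iterations = it))
    if (r < target_band[1]) lo <- g else hi <- g
  }
  list(exc_gain = g, rate_hz = r, iterations = max_iter)
}

.experiments <- c("gain_cv", "rate_modulation", "blockade", "timelocking",
                  "jitter", "rebound")

#' Reproduce a named experiment design at desk scale
#'
#' Orchestrates the condition sweeps of the study: `gain_cv` (ISI
#' irregularity of the CN neuron versus input gain), `rate_modulation`
#' (in-pause rate increase over synchrony type x fraction x pause length),
#' `blockade` (rate increase with and without rebound conductances),
#' `timelocking` (vector strength over fraction x pause length x gain),
#' `jitter` (first spikes within the jitter period for jittered beginning
#' spikes), and `rebound` (1 s post-onset rate increase versus forced
#' pre-pause PN rate).  `scale_factor` shrinks the number of trials per grid
#' cell proportionally (full scale is 100 trials per cell); every cell's
#' seeds derive from `master_seed`, so a rerun with the same seed reproduces
#' the results byte for byte.
#'
#' @param experiment_name one of
#'   `r paste0('\x60', paste(.experiments, collapse = '\x60, \x60'), '\x60')`.
#' @param scale_factor in `(0, 1]`; multiplies the 100-trial cell size.
#' @param master_seed integer seed for the whole run.
#' @param out_dir optional directory; when given, per-cell CSV tables and a
#'   `manifest.json` (seeds, configuration, package version) are written.
#' @param gain_conditions subset of gain conditions to sweep.
#' @return list with `summary` (data.frame over grid cells), `manifest`,
#'   and, when `out_dir` is given, the output paths.
#' @export
reproduce <- function(experiment_name, scale_factor = 0.25,
                      master_seed = 1L, out_dir = NULL,
                      gain_conditions = c("low", "medium", "high")) {
  if (!experiment_name %in% .experiments)
    stop("unknown experiment '", experiment_name, "'; valid names: ",
         paste(.experiments, collapse = ", "))
  if (scale_factor <= 0 || scale_factor > 1)
    stop("scale_factor must be in (0, 1]")
  n_trials <- max(3L, as.integer(round(100 * scale_factor)))
  runner <- switch(experiment_name,
    gain_cv = .exp_gain_cv, rate_modulation = .exp_rate_modulation,
    blockade = .exp_blockade, timelocking = .exp_timelocking,
    jitter = .exp_jitter, rebound = .exp_rebound)
  summary <- runner(n_trials, master_seed, gain_conditions)
  manifest <- list(experiment = experiment_name,
                   scale_factor = scale_factor, n_trials = n_trials,
                   master_seed = master_seed,
                   gain_conditions = gain_conditions,
                   package_version = as.character(utils::packageVersion("pausecode")))
  out <- list(summary = summary, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(experiment_name, "_summary.csv"))
    utils::write.csv(summary, csv, row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    out$paths <- c(csv, file.path(out_dir, "manifest.json"))
  }
  out
}

.exp_gain_cv <- function(n_trials, seed, gains) {
  seeds <- derive_seeds(seed, length(gains))
  do.call(rbind, lapply(seq_along(gains), function(i) {
    cfg <- cn_config(gain_condition = gains[i])
    dur <- 10000
    pop <- generate_pn_population(n_trains = cfg$n_pn_synapses,
                                  duration_ms = dur, seed = seeds[i])
    tr <- simulate_trial(cfg, pop, mf_seed = seeds[i], duration_ms = dur)
    x <- diff(tr$spikes)
    data.frame(gain = gains[i], rate_hz = 1000 * length(tr$spikes) / dur,
               isi_cv = stats::sd(x) / mean(x))
  }))
}

.exp_rate_modulation <- function(n_trials, seed, gains) {
  grid <- expand.grid(gain = gains, sync = c("beginning", "overlapping"),
                      pause = c(20, 40), fraction = c(0.25, 0.5, 0.75, 1),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pairs <- run_trials(n_trials, cn_config(gain_condition = g$gain),
                        sync_type = g$sync, fraction = g$fraction,
                        pause_threshold_ms = g$pause, seed = seeds[i])
    win <- c(1500, 1500 + g$pause)
    ri <- vapply(pairs, rate_increase, numeric(1), window = win)
    data.frame(g, mean_increase_hz = mean(ri), sd_increase_hz = stats::sd(ri),
               reliability_pct = 100 * mean(ri > 0))
  }))
}

.exp_blockade <- function(n_trials, seed, gains) {
  gains <- intersect(gains, c("medium", "high"))
  grid <- expand.grid(gain = gains, blocked = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, length(gains))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cell_seed <- seeds[match(g$gain, gains)]  # same trials +/- blockade
    pairs <- run_trials(n_trials,
                        cn_config(gain_condition = g$gain,
                                  block_rebound = g$blocked),
                        sync_type = "beginning", fraction = 1,
                        pause_threshold_ms = 20, seed = cell_seed)
    ri <- vapply(pairs, rate_increase, numeric(1), window = c(1500, 1520))
    data.frame(g, mean_increase_hz = mean(ri), sd_increase_hz = stats::sd(ri))
  }))
}

.exp_timelocking <- function(n_trials, seed, gains) {
  grid <- expand.grid(gain = gains, pause = c(20, 40),
                      fraction = c(0.25, 0.5, 0.75, 1),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pairs <- run_trials(n_trials, cn_config(gain_condition = g$gain),
                        sync_type = "beginning", fraction = g$fraction,
                        pause_threshold_ms = g$pause, seed = seeds[i])
    lat <- first_spike_latency(pairs, 1500, g$pause)
    vs <- tryCatch(vector_strength(lat), error = function(e) NULL)
    data.frame(g, n_censored = lat$n_censored,
               R = if (is.null(vs)) NA_real_ else vs$R,
               Z = if (is.null(vs)) NA_real_ else vs$Z,
               p = if (is.null(vs)) NA_real_ else vs$p,
               significant = if (is.null(vs)) NA else vs$p < 0.01)
  }))
}

.exp_jitter <- function(n_trials, seed, gains) {
  grid <- expand.grid(gain = gains, jitter = c(1, 3, 5, 7),
                      fraction = c(0.25, 0.5, 0.75, 1),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pairs <- run_trials(n_trials, cn_config(gain_condition = g$gain),
                        sync_type = "beginning", fraction = g$fraction,
                        pause_threshold_ms = 40, jitter_ms = g$jitter,
                        seed = seeds[i])
    lat <- first_spike_latency(pairs, 1500, 40)
    data.frame(g,
               pct_within_jitter = 100 * mean(lat$latencies <= g$jitter),
               median_latency_ms = stats::median(lat$latencies))
  }))
}

.exp_rebound <- function(n_trials, seed, gains) {
  gains <- utils::tail(gains, 1)  # high-gain design
  fractions <- c(0.25, 0.5, 0.75, 1)
  seeds <- derive_seeds(seed, 2L * length(fractions))
  do.call(rbind, lapply(seq_along(fractions), function(i) {
    f_pn <- with_seed(seeds[2L * i - 1L],
                      stats::runif(n_trials, 30, 110))
    pairs <- run_trials(n_trials, cn_config(gain_condition = gains),
                        sync_type = "beginning", fraction = fractions[i],
                        pause_threshold_ms = 20, seed = seeds[2L * i],
                        f_pn = f_pn, record = TRUE)
    ra <- rebound_analysis(pairs, f_pn, onset_ms = 1500)
    data.frame(gain = gains, fraction = fractions[i],
               pearson_r = ra$pearson_r,
               max_increase_hz = max(ra$per_trial$rate_increase_hz))
  }))
}
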