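#' Firing-rate increase inside a window, against the matched control
#'
#' Rate difference between the synchronized run and its control inside a
#' window, `(count_synced - count_control) / width`, in Hz.
#'
#' @param pair a [run_control_pair()] result, or any list with `synced` and
#'   `control` elements carrying `spikes` (ms).
#' @param window numeric length-2 `(start, end)` in ms.
#' @return rate increase in Hz (negative for decreases).
#' @export
rate_increase <- function(pair, window) {
  stopifnot(length(window) == 2)
  if (diff(window) <= 0) stop("window must have positive length")
  dur <- pair$synced$duration_ms %||% Inf
  if (window[1] < 0 || window[2] > dur)
    stop("window outside the simulated interval")
  cs <- sum(pair$synced$spikes >= window[1] & pair$synced$spikes < window[2])
  cc <- sum(pair$control$spikes >= window[1] & pair$control$spikes < window[2])
  1000 * (cs - cc) / diff(window)
}

#' Reliability of the firing-rate increase
#'
#' Percentage of trials whose in-window rate increase is strictly positive.
#'
#' @param pairs list of [run_control_pair()] results.
#' @param window numeric `(start, end)` ms.
#' @return percentage in `[0, 100]`.
#' @export
reliability <- function(pairs, window) {
  if (!length(pairs)) stop("need at least one trial")
  100 * mean(vapply(pairs, rate_increase, numeric(1), window = window) > 0)
}

#' First-spike latency from pause onset
#'
#' Latency of the first CN spike inside the synchronous pause, per trial.
#' Trials with no spike inside the pause are censored (returned as `NA`).
#'
#' @param pairs list of [run_control_pair()] results.
#' @param onset_ms pause onset on the population timeline.
#' @param pause_ms pause duration, ms.
#' @param from measure latency in the synced (default) or control run.
#' @return object of class `latency_sample`: list with `latencies` (ms,
#'   censored trials dropped), `n_trials`, `n_censored`, `pause_ms`.
#' @export
first_spike_latency <- function(pairs, onset_ms, pause_ms,
                                from = c("synced", "control")) {
  from <- match.arg(from)
  lat <- vapply(pairs, function(p) {
    s <- p[[from]]$spikes
    s <- s[s >= onset_ms & s < onset_ms + pause_ms]
    if (length(s)) s[1] - onset_ms else NA_real_
  }, numeric(1))
  structure(list(latencies = lat[!is.na(lat)], n_trials = length(lat),
                 n_censored = sum(is.na(lat)), pause_ms = pause_ms),
            class = "latency_sample")
}

#' @export
print.latency_sample <- function(x, ...) {
  cat(sprintf("<latency_sample> %d/%d trials in-pause (median %.2f ms), %d censored\n",
              length(x$latencies), x$n_trials,
              stats::median(x$latencies), x$n_censored))
  invisible(x)
}

#' Latency variability with a normality gate
#'
#' Spread of first-spike latencies: the standard deviation when the sample
#' passes a Lilliefors normality test at level `alpha`, otherwise the median
#' absolute deviation (scaled to be consistent with the SD under normality).
#' When `other` is supplied, both samples must pass for the SD to be used —
#' variability measures that are compared against each other should share an
#' estimator.
#'
#' @param sample a [first_spike_latency()] result or numeric vector (>= 8
#'   values after censoring).
#' @param alpha Lilliefors significance level (default 0.01, a 99%
#'   confidence criterion).
#' @param other optional second sample entering the same comparison.
#' @return list `(value, estimator)` with `estimator` `"SD"` or `"MAD"`.
#' @export
latency_variability <- function(sample, alpha = 0.01, other = NULL) {
  x <- if (inherits(sample, "latency_sample")) sample$latencies else sample
  if (length(x) < 8) stop("need at least 8 latencies")
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    nortest::lillie.test(v)$p.value > alpha
  }
  use_sd <- normal(x)
  if (!is.null(other)) {
    y <- if (inherits(other, "latency_sample")) other$latencies else other
    use_sd <- use_sd && length(y) >= 8 && normal(y)
  }
  if (use_sd) list(value = stats::sd(x), estimator = "SD")
  else list(value = stats::mad(x), estimator = "MAD")
}

#' Rayleigh test p-value with finite-sample correction
#'
#' Probability of a resultant as long as `R` under circular uniformity for
#' `n` unit vectors, using the series-corrected approximation
#' `p = exp(-Z) [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`
#' with `Z = n R^2`.  The finite-`n` terms matter at the calibration point
#' used throughout: at `n = 100`, `alpha = 0.01` the critical values are
#' `R = 0.2139`, `Z = 4.575` (the uncorrected form gives `Z = 4.605`).
#'
#' @param R resultant vector length in `[0, 1]`.
#' @param n number of vectors.
#' @return p-value (clamped to `(0, 1]`).
#' @export
rayleigh_p <- function(R, n) {
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Critical vector strength and Rayleigh Z for a given sample size
#'
#' Solves `rayleigh_p(R, n) = alpha` for `R`; the corresponding critical
#' statistic is `Z = n R^2`.
#'
#' @param n number of trials.
#' @param alpha significance level.
#' @return list `(threshold_R, z_crit)`; both `NA` when no resultant can
#'   reach significance at this `n` (e.g. `n = 2` at `alpha = 0.01`).
#' @export
rayleigh_threshold <- function(n, alpha = 0.01) {
  f <- function(R) rayleigh_p(R, n) - alpha
  if (f(1 - 1e-9) > 0)
    return(list(threshold_R = NA_real_, z_crit = NA_real_))
  r <- stats::uniroot(f, c(1e-4, 1 - 1e-9), tol = 1e-12)$root
  list(threshold_R = r, z_crit = n * r^2)
}

#' Vector strength of first-spike latencies
#'
#' Maps each latency onto the circle whose full turn is the pause duration,
#' `theta_i = 2 pi latency_i / pause_ms`, and computes the resultant length
#' `R = |sum exp(i theta)| / n` (1 = perfect time-locking, 0 = uniform),
#' the Rayleigh statistic `Z = n R^2`, its corrected p-value and the
#' significance threshold for this `n`.
#'
#' @param sample a [first_spike_latency()] result, or numeric latencies.
#' @param pause_ms pause duration (circle period); taken from the sample if
#'   absent.
#' @param alpha significance level for the threshold.
#' @return object of class `vector_strength`: list with `R`, `Z`, `p`,
#'   `threshold_R`, `n`, `angles`.
#' @export
vector_strength <- function(sample, pause_ms = NULL, alpha = 0.01) {
  if (inherits(sample, "latency_sample")) {
    if (is.null(pause_ms)) pause_ms <- sample$pause_ms
    x <- sample$latencies
  } else x <- as.numeric(sample)
  if (is.null(pause_ms)) stop("pause_ms required")
  if (!length(x)) stop("no uncensored latencies")
  if (length(x) < 2) stop("need at least 2 latencies")
  if (any(x < 0 | x >= pause_ms)) stop("latencies must lie in [0, pause_ms)")
  th <- 2 * pi * x / pause_ms
  n <- length(th)
  R <- Mod(sum(exp(1i * th))) / n
  Z <- n * R^2
  structure(list(R = R, Z = Z, p = rayleigh_p(R, n),
                 threshold_R = rayleigh_threshold(n, alpha)$threshold_R,
                 n = n, angles = th),
            class = "vector_strength")
}

#' @export
print.vector_strength <- function(x, ...) {
  cat(sprintf("<vector_strength> R = %.4f (threshold %.4f), Z = %.3f, p = %.3g, n = %d\n",
              x$R, x$threshold_R, x$Z, x$p, x$n))
  invisible(x)
}

#' Population spike-timing histogram
#'
#' Bins all spikes of a population at `bin_ms` resolution over the common
#' duration and normalizes to the total spike count, so the bins sum to 1.
#'
#' @param trains list of [spike_train()]s (or a single one).
#' @param bin_ms bin width, ms.
#' @return data.frame with `time` (bin left edge, ms) and `density`
#'   (fraction of all spikes per bin).
#' @export
psth <- function(trains, bin_ms = 1) {
  if (is_spike_train(trains)) trains <- list(trains)
  dur <- max(vapply(trains, train_duration, numeric(1)))
  tt <- unlist(lapply(trains, as.numeric), use.names = FALSE)
  if (!length(tt)) stop("no spikes")
  edges <- seq(0, dur + bin_ms, by = bin_ms)
  h <- hist(tt, breaks = edges, plot = FALSE, right = FALSE)
  data.frame(time = h$breaks[-length(h$breaks)],
             density = h$counts / length(tt))
}

#' Pearson correlation coefficient
#'
#' The correlation `cov(X, Y) / (sd(X) * sd(Y))`, implemented directly;
#' errors on degenerate input rather than returning `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y; correlation undefined")
  stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
}

#' Compare two condition samples
#'
#' Either a percentile bootstrap on the difference of means (default
#' `n_boot = 1e4` resamples) or a one-tailed Welch t-test, at a 95%
#' confidence level by default.  The one-sided alternative is that `a` has
#' the greater mean.
#'
#' @param a,b numeric samples (each `n >= 5`).
#' @param test `"bootstrap"` or `"one_tailed_t"`.
#' @param alpha significance level.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return list `(stat, p, significant)`; `stat` is the observed mean
#'   difference (bootstrap) or the t statistic.
#' @export
compare_conditions <- function(a, b, test = c("bootstrap", "one_tailed_t"),
                               alpha = 0.05, n_boot = 1e4, seed = 1L) {
  test <- match.arg(test)
  if (length(a) < 5 || length(b) < 5) stop("each sample needs n >= 5")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(stat = 0, p = 1, significant = FALSE))
  if (test == "one_tailed_t") {
    tt <- stats::t.test(a, b, alternative = "greater")
    return(list(stat = unname(tt$statistic), p = tt$p.value,
                significant = tt$p.value < alpha))
  }
  d_obs <- mean(a) - mean(b)
  p <- with_seed(seed, {
    na <- length(a); nb <- length(b)
    d <- vapply(seq_len(n_boot), function(i)
      mean(a[sample.int(na, na, replace = TRUE)]) -
        mean(b[sample.int(nb, nb, replace = TRUE)]), numeric(1))
    # one-sided percentile p: how often the resampled difference is <= 0
    (1 + sum(d <= 0)) / (n_boot + 1)
  })
  list(stat = d_obs, p = p, significant = p < alpha)
}

#' Rebound analysis against the pre-pause PN rate
#'
#' For trials grouped by forced pre-pause PN rate `f_pn`: the CN firing-rate
#' increase over 1 s from pause onset (against the matched control), the
#' Pearson correlation of that increase with `f_pn` across trials, and the
#' mean inactivation gating variables of the CaLVA and NaP currents over the
#' 100 ms window preceding the pause (recovery from inactivation).
#'
#' @param pairs list of [run_control_pair()] results simulated with
#'   `record = TRUE`.
#' @param f_pn numeric vector, one forced rate per trial, Hz.
#' @param onset_ms pause onset, ms.
#' @param window_ms rebound quantification window (default 1000 ms).
#' @param pre_ms pre-pause gating window (default 100 ms).
#' @return list with `per_trial` (data.frame `f_pn`, `rate_increase_hz`,
#'   `mean_h_calva`, `mean_h_nap`) and `pearson_r`.
#' @export
rebound_analysis <- function(pairs, f_pn, onset_ms, window_ms = 1000,
                             pre_ms = 100) {
  if (length(pairs) != length(f_pn))
    stop("need one f_pn per trial")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p$synced$trace)) stop("trials must carry gating traces")
    ri <- rate_increase(p, c(onset_ms, onset_ms + window_ms))
    tr <- p$synced$trace
    pre <- tr$t >= onset_ms - pre_ms & tr$t < onset_ms
    data.frame(f_pn = f_pn[i], rate_increase_hz = ri,
               mean_h_calva = mean(tr$h_calva[pre]),
               mean_h_nap = mean(tr$h_nap[pre]))
  })
  per_trial <- do.call(rbind, rows)
  r <- pearson_r(per_trial$f_pn, per_trial$rate_increase_hz)
  list(per_trial = per_trial, pearson_r = r)
}

#' Expected ratio of pause rate to complex-spike rate
#'
#' Under spontaneous PN firing at `rate_hz` with a fraction
#' `pause_isi_fraction` of ISIs being pauses, pauses occur at
#' `rate_hz * pause_isi_fraction` per second; relative to a complex-spike
#' rate of `cs_rate_hz` the pauses outnumber complex spikes by this ratio.
#'
#' @param rate_hz spontaneous PN simple-spike rate, Hz.
#' @param pause_isi_fraction fraction of ISIs that are pauses.
#' @param cs_rate_hz complex-spike rate, Hz.
#' @return unitless ratio (25 under the default 50 Hz, 0.5, 1 Hz).
#' @export
pause_cs_ratio <- function(rate_hz = 50, pause_isi_fraction = 0.5,
                           cs_rate_hz = 1) {
  stopifnot(rate_hz > 0, pause_isi_fraction >= 0, cs_rate_hz > 0)
  rate_hz * pause_isi_fraction / cs_rate_hz
}
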