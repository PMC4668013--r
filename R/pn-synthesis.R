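#' Local inter-spike-interval variability (CV2)
#'
#' CV2 of a pair of adjacent inter-spike intervals,
#' `2 * |b - a| / (a + b)`.  The statistic is bounded on `[0, 2]`, is 0 for
#' identical intervals and, unlike the global coefficient of variation, is
#' insensitive to slow rate drift, which makes it the standard measure for
#' separating locally regular Purkinje-neuron firing from pauses.
#'
#' @param isi_a,isi_b adjacent inter-spike intervals in ms; vectorized.
#' @return numeric in `[0, 2]`.
#' @examples
#' cv2(20, 20)  # 0
#' cv2(10, 30)  # 1
#' @export
cv2 <- function(isi_a, isi_b) {
  if (any(isi_a <= 0) || any(isi_b <= 0))
    stop("ISIs must be positive")
  2 * abs(isi_b - isi_a) / (isi_a + isi_b)
}

#' Generate a template Purkinje-neuron spike train
#'
#' Emulates a spontaneous PN simple-spike recording: inter-spike intervals are
#' an alternation of regular patterns (high-order gamma, short ISIs) and
#' pauses (low-order gamma, long ISIs).  Each ISI is a pause with probability
#' `pause_fraction`, so maximal runs of either label form the pattern/pause
#' segments.  The regular-pattern mean ISI is solved from the requested
#' overall rate given `pause_mean_isi`, so the empirical rate matches
#' `rate_hz` for long trains.
#'
#' @param rate_hz target mean firing rate, Hz.
#' @param pause_fraction fraction of ISIs that are pauses, in `[0, 1]`.
#' @param regular_order gamma shape of regular-pattern ISIs (> 0, high).
#' @param pause_order gamma shape of pause ISIs (> 0, low).
#' @param duration_ms train length, ms.
#' @param pause_mean_isi mean pause ISI, ms.
#' @param seed integer seed; a fixed seed gives a byte-identical train.
#' @param unit_id identifier attached to the result.
#' @return a [spike_train()] with a `labels` attribute marking each ISI as
#'   `"regular"` or `"pause"` (generative labels, not a segmentation).
#' @export
generate_template_train <- function(rate_hz = 50, pause_fraction = 0.5,
                                    regular_order = 8, pause_order = 1.5,
                                    duration_ms = 120000,
                                    pause_mean_isi = 30,
                                    seed = 1L, unit_id = 1L) {
  stopifnot(rate_hz > 0, pause_fraction >= 0, pause_fraction <= 1,
            regular_order > 0, pause_order > 0, pause_mean_isi > 0)
  mean_isi <- 1000 / rate_hz
  if (pause_fraction < 1) {
    reg_mean <- (mean_isi - pause_fraction * pause_mean_isi) /
      (1 - pause_fraction)
    if (reg_mean <= 0)
      stop("pause_mean_isi too long for the requested rate and pause_fraction")
  } else reg_mean <- mean_isi
  if (pause_fraction == 1) pause_mean_isi <- mean_isi
  if (duration_ms < 3 * mean_isi)
    stop("duration too short to hold a pattern")

  with_seed(seed, {
    # draw ~20% surplus ISIs, then trim to duration
    n_guess <- ceiling(1.2 * duration_ms / mean_isi) + 20L
    lab <- stats::runif(n_guess) < pause_fraction
    isis <- numeric(n_guess)
    nr <- sum(!lab); np <- sum(lab)
    if (nr) isis[!lab] <- stats::rgamma(nr, shape = regular_order,
                                        scale = reg_mean / regular_order)
    if (np) isis[lab] <- stats::rgamma(np, shape = pause_order,
                                       scale = pause_mean_isi / pause_order)
    t0 <- stats::runif(1, 0, mean_isi)
    times <- t0 + cumsum(isis)
    keep <- times <= duration_ms
    times <- c(t0, times[keep])
    st <- spike_train(times, duration = duration_ms, unit_id = unit_id)
    attr(st, "labels") <- ifelse(lab[keep], "pause", "regular")
    st
  })
}

#' Segment ISIs into regular patterns and pauses
#'
#' An ISI is classified as a pause when it is at least `pause_floor_ms` long
#' and its local CV2 exceeds `cv2_threshold`; the local CV2 of an ISI is the
#' larger of the CV2 values of its two adjacent ISI pairs (edge ISIs use the
#' single available pair).  Maximal runs of the remaining ISIs form regular
#' patterns, so the segments partition the ISI sequence.
#'
#' @param train a [spike_train()] with at least 3 spikes.
#' @param cv2_threshold unitless CV2 cut-off for irregularity.
#' @param pause_floor_ms minimum ISI length (ms) counted as a pause.
#' @return an object of class `isi_segmentation`: list with `segments`
#'   (data.frame `kind`, `start_index`, `end_index` over ISIs, 1-based and
#'   inclusive), `cv2_values` (per adjacent pair, length `n_isi - 1`),
#'   `is_pause` (per ISI), and the thresholds used.
#' @export
segment_isis <- function(train, cv2_threshold = 0.2, pause_floor_ms = 20) {
  x <- isi(train)
  n <- length(x)
  if (n < 2) stop("need at least 3 spikes (2 ISIs) to segment")
  cv2v <- cv2(x[-n], x[-1])
  local_cv2 <- pmax(c(cv2v[1], cv2v), c(cv2v, cv2v[n - 1]))
  is_pause <- x >= pause_floor_ms & local_cv2 > cv2_threshold
  r <- rle(is_pause)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  segs <- data.frame(kind = ifelse(r$values, "pause", "regular_pattern"),
                     start_index = start, end_index = end,
                     stringsAsFactors = FALSE)
  structure(list(segments = segs, cv2_values = cv2v, is_pause = is_pause,
                 cv2_threshold = cv2_threshold,
                 pause_floor_ms = pause_floor_ms),
            class = "isi_segmentation")
}

#' @export
print.isi_segmentation <- function(x, ...) {
  k <- table(x$segments$kind)
  cat(sprintf("<isi_segmentation> %d segments (%d pause, %d regular), CV2 > %g, floor %g ms\n",
              nrow(x$segments), k["pause"] %||% 0L, k["regular_pattern"] %||% 0L,
              x$cv2_threshold, x$pause_floor_ms))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Truncated-gamma maximum likelihood: fit shape/mean of a gamma conditioned
# on floor <= x < ceiling.  Pause ISIs enter the segmentation only above the
# pause floor and regular-pattern ISIs essentially only below it, so each
# class is fitted (and redrawn) on its own range.
fit_gamma_trunc <- function(x, floor_ms = 0, ceiling_ms = Inf) {
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) v <- (0.5 * m)^2
  start <- c(log(max(m^2 / v, 0.05)), log(m))
  nll <- function(par) {
    shape <- exp(par[1]); mu <- exp(par[2])
    sc <- mu / shape
    ll <- sum(stats::dgamma(x, shape = shape, scale = sc, log = TRUE))
    mass <- stats::pgamma(min(ceiling_ms, .Machine$double.xmax),
                          shape = shape, scale = sc) -
      stats::pgamma(floor_ms, shape = shape, scale = sc)
    if (mass < 1e-12) return(1e10)
    ll <- ll - length(x) * log(mass)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 500))
  list(order = exp(fit$par[1]), mean_isi = exp(fit$par[2]))
}

rgamma_trunc <- function(n, shape, scale, floor_ms) {
  if (floor_ms <= 0) return(stats::rgamma(n, shape = shape, scale = scale))
  # inverse-CDF sampling restricted to the upper tail
  p0 <- stats::pgamma(floor_ms, shape = shape, scale = scale)
  u <- stats::runif(n, p0, 1)
  stats::qgamma(pmin(u, 1 - 1e-12), shape = shape, scale = scale)
}

# gamma draws conditioned on x < ceiling_ms (regular ISIs stay below the
# pause floor so a synthesized regular pattern remains a regular pattern)
rgamma_trunc_upper <- function(n, shape, scale, ceiling_ms) {
  if (!is.finite(ceiling_ms))
    return(stats::rgamma(n, shape = shape, scale = scale))
  p1 <- stats::pgamma(ceiling_ms, shape = shape, scale = scale)
  u <- stats::runif(n, 0, max(p1, 1e-12))
  stats::qgamma(pmin(u, 1 - 1e-12), shape = shape, scale = scale)
}

# Two-component gamma mixture fitted by EM (moment-matched M-step).  The
# regular-pattern ISI pool is itself heterogeneous — the gamma orders of
# regular patterns vary across patterns — so a single gamma underfits it;
# two components capture the narrow core plus the broader short-interval
# fringe below the pause floor.
fit_gamma_mix2 <- function(x, max_iter = 40, tol = 1e-6) {
  qs <- stats::quantile(x, c(0.35, 0.85))
  lo <- x[x <= qs[1]]; hi <- x[x > qs[1]]
  comp <- function(v) {
    m <- mean(v); s2 <- stats::var(v)
    if (!is.finite(s2) || s2 <= 0) s2 <- (0.3 * m)^2
    c(shape = m^2 / s2, scale = s2 / m)
  }
  p1 <- comp(lo); p2 <- comp(hi); w <- length(lo) / length(x)
  lx <- log(x)
  ldgamma <- function(p) (p["shape"] - 1) * lx - x / p["scale"] -
    lgamma(p["shape"]) - p["shape"] * log(p["scale"])
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w * exp(ldgamma(p1))
    d2 <- (1 - w) * exp(ldgamma(p2))
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    g1 <- d1 / tot
    ll <- sum(log(tot))
    w <- mean(g1)
    if (w < 1e-3 || w > 1 - 1e-3) break
    m1 <- sum(g1 * x) / sum(g1)
    v1 <- sum(g1 * (x - m1)^2) / sum(g1)
    m2 <- sum((1 - g1) * x) / sum(1 - g1)
    v2 <- sum((1 - g1) * (x - m2)^2) / sum(1 - g1)
    if (v1 > 0) p1 <- c(shape = m1^2 / v1, scale = v1 / m1)
    if (v2 > 0) p2 <- c(shape = m2^2 / v2, scale = v2 / m2)
    if (is.finite(ll) && abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(w = w, comp1 = p1, comp2 = p2)
}

rgamma_mix2_trunc_upper <- function(n, fit, ceiling_ms) {
  pick <- stats::runif(n) < fit$w
  out <- numeric(n)
  if (any(pick))
    out[pick] <- rgamma_trunc_upper(sum(pick), fit$comp1["shape"],
                                    fit$comp1["scale"], ceiling_ms)
  if (any(!pick))
    out[!pick] <- rgamma_trunc_upper(sum(!pick), fit$comp2["shape"],
                                     fit$comp2["scale"], ceiling_ms)
  out
}

#' Synthesize a gamma-process spike train matched to a template
#'
#' Rebuilds a template train segment by segment: every regular pattern and
#' pause keeps its ISI count, while the ISI values are fresh gamma draws.
#' With `match = "pooled"` (default) the gamma statistics are estimated once
#' per ISI class from the whole template — regular ISIs by moment matching,
#' pause ISIs by truncated-gamma maximum likelihood above the segmentation's
#' pause floor — so the synthetic ISI distribution is statistically
#' indistinguishable from the template's.  With `match = "segment"` each
#' segment's draws are matched to that segment's own mean ISI, with the shape
#' taken from `order_sampler` (a function `(kind, n_segments)` returning
#' shapes) or the class default.  Pause draws are always truncated below at the
#' pause floor, so a synthesized pause remains a pause.
#'
#' `preserve_classes` controls a trade-off between marginal fidelity and
#' structural preservation.  With the default `FALSE`, regular-pattern draws
#' are unconstrained, which reproduces the template's full ISI distribution
#' (a small fraction of genuine regular-pattern ISIs does exceed the pause
#' floor at low CV2); with `TRUE`, regular draws are also truncated above at
#' the floor, so re-segmenting the synthetic train recovers the template's
#' pause-segment structure at the cost of clipping that tail.
#'
#' @param template_seg an [segment_isis()] result for `template_train`.
#' @param template_train the template [spike_train()].
#' @param order_sampler optional function `(kind, n)` giving per-segment gamma
#'   shapes (only used when `match = "segment"`).
#' @param seed integer seed.
#' @param match `"pooled"` or `"segment"`.
#' @param regular_order,pause_order fall-back shapes for `"segment"` mode.
#' @param preserve_classes keep every synthesized ISI inside its class range
#'   (see Details).
#' @return a [spike_train()] with the same duration, segment count and
#'   per-segment ISI counts as the template.
#' @export
synthesize_train <- function(template_seg, template_train,
                             order_sampler = NULL, seed = 1L,
                             match = c("pooled", "segment"),
                             regular_order = 8, pause_order = 1.5,
                             preserve_classes = FALSE) {
  match <- match.arg(match)
  segs <- template_seg$segments
  if (is.null(segs) || nrow(segs) == 0) stop("empty segmentation")
  x <- isi(template_train)
  floor_ms <- template_seg$pause_floor_ms
  is_pause_seg <- segs$kind == "pause"

  with_seed(seed, {
    if (match == "pooled") {
      reg_isis <- x[!template_seg$is_pause]
      pse_isis <- x[template_seg$is_pause]
      reg_fit <- if (length(reg_isis) >= 16)
        fit_gamma_mix2(reg_isis)
      else NULL
      pse_fit <- if (length(pse_isis) >= 8)
        fit_gamma_trunc(pse_isis, floor_ms)
      else list(order = pause_order,
                mean_isi = if (length(pse_isis)) mean(pse_isis) else floor_ms * 2)
    }
    out <- vector("list", nrow(segs))
    for (i in seq_len(nrow(segs))) {
      k <- segs$end_index[i] - segs$start_index[i] + 1L
      seg_isis <- x[segs$start_index[i]:segs$end_index[i]]
      if (match == "pooled") {
        ceil <- if (preserve_classes) floor_ms else Inf
        out[[i]] <- if (is_pause_seg[i])
          rgamma_trunc(k, pse_fit$order, pse_fit$mean_isi / pse_fit$order,
                       floor_ms)
        else if (!is.null(reg_fit))
          rgamma_mix2_trunc_upper(k, reg_fit, ceil)
        else {
          mu <- mean(x[segs$start_index[i]:segs$end_index[i]])
          rgamma_trunc_upper(k, regular_order, mu / regular_order, ceil)
        }
      } else {
        ord <- if (!is.null(order_sampler))
          order_sampler(segs$kind[i], 1L)
        else if (is_pause_seg[i]) pause_order else regular_order
        mu <- mean(seg_isis)
        out[[i]] <- if (is_pause_seg[i])
          rgamma_trunc(k, ord, mu / ord, floor_ms)
        else rgamma_trunc_upper(k, ord, mu / ord,
                                if (preserve_classes) floor_ms else Inf)
      }
    }
    isis_new <- pmax(unlist(out), 1e-6)
    t0 <- as.numeric(template_train)[1]
    times <- t0 + c(0, cumsum(isis_new))
    dur <- max(train_duration(template_train), times[length(times)])
    spike_train(times, duration = dur,
                unit_id = attr(template_train, "unit_id"))
  })
}

#' Kolmogorov-Smirnov validation of a synthetic train
#'
#' Two-sample KS test on the ISI distributions of a synthetic train against
#' its template.  A pair passes when the distributions are not significantly
#' different at level `alpha` (default 0.01, i.e. a 99% confidence criterion).
#'
#' @param synthetic,template [spike_train()] objects with at least 2 ISIs each.
#' @param alpha significance level.
#' @return list with `statistic`, `p_value`, `pass` (`p_value > alpha`).
#' @export
ks_validate <- function(synthetic, template, alpha = 0.01) {
  a <- isi(synthetic); b <- isi(template)
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 ISIs per train")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       pass = kt$p.value > alpha)
}

#' Generate a population of synthetic PN trains
#'
#' Convenience pipeline: for each unit, generate a template train, segment it,
#' and synthesize a matched gamma-process train.  Seeds are derived from
#' `seed` per unit, so the population is reproducible as a whole.
#'
#' @param n_trains number of units.
#' @param duration_ms train length in ms.
#' @param seed integer master seed.
#' @param synthesize if `FALSE`, return the templates themselves.
#' @param ensure_pause_ms when > 0, redraw any train that lacks an ISI longer
#'   than this (so every unit holds an eligible pause for synchronization).
#' @param ... passed to [generate_template_train()].
#' @inheritParams segment_isis
#' @return list of [spike_train()]s.
#' @export
generate_pn_population <- function(n_trains = 200, duration_ms = 3000,
                                   seed = 1L, cv2_threshold = 0.2,
                                   pause_floor_ms = 20, synthesize = TRUE,
                                   ensure_pause_ms = 0, ...) {
  seeds <- derive_seeds(seed, 2L * n_trains)
  lapply(seq_len(n_trains), function(i) {
    s_tpl <- seeds[2L * i - 1L]
    s_syn <- seeds[2L * i]
    for (try in 1:50) {
      tpl <- generate_template_train(duration_ms = duration_ms,
                                     seed = s_tpl, unit_id = i, ...)
      tr <- tpl
      if (synthesize) {
        seg <- segment_isis(tpl, cv2_threshold, pause_floor_ms)
        tr <- synthesize_train(seg, tpl, seed = s_syn)
      }
      if (ensure_pause_ms <= 0 || any(isi(tr) > ensure_pause_ms)) return(tr)
      s_tpl <- (s_tpl + 104729) %% .Machine$integer.max
      s_syn <- (s_syn + 104729) %% .Machine$integer.max
    }
    stop("could not generate a train with a pause longer than ",
         ensure_pause_ms, " ms")
  })
}

# Deterministic stream of sub-seeds below 2^31 derived from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
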