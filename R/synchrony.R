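#' Specification of an imposed pause-synchrony event
#'
#' Describes how pauses are synchronized across a PN population: the
#' alignment type (`beginning` aligns the spike that opens the pause,
#' `ending` the spike that closes it, `overlapping` makes the pauses strictly
#' contain a common window with no spike alignment, `mixed` splits the
#' participants equally over the three types, `none` leaves the population
#' untouched), the participating fraction of trains, the pause eligibility
#' threshold, optional one-sided jitter of the aligned beginning spikes, and
#' the anchor time of the event on the population timeline.
#'
#' @param sync_type one of `"beginning"`, `"ending"`, `"overlapping"`,
#'   `"mixed"`, `"none"`.
#' @param fraction participating fraction of trains, in `(0, 1]`.
#' @param pause_threshold_ms minimum pause ISI length, ms (20 or 40 in the
#'   study conditions).
#' @param jitter_ms one-sided uniform jitter applied to aligned beginning
#'   spikes, ms (>= 0).
#' @param event_time_ms anchor of the synchronous pause window.
#' @param seed integer seed for participant choice, pause choice and jitter.
#' @return object of class `synchrony_spec`.
#' @export
synchrony_spec <- function(sync_type = c("beginning", "ending", "overlapping",
                                         "mixed", "none"),
                           fraction = 1, pause_threshold_ms = 20,
                           jitter_ms = 0, event_time_ms = 1500, seed = 1L) {
  sync_type <- match.arg(sync_type)
  stopifnot(fraction > 0, fraction <= 1, pause_threshold_ms > 0,
            jitter_ms >= 0)
  structure(list(sync_type = sync_type, fraction = fraction,
                 pause_threshold_ms = pause_threshold_ms,
                 jitter_ms = jitter_ms, event_time_ms = event_time_ms,
                 seed = as.integer(seed)),
            class = "synchrony_spec")
}

#' @export
print.synchrony_spec <- function(x, ...) {
  cat(sprintf("<synchrony_spec> %s, %.0f%% of trains, pause > %g ms, jitter %g ms, anchor %g ms\n",
              x$sync_type, 100 * x$fraction, x$pause_threshold_ms,
              x$jitter_ms, x$event_time_ms))
  invisible(x)
}

#' Randomly select an eligible pause from a train
#'
#' Chooses uniformly among the ISIs longer than `pause_threshold_ms`.
#'
#' @param train a [spike_train()].
#' @param pause_threshold_ms minimum ISI length, ms.
#' @param min_prepause_ms optionally require at least this much spiking
#'   history before the pause-opening spike (used when a pre-pause window
#'   must be carried along).
#' @return list `(start_ms, end_ms, isi_index)` for the chosen pause.  The
#'   caller supplies randomness through the current RNG state.
#' @export
select_pause <- function(train, pause_threshold_ms, min_prepause_ms = 0) {
  x <- isi(train)
  elig <- which(x > pause_threshold_ms)
  if (min_prepause_ms > 0) {
    tt <- as.numeric(train)
    elig <- elig[tt[elig] >= min_prepause_ms]
  }
  if (!length(elig))
    stop("no eligible pause longer than ", pause_threshold_ms, " ms")
  i <- if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
  tt <- as.numeric(train)
  list(start_ms = tt[i], end_ms = tt[i + 1L], isi_index = i)
}

# Rotate a train circularly so that absolute time `from` maps to `to`.
# Preserves every ISI except the one seam interval created at the wrap
# point; spike count is conserved exactly.
rotate_train <- function(train, shift_ms) {
  dur <- train_duration(train)
  tt <- (as.numeric(train) + shift_ms) %% dur
  ord <- order(tt)
  st <- spike_train(tt[ord], duration = dur, unit_id = attr(train, "unit_id"))
  st
}

#' Impose pause synchrony on a PN population
#'
#' Selects `round(fraction * n)` participating trains (round half up), picks
#' an eligible pause in each (uniformly at random), and rotates each
#' participating train circularly so that its pause lands on the event
#' anchor.  Rotation preserves the full ISI structure of the train apart
#' from one seam interval, so the firing statistics before and after the
#' synchronous pause remain those of the original gamma process.
#'
#' Alignment targets per type (window `W = [event, event + threshold]`):
#' `beginning` puts the pause-opening spike at `event_time_ms` (plus jitter
#' drawn from `Uniform[0, jitter_ms]` per train); `ending` puts the
#' pause-closing spike at `event_time_ms + pause_threshold_ms`; `overlapping`
#' places the pause to strictly contain `W`, with the overhang split
#' uniformly at random so no spike is aligned; `mixed` assigns participants
#' to the three types in equal proportion.
#'
#' @param trains list of [spike_train()]s.
#' @param spec a [synchrony_spec()].
#' @return the population with participating trains rotated; attribute
#'   `sync_info` is a data.frame with one row per train (`participating`,
#'   `assigned_type`, `pause_start`, `pause_end`, `jitter`).  The spec itself
#'   is stored as attribute `sync_spec`; re-applying the identical spec is a
#'   no-op, so the transform is idempotent.
#' @export
align_pauses <- function(trains, spec) {
  stopifnot(inherits(spec, "synchrony_spec"))
  if (identical(attr(trains, "sync_spec"), spec)) return(trains)
  n <- length(trains)
  if (spec$sync_type == "none") {
    info <- data.frame(train = seq_len(n), participating = FALSE,
                       assigned_type = "none", pause_start = NA_real_,
                       pause_end = NA_real_, jitter = 0)
    attr(trains, "sync_info") <- info
    attr(trains, "sync_spec") <- spec
    return(trains)
  }
  n_part <- floor(spec$fraction * n + 0.5)  # round half up
  thr <- spec$pause_threshold_ms
  ev <- spec$event_time_ms
  with_seed(spec$seed, {
    part <- sort(sample.int(n, n_part))
    types <- rep("none", n)
    if (spec$sync_type == "mixed") {
      pool <- rep(c("beginning", "ending", "overlapping"),
                  length.out = n_part)
      types[part] <- sample(pool)
    } else types[part] <- spec$sync_type

    info <- data.frame(train = seq_len(n), participating = FALSE,
                       assigned_type = types, pause_start = NA_real_,
                       pause_end = NA_real_, jitter = 0)
    out <- trains
    for (i in part) {
      ty <- types[i]
      # beginning-aligned pauses must stay longer than threshold after the
      # start spike is delayed by up to jitter_ms
      need <- thr + if (ty == "beginning") spec$jitter_ms else 0
      p <- select_pause(trains[[i]], need)
      len <- p$end_ms - p$start_ms
      jit <- if (ty == "beginning" && spec$jitter_ms > 0)
        stats::runif(1, 0, spec$jitter_ms) else 0
      target_start <- switch(ty,
        beginning = ev + jit,
        ending = ev + thr - len,
        overlapping = ev - stats::runif(1) * (len - thr))
      out[[i]] <- rotate_train(trains[[i]], target_start - p$start_ms)
      info$participating[i] <- TRUE
      info$pause_start[i] <- target_start
      info$pause_end[i] <- target_start + len
      info$jitter[i] <- jit
    }
    attr(out, "sync_info") <- info
    attr(out, "sync_spec") <- spec
    out
  })
}

#' Jitter already-aligned pause-beginning spikes
#'
#' Displaces the pause-opening spike of each participating train by an
#' independent draw from `Uniform[0, jitter_ms]` (one-sided, delaying).  The
#' pause measured from the displaced spike must still exceed the threshold.
#'
#' @param trains a beginning-aligned population from [align_pauses()].
#' @param jitter_ms maximum displacement, ms.
#' @param pause_threshold_ms pause eligibility threshold used at alignment.
#' @param seed integer seed.
#' @return the population with displaced beginning spikes; `sync_info`
#'   updated.
#' @export
jitter_beginning_spikes <- function(trains, jitter_ms, pause_threshold_ms,
                                    seed = 1L) {
  info <- attr(trains, "sync_info")
  if (is.null(info)) stop("trains must come from align_pauses()")
  if (jitter_ms == 0) return(trains)
  with_seed(seed, {
    for (i in which(info$participating & info$assigned_type == "beginning")) {
      tt <- as.numeric(trains[[i]])
      k <- which.min(abs(tt - info$pause_start[i]))
      u <- stats::runif(1, 0, jitter_ms)
      if (tt[k] + u >= tt[k + 1L] ||
          (tt[k + 1L] - (tt[k] + u)) <= pause_threshold_ms)
        stop("jitter would cross a neighbour or erase the pause; ",
             "select pauses longer than threshold + jitter")
      tt[k] <- tt[k] + u
      trains[[i]] <- spike_train(tt, duration = train_duration(trains[[i]]),
                                 unit_id = attr(trains[[i]], "unit_id"))
      info$pause_start[i] <- tt[k]
      info$jitter[i] <- u
    }
    attr(trains, "sync_info") <- info
    trains
  })
}

#' Align pauses while forcing the pre-pause firing rate
#'
#' Beginning-type alignment in which each participating train's pause is
#' chosen, where possible, so that the 100 ms (`window_ms`) of spiking
#' preceding the pause-opening spike contains `round(f_pn * window_ms / 1000)`
#' spikes (within +/- 1).  Because alignment rotates the whole train, the
#' pre-pause spiking is carried along with the pause automatically.  When a
#' train has no eligible pause with the desired pre-pause count, an eligible
#' pause is selected at random instead and the miss is recorded.
#'
#' @param trains list of [spike_train()]s.
#' @param spec a [synchrony_spec()] (`beginning` type).
#' @param f_pn forced pre-pause PN rate, Hz.
#' @param window_ms pre-pause window length, ms (default 100).
#' @return as [align_pauses()]; `sync_info` gains `prepause_count` and
#'   `fallback` columns, and the attribute `fallback_rate` gives the fraction
#'   of participants where the fallback was used.
#' @export
force_prepause_rate <- function(trains, spec, f_pn, window_ms = 100) {
  stopifnot(inherits(spec, "synchrony_spec"), f_pn > 0, window_ms > 0)
  n <- length(trains)
  n_part <- floor(spec$fraction * n + 0.5)
  thr <- spec$pause_threshold_ms
  ev <- spec$event_time_ms
  target <- round(f_pn * window_ms / 1000)
  with_seed(spec$seed, {
    part <- sort(sample.int(n, n_part))
    info <- data.frame(train = seq_len(n), participating = FALSE,
                       assigned_type = ifelse(seq_len(n) %in% part,
                                              "beginning", "none"),
                       pause_start = NA_real_, pause_end = NA_real_,
                       jitter = 0, prepause_count = NA_real_,
                       fallback = FALSE)
    out <- trains
    for (i in part) {
      tt <- as.numeric(trains[[i]])
      x <- diff(tt)
      elig <- which(x > thr & tt[-length(tt)] >= window_ms)
      if (!length(elig)) elig <- which(x > thr)
      if (!length(elig)) stop("no eligible pause in train ", i)
      counts <- vapply(elig, function(j)
        sum(tt >= tt[j] - window_ms & tt < tt[j]), numeric(1))
      ok <- elig[abs(counts - target) <= 1]
      fallback <- !length(ok)
      j <- if (fallback) {
        if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
      } else {
        if (length(ok) == 1L) ok else ok[sample.int(length(ok), 1L)]
      }
      out[[i]] <- rotate_train(trains[[i]], ev - tt[j])
      info$participating[i] <- TRUE
      info$pause_start[i] <- ev
      info$pause_end[i] <- ev + x[j]
      info$prepause_count[i] <- counts[match(j, elig)]
      info$fallback[i] <- fallback
    }
    attr(out, "sync_info") <- info
    attr(out, "sync_spec") <- spec
    attr(out, "fallback_rate") <- mean(info$fallback[info$participating])
    out
  })
}

#' One-call population synchronization
#'
#' Applies [align_pauses()] (or [force_prepause_rate()] when `f_pn` is
#' given) according to `spec`; jitter specified in the spec is drawn inside
#' the alignment itself.
#'
#' @inheritParams align_pauses
#' @param f_pn optional forced pre-pause rate, Hz.
#' @return synchronized population with `sync_info` attribute.
#' @export
synchronize_population <- function(trains, spec, f_pn = NULL) {
  if (is.null(f_pn)) align_pauses(trains, spec)
  else force_prepause_rate(trains, spec, f_pn)
}
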