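#' Spike train objects
#'
#' A `spike_train` holds the ordered spike times of a single unit, in
#' milliseconds, together with the total duration of the recording or
#' simulation it came from.  All generators and transforms in pausecode
#' exchange populations of Purkinje-neuron (PN) activity as plain lists of
#' `spike_train` objects.
#'
#' @param times numeric vector of spike times in ms, strictly increasing,
#'   all within `[0, duration]`.
#' @param duration total length of the train in ms.
#' @param unit_id identifier of the unit (integer or character).
#' @return An object of class `spike_train`: a numeric vector of times with
#'   `duration` and `unit_id` attributes.
#' @examples
#' st <- spike_train(c(10, 30, 55), duration = 100)
#' isi(st)
#' @export
spike_train <- function(times, duration, unit_id = 1L) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA")
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration))
    stop("spike times must lie in [0, duration]")
  structure(times, duration = as.numeric(duration), unit_id = unit_id,
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  n <- length(x)
  dur <- attr(x, "duration")
  cat(sprintf("<spike_train> unit %s: %d spikes over %.6g ms (%.6g Hz)\n",
              format(attr(x, "unit_id")), n, dur, 1000 * n / dur))
  invisible(x)
}

#' Inter-spike intervals of a train
#'
#' @param train a [spike_train()].
#' @return numeric vector of ISIs in ms, length `length(train) - 1`.
#' @export
isi <- function(train) diff(as.numeric(train))

#' @rdname spike_train
#' @param x object to test.
#' @export
is_spike_train <- function(x) inherits(x, "spike_train")

train_duration <- function(train) attr(train, "duration")

#' Read and write spike-train populations as CSV
#'
#' Populations are stored as plain CSV with header `unit_id,time_ms`, one spike
#' per row, sorted by unit then time.
#'
#' @param trains list of [spike_train()] objects.
#' @param path file path.
#' @param duration duration in ms to attach to each train on reading; when
#'   `NULL`, the ceiling of the last spike time across units is used.
#' @return `read_spike_trains()` returns a list of `spike_train`s;
#'   `write_spike_trains()` returns `path` invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = attr(tr, "unit_id"), time_ms = as.numeric(tr))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, duration = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("unit_id", "time_ms") %in% names(df)))
  if (is.null(duration)) duration <- ceiling(max(df$time_ms))
  lapply(split(df$time_ms, df$unit_id), function(tt)
    spike_train(sort(tt), duration = duration,
                unit_id = df$unit_id[match(tt[1], df$time_ms)]))
}

# Evaluate a thunk under a temporary RNG state derived from `seed`, restoring
# the caller's .Random.seed afterwards.  All seeded operations in the package
# go through this so global RNG state is never disturbed.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}
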