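test_that("select_pause picks uniformly among eligible pauses", {
  # unique candidate
  tt <- c(seq(0, 100, by = 10), 145, seq(150, 250, by = 10))
  st <- spike_train(tt, duration = 250)
  p <- select_pause(st, 40)
  expect_equal(c(p$start_ms, p$end_ms), c(100, 145))

  # no eligible pause
  expect_error(select_pause(st, 50), "no eligible pause")

  # uniformity over 4 candidates
  tt4 <- cumsum(c(0, rep(c(rep(10, 5), 60), 4)))
  st4 <- spike_train(tt4, duration = max(tt4))
  draws <- pausecode:::with_seed(99, replicate(1e4, select_pause(st4, 40)$isi_index))
  freq <- as.numeric(table(draws)) / 1e4
  expect_length(freq, 4)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("beginning alignment synchronizes pause-start spikes exactly", {
  pop <- generate_pn_population(n_trains = 50, duration_ms = 3000, seed = 71)
  spec <- synchrony_spec("beginning", fraction = 1, pause_threshold_ms = 20,
                         event_time_ms = 1500, seed = 72)
  out <- align_pauses(pop, spec)
  info <- attr(out, "sync_info")
  expect_true(all(info$participating))
  # the spike at the pause start sits exactly on the anchor in every train
  starts <- vapply(out, function(tr) {
    tt <- as.numeric(tr)
    tt[which.min(abs(tt - 1500))]
  }, numeric(1))
  expect_equal(var(starts), 0)
  expect_equal(unique(starts), 1500)
  # pause extends at least the threshold beyond the anchor
  gap <- vapply(out, function(tr) {
    tt <- as.numeric(tr)
    min(tt[tt > 1500]) - 1500
  }, numeric(1))
  expect_true(all(gap > 20))
  # spike count conservation
  expect_equal(lengths(lapply(out, as.numeric)),
               lengths(lapply(pop, as.numeric)))
})

test_that("alignment preserves ISI structure apart from the seam", {
  pop <- generate_pn_population(n_trains = 10, duration_ms = 3000, seed = 73)
  spec <- synchrony_spec("beginning", fraction = 1, pause_threshold_ms = 20,
                         event_time_ms = 1500, seed = 74)
  out <- align_pauses(pop, spec)
  for (i in seq_along(pop)) {
    a <- sort(isi(pop[[i]]))
    b <- sort(isi(out[[i]]))
    # rotation changes at most two interval values (split + join at the seam)
    expect_lte(sum(!(round(b, 9) %in% round(a, 9))), 2)
  }
})

test_that("overlapping alignment strictly contains the common window with no aligned spikes", {
  pop <- generate_pn_population(n_trains = 60, duration_ms = 3000, seed = 75)
  spec <- synchrony_spec("overlapping", fraction = 1, pause_threshold_ms = 20,
                         event_time_ms = 1500, seed = 76)
  out <- align_pauses(pop, spec)
  win <- c(1500, 1520)
  for (tr in out) {
    tt <- as.numeric(tr)
    expect_false(any(tt >= win[1] & tt <= win[2]))
    expect_lt(max(tt[tt < win[1]]), win[1])  # pause started before window
    expect_gt(min(tt[tt > win[2]]), win[2])  # and ends after it
  }
  # onsets are staggered, not aligned
  info <- attr(out, "sync_info")
  expect_gt(var(info$pause_start), 0)
})

test_that("ending alignment puts the pause-closing spike on the window end", {
  pop <- generate_pn_population(n_trains = 30, duration_ms = 3000, seed = 77)
  spec <- synchrony_spec("ending", fraction = 1, pause_threshold_ms = 40,
                         event_time_ms = 1500, seed = 78)
  out <- align_pauses(pop, spec)
  ends <- vapply(out, function(tr) {
    tt <- as.numeric(tr)
    min(tt[tt >= 1540 - 1e-6])
  }, numeric(1))
  expect_equal(ends, rep(1540, length(ends)), tolerance = 1e-9)
})

test_that("partial participation leaves the rest untouched and is idempotent", {
  pop <- generate_pn_population(n_trains = 40, duration_ms = 3000, seed = 79)
  spec <- synchrony_spec("beginning", fraction = 0.5, pause_threshold_ms = 20,
                         event_time_ms = 1500, seed = 80)
  out <- align_pauses(pop, spec)
  info <- attr(out, "sync_info")
  expect_equal(sum(info$participating), 20L)  # round-half-up of 0.5 * 40
  for (i in which(!info$participating))
    expect_identical(as.numeric(out[[i]]), as.numeric(pop[[i]]))

  # idempotence: second application with the same spec is a no-op
  out2 <- align_pauses(out, spec)
  expect_identical(out2, out)

  # mixed type splits participants over the three mechanisms
  specm <- synchrony_spec("mixed", fraction = 1, pause_threshold_ms = 20,
                          event_time_ms = 1500, seed = 81)
  outm <- align_pauses(pop, specm)
  tab <- table(attr(outm, "sync_info")$assigned_type)
  expect_true(all(c("beginning", "ending", "overlapping") %in% names(tab)))
  expect_lte(diff(range(tab[c("beginning", "ending", "overlapping")])), 1)
})

test_that("jitter delays beginning spikes uniformly without crossing neighbours", {
  pop <- generate_pn_population(n_trains = 100, duration_ms = 3000, seed = 82)
  spec <- synchrony_spec("beginning", fraction = 1, pause_threshold_ms = 20,
                         jitter_ms = 7, event_time_ms = 1500, seed = 83)
  out <- align_pauses(pop, spec)
  info <- attr(out, "sync_info")
  jit <- info$jitter[info$participating]
  expect_true(all(jit >= 0 & jit <= 7))
  expect_lte(max(info$pause_start) - min(info$pause_start), 7)
  # pause measured from the jittered spike still exceeds the threshold
  expect_true(all(info$pause_end - info$pause_start > 20))

  # one-sided uniform jitter: mean displacement ~ J/2
  spec4 <- synchrony_spec("beginning", fraction = 1, pause_threshold_ms = 20,
                          jitter_ms = 4, event_time_ms = 1500, seed = 84)
  jits <- unlist(lapply(1:20, function(k) {
    s <- spec4; s$seed <- 84L + k
    attr(align_pauses(pop, s), "sync_info")$jitter
  }))
  expect_equal(mean(jits), 2, tolerance = 0.1)

  # explicit jitter operator: identity at 0, error when displacement crosses
  out0 <- align_pauses(pop, synchrony_spec("beginning", 1, 20,
                                           event_time_ms = 1500, seed = 85))
  expect_identical(jitter_beginning_spikes(out0, 0, 20), out0)
  expect_error(jitter_beginning_spikes(out0, 1e4, 20, seed = 1), "jitter")
})

test_that("forced pre-pause rate yields the requested spike count or logs a fallback", {
  pop <- generate_pn_population(n_trains = 60, duration_ms = 4000, seed = 86)
  spec <- synchrony_spec("beginning", fraction = 1, pause_threshold_ms = 20,
                         event_time_ms = 2000, seed = 87)
  out <- force_prepause_rate(pop, spec, f_pn = 50, window_ms = 100)
  info <- attr(out, "sync_info")
  ok <- info$participating & !info$fallback
  expect_gt(sum(ok), 0)
  expect_true(all(abs(info$prepause_count[ok] - 5) <= 1))
  # realized counts: window before the anchor holds the aligned spiking
  counts <- vapply(which(ok), function(i) {
    tt <- as.numeric(out[[i]])
    sum(tt >= 1900 & tt < 2000)
  }, numeric(1))
  expect_true(all(abs(counts - 5) <= 1))

  # unattainable rate falls back and says so
  out2 <- force_prepause_rate(pop, spec, f_pn = 300, window_ms = 100)
  expect_gt(attr(out2, "fallback_rate"), 0)
})

test_that("eligible pause count is monotone in the threshold", {
  pop <- generate_pn_population(n_trains = 30, duration_ms = 3000, seed = 88)
  n_elig <- function(thr) vapply(pop, function(tr) sum(isi(tr) > thr),
                                 numeric(1))
  e20 <- n_elig(20); e40 <- n_elig(40); e60 <- n_elig(60)
  expect_true(all(e40 <= e20))
  expect_true(all(e60 <= e40))
})

test_that("ending and overlapping alignments give matching PSTHs in the pause interior", {
  pop <- generate_pn_population(n_trains = 100, duration_ms = 3000, seed = 89)
  mk <- function(ty) align_pauses(pop, synchrony_spec(ty, fraction = 0.5,
                                                      pause_threshold_ms = 40,
                                                      event_time_ms = 1500,
                                                      seed = 90))
  h_end <- psth(mk("ending"))
  h_ovl <- psth(mk("overlapping"))
  interior <- h_end$time >= 1505 & h_end$time < 1535
  ks <- suppressWarnings(ks.test(h_end$density[interior],
                                 h_ovl$density[interior]))
  expect_gt(ks$p.value, 0.01)
})
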