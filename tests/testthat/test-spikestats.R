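fake_pair <- function(synced, control, duration = 3000) {
  list(synced = list(spikes = synced, duration_ms = duration),
       control = list(spikes = control, duration_ms = duration))
}

test_that("rate increase is windowed count arithmetic and antisymmetric", {
  p <- fake_pair(c(1505, 1510, 1530), c(1520))
  expect_equal(rate_increase(p, c(1500, 1540)), 1000 * 2 / 40)  # +50 Hz
  expect_equal(rate_increase(fake_pair(1:10 * 10, 1:10 * 10), c(0, 200)), 0)
  swapped <- fake_pair(p$control$spikes, p$synced$spikes)
  expect_equal(rate_increase(swapped, c(1500, 1540)),
               -rate_increase(p, c(1500, 1540)))
  expect_error(rate_increase(p, c(1500, 1500)), "positive length")
  expect_error(rate_increase(p, c(2900, 3100)), "outside")
})

test_that("reliability counts trials with positive increases", {
  up <- fake_pair(c(1505, 1510), numeric(0))
  down <- fake_pair(numeric(0), c(1505, 1510))
  expect_equal(reliability(rep(list(up), 4), c(1500, 1540)), 100)
  expect_equal(reliability(rep(list(down), 4), c(1500, 1540)), 0)
  expect_equal(reliability(c(rep(list(up), 63), rep(list(down), 37)),
                           c(1500, 1540)), 63)
  expect_error(reliability(list(), c(0, 1)), "at least one")
})

test_that("first-spike latency censors trials without in-pause spikes", {
  pairs <- list(fake_pair(c(1503.5, 1540), numeric(0)),
                fake_pair(c(1519.9), numeric(0)),
                fake_pair(c(1495, 1541), numeric(0)))
  lat <- first_spike_latency(pairs, 1500, 20)
  expect_equal(lat$latencies, c(3.5, 19.9))
  expect_equal(lat$n_censored, 1L)
  expect_equal(lat$n_trials, 3L)
})

test_that("latency variability gates SD vs MAD through Lilliefors", {
  const <- rep(5, 20) + rnorm_fixture(20, 0, 1e-9)
  lv <- latency_variability(const)
  expect_lt(lv$value, 1e-6)

  normals <- rnorm_fixture(100, 10, 1.5)
  expect_equal(latency_variability(normals)$estimator, "SD")
  expect_equal(latency_variability(normals)$value, sd(normals))

  heavy <- c(rnorm_fixture(80, 10, 0.5), rnorm_fixture(20, 25, 8))
  lv2 <- latency_variability(heavy)
  expect_equal(lv2$estimator, "MAD")
  expect_equal(lv2$value, mad(heavy))

  # a comparison partner that fails normality forces MAD for both
  expect_equal(latency_variability(normals, other = heavy)$estimator, "MAD")
  expect_error(latency_variability(1:5), "at least 8")
})

test_that("vector strength equals the brute-force phasor resultant", {
  expect_equal(vector_strength(rep(7.3, 10), pause_ms = 20)$R, 1)
  expect_equal(vector_strength(c(5, 15), pause_ms = 20)$R, 0,
               tolerance = 1e-12)
  set.seed(31)
  for (k in 1:25) {
    n <- sample(5:200, 1)
    lat <- runif(n, 0, 20)
    vs <- vector_strength(lat, pause_ms = 20)
    th <- 2 * pi * lat / 20
    brute <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
    expect_equal(vs$R, brute, tolerance = 1e-12)
    expect_equal(vs$Z, n * vs$R^2, tolerance = 1e-12)
  }
  expect_error(vector_strength(c(1, 25), pause_ms = 20), "pause_ms")
  expect_error(vector_strength(numeric(0), pause_ms = 20), "latencies")
})

test_that("Rayleigh calibration is self-consistent across n and alpha", {
  for (n in c(20, 50, 100, 400)) for (alpha in c(0.05, 0.01)) {
    th <- rayleigh_threshold(n, alpha)
    expect_equal(th$z_crit, n * th$threshold_R^2, tolerance = 1e-4)
    expect_equal(rayleigh_p(th$threshold_R, n), alpha, tolerance = 1e-9)
  }
})

test_that("PSTH is normalized for any bin size", {
  pop <- generate_pn_population(n_trains = 5, duration_ms = 2000, seed = 91)
  for (b in c(1, 2, 5)) expect_equal(sum(psth(pop, b)$density), 1)
  one <- spike_train(rep(10.2, 3) + c(0, 1e-6, 2e-6), duration = 100)
  h <- psth(one, 1)
  expect_equal(max(h$density), 1)
  # homogeneous spiking: law of large numbers flattens the histogram
  set.seed(606)
  tt <- cumsum(rexp(2e5, rate = 210))
  u <- spike_train(tt[tt < 950], duration = 1000)
  h2 <- psth(u, 5)
  core <- h2$density[h2$time < 940]
  expect_lt(max(core) / min(core), 1.5)
})

test_that("Pearson correlation matches the covariance formula and cor()", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(pearson_r(a, b), cor(a, b), tolerance = 1e-12)
  expect_error(pearson_r(a, rep(1, 50)), "variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("condition comparisons detect shifts and keep their size", {
  set.seed(5)
  a <- rnorm(100, 3, 1)
  expect_false(compare_conditions(a, a)$significant)
  b <- rnorm(100, 0, 1)
  expect_true(compare_conditions(a, b)$significant)
  expect_true(compare_conditions(a, b, test = "one_tailed_t")$significant)

  # type-I error calibration on null data
  rej_t <- mean(replicate(1000, {
    x <- rnorm(30); y <- rnorm(30)
    compare_conditions(x, y, test = "one_tailed_t")$significant
  }))
  expect_lte(rej_t, 0.07)
  rej_b <- mean(vapply(1:300, function(i) {
    x <- rnorm(30); y <- rnorm(30)
    compare_conditions(x, y, n_boot = 1000, seed = i)$significant
  }, logical(1)))
  expect_lte(rej_b, 0.09)
})

test_that("rebound analysis recovers an injected linear dependence", {
  set.seed(12)
  f_pn <- runif(30, 30, 110)
  inc <- 0.1 * f_pn + rnorm(30, 0, 0.5)
  tr_t <- seq(1300, 1600, by = 0.5)
  pairs <- lapply(seq_along(f_pn), function(i) {
    n_syn <- round(40 + inc[i])
    p <- fake_pair(seq(1500.5, 2500, length.out = n_syn), seq(1500.5, 2500, length.out = 40))
    p$synced$trace <- data.frame(t = tr_t, h_calva = 0.1 + 1e-3 * f_pn[i],
                                 h_nap = 0.2 + 1e-3 * f_pn[i])
    p
  })
  ra <- rebound_analysis(pairs, f_pn, onset_ms = 1500)
  oracle <- cov(f_pn, ra$per_trial$rate_increase_hz) /
    (sd(f_pn) * sd(ra$per_trial$rate_increase_hz))
  expect_equal(ra$pearson_r, oracle, tolerance = 1e-12)
  expect_gt(ra$pearson_r, 0.9)
  expect_true(all(diff(ra$per_trial$mean_h_calva[order(f_pn)]) >= 0))

  # degenerate input surfaces the undefined correlation
  same <- pairs[c(1, 1, 1)]
  expect_error(rebound_analysis(same, rep(50, 3), onset_ms = 1500),
               "variance")
  no_trace <- list(fake_pair(1:3 * 500, 1:3 * 500))
  expect_error(rebound_analysis(no_trace, 50, onset_ms = 1500), "trace")
})

test_that("pauses outnumber complex spikes 25-fold under the stated rates", {
  expect_equal(pause_cs_ratio(50, 0.5, 1), 25)
  expect_equal(pause_cs_ratio(80, 0.25, 2), 10)
})
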