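test_that("Poisson trains have the configured mass and are reproducible", {
  tr <- poisson_trains(1000, 0.65, 4000, seed = 10)
  expect_s3_class(tr, "ca1_trains")
  mu <- 1000 * 0.65 * 4
  expect_lt(abs(nrow(tr$spikes) - mu), 3 * sqrt(mu))
  expect_identical(poisson_trains(1000, 0.65, 4000, seed = 10)$spikes,
                   tr$spikes)
  expect_equal(nrow(poisson_trains(50, 0, 1000)$spikes), 0)
  expect_error(poisson_trains(10, -1, 100), "rate")
  # times strictly inside [0, duration), sorted per unit
  expect_true(all(tr$spikes$time_ms >= 0 & tr$spikes$time_ms < 4000))
  expect_true(all(tapply(tr$spikes$time_ms, tr$spikes$unit,
                         function(x) all(diff(x) > 0))))
})

test_that("Poisson interspike intervals pass a KS test against exponential", {
  tr <- poisson_trains(20, 100, 10000, seed = 3)
  isi <- unlist(tapply(tr$spikes$time_ms, tr$spikes$unit, diff),
                use.names = FALSE)
  expect_gt(length(isi), 1e4)
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 0.1))  # /ms
  expect_gt(ks$p.value, 0.01)
})

test_that("afferent arithmetic reproduces the published worked examples", {
  expect_equal(spikes_per_theta_cycle(454700, 0.65, 7.8), 37892)
  expect_equal(afferent_drive_estimate(204700, 0.04, 4), 32752)
  expect_equal(afferent_drive_estimate(250000, 0.02, 1), 5000)
  expect_equal(spikes_per_theta_cycle(0, 0.65, 7.8), 0)
  expect_equal(spikes_per_theta_cycle(100, 1, 10), 10)
  expect_equal(afferent_drive_estimate(1000, 0, 4), 0)
  expect_error(spikes_per_theta_cycle(100, 1, 0), "theta")
  expect_error(afferent_drive_estimate(100, 1.5, 1), "fraction")
})

test_that("unmodulated phase-locked trains reduce to homogeneous Poisson", {
  tr <- phase_locked_trains(500, 10, 7.8, kappa = 0,
                            preferred_phase_deg = 0, duration_ms = 4000,
                            seed = 4)
  mu <- 500 * 10 * 4
  expect_lt(abs(nrow(tr$spikes) - mu), 3 * sqrt(mu))
})

test_that("phase-locked trains carry the von Mises modulation", {
  theta_hz <- 7.8
  tr <- phase_locked_trains(300, 12, theta_hz, kappa = 2,
                            preferred_phase_deg = 90,
                            duration_ms = 30000, seed = 8)
  expect_gt(nrow(tr$spikes), 1e4)
  # phase of the ideal oscillator (trough = 0)
  ph <- (360 * theta_hz * tr$spikes$time_ms / 1000) %% 360
  st <- phase_stats(ph)
  r_expect <- besselI(2, 1) / besselI(2, 0)   # ~0.698
  expect_equal(st$r, r_expect, tolerance = 0.02)
  expect_lt(abs(st$mean_deg - 90), 5)
  expect_lt(st$p, 1e-6)
  # time-averaged rate is preserved
  expect_equal(nrow(tr$spikes) / 300 / 30, 12, tolerance = 0.05)
})
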