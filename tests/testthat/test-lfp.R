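test_that("spike density function conserves spike mass", {
  s0 <- sdf(numeric(0), 1000)
  expect_true(all(s0$rate == 0))
  s1 <- sdf(500, 1000)
  expect_equal(sum(s1$rate) / 1000, 1, tolerance = 1e-6)
  # edge spikes keep unit mass too
  s2 <- sdf(c(1, 998.2), 1000)
  expect_equal(sum(s2$rate) / 1000, 2, tolerance = 1e-6)
  # arbitrary raster
  set.seed(1)
  sp <- runif(257, 0, 2000)
  s3 <- sdf(sp, 2000)
  expect_equal(sum(s3$rate) / 1000, 257, tolerance = 1e-6)
})

test_that("SDF of a homogeneous Poisson train estimates its rate", {
  set.seed(2)
  sp <- cumsum(rexp(2000, rate = 50 / 1000))
  sp <- sp[sp < 10000]
  s <- sdf(sp, 10000)
  se <- sqrt(50 / 10)   # SE of the mean rate over 10 s
  expect_lt(abs(mean(s$rate) - 50), 3 * se)
})

test_that("Welch periodogram finds pure and mixed tones", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  x <- sin(2 * pi * 7.8 * t)
  p <- welch_psd(x, fs)
  expect_equal(p$peaks$freq[p$peaks$band == "theta"], 7.8,
               tolerance = 0.08)
  y <- sin(2 * pi * 7.8 * t) + 0.7 * sin(2 * pi * 71 * t)
  p2 <- welch_psd(y, fs)
  expect_equal(p2$peaks$freq[p2$peaks$band == "theta"], 7.8,
               tolerance = 0.08)
  expect_equal(p2$peaks$freq[p2$peaks$band == "gamma"], 71,
               tolerance = 0.02)
  expect_error(welch_psd(y[1:100], fs), "shorter")
})

test_that("Welch periodogram satisfies Parseval for white noise", {
  set.seed(3)
  x <- rnorm(8192)
  p <- welch_psd(x, 1000)
  total <- sum(p$power) * (p$freq[2] - p$freq[1])
  expect_equal(total, var(x), tolerance = 0.05)
})

test_that("spectrogram tracks stationary tones and chirps", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  sg <- spectrogram(sin(2 * pi * 7.8 * t), fs, 1024, 256)
  ridge <- sg$freq[apply(sg$power, 1, which.max)]
  expect_true(all(abs(ridge - 7.8) < 1))
  sg0 <- spectrogram(rep(0, 4000), fs, 1024, 256)
  expect_true(all(sg0$power == 0))
  # chirp 5 -> 10 Hz: instantaneous ridge increases monotonically
  f_inst <- 5 + 5 * t / 4
  chirp <- sin(2 * pi * cumsum(f_inst) / fs)
  sgc <- spectrogram(chirp, fs, 1024, 256)
  ridge_c <- sgc$freq[apply(sgc$power, 1, which.max)]
  expect_true(all(diff(ridge_c) >= 0))
  expect_error(spectrogram(rep(0, 100), fs, 1024, 256), "window")
})

test_that("band-pass filtering is zero-phase and selective", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  x <- sin(2 * pi * 7.8 * t)
  y <- bandpass(x, fs, 5, 10)
  mid <- 1000:3000
  expect_gt(max(y[mid]) / max(x[mid]), 0.95)
  # no peak-time shift (zero phase): compare within a single cycle
  cyc <- 2000:2128
  expect_lt(abs(which.max(y[cyc]) - which.max(x[cyc])), 2)
  # out-of-band attenuation
  z <- bandpass(sin(2 * pi * 40 * t), fs, 5, 10)
  expect_lt(max(abs(z[mid])), 0.1)
  # DC removed
  d <- bandpass(rep(2, 4000), fs, 5, 10)
  expect_lt(max(abs(d[mid])), 0.01)
  expect_error(bandpass(x, fs, 10, 5), "invalid band")
})

test_that("spike phases follow the trough-is-zero convention exactly", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)    # sample 1 at t = 0
  f <- 7.8
  lfp <- -cos(2 * pi * f * t)       # troughs at t = k/f
  troughs_ms <- (1:25) / f * 1000
  # trough location is quantized to the sample grid: +-0.5 ms ~ +-1.5 deg
  ph0 <- spike_phases(troughs_ms[troughs_ms > 100 & troughs_ms < 3500],
                      lfp, fs)
  expect_true(all(pmin(ph0, 360 - ph0) < 2.5))
  peaks_ms <- troughs_ms + 1000 / f / 2
  ph180 <- spike_phases(peaks_ms[peaks_ms > 100 & peaks_ms < 3500], lfp, fs)
  expect_true(all(abs(ph180 - 180) < 2.5))
  # midpoint of the rising quarter-cycle after a trough -> 90 degrees
  quarter_ms <- troughs_ms + 1000 / f / 4
  ph90 <- spike_phases(quarter_ms[quarter_ms > 100 & quarter_ms < 3500],
                       lfp, fs)
  expect_true(all(abs(ph90 - 90) < 2.5))
  # spikes in the first 50 ms are cropped
  expect_length(spike_phases(c(10, 40), lfp, fs), 0)
  expect_error(spike_phases(500, rep(0, 10), fs), "troughs")
})

test_that("circular statistics behave at the analytic anchors", {
  st1 <- phase_stats(rep(123, 50))
  expect_equal(st1$r, 1)
  expect_equal(st1$mean_deg, 123)
  expect_lt(st1$p, 1e-6)
  st2 <- phase_stats(seq(0, 359, by = 1))
  expect_lt(st2$r, 1e-6)
  expect_gt(st2$p, 0.9)
  expect_error(phase_stats(numeric(0)), "no phases")
})

test_that("resultant length of a von Mises sample matches the Bessel ratio", {
  set.seed(7)
  n <- 1e5
  # von Mises sampling via rejection from a wrapped Cauchy envelope is not
  # needed at kappa = 2: numeric inversion of the CDF on a fine grid
  grid <- seq(-pi, pi, length.out = 65536)
  dens <- exp(2 * cos(grid))
  cdf <- cumsum(dens) / sum(dens)
  th <- grid[findInterval(runif(n), cdf) + 1]
  st <- phase_stats((th * 180 / pi) %% 360)
  expect_equal(st$r, besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
})

test_that("firing rates are reported per cell and per active cell", {
  # 10 cells, 5 active, 100 spikes in 1 s (after crop)
  ids <- rep(1:5, each = 20)
  times <- seq(51, 1049.9, length.out = 100)
  fr <- firing_rates(ids, times, n_total = 10, duration = 1050, crop = 50)
  expect_equal(fr$rate_all, 10)
  expect_equal(fr$rate_active, 20)
  fr0 <- firing_rates(integer(0), numeric(0), 10, 1000)
  expect_equal(fr0$rate_all, 0)
  expect_true(is.na(fr0$rate_active))
  # crop removes early spikes
  fr2 <- firing_rates(c(1, 1), c(10, 500), 1, duration = 1050, crop = 50)
  expect_equal(fr2$rate_all, 1)
})

test_that("LFP analog follows the inverse-distance law", {
  pos <- data.frame(x = c(110, 220), y = c(0, 0), z = c(0, 0))
  cur <- cbind(rep(1, 100), rep(1, 100))
  one <- lfp_analog(cur[, 1, drop = FALSE], pos[1, ], c(0, 0, 0),
                    inner_radius = 1000)
  two <- lfp_analog(cur[, 2, drop = FALSE], pos[2, ], c(0, 0, 0),
                    inner_radius = 1000)
  expect_equal(one$samples / two$samples, rep(2, 100))
  none <- lfp_analog(matrix(0, 100, 0), pos[0, ], c(0, 0, 0))
  expect_true(all(none$samples == 0))
})

test_that("outer-cell subsampling is an unbiased estimator", {
  set.seed(9)
  n <- 1000
  pos <- data.frame(x = runif(n, 0, 2000), y = runif(n, 0, 2000),
                    z = runif(n, 0, 100))
  cur <- matrix(rnorm(20 * n, mean = 5), 20, n)
  electrode <- c(1000, 1000, 50)
  d <- sqrt((pos$x - 1000)^2 + (pos$y - 1000)^2 + (pos$z - 50)^2)
  w_full <- 1 / pmax(d, 10)
  full_sum <- as.numeric(cur %*% w_full)    # exhaustive reference
  est <- sapply(1:100, function(s)
    lfp_analog(cur, pos, electrode, seed = s)$samples)
  avg <- rowMeans(est)
  se <- apply(est, 1, sd) / sqrt(100)
  expect_true(all(abs(avg - full_sum) <= 2 * se + 1e-9))
})

test_that("cross-frequency coupling locates gamma bursts at the theta trough", {
  fs <- 1000
  t <- seq(0, 8, by = 1 / fs)[-1]
  f_th <- 7.8
  theta <- -cos(2 * pi * f_th * t)           # LFP; trough = minimum
  burst <- (1 - theta) / 2                    # maximal at the trough
  x <- theta + 0.5 * burst * sin(2 * pi * 40 * t)
  cfc <- cross_frequency_coupling(x, fs)
  expect_true(min(cfc$peak_phase_deg, 360 - cfc$peak_phase_deg) <= 30)
  # constant-amplitude gamma: flat profile
  x2 <- theta + 0.5 * sin(2 * pi * 40 * t)
  cfc2 <- cross_frequency_coupling(x2, fs)
  expect_lt(max(cfc2$envelope) / min(cfc2$envelope), 1.05)
  # no gamma: envelope near zero
  cfc3 <- cross_frequency_coupling(theta, fs)
  expect_lt(max(cfc3$envelope), 0.02)
})
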