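test_that("double-exponential peak time matches a numeric maximization", {
  syn <- syn_params(1, 10, 1, -60)
  tp <- syn_peak_time(syn)
  expect_equal(tp, 10 / 9 * log(10), tolerance = 1e-10)   # ~2.5584 ms
  tt <- seq(0, 30, by = 1e-4)
  expect_equal(tt[which.max(conductance_waveform(syn, tt))], tp,
               tolerance = 1e-3)
  # peak normalization: max conductance equals gmax
  expect_equal(max(conductance_waveform(syn, tt)), 1, tolerance = 1e-8)
})

test_that("waveform starts at zero and rejects invalid kinetics", {
  expect_equal(conductance_waveform(syn_params(0.5, 3, 2, 0), 0), 0)
  expect_error(syn_params(5, 5, 1, 0), "tau1 < tau2")
  expect_error(syn_params(8, 3, 1, 0), "tau1 < tau2")
})

test_that("near-equal time constants approach the alpha-function limit", {
  tau <- 5
  syn <- syn_params(tau * (1 - 1e-4), tau, 1, 0)
  expect_equal(syn_peak_time(syn), tau, tolerance = 1e-3)
})

test_that("closed-form charge equals numeric quadrature", {
  syn <- syn_params(1, 10, 1, -60)
  dt <- 0.005
  tt <- seq(0, 5000, by = dt)
  q_num <- sum(conductance_waveform(syn, tt)) * dt * 10 / 1000
  expect_equal(synaptic_charge(syn, 10), q_num, tolerance = 1e-3)
  # linearity in gmax
  syn2 <- syn_params(1, 10, 2, -60)
  expect_equal(synaptic_charge(syn2, 10), 2 * synaptic_charge(syn, 10))
  expect_equal(synaptic_charge(syn_params(1, 10, 0, -60), 10), 0)
  # finite horizon converges to the closed form
  expect_equal(synaptic_charge(syn, 10, horizon = 500),
               synaptic_charge(syn, 10), tolerance = 1e-6)
})

test_that("charge matching with identical kinetics reduces to a ratio", {
  a <- syn_params(1, 10, 2, -60)
  b <- syn_params(1, 10, 5, -60)
  expect_equal(charge_match_scale(a, b, reference_mv = -50), 2.5)
  expect_error(charge_match_scale(syn_params(1, 10, 0, -60), b),
               "zero charge")
})

test_that("packaged neurogliaform charge-match factor is in the low hundreds", {
  cfg <- full_cfg()
  syn <- ngf_synapse(cfg)
  k <- charge_match_scale(syn$gabaa, syn$gabab, cfg$gabab$reference_mv)
  expect_gt(k, 100)
  expect_lt(k, 400)
  # after scaling, total charges agree within 1% by independent quadrature
  dt <- 0.01
  tt <- seq(0, 20000, by = dt)
  ref <- cfg$gabab$reference_mv
  qa <- sum(conductance_waveform(syn$gabaa, tt)) * dt *
    abs(ref - syn$gabaa$erev) / 1000
  qb <- sum(conductance_waveform(syn$gabab, tt)) * dt *
    abs(ref - syn$gabab$erev) / 1000
  expect_equal(k * qa, qb, tolerance = 0.01)
})

test_that("toy charge-match factor verified against a quadrature oracle", {
  a <- syn_params(0.7, 9, 1.5, -60)
  b <- syn_params(30, 150, 0.8, -90)
  k <- charge_match_scale(a, b, reference_mv = -55)
  dt <- 0.01
  tt <- seq(0, 10000, by = dt)
  k_num <- (sum(conductance_waveform(b, tt)) * 35) /
           (sum(conductance_waveform(a, tt)) * 5)
  expect_equal(k, k_num, tolerance = 0.005)
})

test_that("ideal-clamp PSC amplitude is conductance times driving force", {
  pr <- paired_recording(syn = syn_params(0.3, 8, 1, -60), hold = -50,
                         trials = 3)
  expect_equal(pr$amplitude_pa, 10, tolerance = 1e-3)   # outward
  pr0 <- paired_recording(syn = syn_params(0.3, 8, 0, -60), hold = -50,
                          trials = 2)
  expect_equal(pr0$amplitude_pa, 0)
  # linear in driving force
  pr2 <- paired_recording(syn = syn_params(0.3, 8, 1, -60), hold = -40,
                          trials = 1)
  expect_equal(pr2$amplitude_pa / pr$amplitude_pa, 2, tolerance = 1e-6)
})

test_that("neurogliaform-to-pyramidal PSC is biphasic with a slow tail", {
  cfg <- full_cfg()
  pr <- paired_recording("ngf", "pyr", cfg, hold = -50, trials = 10,
                         seed = 2)
  tr <- pr$trace
  early <- tr$I[tr$t > 2 & tr$t < 6]      # fast GABA-A component
  late <- tr$I[tr$t > 150 & tr$t < 400]   # slow GABA-B tail
  expect_gt(max(early), 0)                # fast outward peak at -50 mV
  expect_gt(max(late), 0.1 * max(early))  # sustained slow tail
  expect_gt(pr$decay_ms, 50)   # tail decay dominated by the GABA-B kinetics
  # GABA-A alone decays fast: the mixed synapse is biphasic
  pa <- paired_recording(syn = ngf_synapse(cfg)$gabaa, hold = -50,
                         trials = 1)
  expect_lt(pa$decay_ms, 15)
  expect_error(paired_recording("axo", "olm", cfg), "undeclared")
})
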