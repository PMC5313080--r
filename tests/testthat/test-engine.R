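silent_stim <- function(cfg, duration = 500)
  poisson_trains(sum(cfg$afferents$count), 0, duration)

test_that("a network with no afferent input is silent", {
  cfg <- toy_config()
  net <- build_network(cfg, seed = 1)
  sim <- simulate_network(net, stim = silent_stim(cfg), duration = 500)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("an isolated cell in the engine matches the single-cell integrator", {
  cfg <- toy_config(nA = 3, nB = 2)
  net <- build_network(cfg, seed = 1)
  p <- neuron_params("A", cfg)
  Iext <- numeric(5); Iext[2] <- 250
  sim <- simulate_network(net, stim = silent_stim(cfg, 1000),
                          duration = 1000, dt = 0.05, Iext = Iext)
  # the driven cell receives no synaptic events (everyone else is silent)
  n_engine <- sum(sim$spikes$gid == 2)
  n_single <- length(membrane_step(p, 250, 1000, dt = 0.05)$spikes)
  expect_gt(n_single, 5)
  expect_lt(abs(n_engine - n_single) / n_single, 0.05)
})

test_that("identical configuration and seed give identical rasters", {
  cfg <- toy_config()
  net <- build_network(cfg, seed = 3)
  s1 <- simulate_network(net, duration = 400, seed = 3)
  s2 <- simulate_network(net, duration = 400, seed = 3)
  expect_identical(s1$spikes, s2$spikes)
  expect_gt(nrow(s1$spikes), 0)
})

test_that("halving the time step changes the toy spike count by under 1%", {
  cfg <- toy_config()
  net <- build_network(cfg, seed = 2)
  stim <- poisson_trains(5, 40, 1000, seed = 11)
  n1 <- nrow(simulate_network(net, stim, duration = 1000, dt = 0.025)$spikes)
  n2 <- nrow(simulate_network(net, stim, duration = 1000, dt = 0.0125)$spikes)
  expect_gt(n1, 50)
  expect_lt(abs(n1 - n2) / n1, 0.01)
})

test_that("muting is targeted, complete and reversible", {
  cfg <- toy_config()
  net <- build_network(cfg, seed = 4)
  stim <- poisson_trains(5, 20, 600, seed = 4)
  ctrl <- simulate_network(net, stim, duration = 600)

  # fraction 0: network unchanged
  net0 <- apply_perturbation(net, perturbation("mute_outputs", target = "A",
                                               fraction = 0))
  expect_identical(net0$edges, net$edges)

  # full muting of the principal type: no excitatory events from local cells
  netm <- apply_perturbation(net, perturbation("mute_outputs", target = "A"))
  simm <- simulate_network(netm, stim, duration = 600)
  ampa <- which(netm$config$channels$name == "AMPA")
  expect_equal(simm$wsum_local[ampa], 0)
  expect_gt(ctrl$wsum_local[ampa], 0)

  # restoring the original weights reproduces the control raster exactly
  netr <- netm
  netr$edges$weight <- net$edges$weight
  simr <- simulate_network(netr, stim, duration = 600)
  expect_identical(simr$spikes, ctrl$spikes)

  # partial muting hits the requested fraction of cells
  neth <- apply_perturbation(net, perturbation("mute_fraction", target = "A",
                                               fraction = 0.5, seed = 9))
  expect_equal(length(neth$muted), 5)
  expect_error(apply_perturbation(net, perturbation("mute_outputs",
                                                    target = "nope")),
               "unknown target")
})

test_that("charge-matched GABA-A replacement conserves inhibitory charge", {
  cfg <- full_cfg()
  syn <- ngf_synapse(cfg)
  ref <- cfg$gabab$reference_mv
  k <- charge_match_scale(syn$gabaa, syn$gabab, ref)
  # control mixed synapse charge vs scaled GABA-A-only charge, by quadrature
  dt <- 0.01; tt <- seq(0, 20000, by = dt)
  q <- function(s, scale = 1) sum(conductance_waveform(s, tt)) * dt *
    scale * abs(ref - s$erev) / 1000
  q_ctrl <- q(syn$gabaa) + q(syn$gabab)
  q_matched <- q(syn$gabaa, scale = 1 + k)
  expect_equal(q_matched, q_ctrl, tolerance = 0.01)
  # the perturbation stores exactly that scale factor
  net <- list(config = cfg)
  class(net) <- "ca1_network"
  net2 <- apply_perturbation(net, perturbation("charge_matched_gabaa"))
  expect_true(net2$gabab_removed)
  expect_equal(net2$gabaa_scale_ngf, 1 + k)
})

test_that("structural perturbations act as configuration transforms", {
  cfg <- full_cfg()
  c2 <- apply_perturbation(cfg, perturbation("scale_pyr_pyr", factor = 2))
  expect_equal(c2$budgets["pyr", "pyr"], 2 * cfg$budgets["pyr", "pyr"])
  c0 <- apply_perturbation(cfg, perturbation("scale_pyr_pyr", factor = 0))
  expect_equal(c0$budgets["pyr", "pyr"], 0)

  h1 <- apply_perturbation(cfg, perturbation("homogenize_interneurons",
                                             stage = "ephys"))
  np <- h1$neuron_params
  for (ty in c("cck", "olm", "ngf"))
    expect_equal(unlist(np[np$name == ty, -1]),
                 unlist(np[np$name == "pvb", -1]), ignore_attr = TRUE)
  expect_equal(np[np$name == "pyr", ], cfg$neuron_params[
    cfg$neuron_params$name == "pyr", ])  # principal untouched

  h4 <- apply_perturbation(cfg, perturbation("homogenize_interneurons",
                                             stage = "full"))
  # output budgets scale with population size relative to the reference
  expect_equal(h4$budgets["olm", "pyr"],
               cfg$budgets["pvb", "pyr"] * 1640 / 5530)
  expect_equal(h4$channel_of[["ngf"]], "GABAA")
  h5 <- apply_perturbation(cfg, perturbation("homogenize_interneurons",
                                             stage = "variable_rmp",
                                             rmp_sd = 8))
  expect_equal(h5$rmp_jitter$sd, 8)
})

test_that("network clamp reproduces the embedded cell", {
  cfg <- toy_config(nA = 60, nB = 40, budget_AA = 600, budget_AB = 300,
                    budget_BA = 600, budget_extA = 300)
  net <- build_network(cfg, seed = 6)
  target <- 5
  trains <- poisson_trains(5, 30, 1000, seed = 12)

  # silent afferents, everything else muted: the clamped cell is silent
  cl0 <- network_clamp(net, target, poisson_trains(5, 0, 1000),
                       duration = 1000)
  expect_equal(nrow(cl0$spikes), 0)

  # full run with every other cell muted == clamp driven by the afferents
  netm <- apply_perturbation(net, perturbation("mute_outputs",
                                               target = c("A", "B")))
  full <- simulate_network(netm, trains, duration = 1000)
  n_full <- sum(full$spikes$gid == target)
  cl <- network_clamp(net, target, trains, duration = 1000)
  expect_gt(n_full, 3)
  expect_lt(abs(nrow(cl$spikes) - n_full) / n_full, 0.10)

  # firing rate is non-decreasing in the afferent excitatory weight
  rates <- sapply(c(0.5, 1, 2), function(sc)
    nrow(network_clamp(net, target, trains, duration = 1000,
                       weight_scale = c(ext = sc))$spikes))
  expect_true(all(diff(rates) >= 0))
  expect_error(network_clamp(net, 10000, trains), "unknown cell id")
})
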