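# Shared fixtures: the packaged full-scale configuration (loaded once) and a
# small two-type toy configuration built in code.

full_cfg <- function() {
  if (is.null(.fixture_env$full)) .fixture_env$full <- default_config()
  .fixture_env$full
}
.fixture_env <- new.env()

# Toy network: principal type "A" (excitatory) and interneuron "B", driven
# by external units "ext". Counts and budgets are chosen so every projection
# has plentiful candidate pairs.
toy_config <- function(nA = 10, nB = 20, next_ = 5,
                       budget_AA = 90, budget_AB = 40, budget_BA = 200,
                       budget_extA = 50, weight = 4, seed = 1) {
  lst <- list(
    cell_types = list(
      list(name = "A", count = nA, layer = "SP", is_principal = TRUE),
      list(name = "B", count = nB, layer = "SP", is_principal = FALSE)),
    afferents = list(list(name = "ext", count = next_, layer = "SR")),
    geometry = list(longitudinal_um = 400, transverse_um = 400,
                    layer_bounds = list(SO = c(0, 50), SP = c(50, 100),
                                        SR = c(100, 150),
                                        SLM = c(150, 200))),
    budgets = list(A = list(A = budget_AA, B = budget_AB),
                   B = list(A = budget_BA),
                   ext = list(A = budget_extA)),
    syn_per_conn = list(A = list(A = 1, B = 1), B = list(A = 2),
                        ext = list(A = 1)),
    weights = list(A = list(A = weight, B = weight),
                   B = list(A = weight), ext = list(A = weight)),
    axonal_profiles = list(
      list(name = "A", mean_um = 0, sd_um = 200, extent_um = 600,
           bin_um = 100),
      list(name = "B", mean_um = 0, sd_um = 200, extent_um = 600,
           bin_um = 100),
      list(name = "ext", mean_um = 0, sd_um = 300, extent_um = 600,
           bin_um = 100)),
    zones = list(`A->A` = list("basal_dendrite"),
                 default = list("soma", "proximal_dendrite_SR")),
    neuron_params = list(
      list(name = "A", EL = -65, R = 100, taum = 10, VT = -48, DeltaT = 2,
           Vreset = -65, Vpeak = -23, tref = 2, b = 20, tauw = 100),
      list(name = "B", EL = -65, R = 100, taum = 10, VT = -48, DeltaT = 2,
           Vreset = -65, Vpeak = -23, tref = 1, b = 0, tauw = 50)),
    channels = list(
      list(name = "AMPA", tau1 = 0.5, tau2 = 3, erev = 0),
      list(name = "GABAA", tau1 = 0.3, tau2 = 8, erev = -70),
      list(name = "GABAB", tau1 = 50, tau2 = 200, erev = -90)),
    channel_of = list(A = "AMPA", B = "GABAA", ext = "AMPA"),
    gabab = list(channel = "GABAB", g_ratio = 0, reference_mv = -63,
                 targets = list()),
    delay = list(base_ms = 0.5, velocity_um_per_ms = 300),
    stim = list(rate_hz = 40),
    electrode = list(longitudinal_um = 200, transverse_um = 200,
                     height_um = 75),
    seed = seed)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lst, path)
  load_config(path)
}

# analytic passive cell used for closed-form checks
passive_cell <- function(R = 100, taum = 10, EL = -65) {
  p <- list(name = "passive", EL = EL, R = R, taum = taum, VT = 1e6,
            DeltaT = 2, Vreset = EL, Vpeak = 1e6 + 25, tref = 2, b = 0,
            tauw = 100)
  p$gL <- 1000 / p$R
  p$C <- p$taum * p$gL
  p
}
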