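# The perturbation-experiment battery: every altered-network condition
# (control, excitation sweep, per-type muting, pyramidal-recurrence scaling,
# partial PV+/SOM+ muting, staged interneuron homogenization, GABA-B
# removal / charge-matched replacement) as a named, reproducible entry.

#' Names and definitions of the packaged experiment battery
#'
#' @return a named list; each entry describes how the condition modifies the
#'   control network (\code{rate} override, \code{perturbations} list).
#' @export
experiment_battery <- function() {
  b <- list(control = list())
  for (r in c(0.2, 0.4, 0.5, 0.65, 0.8, 1.0, 1.2, 1.4))
    b[[sprintf("excitation_%.2f", r)]] <- list(rate = r)
  for (ty in c("pyr", "pvb", "cck", "sca", "axo", "bis", "olm", "ivy",
               "ngf"))
    b[[paste0("mute_", ty)]] <-
      list(perturbations = list(perturbation("mute_outputs", target = ty)))
  b$pyrpyr_0.0x <- list(config_perturbations =
    list(perturbation("scale_pyr_pyr", factor = 0)))
  b$pyrpyr_0.5x <- list(config_perturbations =
    list(perturbation("scale_pyr_pyr", factor = 0.5)))
  b$pyrpyr_2.0x <- list(config_perturbations =
    list(perturbation("scale_pyr_pyr", factor = 2)))
  b$mute_pv_50 <- list(perturbations = list(
    perturbation("mute_fraction", target = c("pvb", "bis", "axo"),
                 fraction = 0.5)))
  b$mute_som_50 <- list(perturbations = list(
    perturbation("mute_fraction", target = c("olm", "bis"),
                 fraction = 0.5)))
  for (st in c("ephys", "input_weights", "input_numbers", "full",
               "variable_rmp"))
    b[[paste0("homogenize_", st)]] <- list(config_perturbations =
      list(perturbation("homogenize_interneurons", stage = st)))
  b$gabab_removed <- list(perturbations =
    list(perturbation("remove_gabab")))
  b$gabab_matched <- list(perturbations =
    list(perturbation("charge_matched_gabaa")))
  b
}

#' Run one battery condition end to end
#'
#' Scales the configuration, applies the condition's structural transforms,
#' builds the network, applies network-level perturbations, simulates and
#' summarizes the pyramidal spike density function spectrum (theta, gamma
#' and overall peak frequency and power).
#'
#' @param entry condition name from \code{\link{experiment_battery}}.
#' @param scale scale fraction (default 0.02).
#' @param seed run seed.
#' @param duration simulation duration (ms).
#' @param config base configuration (default packaged full scale).
#' @param out_dir if given, raster, spectral summary and manifest are
#'   written there.
#' @param dt integration step (ms).
#' @return an object of class \code{ca1_experiment}: \code{entry},
#'   \code{summary} (one-row data.frame in the shape of the spectral table:
#'   theta/gamma/overall frequency and power), \code{sim}, \code{network}.
#' @export
run_experiment <- function(entry, scale = 0.02, seed = 1, duration = 2000,
                           config = default_config(), out_dir = NULL,
                           dt = 0.05) {
  battery <- experiment_battery()
  if (!entry %in% names(battery))
    stop("unknown battery entry: ", entry, call. = FALSE)
  cond <- battery[[entry]]
  cfg <- scale_config(config, scale)
  if (!is.null(cond$rate)) cfg$stim$rate_hz <- cond$rate
  for (p in cond$config_perturbations) cfg <- apply_perturbation(cfg, p)
  net <- build_network(cfg, seed = seed)
  pert <- NULL
  for (p in cond$perturbations) {
    net <- apply_perturbation(net, p)
    pert <- p
  }
  sim <- simulate_network(net, duration = duration, dt = dt, seed = seed)
  psd <- sim_psd(sim, principal_type(cfg))
  pk <- psd$peaks
  summary <- data.frame(
    condition = entry,
    theta_freq = pk$freq[pk$band == "theta"],
    theta_power = pk$power[pk$band == "theta"],
    gamma_freq = pk$freq[pk$band == "gamma"],
    gamma_power = pk$power[pk$band == "gamma"],
    overall_freq = pk$freq[pk$band == "overall"],
    overall_power = pk$power[pk$band == "overall"])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_raster(sim, file.path(out_dir, "raster.tsv"))
    write.table(summary, file.path(out_dir, "spectral_summary.csv"),
                sep = ",", row.names = FALSE, quote = FALSE)
    run_manifest(net, sim, pert, path = file.path(out_dir, "manifest.json"))
  }
  structure(list(entry = entry, summary = summary, sim = sim,
                 network = net),
            class = "ca1_experiment")
}

#' @export
print.ca1_experiment <- function(x, ...) {
  cat("Experiment '", x$entry, "':\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' GABA-B battery with replicate seeds and ANOVA on theta power
#'
#' Runs the control, GABA-B-removed and charge-matched-GABA-A conditions
#' with \code{n} seeds each and performs a one-way ANOVA on the theta-band
#' peak power of the pyramidal spike density function across conditions.
#'
#' @param scale scale fraction.
#' @param seeds integer vector of seeds (one replicate per seed).
#' @param duration simulation duration (ms).
#' @param config base configuration.
#' @param dt integration step (ms).
#' @return list with \code{table} (condition x seed theta powers),
#'   \code{anova} (the \code{aov} fit), \code{F}, \code{p}.
#' @export
run_gabab_battery <- function(scale = 0.02, seeds = 1:3, duration = 2000,
                              config = default_config(), dt = 0.05) {
  conds <- c("control", "gabab_removed", "gabab_matched")
  rows <- list()
  for (cn in conds)
    for (s in seeds) {
      ex <- run_experiment(cn, scale = scale, seed = s,
                           duration = duration, config = config, dt = dt)
      rows[[length(rows) + 1]] <- data.frame(condition = cn, seed = s,
        theta_power = ex$summary$theta_power,
        theta_freq = ex$summary$theta_freq)
    }
  tab <- do.call(rbind, rows)
  fit <- aov(theta_power ~ condition, data = tab)
  sm <- summary(fit)[[1]]
  list(table = tab, anova = fit, F = sm[["F value"]][1],
       p = sm[["Pr(>F)"]][1])
}
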