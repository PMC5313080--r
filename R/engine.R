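# Clock-driven simulation of the constructed network, perturbation
# operators, and the single-cell network clamp.

#' Simulate a built network
#'
#' Integrates all neurons (adaptive exponential integrate-and-fire) and
#' conductance synapses (double exponentials grouped into receptor channels)
#' with per-edge conduction delays, driven by afferent spike trains. The run
#' is deterministic given the network, stimulus and time step.
#'
#' @param network a \code{ca1_network}.
#' @param stim a \code{ca1_trains} over the afferent units (unit 1 maps to
#'   the first afferent gid); by default independent Poisson trains at the
#'   configured afferent rate are generated from \code{seed}.
#' @param duration simulation duration (ms).
#' @param dt integration step (ms); 0.05 default for network runs.
#' @param seed seed for the default stimulus.
#' @param record list: \code{vm} (gids to record, sampled each
#'   \code{vm_every_ms}), \code{lfp} (logical: record the online LFP analog
#'   at \code{lfp_fs} Hz).
#' @param Iext optional per-cell constant injected current (pA).
#' @return an object of class \code{ca1_sim}: \code{spikes} (data.frame
#'   \code{gid}, \code{time_ms}, \code{type}), \code{vm}, \code{lfp}
#'   (\code{ca1_lfp} or NULL), \code{duration}, \code{dt}, \code{seed},
#'   \code{config_digest}, and per-channel delivered conductance totals
#'   (\code{wsum_local}, \code{wsum_aff}).
#' @export
simulate_network <- function(network, stim = NULL, duration = 2000,
                             dt = 0.05, seed = network$seed,
                             record = list(), Iext = NULL) {
  stopifnot(inherits(network, "ca1_network"), dt > 0)
  cfg <- network$config
  n_local <- sum(cfg$cell_types$count)
  n_aff <- sum(cfg$afferents$count)
  if (is.null(stim) && n_aff > 0)
    stim <- poisson_trains(n_aff, cfg$stim$rate_hz, duration, seed = seed)
  inp <- engine_inputs(network, dt)

  aff_step <- integer(0); aff_unit <- integer(0)
  if (!is.null(stim) && nrow(stim$spikes)) {
    sp <- stim$spikes[stim$spikes$time_ms < duration, ]
    o <- order(sp$time_ms)
    aff_step <- as.integer(floor(sp$time_ms[o] / dt))
    aff_unit <- as.integer(sp$unit[o] - 1L)
  }
  if (is.null(Iext)) Iext <- numeric(n_local)

  vm_ids <- as.integer(record$vm %||% integer(0))
  vm_every <- max(1L, as.integer(round((record$vm_every_ms %||% 1) / dt)))
  lfp_w <- numeric(0)
  lfp_fs <- record$lfp_fs %||% 1000
  if (isTRUE(record$lfp)) {
    pos <- network$positions[seq_len(n_local), ]
    w <- numeric(n_local)
    is_pyr <- pos$type == principal_type(cfg)
    w[is_pyr] <- lfp_weights(pos[is_pyr, ], cfg$electrode,
                             seed = seed + 7L)
    lfp_w <- w
  }
  lfp_every <- max(1L, as.integer(round(1000 / lfp_fs / dt)))

  nsteps <- as.integer(round(duration / dt))
  res <- cpp_simulate(inp$neurons, inp$channels, inp$edges, inp$aff_edges,
                      aff_step, aff_unit, Iext, nsteps, dt, vm_ids, vm_every,
                      lfp_w, lfp_every)
  spikes <- data.frame(gid = res$spike_id, time_ms = res$spike_t)
  spikes$type <- type_of_gid(network, spikes$gid)
  lfp <- if (isTRUE(record$lfp))
    structure(list(fs = 1000 / (lfp_every * dt), samples = res$lfp,
                   electrode = cfg$electrode), class = "ca1_lfp")
  vm <- NULL
  if (length(vm_ids))
    vm <- list(gids = vm_ids, t = seq(0, by = vm_every * dt,
                                      length.out = nrow(res$vm)),
               V = res$vm)
  structure(list(spikes = spikes, vm = vm, lfp = lfp, duration = duration,
                 dt = dt, seed = seed, config_digest = digest_of(cfg),
                 wsum_local = res$wsum_local, wsum_aff = res$wsum_aff,
                 channels = inp$channel_names),
            class = "ca1_sim")
}

#' @export
print.ca1_sim <- function(x, ...) {
  cat("CA1 simulation: ", x$duration, " ms at dt ", x$dt, " ms, ",
      nrow(x$spikes), " spikes\n", sep = "")
  if (nrow(x$spikes)) {
    tab <- table(x$spikes$type)
    cat("  spikes per type: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

principal_type <- function(cfg)
  cfg$cell_types$name[cfg$cell_types$is_principal][1]

type_of_gid <- function(network, gid) {
  gr <- network$gid_ranges
  gr$type[findInterval(gid, gr$first)]
}

#' Gids of all cells of one type
#' @param network a \code{ca1_network}.
#' @param type type name.
#' @return integer vector of gids.
#' @export
gids_of_type <- function(network, type) {
  gr <- network$gid_ranges
  i <- match(type, gr$type)
  if (is.na(i)) stop("unknown type: ", type, call. = FALSE)
  seq(gr$first[i], gr$last[i])
}

# Assemble per-neuron arrays, channel table and CSR edge lists for the C++
# engine. NGF outputs onto the configured GABA-B targets carry an extra
# GABA-B component edge (weight = g_ratio x GABA-A weight) unless removed.
engine_inputs <- function(network, dt) {
  cfg <- network$config
  ct <- cfg$cell_types
  n_local <- sum(ct$count)
  type_idx <- rep(seq_len(nrow(ct)), ct$count)
  pars <- lapply(ct$name, neuron_params, config = cfg)
  arr <- function(f) vapply(pars, function(p) p[[f]], numeric(1))[type_idx]
  EL <- arr("EL")
  if (!is.null(cfg$rmp_jitter)) {
    jt <- cfg$rmp_jitter
    targets <- which(type_of_gid(network, seq_len(n_local)) %in% jt$types)
    EL[targets] <- EL[targets] +
      with_seed(jt$seed %||% 1L, stats::rnorm(length(targets), 0, jt$sd))
  }
  neurons <- list(EL = EL, gL = arr("gL"), C = arr("C"), VT = arr("VT"),
                  DeltaT = arr("DeltaT"), Vreset = arr("Vreset"),
                  Vpeak = arr("Vpeak"), b = arr("b"), tauw = arr("tauw"),
                  refsteps = as.integer(round(arr("tref") / dt)))
  ch <- cfg$channels
  channels <- list(tau1 = ch$tau1, tau2 = ch$tau2, erev = ch$erev)
  chan_idx <- stats::setNames(seq_len(nrow(ch)) - 1L, ch$name)

  e <- network$edges
  src <- e$pre_gid; dst <- e$post_gid; w <- e$weight
  chan <- chan_idx[unlist(cfg$channel_of[e$pre_type], use.names = FALSE)]
  delay <- pmax(1L, as.integer(round(e$delay_ms / dt)))
  # extra GABA-B component for mixed NGF synapses
  if (!isTRUE(network$gabab_removed)) {
    gb <- which(e$pre_type == "ngf" & e$post_type %in% cfg$gabab$targets)
    if (length(gb)) {
      src <- c(src, e$pre_gid[gb]); dst <- c(dst, e$post_gid[gb])
      w <- c(w, e$weight[gb] * cfg$gabab$g_ratio)
      chan <- c(chan, rep(chan_idx[[cfg$gabab$channel]], length(gb)))
      delay <- c(delay, delay[gb])
    }
  }
  sc <- network$gabaa_scale_ngf
  if (!is.null(sc)) {
    i <- which(e$pre_type == "ngf" &
               e$post_type %in% cfg$gabab$targets)
    w[i] <- w[i] * sc
  }
  local <- src <= n_local
  edges <- csr(src[local], dst[local] - 1L, chan[local], w[local],
               delay[local], n_local)
  affsel <- !local
  aff_edges <- csr(src[affsel] - n_local, dst[affsel] - 1L, chan[affsel],
                   w[affsel], delay[affsel], sum(cfg$afferents$count))
  list(neurons = neurons, channels = channels, edges = edges,
       aff_edges = aff_edges, channel_names = ch$name)
}

csr <- function(src, dst0, chan, w, delay, n_src) {
  o <- order(src)
  cnt <- tabulate(src, nbins = n_src)
  list(ptr = as.integer(c(0, cumsum(cnt))), dst = as.integer(dst0[o]),
       chan = as.integer(chan[o]), w = as.numeric(w[o]),
       delay = as.integer(delay[o]))
}

digest_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2)
  unname(tools::md5sum(f))
}

#' Perturbation specification
#'
#' @param kind one of \code{"mute_outputs"}, \code{"mute_fraction"},
#'   \code{"remove_gabab"}, \code{"charge_matched_gabaa"},
#'   \code{"homogenize_interneurons"}, \code{"scale_pyr_pyr"}.
#' @param target cell type name(s) targeted (muting).
#' @param fraction fraction of the targeted cells muted (in [0, 1]).
#' @param factor multiplier for the pyramidal-to-pyramidal synapse budget.
#' @param stage homogenization stage: \code{"ephys"},
#'   \code{"input_weights"}, \code{"input_numbers"}, \code{"full"} or
#'   \code{"variable_rmp"}.
#' @param rmp_sd SD (mV) of resting-potential variability for
#'   \code{"variable_rmp"}.
#' @param seed seed used when sampling a fraction of cells.
#' @return a \code{ca1_perturbation} list.
#' @export
perturbation <- function(kind, target = NULL, fraction = 1, factor = NULL,
                         stage = NULL, rmp_sd = 8, seed = 1) {
  kinds <- c("mute_outputs", "mute_fraction", "remove_gabab",
             "charge_matched_gabaa", "homogenize_interneurons",
             "scale_pyr_pyr")
  kind <- match.arg(kind, kinds)
  if (fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  structure(list(kind = kind, target = target, fraction = fraction,
                 factor = factor, stage = stage, rmp_sd = rmp_sd,
                 seed = seed),
            class = "ca1_perturbation")
}

#' Apply a perturbation
#'
#' Muting and GABA-B operations act on a built network (outgoing weights of
#' the targeted cells set to zero without touching placement or the
#' per-projection RNG streams; GABA-B components removed and optionally
#' replaced by a charge-matched scaled GABA-A component). Structural
#' operations (pyramidal-to-pyramidal budget scaling, staged interneuron
#' homogenization) act on a configuration, which is then rebuilt.
#'
#' @param x a \code{ca1_network} (muting, GABA-B kinds) or \code{ca1_config}
#'   (structural kinds).
#' @param spec a \code{ca1_perturbation}.
#' @return the perturbed object (same class as \code{x}).
#' @export
apply_perturbation <- function(x, spec) {
  stopifnot(inherits(spec, "ca1_perturbation"))
  switch(spec$kind,
    mute_outputs = ,
    mute_fraction = {
      stopifnot(inherits(x, "ca1_network"))
      if (spec$fraction == 0) return(x)
      bad <- setdiff(spec$target, x$config$cell_types$name)
      if (length(bad))
        stop("unknown target type: ", paste(bad, collapse = ", "),
             call. = FALSE)
      muted <- unlist(lapply(spec$target, function(ty) {
        g <- gids_of_type(x, ty)
        if (spec$fraction >= 1) g
        else {
          rng <- local_rng(stream_seed(spec$seed, "mute", ty))
          g[rank(rng(length(g)), ties.method = "first") <=
              floor(spec$fraction * length(g))]
        }
      }))
      x$edges$weight[x$edges$pre_gid %in% muted] <- 0
      x$muted <- sort(unique(c(x$muted, muted)))
      x
    },
    remove_gabab = {
      stopifnot(inherits(x, "ca1_network"))
      x$gabab_removed <- TRUE
      x
    },
    charge_matched_gabaa = {
      stopifnot(inherits(x, "ca1_network"))
      x$gabab_removed <- TRUE
      syn <- ngf_synapse(x$config)
      x$gabaa_scale_ngf <- 1 + charge_match_scale(
        syn$gabaa, syn$gabab, x$config$gabab$reference_mv)
      x
    },
    scale_pyr_pyr = {
      stopifnot(inherits(x, "ca1_config"))
      pt <- principal_type(x)
      x$budgets[pt, pt] <- x$budgets[pt, pt] * spec$factor
      x
    },
    homogenize_interneurons = homogenize_config(x, spec)
  )
}

# Staged interneuron homogenization toward the PV+ basket profile,
# expressed purely as configuration transforms.
homogenize_config <- function(cfg, spec) {
  stopifnot(inherits(cfg, "ca1_config"))
  stages <- c("ephys", "input_weights", "input_numbers", "full",
              "variable_rmp")
  stage <- match.arg(spec$stage, stages)
  lvl <- match(stage, stages)
  ref <- "pvb"
  ints <- setdiff(cfg$cell_types$name[!cfg$cell_types$is_principal], ref)
  np <- cfg$neuron_params
  refrow <- np[np$name == ref, -1]
  for (ty in ints) np[np$name == ty, -1] <- refrow
  cfg$neuron_params <- np
  if (lvl >= 2)
    for (ty in ints) cfg$weights[, ty] <- cfg$weights[, ref]
  if (lvl >= 3) {
    n_ref <- population_count(cfg, ref)
    for (ty in ints) {
      n_ty <- population_count(cfg, ty)
      cfg$budgets[, ty] <- cfg$budgets[, ref] * n_ty / n_ref
      cfg$syn_per_conn[, ty] <- cfg$syn_per_conn[, ref]
    }
  }
  if (lvl >= 4) {
    n_ref <- population_count(cfg, ref)
    for (ty in ints) {
      n_ty <- population_count(cfg, ty)
      cfg$budgets[ty, ] <- cfg$budgets[ref, ] * n_ty / n_ref
      cfg$syn_per_conn[ty, ] <- cfg$syn_per_conn[ref, ]
      cfg$weights[ty, ] <- cfg$weights[ref, ]
      cfg$channel_of[[ty]] <- cfg$channel_of[[ref]]
      i <- cfg$axonal$name == ty
      cfg$axonal[i, -1] <- cfg$axonal[cfg$axonal$name == ref, -1]
    }
  }
  if (lvl >= 5)
    cfg$rmp_jitter <- list(sd = spec$rmp_sd, seed = spec$seed,
                           types = c(ref, ints))
  cfg
}

#' Network clamp: simulate one cell with its afferent synapses intact
#'
#' Extracts a single cell from the network together with all of its incoming
#' connections and drives those connections with prescribed spike trains
#' (afferent-unit trains, and optionally a raster supplying the spikes of
#' its local presynaptic cells).
#'
#' @param network a \code{ca1_network}.
#' @param target_gid gid of the clamped cell.
#' @param afferent_trains a \code{ca1_trains} over the afferent units.
#' @param local_spikes optional data.frame (\code{gid}, \code{time_ms}) of
#'   spikes for local presynaptic cells.
#' @param duration duration (ms).
#' @param dt integration step (ms).
#' @param weight_scale optional named vector scaling incoming weights by
#'   presynaptic type.
#' @return a \code{ca1_sim} for the single clamped cell (gid remapped to 1).
#' @export
network_clamp <- function(network, target_gid, afferent_trains = NULL,
                          local_spikes = NULL, duration = 2000, dt = 0.05,
                          weight_scale = NULL) {
  cfg <- network$config
  n_local <- sum(cfg$cell_types$count)
  if (!(target_gid >= 1 && target_gid <= n_local))
    stop("unknown cell id: ", target_gid, call. = FALSE)
  ty <- type_of_gid(network, target_gid)
  ine <- network$edges[network$edges$post_gid == target_gid, , drop = FALSE]
  if (!is.null(weight_scale))
    for (nm in names(weight_scale))
      ine$weight[ine$pre_type == nm] <- ine$weight[ine$pre_type == nm] *
        weight_scale[[nm]]
  pres <- unique(ine$pre_gid)
  unit_of <- stats::setNames(seq_along(pres), pres)
  sub_cfg <- cfg
  sub_cfg$cell_types <- cfg$cell_types[cfg$cell_types$name == ty, ]
  sub_cfg$cell_types$count <- 1
  sub_net <- network
  sub_net$config <- sub_cfg
  # spikes of the presynaptic drivers
  drv <- data.frame(unit = integer(0), time_ms = numeric(0))
  if (!is.null(afferent_trains) && nrow(afferent_trains$spikes)) {
    sp <- afferent_trains$spikes
    agid <- sp$unit + n_local
    keep <- as.character(agid) %in% names(unit_of)
    drv <- rbind(drv, data.frame(unit = unit_of[as.character(agid[keep])],
                                 time_ms = sp$time_ms[keep]))
  }
  if (!is.null(local_spikes) && nrow(local_spikes)) {
    keep <- as.character(local_spikes$gid) %in% names(unit_of)
    drv <- rbind(drv,
                 data.frame(unit = unit_of[as.character(local_spikes$gid[keep])],
                            time_ms = local_spikes$time_ms[keep]))
  }
  drv <- drv[order(drv$time_ms), ]
  # assemble a one-neuron engine problem directly
  p <- neuron_params(ty, cfg)
  neurons <- list(EL = p$EL, gL = p$gL, C = p$C, VT = p$VT,
                  DeltaT = p$DeltaT, Vreset = p$Vreset, Vpeak = p$Vpeak,
                  b = p$b, tauw = p$tauw,
                  refsteps = as.integer(round(p$tref / dt)))
  ch <- cfg$channels
  chan_idx <- stats::setNames(seq_len(nrow(ch)) - 1L, ch$name)
  chan <- chan_idx[unlist(cfg$channel_of[ine$pre_type], use.names = FALSE)]
  w <- ine$weight
  srcu <- unit_of[as.character(ine$pre_gid)]
  delay <- pmax(1L, as.integer(round(ine$delay_ms / dt)))
  if (!isTRUE(network$gabab_removed)) {
    gb <- which(ine$pre_type == "ngf" & ty %in% cfg$gabab$targets)
    if (length(gb)) {
      srcu <- c(srcu, srcu[gb]); w <- c(w, w[gb] * cfg$gabab$g_ratio)
      chan <- c(chan, rep(chan_idx[[cfg$gabab$channel]], length(gb)))
      delay <- c(delay, delay[gb])
    }
  }
  aff_edges <- csr(srcu, rep(0L, length(srcu)), chan, w, delay,
                   length(pres))
  edges <- csr(integer(0), integer(0), integer(0), numeric(0), integer(0), 1L)
  nsteps <- as.integer(round(duration / dt))
  res <- cpp_simulate(neurons, list(tau1 = ch$tau1, tau2 = ch$tau2,
                                    erev = ch$erev),
                      edges, aff_edges,
                      as.integer(floor(drv$time_ms / dt)),
                      as.integer(drv$unit - 1L), 0, nsteps, dt,
                      1L, max(1L, as.integer(round(1 / dt))),
                      numeric(0), 1L)
  spikes <- data.frame(gid = res$spike_id, time_ms = res$spike_t)
  spikes$type <- rep(ty, nrow(spikes))
  structure(list(spikes = spikes,
                 vm = list(gids = target_gid,
                           t = seq(0, by = 1, length.out = nrow(res$vm)),
                           V = res$vm),
                 lfp = NULL, duration = duration, dt = dt,
                 seed = NA_integer_, config_digest = digest_of(cfg),
                 target_gid = target_gid),
            class = "ca1_sim")
}

#' Spike density function of one cell type in a simulation
#'
#' @param sim a \code{ca1_sim}.
#' @param type cell type name, or \code{"interneurons"} (all non-principal
#'   local types pooled) or \code{"all"}.
#' @param crop initial transient discarded before spectral analysis (ms).
#' @return as \code{\link{sdf}} over the cropped window.
#' @export
sim_sdf <- function(sim, type, crop = 50) {
  sel <- if (identical(type, "all")) rep(TRUE, nrow(sim$spikes))
         else if (identical(type, "interneurons"))
           !sim$spikes$type %in% c("pyr", "ca3", "ec3")
         else sim$spikes$type == type
  sp <- sim$spikes$time_ms[sel]
  sdf(sp[sp >= crop] - crop, sim$duration - crop)
}

#' Theta-band summary of a simulation
#'
#' Welch periodogram of the spike density function of one cell type, with
#' the theta (5-10 Hz), gamma (25-80 Hz) and overall peaks.
#'
#' @param sim a \code{ca1_sim}.
#' @param type cell type name (default the principal type of the run).
#' @param segment_s Welch segment (samples at 1 kHz).
#' @return the \code{ca1_psd}.
#' @export
sim_psd <- function(sim, type = "pyr", segment_s = 1024) {
  s <- sim_sdf(sim, type)
  welch_psd(s$rate, s$fs, segment_s = min(segment_s, length(s$rate)))
}
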