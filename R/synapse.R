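# Double-exponential conductance synapses, mixed GABA-A/GABA-B components,
# paired-recording protocol and charge-transfer arithmetic.

# Dendritic-filtering attenuation applied per compartment zone (estimates;
# somatic/AIS contacts unattenuated, distal contacts most attenuated).
ZONE_FACTOR <- c(AIS = 1, soma = 1, basal_dendrite = 0.9,
                 proximal_dendrite_SO = 0.9, proximal_dendrite_SR = 0.9,
                 distal_dendrite_SLM = 0.75)

#' Double-exponential synapse parameters
#'
#' @param tau1 rise time constant (ms), must be < \code{tau2}.
#' @param tau2 decay time constant (ms).
#' @param gmax peak conductance (nS).
#' @param erev reversal potential (mV).
#' @return a \code{ca1_syn} parameter list.
#' @export
syn_params <- function(tau1, tau2, gmax, erev) {
  if (tau1 <= 0 || tau1 >= tau2)
    stop("require 0 < tau1 < tau2", call. = FALSE)
  if (gmax < 0) stop("gmax must be >= 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, gmax = gmax, erev = erev),
            class = "ca1_syn")
}

# peak-normalization factor and time of peak
syn_norm <- function(syn) {
  tp <- syn_peak_time(syn)
  1 / (exp(-tp / syn$tau2) - exp(-tp / syn$tau1))
}

#' Time of peak conductance of a double-exponential synapse
#' @param syn a \code{ca1_syn}.
#' @return peak time (ms): \code{tau1*tau2/(tau2-tau1) * log(tau2/tau1)}.
#' @export
syn_peak_time <- function(syn)
  syn$tau1 * syn$tau2 / (syn$tau2 - syn$tau1) * log(syn$tau2 / syn$tau1)

#' Conductance waveform of a double-exponential synapse
#'
#' \code{g(t) = gmax * N * (exp(-t/tau2) - exp(-t/tau1))} with N chosen so
#' the maximum equals \code{gmax}.
#'
#' @param syn a \code{ca1_syn}.
#' @param t times since the presynaptic event (ms, >= 0).
#' @return conductance values (nS).
#' @export
conductance_waveform <- function(syn, t) {
  stopifnot(all(t >= 0))
  syn$gmax * syn_norm(syn) * (exp(-t / syn$tau2) - exp(-t / syn$tau1))
}

#' Synaptic charge transfer
#'
#' Time integral of the synaptic current \code{g(t) * driving_force}. For an
#' infinite horizon the closed form is
#' \code{gmax * N * (tau2 - tau1) * driving_force}.
#'
#' @param syn a \code{ca1_syn}.
#' @param driving_force holding potential minus reversal potential (mV).
#' @param horizon integration horizon (ms), default infinite.
#' @return charge in pC.
#' @export
synaptic_charge <- function(syn, driving_force, horizon = Inf) {
  N <- syn_norm(syn)
  q <- if (is.infinite(horizon)) {
    syn$gmax * N * (syn$tau2 - syn$tau1) * driving_force
  } else {
    syn$gmax * N * (syn$tau2 * (1 - exp(-horizon / syn$tau2)) -
                    syn$tau1 * (1 - exp(-horizon / syn$tau1))) * driving_force
  }
  q / 1000    # nS*ms*mV = fC -> pC
}

#' Conductance scale factor equating GABA-A and GABA-B charge transfer
#'
#' Returns the factor k such that the GABA-A component scaled by k transfers
#' the same total charge as the GABA-B component, with driving forces
#' evaluated at a common reference potential (each component keeps its own
#' reversal potential).
#'
#' @param gabaa,gabab \code{ca1_syn} parameter lists.
#' @param reference_mv membrane potential at which driving forces are
#'   evaluated (default -63 mV, the pyramidal resting potential).
#' @return scale factor k (dimensionless).
#' @export
charge_match_scale <- function(gabaa, gabab, reference_mv = -63) {
  qa <- abs(synaptic_charge(gabaa, reference_mv - gabaa$erev))
  qb <- abs(synaptic_charge(gabab, reference_mv - gabab$erev))
  if (qa == 0) stop("GABA-A component transfers zero charge", call. = FALSE)
  qb / qa
}

#' Packaged neurogliaform output synapse (mixed GABA-A/GABA-B)
#'
#' @param config a \code{ca1_config}.
#' @param post postsynaptic type (default pyramidal); sets the per-connection
#'   synapse count.
#' @return list with components \code{gabaa} and \code{gabab}
#'   (\code{ca1_syn} each, per-connection conductances).
#' @export
ngf_synapse <- function(config = default_config(), post = "pyr") {
  ch <- config$channels
  a <- ch[ch$name == config$channel_of[["ngf"]], ]
  b <- ch[ch$name == config$gabab$channel, ]
  nsyn <- max(1, config$syn_per_conn["ngf", post])
  g <- config$weights["ngf", post] * nsyn
  list(gabaa = syn_params(a$tau1, a$tau2, g, a$erev),
       gabab = syn_params(b$tau1, b$tau2, g * config$gabab$g_ratio, b$erev))
}

#' Simulated paired recording
#'
#' Triggers a presynaptic spike and measures the postsynaptic current under
#' ideal voltage clamp: \code{I(t) = g(t) * (V_hold - E_rev)} summed over the
#' connection's synapses (and over the GABA-B component for mixed
#' neurogliaform synapses). Trial-to-trial variability enters through
#' re-sampling of the synaptic contact zone, whose dendritic-filtering factor
#' scales the conductance.
#'
#' @param pre,post cell type names (the pair must be connectable), or pass
#'   \code{syn} to measure an explicit synapse.
#' @param config a \code{ca1_config}.
#' @param hold holding potential (mV), default -50.
#' @param trials number of repeated recordings, default 10.
#' @param seed RNG seed for zone resampling.
#' @param syn optional \code{ca1_syn} (or list of them) measured directly,
#'   bypassing the configuration and zone jitter.
#' @param t_max,dt trace length and sampling step (ms).
#' @return an object of class \code{ca1_psc}: \code{amplitude_pa} (signed
#'   peak), \code{rise_ms} (10-90\%), \code{decay_ms} (exponential fit),
#'   \code{trials}, and the averaged \code{trace} (data.frame t, I).
#' @export
paired_recording <- function(pre = NULL, post = NULL,
                             config = default_config(), hold = -50,
                             trials = 10, seed = 1, syn = NULL,
                             t_max = 1000, dt = 0.1) {
  t <- seq(0, t_max, by = dt)
  if (is.null(syn)) {
    if (config$budgets[pre, post] <= 0)
      stop("undeclared projection: ", pre, " -> ", post, call. = FALSE)
    ch <- config$channels
    a <- ch[ch$name == config$channel_of[[pre]], ]
    nsyn <- max(1, config$syn_per_conn[pre, post])
    g <- config$weights[pre, post] * nsyn
    comps <- list(syn_params(a$tau1, a$tau2, g, a$erev))
    if (identical(pre, "ngf") && post %in% config$gabab$targets) {
      b <- ch[ch$name == config$gabab$channel, ]
      comps <- c(comps, list(syn_params(b$tau1, b$tau2,
                                        g * config$gabab$g_ratio, b$erev)))
    }
    zones <- assign_compartment_zone(pre, post, config, trials, seed = seed)
    factors <- ZONE_FACTOR[zones]
  } else {
    comps <- if (inherits(syn, "ca1_syn")) list(syn) else syn
    factors <- rep(1, trials)
  }
  I <- matrix(0, length(t), trials)
  for (k in seq_len(trials))
    for (cm in comps)
      I[, k] <- I[, k] + factors[k] *
        conductance_waveform(cm, t) * (hold - cm$erev)
  avg <- rowMeans(I)
  ipk <- which.max(abs(avg))
  amp <- avg[ipk]
  # 10-90% rise on the rising limb, exponential fit on the decay
  rise <- {
    up <- abs(avg[seq_len(ipk)])
    t10 <- t[which(up >= 0.1 * abs(amp))[1]]
    t90 <- t[which(up >= 0.9 * abs(amp))[1]]
    t90 - t10
  }
  dec <- {
    post_i <- seq(ipk, length(t))
    y <- abs(avg[post_i])
    keep <- y > 0.05 * abs(amp)
    if (sum(keep) > 3) {
      fit <- lm(log(y[keep]) ~ t[post_i][keep])
      -1 / coef(fit)[[2]]
    } else NA_real_
  }
  structure(list(amplitude_pa = amp, rise_ms = rise, decay_ms = dec,
                 trials = trials, trace = data.frame(t = t, I = avg)),
            class = "ca1_psc")
}

#' @export
print.ca1_psc <- function(x, ...) {
  cat(sprintf("PSC: peak %.2f pA | 10-90%% rise %.2f ms | decay tau %.1f ms | %d trials\n",
              x$amplitude_pa, x$rise_ms, x$decay_ms, x$trials))
  invisible(x)
}
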