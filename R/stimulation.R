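# Afferent drive: Poisson and theta-modulated spike trains, and the
# afferent-arithmetic estimates of spikes per theta cycle.

#' Independent homogeneous Poisson spike trains
#'
#' One independent homogeneous Poisson process per afferent unit,
#' reproducible by seed.
#'
#' @param n_units number of stimulating units.
#' @param rate_hz mean firing rate (Hz, >= 0).
#' @param duration_ms train duration (ms).
#' @param seed integer RNG seed.
#' @return an object of class \code{ca1_trains}: list with \code{n_units},
#'   \code{duration_ms}, \code{rate_hz}, \code{seed} and \code{spikes}
#'   (data.frame \code{unit}, \code{time_ms}, times strictly increasing per
#'   unit).
#' @export
poisson_trains <- function(n_units, rate_hz, duration_ms, seed = 1) {
  if (rate_hz < 0) stop("rate must be >= 0", call. = FALSE)
  sp <- with_seed(seed, {
    counts <- stats::rpois(n_units, rate_hz * duration_ms / 1000)
    unit <- rep(seq_len(n_units), counts)
    time <- runif(sum(counts)) * duration_ms
    df <- data.frame(unit = unit, time_ms = time)
    df[order(df$unit, df$time_ms), , drop = FALSE]
  })
  rownames(sp) <- NULL
  structure(list(n_units = n_units, duration_ms = duration_ms,
                 rate_hz = rate_hz, seed = seed, spikes = sp),
            class = "ca1_trains")
}

#' @export
print.ca1_trains <- function(x, ...) {
  cat("Spike train set: ", x$n_units, " units, ",
      nrow(x$spikes), " spikes over ", x$duration_ms, " ms\n", sep = "")
  invisible(x)
}

#' Afferent spikes per theta cycle
#'
#' Number of incoming spikes delivered to the network per theta cycle by
#' \code{n_afferents} units firing at \code{rate_hz}, given the theta
#' frequency: \code{n * rate / theta}, rounded to the nearest integer.
#'
#' @param n_afferents number of stimulating units.
#' @param rate_hz mean unit firing rate (Hz).
#' @param theta_hz theta frequency (Hz, > 0).
#' @return spikes per cycle (integer-rounded).
#' @export
spikes_per_theta_cycle <- function(n_afferents, rate_hz, theta_hz) {
  if (theta_hz <= 0) stop("theta frequency must be positive", call. = FALSE)
  round(n_afferents * rate_hz / theta_hz)
}

#' Estimated afferent spikes per theta cycle from an upstream region
#'
#' \code{n_cells * active_fraction * spikes_per_active}, rounded: the number
#' of spikes an upstream population (e.g. ipsilateral CA3 or entorhinal
#' layer III) contributes per theta cycle.
#'
#' @param n_cells upstream population size.
#' @param active_fraction fraction of cells active per cycle (in [0, 1]).
#' @param spikes_per_active spikes fired by each active cell per cycle.
#' @return estimated spikes per cycle (integer-rounded).
#' @export
afferent_drive_estimate <- function(n_cells, active_fraction,
                                    spikes_per_active) {
  if (active_fraction < 0 || active_fraction > 1)
    stop("active_fraction must lie in [0, 1]", call. = FALSE)
  round(n_cells * active_fraction * spikes_per_active)
}

#' Theta-phase-locked spike trains
#'
#' Inhomogeneous Poisson trains with a von Mises intensity profile around a
#' preferred phase of an ideal theta oscillator (trough = 0 degrees), with
#' time-averaged rate equal to \code{mean_rate}. Generated by thinning.
#'
#' @param n_units number of units.
#' @param mean_rate time-averaged rate per unit (Hz).
#' @param theta_hz theta frequency (Hz).
#' @param kappa von Mises concentration (>= 0; 0 gives homogeneous Poisson).
#' @param preferred_phase_deg preferred firing phase (degrees, trough = 0).
#' @param duration_ms duration (ms).
#' @param seed integer RNG seed.
#' @return a \code{ca1_trains} object.
#' @export
phase_locked_trains <- function(n_units, mean_rate, theta_hz, kappa,
                                preferred_phase_deg, duration_ms, seed = 1) {
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  lam_max <- mean_rate * exp(kappa) / besselI(kappa, 0)
  phi <- preferred_phase_deg * pi / 180
  sp <- with_seed(seed, {
    base <- {
      counts <- stats::rpois(n_units, lam_max * duration_ms / 1000)
      data.frame(unit = rep(seq_len(n_units), counts),
                 time_ms = runif(sum(counts)) * duration_ms)
    }
    phase <- 2 * pi * theta_hz * base$time_ms / 1000  # trough at phase 0
    lam <- mean_rate * exp(kappa * cos(phase - phi)) / besselI(kappa, 0)
    keep <- runif(nrow(base)) < lam / lam_max
    df <- base[keep, , drop = FALSE]
    df[order(df$unit, df$time_ms), , drop = FALSE]
  })
  rownames(sp) <- NULL
  structure(list(n_units = n_units, duration_ms = duration_ms,
                 rate_hz = mean_rate, theta_hz = theta_hz, kappa = kappa,
                 preferred_phase_deg = preferred_phase_deg, seed = seed,
                 spikes = sp),
            class = "ca1_trains")
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
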