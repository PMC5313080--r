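# LFP analog and the oscillation-analysis pipeline: spike density function,
# Welch periodogram, spectrogram, zero-phase band filtering, trough-referenced
# spike phases, Rayleigh statistics, firing rates, cross-frequency coupling.

THETA_BAND <- c(5, 10)
GAMMA_BAND <- c(25, 80)

#' Local field potential analog
#'
#' Distance-weighted sum of per-cell membrane currents at a reference
#' electrode (point-source approximation, contributions scaled in inverse
#' proportion to distance, floored at 10 um). All cells within
#' \code{inner_radius} of the electrode contribute; of the cells outside the
#' radius a random fraction \code{outer_fraction} is selected and scaled up
#' by \code{1/outer_fraction}, an unbiased estimator of the full outer sum.
#'
#' @param currents numeric matrix, one column per cell (membrane current
#'   samples at a uniform rate).
#' @param positions data.frame with \code{x}, \code{y}, \code{z} per cell
#'   (columns matching \code{currents}).
#' @param electrode numeric length-3 electrode position (um).
#' @param fs sampling rate of the current traces (Hz).
#' @param inner_radius radius of the fully-summed shell (um).
#' @param outer_fraction sampled fraction of the outer cells.
#' @param seed RNG seed for the outer sample.
#' @return an object of class \code{ca1_lfp}: list with \code{fs},
#'   \code{samples} (arbitrary units) and \code{electrode}.
#' @export
lfp_analog <- function(currents, positions, electrode, fs = 1000,
                       inner_radius = 100, outer_fraction = 0.1, seed = 1) {
  stopifnot(ncol(currents) == nrow(positions))
  if (ncol(currents) == 0)
    return(structure(list(fs = fs, samples = rep(0, nrow(currents)),
                          electrode = electrode), class = "ca1_lfp"))
  d <- sqrt((positions$x - electrode[1])^2 + (positions$y - electrode[2])^2 +
            (positions$z - electrode[3])^2)
  w <- 1 / pmax(d, 10)
  inner <- d <= inner_radius
  outer_idx <- which(!inner)
  pick <- with_seed(seed,
    sort(sample(outer_idx, size = round(outer_fraction * length(outer_idx)))))
  wfull <- numeric(length(d))
  wfull[inner] <- w[inner]
  wfull[pick] <- w[pick] / outer_fraction
  structure(list(fs = fs, samples = as.numeric(currents %*% wfull),
                 electrode = electrode), class = "ca1_lfp")
}

# per-cell electrode weights (same scheme), used by the engine's online
# LFP recorder
lfp_weights <- function(positions, electrode, inner_radius = 100,
                        outer_fraction = 0.1, seed = 1) {
  d <- sqrt((positions$x - electrode[1])^2 + (positions$y - electrode[2])^2 +
            (positions$z - electrode[3])^2)
  w <- numeric(length(d))
  inner <- d <= inner_radius
  w[inner] <- 1 / pmax(d[inner], 10)
  outer_idx <- which(!inner)
  if (length(outer_idx) && outer_fraction > 0) {
    pick <- with_seed(seed, sort(sample(outer_idx,
      size = round(outer_fraction * length(outer_idx)))))
    w[pick] <- 1 / pmax(d[pick], 10) / outer_fraction
  }
  w
}

#' Spike density function
#'
#' Continuous firing-rate estimate: spike times are binned (1 ms default)
#' and convolved with a unit-mass Gaussian kernel (SD 3 ms, truncated at
#' 3 SD). Kernel mass falling outside the recording is folded back per
#' spike (edge correction), so the time integral of the series equals the
#' spike count.
#'
#' @param spike_times spike times (ms).
#' @param duration recording duration (ms).
#' @param bin bin width (ms).
#' @param kernel_sd Gaussian kernel standard deviation (ms).
#' @return list with \code{t} (bin centers, ms), \code{rate} (spikes/s) and
#'   \code{fs} (samples per second).
#' @export
sdf <- function(spike_times, duration, bin = 1, kernel_sd = 3) {
  stopifnot(duration > 0)
  nb <- ceiling(duration / bin)
  counts <- numeric(nb)
  if (length(spike_times)) {
    spike_times <- spike_times[spike_times >= 0 & spike_times < duration]
    half <- ceiling(3 * kernel_sd / bin)
    kt <- (-half:half) * bin
    kern <- exp(-kt^2 / (2 * kernel_sd^2))
    kern <- kern / sum(kern)
    ctr <- floor(spike_times / bin) + 1
    for (s in seq_along(ctr)) {
      lo <- ctr[s] - half; hi <- ctr[s] + half
      klo <- max(1, lo); khi <- min(nb, hi)
      kseg <- kern[(klo - lo + 1):(khi - lo + 1)]
      counts[klo:khi] <- counts[klo:khi] + kseg / sum(kseg)
    }
  }
  list(t = (seq_len(nb) - 0.5) * bin, rate = counts * 1000 / bin,
       fs = 1000 / bin)
}

#' Welch power spectral density with band-peak extraction
#'
#' One-sided Welch periodogram (Hamming window, 50\% overlap, mean removed
#' per segment), with peak frequency and power reported for the theta
#' (5-10 Hz) and gamma (25-80 Hz) bands and overall.
#'
#' @param series numeric signal.
#' @param fs sampling rate (Hz).
#' @param segment_s segment length in samples (default 1024).
#' @param overlap fractional overlap between segments.
#' @return an object of class \code{ca1_psd}: list with \code{freq},
#'   \code{power} (units^2/Hz) and \code{peaks} (data.frame band, freq,
#'   power).
#' @export
welch_psd <- function(series, fs, segment_s = 1024, overlap = 0.5) {
  n <- length(series)
  if (n < segment_s)
    stop("series shorter than one Welch segment", call. = FALSE)
  win <- signal::hamming(segment_s)
  step <- max(1, round(segment_s * (1 - overlap)))
  starts <- seq(1, n - segment_s + 1, by = step)
  nfreq <- floor(segment_s / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- series[s:(s + segment_s - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2
    acc <- acc + sp[seq_len(nfreq)]
  }
  scale <- 1 / (fs * sum(win^2) * length(starts))
  pxx <- acc * scale
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- 2:(nfreq - if (segment_s %% 2 == 0) 1 else 0)
  pxx[dbl] <- 2 * pxx[dbl]
  freq <- (seq_len(nfreq) - 1) * fs / segment_s
  band_peak <- function(b) {
    i <- which(freq >= b[1] & freq <= b[2])
    if (!length(i) || all(pxx[i] == 0))
      return(c(freq = NA_real_, power = 0))
    j <- i[which.max(pxx[i])]
    c(freq = freq[j], power = pxx[j])
  }
  pk_t <- band_peak(THETA_BAND); pk_g <- band_peak(GAMMA_BAND)
  pk_all <- band_peak(c(freq[2], max(freq)))
  peaks <- data.frame(band = c("theta", "gamma", "overall"),
                      freq = c(pk_t[1], pk_g[1], pk_all[1]),
                      power = c(pk_t[2], pk_g[2], pk_all[2]),
                      row.names = NULL)
  structure(list(freq = freq, power = pxx, peaks = peaks, fs = fs),
            class = "ca1_psd")
}

#' @export
print.ca1_psd <- function(x, ...) {
  cat("Welch PSD (", length(x$freq), " frequencies up to ",
      max(x$freq), " Hz)\n", sep = "")
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Spectrogram (sliding-window periodogram)
#'
#' @param series numeric signal.
#' @param fs sampling rate (Hz).
#' @param window_s window length (samples).
#' @param step_s hop between windows (samples).
#' @return list with \code{t} (window centers, s), \code{freq} (Hz) and
#'   \code{power} (time x frequency matrix).
#' @export
spectrogram <- function(series, fs, window_s = 512, step_s = 256) {
  n <- length(series)
  if (window_s > n) stop("window exceeds series length", call. = FALSE)
  win <- signal::hamming(window_s)
  starts <- seq(1, n - window_s + 1, by = step_s)
  nfreq <- floor(window_s / 2) + 1
  P <- matrix(0, length(starts), nfreq)
  for (k in seq_along(starts)) {
    seg <- series[starts[k]:(starts[k] + window_s - 1)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(fft(seg))^2 / (fs * sum(win^2))
    sp <- sp[seq_len(nfreq)]
    sp[-1] <- 2 * sp[-1]
    P[k, ] <- sp
  }
  list(t = (starts + window_s / 2) / fs, freq = (seq_len(nfreq) - 1) * fs /
         window_s, power = P)
}

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth band-pass applied forward and backward
#' (zero-phase), preserving in-band amplitude and peak timing.
#'
#' @param series numeric signal.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz), \code{0 < lo < hi < fs/2}.
#' @return filtered series.
#' @export
bandpass <- function(series, fs, lo, hi) {
  if (!(lo > 0 && hi > lo && hi < fs / 2))
    stop("invalid band: require 0 < lo < hi < fs/2", call. = FALSE)
  bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, series))
}

#' Convert spike times to theta phases
#'
#' Troughs of the theta-filtered LFP analog are located as local minima
#' (sign change of the first difference, minimum 50 ms separation); phase
#' advances linearly from 0 to 360 degrees between consecutive troughs
#' (trough = 0/360 convention). Spikes before the first trough, after the
#' last trough, or within the first \code{crop} ms are discarded.
#'
#' @param spike_times spike times (ms).
#' @param theta_lfp theta-filtered LFP samples.
#' @param fs sampling rate of the LFP (Hz).
#' @param crop initial segment to discard (ms).
#' @return numeric vector of phases in [0, 360).
#' @export
spike_phases <- function(spike_times, theta_lfp, fs = 1000, crop = 50) {
  troughs <- find_troughs(theta_lfp, fs)
  if (length(troughs) < 2) stop("no theta troughs found", call. = FALSE)
  tt <- (troughs - 1) / fs * 1000    # ms
  spike_times <- spike_times[spike_times >= crop &
                             spike_times >= tt[1] &
                             spike_times <= tt[length(tt)]]
  if (!length(spike_times)) return(numeric(0))
  cyc <- findInterval(spike_times, tt, rightmost.closed = TRUE)
  cyc[cyc >= length(tt)] <- length(tt) - 1
  ph <- 360 * (spike_times - tt[cyc]) / (tt[cyc + 1] - tt[cyc])
  ph %% 360
}

# local minima with minimum separation (in ms)
find_troughs <- function(x, fs, min_sep_ms = 50) {
  d <- diff(x)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1
  if (!length(cand)) return(integer(0))
  min_sep <- min_sep_ms / 1000 * fs
  keep <- cand[1]
  for (i in cand[-1]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
    else if (x[i] < x[keep[length(keep)]]) keep[length(keep)] <- i
  }
  keep
}

#' Circular statistics of spike phases
#'
#' Circular mean, resultant vector length r and the Rayleigh test of
#' nonuniformity (the level of theta modulation).
#'
#' @param phases phases in degrees.
#' @return an object of class \code{ca1_phase_stats}: \code{mean_deg},
#'   \code{r}, \code{p} (Rayleigh), \code{n}.
#' @export
phase_stats <- function(phases) {
  n <- length(phases)
  if (n == 0) stop("no phases supplied", call. = FALSE)
  th <- phases * pi / 180
  C <- sum(cos(th)); S <- sum(sin(th))
  r <- sqrt(C^2 + S^2) / n
  mu <- (atan2(S, C) * 180 / pi) %% 360
  R <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(list(mean_deg = mu, r = r, p = min(1, p), n = n),
            class = "ca1_phase_stats")
}

#' @export
print.ca1_phase_stats <- function(x, ...) {
  cat(sprintf("phase %.1f deg (trough = 0) | r = %.3f | Rayleigh p = %.3g | n = %d\n",
              x$mean_deg, x$r, x$p, x$n))
  invisible(x)
}

#' Firing rates per population
#'
#' Two definitions: total spikes (after cropping the initial transient)
#' divided by all cells and by duration; and the same count divided by the
#' number of active cells (cells with at least one spike after the crop).
#'
#' @param spike_ids cell ids, one per spike.
#' @param spike_times spike times (ms), parallel to \code{spike_ids}.
#' @param n_total number of cells in the population.
#' @param duration recording duration (ms).
#' @param crop initial segment to discard (ms).
#' @return list with \code{rate_all} (Hz), \code{rate_active} (Hz, \code{NA}
#'   when no cell is active) and \code{n_active}.
#' @export
firing_rates <- function(spike_ids, spike_times, n_total, duration,
                         crop = 50) {
  stopifnot(duration > crop)
  keep <- spike_times >= crop
  nsp <- sum(keep)
  n_active <- length(unique(spike_ids[keep]))
  eff_s <- (duration - crop) / 1000
  list(rate_all = if (n_total > 0) nsp / n_total / eff_s else 0,
       rate_active = if (n_active > 0) nsp / n_active / eff_s else NA_real_,
       n_active = n_active)
}

# FFT-based analytic signal (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Theta-gamma cross-frequency coupling
#'
#' Filters the signal in the theta and gamma bands, takes the Hilbert
#' transform of each, and averages the gamma envelope within 20-degree bins
#' of the theta phase (trough = 0/360 convention). Reports the profile and
#' the phase of maximal gamma envelope.
#'
#' @param lfp a \code{ca1_lfp} or numeric vector.
#' @param fs sampling rate (Hz; taken from the \code{ca1_lfp} if supplied).
#' @param theta_band,gamma_band band edges (Hz).
#' @param bin_deg theta-phase bin width (degrees).
#' @return list with \code{phase_deg} (bin centers), \code{envelope} (mean
#'   gamma envelope per bin) and \code{peak_phase_deg}.
#' @export
cross_frequency_coupling <- function(lfp, fs = NULL,
                                     theta_band = THETA_BAND,
                                     gamma_band = GAMMA_BAND, bin_deg = 20) {
  if (inherits(lfp, "ca1_lfp")) { fs <- lfp$fs; x <- lfp$samples }
  else x <- as.numeric(lfp)
  th <- bandpass(x, fs, theta_band[1], theta_band[2])
  gm <- bandpass(x, fs, gamma_band[1], gamma_band[2])
  # analytic phase is 0 at the peak of a cosine; shift so trough = 0
  phase <- (Arg(analytic_signal(th)) * 180 / pi + 180) %% 360
  env <- Mod(analytic_signal(gm))
  bins <- floor(phase / bin_deg) + 1
  nb <- 360 / bin_deg
  prof <- vapply(seq_len(nb), function(b) {
    i <- bins == b
    if (any(i)) mean(env[i]) else 0
  }, numeric(1))
  centers <- (seq_len(nb) - 0.5) * bin_deg
  list(phase_deg = centers, envelope = prof,
       peak_phase_deg = centers[which.max(prof)])
}
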