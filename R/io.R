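# File formats: spike raster TSV, edge-list CSV, run manifests.

#' Write / read a spike raster
#'
#' Tab-separated \code{gid<TAB>time_ms} records (times written to
#' microsecond precision), the universal exchange format between the engine,
#' the stimulus generators and the analysis pipeline.
#'
#' @param x a \code{ca1_sim}, \code{ca1_trains} or data.frame with columns
#'   \code{gid} (or \code{unit}) and \code{time_ms}.
#' @param path file path.
#' @return \code{path} invisibly (writer); data.frame \code{gid},
#'   \code{time_ms} (reader).
#' @export
write_raster <- function(x, path) {
  df <- raster_frame(x)
  write.table(data.frame(gid = df$gid, time_ms = sprintf("%.3f", df$time_ms)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("integer", "numeric"))
  if (!identical(names(df), c("gid", "time_ms")))
    stop("malformed raster file (expected header gid, time_ms): ", path,
         call. = FALSE)
  df
}

raster_frame <- function(x) {
  if (inherits(x, "ca1_sim")) return(x$spikes[, c("gid", "time_ms")])
  if (inherits(x, "ca1_trains"))
    return(data.frame(gid = x$spikes$unit, time_ms = x$spikes$time_ms))
  if (is.data.frame(x)) {
    if ("unit" %in% names(x) && !("gid" %in% names(x)))
      return(data.frame(gid = x$unit, time_ms = x$time_ms))
    return(x[, c("gid", "time_ms")])
  }
  stop("cannot interpret object as a spike raster", call. = FALSE)
}

EDGE_COLS <- c("pre_gid", "post_gid", "n_syn", "dist_um", "zone", "weight",
               "delay_ms")

#' Write / read an edge list
#'
#' CSV with fixed header
#' \code{pre_gid,post_gid,n_syn,dist_um,zone,weight,delay_ms}.
#'
#' @param x a \code{ca1_network} or edge-list data.frame.
#' @param path file path.
#' @return \code{path} invisibly (writer); edge data.frame (reader).
#' @export
write_edges <- function(x, path) {
  e <- if (inherits(x, "ca1_network")) x$edges else x
  out <- e[, EDGE_COLS]
  out$dist_um <- round(out$dist_um, 3)
  out$delay_ms <- round(out$delay_ms, 4)
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), EDGE_COLS))
    stop("malformed edge file (header mismatch): ", path, call. = FALSE)
  df
}

#' Run manifest
#'
#' All parameters needed to reproduce a run: configuration digest, seeds,
#' scale, perturbation, tool version and timestamp.
#'
#' @param network a \code{ca1_network}.
#' @param sim a \code{ca1_sim} (optional).
#' @param perturbation a \code{ca1_perturbation} (optional).
#' @param path if given, the manifest is written there as JSON.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(network, sim = NULL, perturbation = NULL,
                         path = NULL) {
  m <- list(
    config_digest = digest_of(network$config),
    build_seed = network$seed,
    scale = network$config$scale %||% list(fraction = 1, mode = "full"),
    perturbation = if (!is.null(perturbation)) unclass(perturbation),
    sim = if (!is.null(sim)) list(duration = sim$duration, dt = sim$dt,
                                  seed = sim$seed),
    version = as.character(packageVersion("ca1net")),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    return(invisible(m))
  }
  m
}

#' Check a manifest against a network
#'
#' Recomputes the configuration digest and compares it with the stored one.
#'
#' @param manifest manifest list (or path to a manifest JSON).
#' @param network the \code{ca1_network} to verify.
#' @return TRUE if the digests match.
#' @export
verify_manifest <- function(manifest, network) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  identical(manifest$config_digest[[1]], digest_of(network$config))
}

#' Write a power spectral density as CSV
#' @param psd a \code{ca1_psd}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_psd <- function(psd, path) {
  write.table(data.frame(freq_hz = psd$freq, power = psd$power), path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-type phase-statistics report
#'
#' One row per cell type: firing rate (all cells), resultant length r,
#' Rayleigh p and preferred phase (trough = 0/360).
#'
#' @param sim a \code{ca1_sim} with an LFP recording, or a raster data.frame.
#' @param theta_lfp theta-filtered LFP samples (computed from
#'   \code{sim$lfp} when omitted).
#' @param config the network configuration (per-type cell counts).
#' @param fs LFP sampling rate (Hz).
#' @param path optional CSV output path.
#' @return data.frame with columns \code{type}, \code{rate_hz}, \code{r},
#'   \code{p}, \code{phase_deg}, \code{n_spikes}.
#' @export
phase_report <- function(sim, config, theta_lfp = NULL, fs = 1000,
                         path = NULL) {
  if (is.null(theta_lfp)) {
    if (is.null(sim$lfp)) stop("no LFP available", call. = FALSE)
    fs <- sim$lfp$fs
    theta_lfp <- bandpass(sim$lfp$samples, fs, THETA_BAND[1], THETA_BAND[2])
  }
  rows <- lapply(config$cell_types$name, function(ty) {
    sel <- sim$spikes$type == ty
    n_cells <- config$cell_types$count[config$cell_types$name == ty]
    fr <- firing_rates(sim$spikes$gid[sel], sim$spikes$time_ms[sel],
                       n_cells, sim$duration)
    ph <- spike_phases(sim$spikes$time_ms[sel], theta_lfp, fs)
    st <- if (length(ph)) phase_stats(ph) else
      list(mean_deg = NA_real_, r = NA_real_, p = NA_real_, n = 0L)
    data.frame(type = ty, rate_hz = fr$rate_all, r = st$r, p = st$p,
               phase_deg = st$mean_deg, n_spikes = st$n)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path))
    write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  out
}

#' Export current-sweep voltage traces
#'
#' Runs the characterization sweep on a neuron model and writes each trace
#' as tab-delimited time/voltage columns (time_ms, then one column per
#' injection current).
#'
#' @param params neuron parameter list.
#' @param path output file path.
#' @param sweep injection currents (pA); default per
#'   \code{\link{sweep_currents}}.
#' @param duration step duration (ms).
#' @param dt integration step (ms).
#' @return \code{path}, invisibly.
#' @export
write_sweep_traces <- function(params, path, sweep = NULL, duration = 1000,
                               dt = 0.025) {
  if (is.null(sweep)) sweep <- sweep_currents(params$name %||% "generic")
  traces <- lapply(sweep, function(I)
    membrane_step(params, I, duration, dt = dt)$V)
  out <- data.frame(time_ms = seq(0, by = dt,
                                  length.out = length(traces[[1]])))
  for (i in seq_along(sweep))
    out[[sprintf("pA_%g", sweep[i])]] <- traces[[i]]
  write.table(format(out, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
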