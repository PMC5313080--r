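#' @useDynLib ca1net, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm rexp runif approx coef lm median sd var fft aov
#' @importFrom utils head tail read.table write.table packageVersion
NULL

# Laminar labels used throughout (stacked from the base of stratum oriens).
LAYERS <- c("SO", "SP", "SR", "SLM")

# Compartment zone labels for synapse placement on the postsynaptic cell.
ZONES <- c("AIS", "soma", "proximal_dendrite_SO", "proximal_dendrite_SR",
           "distal_dendrite_SLM", "basal_dendrite")

#' Default full-scale CA1 network configuration
#'
#' Builds the packaged full-scale parameterization of the CA1 microcircuit:
#' 311,500 pyramidal cells plus eight interneuron classes (27,240
#' interneurons, 338,740 cells in total), 454,700 afferent stimulating units
#' (204,700 CA3 + 250,000 entorhinal layer-III), the pairwise synapse-count
#' budget matrix, axonal bouton-distance profiles, synapse kinetics and the
#' reduced neuron parameter table.
#'
#' Prism dimensions, per-layer heights, axonal Gaussian parameters,
#' synapses-per-connection values and unitary conductances are documented
#' estimates (they are configurable; see the methods vignette).
#'
#' @param seed integer; global seed recorded in the configuration.
#' @return an object of class \code{ca1_config}.
#' @export
default_config <- function(seed = 1L) {
  path <- system.file("extdata", "ca1_full.yaml", package = "ca1net")
  load_config(path, seed = seed)
}

#' Load and validate a network configuration
#'
#' Reads a structured-text (YAML) configuration file describing cell types,
#' layer geometry, synapse budgets, axonal profiles, afferents and neuron /
#' synapse parameters, cross-checks all references and returns a validated
#' \code{ca1_config}.
#'
#' @param path path to a YAML configuration file.
#' @param seed optional integer overriding the seed stored in the file.
#' @return an object of class \code{ca1_config}.
#' @export
load_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  cfg <- config_from_list(raw)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
}

#' Write a configuration back to structured text
#' @param config a \code{ca1_config}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ca1_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_from_list <- function(raw) {
  ct <- do.call(rbind, lapply(raw$cell_types, function(x)
    data.frame(name = x$name, count = as.numeric(x$count), layer = x$layer,
               is_principal = isTRUE(x$is_principal),
               stringsAsFactors = FALSE)))
  af <- do.call(rbind, lapply(raw$afferents, function(x)
    data.frame(name = x$name, count = as.numeric(x$count), layer = x$layer,
               stringsAsFactors = FALSE)))
  pre_names  <- c(ct$name, af$name)
  post_names <- ct$name
  mat_of <- function(field) {
    m <- matrix(0, length(pre_names), length(post_names),
                dimnames = list(pre_names, post_names))
    for (pre in names(raw[[field]])) {
      row <- raw[[field]][[pre]]
      for (post in names(row)) m[pre, post] <- as.numeric(row[[post]])
    }
    m
  }
  ax <- do.call(rbind, lapply(raw$axonal_profiles, function(x)
    data.frame(name = x$name, mean_um = x$mean_um, sd_um = x$sd_um,
               extent_um = x$extent_um, bin_um = x$bin_um,
               stringsAsFactors = FALSE)))
  zones <- lapply(raw$zones, function(x) unlist(x))
  np <- do.call(rbind, lapply(raw$neuron_params, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  ch <- do.call(rbind, lapply(raw$channels, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  structure(list(
    cell_types = ct, afferents = af,
    geometry = list(
      longitudinal_um = raw$geometry$longitudinal_um,
      transverse_um   = raw$geometry$transverse_um,
      layer_bounds    = lapply(raw$geometry$layer_bounds, unlist)),
    budgets      = mat_of("budgets"),
    syn_per_conn = mat_of("syn_per_conn"),
    weights      = mat_of("weights"),
    axonal       = ax,
    zones        = zones,
    neuron_params = np,
    channels     = ch,
    channel_of   = unlist(raw$channel_of),
    gabab        = raw$gabab,
    delay        = raw$delay,
    stim         = raw$stim,
    electrode    = unlist(raw$electrode),
    seed         = as.integer(raw$seed %||% 1L)
  ), class = "ca1_config")
}

config_to_list <- function(cfg) {
  mat_list <- function(m) {
    out <- list()
    for (pre in rownames(m)) {
      nz <- which(m[pre, ] != 0)
      if (length(nz))
        out[[pre]] <- stats::setNames(as.list(m[pre, nz]), colnames(m)[nz])
    }
    out
  }
  list(
    cell_types = lapply(seq_len(nrow(cfg$cell_types)), function(i)
      as.list(cfg$cell_types[i, ])),
    afferents = lapply(seq_len(nrow(cfg$afferents)), function(i)
      as.list(cfg$afferents[i, ])),
    geometry = list(longitudinal_um = cfg$geometry$longitudinal_um,
                    transverse_um = cfg$geometry$transverse_um,
                    layer_bounds = lapply(cfg$geometry$layer_bounds, as.list)),
    budgets = mat_list(cfg$budgets),
    syn_per_conn = mat_list(cfg$syn_per_conn),
    weights = mat_list(cfg$weights),
    axonal_profiles = lapply(seq_len(nrow(cfg$axonal)), function(i)
      as.list(cfg$axonal[i, ])),
    zones = lapply(cfg$zones, as.list),
    neuron_params = lapply(seq_len(nrow(cfg$neuron_params)), function(i)
      as.list(cfg$neuron_params[i, ])),
    channels = lapply(seq_len(nrow(cfg$channels)), function(i)
      as.list(cfg$channels[i, ])),
    channel_of = as.list(cfg$channel_of),
    gabab = cfg$gabab, delay = cfg$delay, stim = cfg$stim,
    electrode = as.list(cfg$electrode), seed = cfg$seed)
}

validate_config <- function(cfg) {
  ct <- cfg$cell_types
  if (is.null(ct) || nrow(ct) == 0)
    stop("configuration declares no cell types", call. = FALSE)
  if (any(ct$count < 0))
    stop("negative cell count for type: ",
         paste(ct$name[ct$count < 0], collapse = ", "), call. = FALSE)
  if (anyDuplicated(ct$name))
    stop("duplicated cell type name", call. = FALSE)
  bad <- setdiff(ct$layer, LAYERS)
  if (length(bad))
    stop("unknown layer label: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(cfg$afferents$count < 0))
    stop("negative afferent count", call. = FALSE)
  lb <- cfg$geometry$layer_bounds
  if (cfg$geometry$longitudinal_um <= 0 || cfg$geometry$transverse_um <= 0)
    stop("prism extents must be positive", call. = FALSE)
  ord <- LAYERS[LAYERS %in% names(lb)]
  hi_prev <- -Inf
  for (l in ord) {
    b <- lb[[l]]
    if (b[2] <= b[1]) stop("empty layer bounds for ", l, call. = FALSE)
    if (b[1] < hi_prev)
      stop("overlapping layer bounds at ", l, call. = FALSE)
    hi_prev <- b[2]
  }
  known <- c(ct$name, cfg$afferents$name)
  bad <- setdiff(rownames(cfg$budgets), known)
  if (length(bad))
    stop("unknown cell type in budget matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(colnames(cfg$budgets), ct$name)
  if (length(bad))
    stop("unknown postsynaptic type in budget matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(cfg$budgets < 0))
    stop("negative synapse budget", call. = FALSE)
  spc <- cfg$syn_per_conn[cfg$budgets > 0]
  if (any(spc < 1 | spc > 10))
    stop("synapses-per-connection must lie in [1,10]", call. = FALSE)
  bad <- setdiff(rownames(cfg$budgets)[rowSums(cfg$budgets) > 0],
                 cfg$axonal$name)
  if (length(bad))
    stop("missing axonal profile for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(cfg$axonal$sd_um <= 0) || any(cfg$axonal$extent_um <= 0) ||
      any(cfg$axonal$bin_um <= 0))
    stop("axonal profile parameters must be positive", call. = FALSE)
  cfg
}

#' Census of a network configuration
#'
#' Totals over the configuration: all cells, principal cells, interneurons
#' (the sum over non-principal types), afferent stimulating units and the
#' per-type counts. The census is a pure function of the configuration.
#'
#' @param config a \code{ca1_config}.
#' @return an object of class \code{ca1_census}: a list with elements
#'   \code{total}, \code{principal}, \code{interneurons}, \code{afferent},
#'   and \code{per_type} (named vector).
#' @export
census <- function(config) {
  stopifnot(inherits(config, "ca1_config"))
  ct <- config$cell_types
  per <- stats::setNames(ct$count, ct$name)
  structure(list(
    total        = sum(ct$count),
    principal    = sum(ct$count[ct$is_principal]),
    interneurons = sum(ct$count[!ct$is_principal]),
    afferent     = sum(config$afferents$count),
    per_type     = per
  ), class = "ca1_census")
}

#' @export
print.ca1_census <- function(x, ...) {
  cat("total\t", format(x$total, big.mark = ","), "\n", sep = "")
  cat("principal\t", format(x$principal, big.mark = ","), "\n", sep = "")
  cat("interneurons\t", format(x$interneurons, big.mark = ","), "\n", sep = "")
  cat("afferent\t", format(x$afferent, big.mark = ","), "\n", sep = "")
  for (n in names(x$per_type))
    cat(n, "\t", format(x$per_type[[n]], big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Rescale a network configuration
#'
#' Multiplies all cell (and afferent) counts by \code{fraction} and rescales
#' the synapse budgets under one of two regimes. With
#' \code{mode = "preserve_convergence"} the per-cell in-degree is kept:
#' budgets scale by \code{fraction} and unitary weights are unchanged. With
#' \code{mode = "preserve_probability"} (the default) the pairwise connection
#' probability is kept: budgets scale by \code{fraction^2} and per-connection
#' weights are multiplied by \code{1/fraction} so that the expected total
#' synaptic drive per cell is conserved.
#'
#' Counts are rounded half-up per type (types with a nonzero full-scale count
#' keep at least one cell), then the total is fixed up by adjusting the most
#' numerous type.
#'
#' @param config a \code{ca1_config}.
#' @param fraction scale fraction in (0, 1].
#' @param mode \code{"preserve_probability"} or \code{"preserve_convergence"}.
#' @return a rescaled \code{ca1_config}.
#' @export
scale_config <- function(config, fraction,
                         mode = c("preserve_probability",
                                  "preserve_convergence")) {
  stopifnot(inherits(config, "ca1_config"))
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  if (fraction == 1) return(config)
  round_half_up <- function(x) floor(x + 0.5)
  scale_counts <- function(counts) {
    sc <- round_half_up(counts * fraction)
    sc[counts > 0 & sc < 1] <- 1
    # fix the total by adjusting the largest type
    target <- round_half_up(sum(counts) * fraction)
    i <- which.max(counts)
    sc[i] <- max(1, sc[i] + (target - sum(sc)))
    sc
  }
  cfg <- config
  cfg$cell_types$count <- scale_counts(config$cell_types$count)
  cfg$afferents$count  <- scale_counts(config$afferents$count)
  if (mode == "preserve_convergence") {
    cfg$budgets <- config$budgets * fraction
  } else {
    cfg$budgets <- config$budgets * fraction^2
    cfg$weights <- config$weights / fraction
  }
  cfg$scale <- list(fraction = fraction, mode = mode)
  cfg
}

#' @export
print.ca1_config <- function(x, ...) {
  cz <- census(x)
  cat("CA1 network configuration: ", nrow(x$cell_types), " cell types, ",
      format(cz$total, big.mark = ","), " cells (",
      format(cz$principal, big.mark = ","), " principal), ",
      format(cz$afferent, big.mark = ","), " afferent units\n", sep = "")
  if (!is.null(x$scale))
    cat("scaled: fraction ", x$scale$fraction, " (", x$scale$mode, ")\n",
        sep = "")
  invisible(x)
}

#' Configured divergence of a projection
#'
#' Number of postsynaptic targets contacted by one presynaptic cell of
#' \code{pre}, derived from the synapse budget, the presynaptic population
#' size and the synapses-per-connection count.
#'
#' @param config a \code{ca1_config}.
#' @param pre,post type names.
#' @return divergence (connections per presynaptic cell), rounded.
#' @export
divergence <- function(config, pre, post) {
  n_pre <- population_count(config, pre)
  if (n_pre == 0) return(0)
  spc <- max(1, config$syn_per_conn[pre, post])
  round(config$budgets[pre, post] / (n_pre * spc))
}

population_count <- function(config, name) {
  i <- match(name, config$cell_types$name)
  if (!is.na(i)) return(config$cell_types$count[i])
  j <- match(name, config$afferents$name)
  if (!is.na(j)) return(config$afferents$count[j])
  stop("unknown population: ", name, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
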