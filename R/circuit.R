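# Cell placement and distance-dependent connectivity generation.

#' Place cells on regular lattices within their layers
#'
#' Cells of each type are distributed evenly within their layer: a 3D lattice
#' is chosen whose integer dimensions factorize the cell count as closely as
#' possible to the layer's aspect ratio, and cells sit at the centers of the
#' lattice boxes. Placement is deterministic given the configuration.
#'
#' @param config a \code{ca1_config}.
#' @param include_afferents also place the afferent stimulating units (in
#'   their target layer); used for topographic afferent wiring.
#' @return a data.frame with columns \code{gid}, \code{type}, \code{x},
#'   \code{y}, \code{z} (micrometers; x longitudinal, y transverse, z height
#'   from the base of stratum oriens).
#' @export
place_cells <- function(config, include_afferents = TRUE) {
  geom <- config$geometry
  pops <- config$cell_types[, c("name", "count", "layer")]
  if (include_afferents && nrow(config$afferents))
    pops <- rbind(pops, config$afferents[, c("name", "count", "layer")])
  out <- vector("list", nrow(pops))
  gid0 <- 0L
  for (i in seq_len(nrow(pops))) {
    n <- as.integer(pops$count[i])
    zb <- geom$layer_bounds[[pops$layer[i]]]
    if (n > 0 && (diff(zb) <= 0 || geom$longitudinal_um <= 0 ||
                  geom$transverse_um <= 0))
      stop("zero layer volume with nonzero count for ", pops$name[i],
           call. = FALSE)
    p <- lattice_positions(n, geom$longitudinal_um, geom$transverse_um,
                           zb[1], zb[2])
    out[[i]] <- data.frame(gid = gid0 + seq_len(n), type = pops$name[i],
                           x = p$x, y = p$y, z = p$z,
                           stringsAsFactors = FALSE)
    gid0 <- gid0 + n
  }
  do.call(rbind, out)
}

# Integer lattice dims ~ proportional to (Lx, Ly, Lz), covering n cells with
# minimal excess; cells fill boxes x-fastest, then y, then z.
lattice_positions <- function(n, Lx, Ly, z0, z1) {
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  Lz <- z1 - z0
  gm <- (Lx * Ly * Lz)^(1 / 3)
  ideal <- n^(1 / 3) * c(Lx, Ly, Lz) / gm
  best <- NULL; best_score <- Inf
  nz_max <- max(1L, min(n, ceiling(ideal[3] * 3)))
  for (nz in seq_len(nz_max)) {
    ny_max <- max(1L, min(ceiling(n / nz), ceiling(ideal[2] * 3)))
    for (ny in seq_len(ny_max)) {
      nx <- ceiling(n / (ny * nz))
      excess <- nx * ny * nz - n
      score <- abs(log(nx / ideal[1])) + abs(log(ny / ideal[2])) +
        abs(log(nz / ideal[3])) + 2 * excess / n
      if (score < best_score) { best <- c(nx, ny, nz); best_score <- score }
    }
  }
  nx <- best[1]; ny <- best[2]; nz <- best[3]
  k <- seq_len(n) - 1L
  ix <- k %% nx
  iy <- (k %/% nx) %% ny
  iz <- k %/% (nx * ny)
  data.frame(x = (ix + 0.5) * Lx / nx, y = (iy + 0.5) * Ly / ny,
             z = z0 + (iz + 0.5) * Lz / nz)
}

# Connection-count quotas per radial distance bin, following the Gaussian
# bouton-distance distribution truncated to [0, extent]; largest-remainder
# rounding so the quotas sum exactly to the target.
gaussian_bin_quotas <- function(target, mean_um, sd_um, extent_um, bin_um) {
  nb <- max(1L, ceiling(extent_um / bin_um))
  edges <- seq(0, nb * bin_um, by = bin_um)
  edges[length(edges)] <- extent_um
  p <- pnorm(edges[-1], mean_um, sd_um) - pnorm(edges[-length(edges)],
                                                mean_um, sd_um)
  if (sum(p) <= 0) p <- rep(1, nb)
  p <- p / sum(p)
  q <- floor(target * p)
  rem <- target - sum(q)
  if (rem > 0) {
    frac <- target * p - q
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    q[take] <- q[take] + 1L
  }
  as.integer(q)
}

# Deterministic per-projection RNG stream seed (independent streams per
# presynaptic/postsynaptic type pair).
stream_seed <- function(seed, pre, post) {
  h <- function(s) {
    v <- utf8ToInt(s)
    sum(v * 31^(seq_along(v) - 1)) %% 1048573
  }
  as.integer((as.numeric(seed) * 1000003 + h(pre) * 8191 + h(post)) %%
               2147483647)
}

#' Sample connections for one projection
#'
#' Distance-binned connection sampling between two placed populations:
#' all pairwise distances are computed in the XY plane only, the requested
#' connection count is split into radial distance bins according to the
#' presynaptic Gaussian bouton-distance profile, and each bin's quota is
#' drawn uniformly without replacement from the candidate pairs in that bin.
#' Bins short of candidates are exhausted and their deficit reassigned to the
#' nearest bins with spare pairs.
#'
#' @param pre_pos,post_pos data.frames with \code{gid}, \code{x}, \code{y}
#'   (rows of \code{\link{place_cells}} output).
#' @param profile one row of the axonal profile table (\code{mean_um},
#'   \code{sd_um}, \code{extent_um}, \code{bin_um}).
#' @param target_n_connections requested number of connections.
#' @param seed RNG stream seed for this projection.
#' @param same_pop exclude self-pairs (matched row indices).
#' @return a data.frame \code{pre_gid}, \code{post_gid}, \code{dist_um},
#'   with attributes \code{quota} and \code{candidates} (per-bin vectors).
#' @export
sample_connections <- function(pre_pos, post_pos, profile,
                               target_n_connections, seed,
                               same_pop = FALSE) {
  stopifnot(target_n_connections >= 0, profile$sd_um > 0,
            profile$extent_um > 0, profile$bin_um > 0)
  quota <- gaussian_bin_quotas(as.integer(round(target_n_connections)),
                               profile$mean_um, profile$sd_um,
                               profile$extent_um, profile$bin_um)
  res <- cpp_sample_connections(pre_pos$x, pre_pos$y, post_pos$x, post_pos$y,
                                same_pop, profile$extent_um, profile$bin_um,
                                quota, seed)
  out <- data.frame(pre_gid = pre_pos$gid[res$pre],
                    post_gid = post_pos$gid[res$post],
                    dist_um = res$dist)
  attr(out, "quota") <- res$quota
  attr(out, "candidates") <- res$candidates
  out
}

#' Sample compartment zones for a projection
#'
#' Draws postsynaptic compartment zones uniformly from the pair's allowed-zone
#' set in the packaged target table (e.g. axo-axonic output onto pyramidal
#' cells is always the axon initial segment; O-LM and neurogliaform outputs
#' always target distal dendrites in stratum lacunosum-moleculare).
#'
#' @param pre,post type names; the pair must be declared connectable (nonzero
#'   synapse budget).
#' @param config a \code{ca1_config}.
#' @param n number of zones to draw.
#' @param seed RNG stream seed.
#' @return character vector of zone labels.
#' @export
assign_compartment_zone <- function(pre, post, config, n = 1, seed = 1) {
  if (!(pre %in% rownames(config$budgets)) ||
      !(post %in% colnames(config$budgets)) ||
      config$budgets[pre, post] <= 0)
    stop("undeclared projection: ", pre, " -> ", post, call. = FALSE)
  zones <- config$zones[[paste0(pre, "->", post)]]
  if (is.null(zones)) zones <- config$zones[["default"]]
  if (length(zones) == 1) return(rep(zones, n))
  rng <- local_rng(seed)
  zones[floor(rng(n) * length(zones)) + 1]
}

# Small deterministic uniform RNG independent of R's global stream
# (splitmix-style), so projection sampling never perturbs user RNG state.
local_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  if (state <= 0) state <- state + 2147483646
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

#' Build the full edge list of a configured network
#'
#' Places all cells and afferent units and generates every projection with a
#' nonzero synapse budget using the distance-binned sampling algorithm, with
#' an independent RNG stream per (presynaptic type, postsynaptic type) pair.
#' Each connection carries its synapse count, XY distance, compartment zone,
#' peak conductance (unitary conductance times synapse count) and conduction
#' delay (base plus distance over velocity).
#'
#' @param config a \code{ca1_config} (typically rescaled with
#'   \code{\link{scale_config}} first).
#' @param seed integer build seed (defaults to the configuration seed).
#' @return an object of class \code{ca1_network}: list with
#'   \code{config}, \code{positions}, \code{edges} (the edge list
#'   data.frame) and \code{gid_ranges}.
#' @export
build_network <- function(config, seed = config$seed) {
  pos <- place_cells(config, include_afferents = TRUE)
  pos_by <- split(pos, pos$type)
  edges <- list()
  for (pre in rownames(config$budgets)) {
    prof <- config$axonal[config$axonal$name == pre, ]
    for (post in colnames(config$budgets)) {
      if (config$budgets[pre, post] <= 0) next
      spc <- max(1, config$syn_per_conn[pre, post])
      target <- round(config$budgets[pre, post] / spc)
      if (target < 1) next
      pp <- pos_by[[pre]]; qq <- pos_by[[post]]
      if (is.null(pp) || is.null(qq) || nrow(pp) == 0 || nrow(qq) == 0) next
      s <- stream_seed(seed, pre, post)
      e <- sample_connections(pp, qq, prof, target, s,
                              same_pop = identical(pre, post))
      if (nrow(e) == 0) next
      e$n_syn <- as.integer(spc)
      e$zone <- assign_compartment_zone(pre, post, config, nrow(e),
                                        seed = s + 1L)
      e$weight <- config$weights[pre, post] * spc
      e$delay_ms <- config$delay$base_ms +
        e$dist_um / config$delay$velocity_um_per_ms
      e$pre_type <- pre; e$post_type <- post
      edges[[paste0(pre, "->", post)]] <- e
    }
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
           else data.frame(pre_gid = integer(0), post_gid = integer(0),
                           dist_um = numeric(0), n_syn = integer(0),
                           zone = character(0), weight = numeric(0),
                           delay_ms = numeric(0), pre_type = character(0),
                           post_type = character(0))
  counts <- c(stats::setNames(config$cell_types$count,
                              config$cell_types$name),
              stats::setNames(config$afferents$count,
                              config$afferents$name))
  ends <- cumsum(counts)
  gid_ranges <- data.frame(type = names(counts),
                           first = c(1, head(ends, -1) + 1), last = ends,
                           stringsAsFactors = FALSE)
  structure(list(config = config, positions = pos, edges = edges,
                 gid_ranges = gid_ranges, seed = as.integer(seed)),
            class = "ca1_network")
}

#' @export
print.ca1_network <- function(x, ...) {
  cat("CA1 network: ", format(sum(x$config$cell_types$count),
                              big.mark = ","),
      " cells, ", format(nrow(x$edges), big.mark = ","),
      " connections (", format(sum(x$edges$n_syn), big.mark = ","),
      " synapses), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Synapse census
#'
#' Per (presynaptic type, postsynaptic type) synapse totals. For a built
#' network, sums the per-connection synapse counts over the edge list. For a
#' configuration, returns the expectation-mode census
#' \code{N_pre * divergence * synapses_per_connection}.
#'
#' @param x a \code{ca1_network} or \code{ca1_config}.
#' @return a matrix (presynaptic types in rows, postsynaptic in columns).
#' @export
synapse_census <- function(x) {
  if (inherits(x, "ca1_network")) {
    cfg <- x$config
    m <- matrix(0, nrow(cfg$budgets), ncol(cfg$budgets),
                dimnames = dimnames(cfg$budgets))
    if (nrow(x$edges)) {
      agg <- tapply(x$edges$n_syn,
                    list(x$edges$pre_type, x$edges$post_type), sum)
      m[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
    }
    return(m)
  }
  stopifnot(inherits(x, "ca1_config"))
  m <- x$budgets * 0
  for (pre in rownames(m)) {
    n_pre <- population_count(x, pre)
    for (post in colnames(m))
      if (x$budgets[pre, post] > 0)
        m[pre, post] <- n_pre * divergence(x, pre, post) *
          max(1, x$syn_per_conn[pre, post])
  }
  m
}
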