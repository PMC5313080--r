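test_that("single cell is placed at the layer center", {
  p <- ca1net:::lattice_positions(1, 100, 100, 0, 10)
  expect_equal(unlist(p), c(x = 50, y = 50, z = 5))
})

test_that("four cells form a centered 2x2 lattice", {
  p <- ca1net:::lattice_positions(4, 100, 100, 0, 10)
  got <- p[order(p$y, p$x), ]
  expect_equal(got$x, c(25, 75, 25, 75))
  expect_equal(got$y, c(25, 25, 75, 75))
  expect_equal(got$z, rep(5, 4))
  # brute-force check: each cell is the nearest lattice-box center
  centers <- expand.grid(x = c(25, 75), y = c(25, 75))
  for (i in seq_len(4)) {
    d <- sqrt((centers$x - p$x[i])^2 + (centers$y - p$y[i])^2)
    expect_equal(min(d), 0)
  }
})

test_that("all placed cells lie inside their type's layer bounds", {
  cfg <- toy_config(nA = 37, nB = 53)
  pos <- place_cells(cfg)
  for (ty in c("A", "B", "ext")) {
    layer <- if (ty == "ext") cfg$afferents$layer[1]
             else cfg$cell_types$layer[cfg$cell_types$name == ty]
    zb <- cfg$geometry$layer_bounds[[layer]]
    z <- pos$z[pos$type == ty]
    expect_true(all(z >= zb[1] & z <= zb[2]))
    expect_true(all(pos$x[pos$type == ty] >= 0 &
                    pos$x[pos$type == ty] <= 400))
  }
  expect_equal(sum(pos$type == "A"), 37)
})

test_that("no candidates within the axonal extent yields no edges", {
  pre <- data.frame(gid = 1, x = 0, y = 0)
  post <- data.frame(gid = 2, x = 500, y = 0)
  prof <- list(mean_um = 0, sd_um = 100, extent_um = 100, bin_um = 50)
  e <- sample_connections(pre, post, prof, 10, seed = 1)
  expect_equal(nrow(e), 0)
})

test_that("dense layouts realize the Gaussian bin quotas exactly", {
  set.seed(11)
  n <- 300
  pre <- data.frame(gid = seq_len(n), x = runif(n, 0, 1000),
                    y = runif(n, 0, 1000))
  post <- data.frame(gid = seq_len(n) + n, x = runif(n, 0, 1000),
                     y = runif(n, 0, 1000))
  prof <- list(mean_um = 0, sd_um = 300, extent_um = 800, bin_um = 100)
  e <- sample_connections(pre, post, prof, 500, seed = 99)
  expect_equal(nrow(e), 500)

  # independent oracle: numeric quadrature of the Gaussian over each bin
  # plus largest-remainder rounding
  edges <- seq(0, 800, by = 100)
  dens <- function(x) exp(-(x)^2 / (2 * 300^2))
  mass <- vapply(seq_len(8), function(b) {
    xs <- seq(edges[b], edges[b + 1], length.out = 2001)
    sum(dens(xs)) * diff(xs[1:2])
  }, numeric(1))
  p <- mass / sum(mass)
  q <- floor(500 * p)
  rem <- 500 - sum(q)
  frac <- 500 * p - q
  q[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
    q[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1

  hist_counts <- hist(e$dist_um, breaks = edges, plot = FALSE)$counts
  expect_equal(hist_counts, as.integer(q))
  # every bin had >= 10x its quota, so no reassignment occurred
  expect_true(all(attr(e, "candidates") >= 10 * attr(e, "quota") |
                    attr(e, "quota") == 0))
})

test_that("bin shortfall reassigns the deficit and preserves the total", {
  # pre at origin, all candidates between 250 and 450 um: the 0-100 and
  # 100-200 bins have zero candidates, their quota must be reassigned
  set.seed(5)
  npost <- 400
  r <- runif(npost, 250, 450); a <- runif(npost, 0, 2 * pi)
  pre <- data.frame(gid = 1, x = 0, y = 0)
  post <- data.frame(gid = seq_len(npost) + 1, x = r * cos(a),
                     y = r * sin(a))
  prof <- list(mean_um = 0, sd_um = 150, extent_um = 500, bin_um = 100)
  e <- sample_connections(pre, post, prof, 300, seed = 3)
  expect_equal(nrow(e), 300)
  expect_true(all(e$dist_um >= 250 & e$dist_um <= 450))
})

test_that("connection sampling is deterministic and self-edge free", {
  set.seed(2)
  n <- 60
  pos <- data.frame(gid = seq_len(n), x = runif(n, 0, 300),
                    y = runif(n, 0, 300))
  prof <- list(mean_um = 0, sd_um = 200, extent_um = 400, bin_um = 100)
  e1 <- sample_connections(pos, pos, prof, 500, seed = 7, same_pop = TRUE)
  e2 <- sample_connections(pos, pos, prof, 500, seed = 7, same_pop = TRUE)
  expect_identical(e1, e2)
  expect_true(all(e1$pre_gid != e1$post_gid))
  e3 <- sample_connections(pos, pos, prof, 500, seed = 8, same_pop = TRUE)
  expect_false(identical(e1$pre_gid, e3$pre_gid))
})

test_that("compartment zones come from the packaged target table", {
  cfg <- full_cfg()
  expect_equal(unique(assign_compartment_zone("axo", "pyr", cfg, 50)),
               "AIS")
  expect_equal(unique(assign_compartment_zone("olm", "pyr", cfg, 50)),
               "distal_dendrite_SLM")
  zs <- assign_compartment_zone("pvb", "pyr", cfg, 200, seed = 4)
  expect_setequal(unique(zs), c("soma", "proximal_dendrite_SR"))
  # zero-budget pair is rejected
  expect_error(assign_compartment_zone("axo", "olm", cfg), "undeclared")
})

test_that("expectation-mode synapse census matches the published totals", {
  m <- synapse_census(full_cfg())
  expect_equal(signif(m["pyr", "pyr"], 3), 6.14e7)
  expect_equal(m["pyr", "pyr"], 311500 * 197 * 1)
})

test_that("instantiated census equals expectation census without shortfall", {
  cfg <- toy_config(nA = 30, nB = 40, budget_AA = 210, budget_AB = 120,
                    budget_BA = 320, budget_extA = 60)
  net <- build_network(cfg, seed = 2)
  inst <- synapse_census(net)
  expd <- synapse_census(cfg)
  expect_equal(inst, expd)
  # toy arithmetic: 10 pre cells, divergence 3, 2 synapses/connection -> 60
  cfg2 <- toy_config(nA = 20, nB = 10, budget_BA = 60)
  expect_equal(synapse_census(cfg2)["B", "A"], 10 * 3 * 2)
  # empty network
  empty <- net; empty$edges <- net$edges[0, ]
  expect_true(all(synapse_census(empty) == 0))
})

test_that("network build is byte-identical for identical config and seed", {
  cfg <- toy_config()
  n1 <- build_network(cfg, seed = 5)
  n2 <- build_network(cfg, seed = 5)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$positions, n2$positions)
})

test_that("per-projection RNG streams are independent", {
  cfg <- toy_config()
  n1 <- build_network(cfg, seed = 5)
  # removing one projection must not perturb the sampling of the others
  cfg2 <- cfg
  cfg2$budgets["A", "B"] <- 0
  n2 <- build_network(cfg2, seed = 5)
  e1 <- n1$edges[n1$edges$pre_type == "B" & n1$edges$post_type == "A", ]
  e2 <- n2$edges[n2$edges$pre_type == "B" & n2$edges$post_type == "A", ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_identical(e1, e2)
})
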