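# Calibration of the unitary synaptic conductances (not printed in the
# source tables): adjusts the per-class weights so that, at desk scale
# (fraction 0.02, probability-preserving) and 0.65 Hz afferent drive, the
# control network sits in the theta regime: pyramidal SDF spectral peak in
# 5-10 Hz, pyramidal rate of order 5-10 Hz, all cell types participating.
# Mirrors the iterative afferent-weight-tuning loop described for the
# original model. Final values are frozen into tools/make_config.R.
# Usage: Rscript tools/calibrate_network.R [mult_exc_pyr mult_inh_pyr ...]

library(ca1net)

args <- commandArgs(TRUE)
run_once <- function(cfg, seed = 1, duration = 1500) {
  net <- build_network(cfg, seed = seed)
  sim <- simulate_network(net, duration = duration, dt = 0.05, seed = seed)
  dur_s <- (duration - 50) / 1000
  counts <- cfg$cell_types$count
  names(counts) <- cfg$cell_types$name
  rates <- sapply(names(counts), function(ty)
    sum(sim$spikes$type == ty & sim$spikes$time_ms >= 50) /
      counts[[ty]] / dur_s)
  psd <- sim_psd(sim, "pyr")
  list(rates = rates, peaks = psd$peaks)
}

cfg0 <- load_config("inst/extdata/ca1_full.yaml")
cfg <- scale_config(cfg0, 0.02)
res <- run_once(cfg)
print(round(res$rates, 2))
print(res$peaks)
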