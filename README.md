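# ca1net

A configurable-scale spiking-network model of the rodent hippocampal CA1
microcircuit, together with the complete oscillation-analysis pipeline used
to study the spontaneous theta (5–10 Hz) and gamma (25–80 Hz) rhythms that
emerge from it under tonic, arrhythmic afferent drive.

The package is for computational neuroscientists who want to (i) rebuild
the full-scale CA1 parameterization — 338,740 cells across one pyramidal
type and eight interneuron classes (PV+ basket, CCK+ basket,
Schaffer-collateral-associated, axo-axonic, bistratified, O-LM, ivy,
neurogliaform), 454,700 Poisson stimulating units, and a budget matrix of
~5 × 10⁹ synapses — at a scale their hardware can run, (ii) perturb it the
way the original experiments did (muting cell types, scaling
pyramidal-to-pyramidal recurrence, homogenizing interneurons, removing
GABA-B or replacing it with a charge-matched GABA-A conductance), and
(iii) quantify the resulting oscillations.

## The model in brief

* **Connectivity.** Cells are placed evenly on lattices within their
  laminae of a 15,000 × 1,000 μm prism. For each type pair, connections are
  drawn by the three-step distance-binned algorithm: XY-plane distances,
  connection counts split over radial bins by the presynaptic Gaussian
  bouton-distance profile, and uniform sampling without replacement within
  each bin. Each connection carries 1–10 synapses; each pyramidal cell
  contacts 197 other pyramidal cells.
* **Neurons.** Reduced adaptive exponential integrate-and-fire models,
  `dV/dt = (−g_L(V−E_L) + g_L Δ_T e^{(V−V_T)/Δ_T} − w + I)/C`, fit per type
  so the measured resting potential, input resistance, membrane time
  constant, rheobase and spike threshold reproduce the published
  single-cell table.
* **Synapses.** Double-exponential conductances
  `g(t) = g_max N (e^{−t/τ₂} − e^{−t/τ₁})`; neurogliaform outputs are mixed
  GABA-A/GABA-B events (reversals −60/−90 mV). Charge transfer has the
  closed form `g_max N (τ₂−τ₁) ΔV`, the basis of the charge-matched GABA-A
  substitution experiment.
* **Analysis.** LFP analog (inverse-distance sum of pyramidal synaptic
  currents, 10% subsampling outside a 100 μm radius), spike density
  function (1 ms bins, 3 ms Gaussian kernel), one-sided Welch periodograms
  (Hamming, 50% overlap), spectrograms, zero-phase Butterworth band
  filters, trough-referenced spike phases (trough = 0°/360°) with Rayleigh
  statistics `r` and `p = exp(√(1+4n+4(n²−R²)) − (1+2n))`, per-type firing
  rates, and theta-phase/gamma-envelope cross-frequency coupling.

## Worked example

```r
library(ca1net)

cfg <- default_config()
census(cfg)
#> total    338,740
#> principal        311,500
#> interneurons     27,240
#> afferent 454,700
#> ...

spikes_per_theta_cycle(454700, 0.65, 7.8)
#> [1] 37892

# a desk-scale network (2% of full scale, connection probability preserved,
# weights compensated by 1/fraction)
net <- build_network(scale_config(cfg, 0.02), seed = 1)
net
#> CA1 network: 6,775 cells, 1,933,839 connections (2,057,498 synapses), seed 1

sim <- simulate_network(net, duration = 4000, seed = 1)
sim_psd(sim, "pyr")$peaks
#>     band      freq    power
#>    theta  8.789062 36876018
#>    gamma 25.390625  2613620
#>  overall  8.789062 36876018
```

The census lines are the published cell totals; 37,892 is the worked
afferent-arithmetic example (454,700 afferents at 0.65 Hz over 7.8 theta
cycles per second); and the periodogram of the pyramidal spike density
function peaks inside the theta band — the desk-scale signature of the
spontaneous theta rhythm (exact peak frequency and power vary by one or two
frequency bins across seeds).

Single cells and synapses:

```r
characterize(neuron_params("pyr", cfg))
#> Electrophysiological profile (pyr)
#>   RMP -63.0 mV | Rin 62.2 MOhm | tau_m 4.8 ms
#>   rheobase 251 pA | threshold -37.2 mV | delay 123.8 ms | half-width 0.03 ms

syn <- ngf_synapse(cfg)
charge_match_scale(syn$gabaa, syn$gabab, reference_mv = -63)
#> [1] 286.1246   # the GABA-A conductance must grow ~300x to carry the GABA-B charge
```

A command-line surface over the same functions lives in
`inst/cli/ca1net.R` (`census`, `build`, `characterize`, `simulate`,
`clamp`, `analyze`, `experiment` subcommands).

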