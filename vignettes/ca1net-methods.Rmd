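---
title: "Methods: a configurable-scale CA1 network model and its oscillation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a configurable-scale CA1 network model and its oscillation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ca1net` implements a data-driven spiking-network model of the isolated
rodent hippocampal CA1 region and the analysis pipeline used to study the
theta (5–10 Hz) and gamma (25–80 Hz) oscillations that emerge from it under
arrhythmic afferent drive. The full-scale parameterization — 338,740 cells
(311,500 pyramidal cells and 27,240 interneurons of eight classes: PV+
basket, CCK+ basket, Schaffer-collateral-associated, axo-axonic,
bistratified, O-LM, ivy and neurogliaform), 454,700 Poisson stimulating
units standing in for CA3 (204,700) and entorhinal-layer-III (250,000)
afferents, and a pairwise synapse-count budget matrix totalling about
5.1 billion synapses — ships as a structured text file
(`inst/extdata/ca1_full.yaml`) and is retained as data. Dynamical
experiments run at a reduced scale produced by `scale_config()`.

### Scaling modes

Small networks face a connectivity trade-off: preserving per-cell
convergence in a reduced population forces connection probabilities (and
hence effective coupling) far above biology. `scale_config()` therefore
offers two regimes and makes the compensation explicit:

* `preserve_probability` (default): budgets scale with the square of the
  cell-count fraction, keeping pairwise connection probability; unitary
  weights are multiplied by `1/fraction`, conserving the expected synaptic
  drive per cell. This is the regime used for all packaged dynamical
  experiments.
* `preserve_convergence`: budgets scale linearly, keeping per-cell
  in-degree, with weights untouched.

Counts are rounded half-up per type (nonzero types keep at least one cell)
and the total is trued up on the most numerous type, so proportions are
preserved deterministically.

### Cell placement and connectivity

Cells are distributed evenly: each type fills its layer (stratum oriens,
pyramidale, radiatum or lacunosum-moleculare of a 15,000 × 1,000 μm prism;
layer heights 100/30/220/100 μm) on a regular 3D lattice whose integer
dimensions track the layer's aspect ratio, with cells at box centers. The
prism and layer dimensions are estimates taken from the quantitative
anatomical assessment the cell counts come from; they are fully
configurable.

Connections are generated per (presynaptic type, postsynaptic type) pair by
the three-step distance-binned algorithm: (1) all pairwise distances are
computed in the XY plane only; (2) the pair's total connection count
(budget divided by synapses-per-connection) is split into 100 μm radial
bins following the presynaptic Gaussian bouton-distance profile truncated
at the axonal extent, with largest-remainder rounding; (3) candidate pairs
are assigned to bins and each bin's quota is sampled uniformly *without*
replacement (a single-pass sequential scheme, exact and O(pairs)). A bin
short of candidates is exhausted and its deficit moves to the nearest
non-exhausted bins, alternating inward/outward — this preserves the total
connection count while minimally distorting the distance distribution; the
source publications do not state their shortfall rule. Each ordered pair
connects at most once, carrying 1–10 synapses. Every projection uses its
own deterministic RNG stream, so muting or removing one projection never
perturbs the realization of the others.

Axonal Gaussian parameters (mean 0, SD 200–3,000 μm, extents 500–10,000 μm
by type) are estimates standing in for bouton-distance profiles published
only as figures; they are configuration fields, not code.

Conduction delays are not reported in the source material; the default is
0.5 ms plus distance at 300 μm/ms, recorded per edge so the engine stays
agnostic.

### Reduced neuron models

The original model used a 200-compartment pyramidal cell with six ion
channel types; this package deliberately replaces all cell types with
single-compartment adaptive exponential integrate-and-fire neurons, because
the published single-cell contract is a table of seven electrophysiological
measurements per type, which this family can satisfy at desk scale. For
each type the passive parameters are analytic (resting potential = E_L,
input resistance = 1/g_L, time constant = C/g_L); the spike threshold V_T
and sharpness ΔT are fit per type (`tools/fit_cells.R`) so that the
*measured* rheobase (500 ms steps, bisection to 1 pA) and the measured
threshold (first crossing of dV/dt = 20 mV/ms — a standard criterion; the
source does not state its own) match the published values. The published
pyramidal and O-LM threshold/half-width entries are physiologically
implausible (apparent sign/formatting errors) and are excluded as fit
targets; they are flagged in `ephys_targets()`. Spike-triggered adaptation
(b, τ_w) is an estimate per firing class — strong for pyramidal cells
(100 pA, 100 ms), absent in fast-spiking types — and contributes to the
population rhythm below.

### Synapses

All synapses are conductance-based double exponentials
g(t) = g_max·N·(e^(−t/τ₂) − e^(−t/τ₁)), peak-normalized. Receptor channels:
AMPA (0.5/3 ms, 0 mV), GABA-A (0.3/8 ms, −60 mV), a slower neurogliaform
GABA-A (1/11 ms, −60 mV), and GABA-B (50/200 ms, −90 mV). The −60/−90 mV
reversals are published; the GABA-B kinetics are estimates (published data
give only their "slow" character). Neurogliaform outputs onto pyramidal and
neurogliaform targets are mixed GABA-A,B events with a GABA-B/GABA-A
conductance ratio of 1.4.

Charge transfer ∫g·ΔV dt has the closed form g_max·N·(τ₂−τ₁)·ΔV.
`charge_match_scale()` returns the factor that equates GABA-A and GABA-B
charge with driving forces evaluated at a reference potential, default
−63 mV — the pyramidal resting potential, where the charge actually acts
during network activity. With the packaged neurogliaform defaults the
factor is ≈286, consistent with the published observation that conveying
the GABA-B charge through the fast GABA-A conductance requires scaling it
up by roughly three hundred.

Unitary peak conductances are not published. They were calibrated once
(`tools/calibrate_network.R`) at the desk-scale study conditions so that
the control network exhibits spontaneous theta and all types participate —
the same iterative tuning loop the original study describes for its
afferent synapse weights — and then frozen in the packaged configuration.

### Engine

Clock-driven integration: forward Euler on the membrane with a clamped
exponential term, exact per-step decay of the synapse states, events
delivered through a ring buffer with per-edge delays rounded to the step.
Network runs default to dt = 0.05 ms; single-cell characterization uses
0.025 ms (the original model's fixed-step range is 0.01–0.025 ms). Spike
counts in a driven toy network change by well under 1% when dt is refined
from 0.025 to 0.0125 ms. The engine is deterministic given (network,
stimulus, dt): re-running a seed reproduces the raster byte for byte.

Perturbations mirror the published battery: muting (outgoing weights of a
type, or a fraction of its cells, set to zero — placement and RNG streams
untouched, so muting is exactly reversible), partial muting of the PV+ and
SOM+ families, pyramidal-recurrence scaling (0×/0.5×/2× of the Pyr→Pyr
budget), staged homogenization of all interneurons toward the PV+ basket
profile (electrophysiology → +input weights → +input numbers → full
conversion → added resting-potential variability), and GABA-B removal with
optional charge-matched GABA-A substitution. Structural conditions are
expressed as configuration transforms followed by a rebuild, so each stage
is itself a plain configuration.

`network_clamp()` extracts one cell with all afferent synapses intact and
drives those synapses with prescribed trains — the strategy used in the
original work to constrain synapse weights where no paired recordings
exist.

### Study conditions at desk scale

Packaged dynamical experiments use fraction 0.02 (6,775 cells, ~6,700
stimulating units), probability-preserving scaling, 0.65 Hz Poisson drive,
4,000 ms runs (one of the original simulation durations) with the first
50 ms cropped from all analyses, and three replicate seeds per condition.
Full-scale quantitative results (absolute firing phases, Table-scale
powers, the exact 7.8 Hz control peak) are *not* reproducible at this
scale; the package reproduces them directionally: the pyramidal
spike-density spectrum peaks inside the theta band in the control condition
(typically 8–10 Hz here; single-realization periodograms jitter by one to
two frequency bins, so the acceptance script averages the spectra over the
three replicates before locating the peak — the standard
variance-reduction step for periodograms), and muting pyramidal outputs
collapses the interneurons' theta-band power by two orders of magnitude.

## The analysis pipeline

* **LFP analog** — point-source approximation: per-cell synaptic currents
  scaled in inverse proportion to distance from the reference electrode
  (longitudinal 200, transverse 500, height 120 μm), distance floored at
  10 μm to avoid the singularity. All pyramidal cells within 100 μm
  contribute; 10% of the outer cells are sampled and scaled by 10 — an
  unbiased estimator of the outer sum (verified by Monte-Carlo against the
  exhaustive sum). Units are relative; the extracellular conductivity is
  absorbed into the arbitrary scale.
* **Spike density function** — 1 ms bins convolved with a unit-mass
  Gaussian kernel. The published description gives a "window of 3 ms";
  this is read as the kernel SD (the cited SDF method parameterizes by SD),
  truncated at ±3 SD, with per-spike edge renormalization so the integral
  of the series equals the spike count exactly.
* **Spectra** — one-sided Welch periodogram of the SDF, Hamming window, 50%
  overlap; the segment length is not published, the default is 1024 ms.
  Band peaks are reported for theta (5–10 Hz), gamma (25–80 Hz) and
  overall. The spectrogram is the sliding-window analog.
* **Band filtering** — zero-phase third-order Butterworth applied
  forward-backward (filter family unpublished; zero-phase is required so
  trough times are not shifted before phase assignment).
* **Spike phases** — troughs of the theta-filtered trace are local minima
  (sign change of the first difference, ≥50 ms apart); phase runs linearly
  0→360° between consecutive troughs (trough = 0°/360° convention); spikes
  before the first/after the last trough and the first 50 ms are dropped.
* **Rayleigh statistics** — circular mean, resultant length r (the
  "modulation level"), and the standard Rayleigh p approximation
  p = exp(√(1+4n+4(n²−R²)) − (1+2n)).
* **Firing rates** — two conventions: spikes over all cells of a type, and
  over the active cells only (≥1 spike after the 50 ms crop).
* **Cross-frequency coupling** — Hilbert transform (FFT analytic signal) of
  the theta- and gamma-filtered traces; mean gamma envelope in 20° bins of
  theta phase, reporting the phase of the maximal envelope.

## What the stimulus generator emulates — and what it does not

`poisson_trains()` produces independent homogeneous Poisson trains: tonic,
arrhythmic excitation with no information content, exactly the regime the
perturbation experiments probe. `phase_locked_trains()` adds a von Mises
intensity profile around a preferred phase of an ideal theta oscillator —
used as the fixture generator for the phase-statistics tests and for
network clamp, because the original in-vivo-like generator is unpublished;
the von Mises family is the standard unimodal circular model matching the
Rayleigh/resultant analysis. Neither generator represents CA3/entorhinal
content, sequences, phase precession, or non-Poisson irregularity, so
passing tests say nothing about information processing in real afferents —
only about oscillation mechanics under tonic drive.

## Numerical and design notes

* Rounding of the afferent-arithmetic outputs is to the nearest integer,
  matching the published worked examples (454,700·0.65/7.8 → 37,892).
* Largest-remainder rounding makes bin quotas sum exactly to the target;
  per-bin histograms of generated distances equal the quota vector by
  construction, not statistically.
* The packaged synapse-budget matrix sums to 5.13 × 10⁹, about 1.1% below
  the published 5.19-billion total, because the published per-pair entries
  are rounded to three significant figures.
* Synapses-per-connection values (1 for excitatory connections, 3 between
  interneurons, 5–10 from interneurons onto pyramidal cells) are estimates
  within the published 1–10 range; the pyramidal→pyramidal divergence of
  197 is exact by construction.
* Zone-dependent attenuation (AIS/soma 1.0, proximal/basal 0.9, distal
  0.75) stands in for dendritic filtering; trial-to-trial variability in
  paired recordings comes only from re-sampling the contact zone, matching
  the published protocol of re-drawing the connection location per trial.
* Degenerate inputs: empty rasters yield zero SDFs and empty censuses;
  rheobase is reported as not-found when the search ceiling (5 nA) elicits
  no spike; a diverging membrane aborts the run naming the cell.

## Known limitations

* Point neurons cannot reproduce dendritic nonlinearities, the
  200-compartment pyramidal morphology, channel kinetics, or
  compartment-resolved synaptic integration; compartment zones are labels
  with scalar attenuation, not positions.
* Desk-scale networks with 1/fraction weight compensation have lumpy,
  high-variance synaptic input; only directional oscillation properties are
  expected to survive, and spectral peaks jitter by one to two frequency
  bins across seeds.
* The theta regime at desk scale was placed by calibrating unpublished
  unitary weights; the packaged values are one defensible configuration,
  not a fit to unavailable data.
* No gap junctions, short-term plasticity, neuromodulation, or cell-to-cell
  parameter variability (beyond the optional resting-potential jitter of
  the homogenization battery).
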