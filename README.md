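# cortexsheet

Why does visual cortex in cats and primates arrange neurons with similar
stimulus preferences into columns, when rodents do fine with a
salt-and-pepper arrangement? `cortexsheet` explores one answer in
simulation: because cortical pyramidal cells preferentially wire to
physically close *and* similarly tuned partners, a columnar layout produces
more tightly clustered, more strongly coupled cell ensembles — and those
ensembles recover the correct population response faster and more
accurately when the input is noisy.

The package simulates 1 mm² of a layer-2/3-like sheet of pyramidal neurons
(20 164 cells at full scale) and provides every stage as composable,
pipe-friendly functions returning tibbles:

* **Feature maps** — noisy linear gradients of preferred orientation and a
  second mapped parameter plus two unmapped parameters (`columnar`), or
  fully random preferences (`noncolumnar`). Tuning distance
  $td = \sqrt{\sum_i \Delta_i^2}$ uses per-axis differences normalized to a
  common maximum of 1; feedforward drive is Gaussian in tuning distance,
  $g_{in} = \frac{C}{2\pi\sigma^2} e^{-td^2/2\sigma^2}$ (σ² = 0.1, C = 15).
* **Wiring** — independent Bernoulli edges with
  $P = (1 - pd/600\,\mu m)_+ (1 - td/1.1)_+$ on a toroidal sheet,
  calibrated to ~1000 synapses per cell (2×10⁷ at full scale).
* **Synaptic strengths** — EPSC amplitude $= CN \cdot CC \cdot B$ from the
  edge's normalized common-neighbor product CN, the target cell's
  saturating cluster-connectivity factor CC, and base conductance
  B = 0.5 nS; plus a piecewise-linear synaptic-failure correction that
  silences the weakest synapses, amplitude shuffling, distance-only wiring
  and simple-Hebbian controls.
* **Dynamics** — three-compartment conductance neurons (RK4, 10 µs step),
  rectangular synaptic pulses with exact delays, global delayed shunting
  inhibition driven by summed pyramidal spiking, and two noise processes
  (per-trial ±33% feedforward jitter; a 5 nS telegraph conductance with a
  1/3 duty cycle).
* **Evaluation** — Pearson similarity between whole-network spike-count
  vectors: discrimination curves, noise-recovery curves, and time to reach
  95% of asymptotic noise recovery.

## A worked example

A reduced sheet (40×40 cells, same 1 mm extent, conductances
density-compensated) shows the core phenomena in seconds:

```r
library(cortexsheet)

map   <- generate_feature_map(grid_side = 40, mode = "columnar", seed = 1)
net   <- build_network(map, seed = 2)        # wiring + amplitudes + failures
glance(net)
#> # A tibble: 1 × 9
#>   n_cells n_edges mean_out_degree mean_pd_um mean_td mean_amplitude_nS ...
#> 1    1600  126980            79.4       232.   0.638             0.097

trial <- run_trial(net, map, stimulus_at(0), trial_config())
base  <- run_trial(NULL, map, stimulus_at(0), trial_config())  # unconnected
trial$diagnostics$total_spikes / base$diagnostics$total_spikes
#> [1] 1.714585
```

The connected network fires ~1.7× the spikes of the same cells without
recurrent synapses — recurrent amplification of the stimulus-matched
ensemble — while spiking stays confined to cells preferring orientations
within ~46° of the stimulus (the 99th percentile of spiking cells'
orientation offsets), even though subthreshold depolarization spreads to
orthogonal cells.

Noise robustness is where the architectures separate. Pearson similarity
between the noisy and noise-free response (relative noise amplitude 1,
five noise seeds, same reduced sheet):

```r
nr <- function(mode) {
  n <- network_for_mode(mode, grid_side = 40, seed = 1)
  noise_recovery(n$graph, n$map, trial_config(), amplitudes = 1, seeds = 1:5)$mean_r
}
sapply(c("columnar", "noncolumnar", "unconnected", "shuffled", "distance_only"), nr)
#>      columnar   noncolumnar   unconnected      shuffled distance_only
#>         0.919         0.858         0.815         0.851         0.828
```

Columnar > non-columnar > unconnected; shuffling the synaptic strengths or
wiring by distance alone forfeits most of the columnar advantage — the
benefit lives in the alignment of strong synapses with functionally
clustered ensembles, not in gross connectivity statistics.

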