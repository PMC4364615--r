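---
title: "The cortexsheet model: maps, wiring, dynamics and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cortexsheet model: maps, wiring, dynamics and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cortexsheet` simulates 1 mm² of layer 2/3 of a primary-visual-cortex-like
sheet of pyramidal neurons and asks one question: what does a *columnar*
arrangement of feature preferences buy a cortical network, compared to the
salt-and-pepper arrangement seen in rodents? The package implements the full
chain — feature maps, probabilistic wiring, common-neighbor synaptic
weighting, conductance-based spiking dynamics with global inhibition — and
the evaluation protocol (Pearson similarity of population spike-count
vectors) used to compare the two architectures.

This vignette documents the model itself, the package's default parameter
choices and their provenance, the places where the original model description is
ambiguous and what we chose there, and what the reduced-scale test runs do
and do not demonstrate.

## 1. Feature maps

Each of the `grid_side²` cells (default 142², i.e. 20 164 cells at ≈7 µm
pitch) carries a preferred value for four stimulus parameters, each
normalized to [0, 1). In columnar mode, parameter 1 (orientation, 0–180°)
follows the horizontal axis and parameter 2 the vertical axis, with Gaussian
noise generated by an explicit Box–Muller transform

$$p = m + SD\,\sqrt{-2\ln x}\,\cos(2\pi y),$$

where *m* is the normalized axis coordinate. The orientation noise SD is 7°
(0.0389 of the range; orientation is the most strongly mapped parameter) and
the second parameter's SD is 10% of its range. Parameters 3 and 4 are
uniform, standing for weakly- or non-mapped features. In non-columnar mode
all four parameters are i.i.d. uniform — the marginal distribution of
preferences is identical in the two modes; only their spatial arrangement
differs. The Box–Muller form is implemented literally rather than through a
generic normal sampler so the generating formula itself is exercised;
statistically the two are equivalent.

### Tuning distance and its normalization

The tuning distance between two points of the feature space is the
Euclidean norm of per-axis differences, with each axis normalized so that
its **maximal separation equals 1**: the two mapped parameters are circular,
so their wrapped difference is scaled by 2 (a 90° orientation difference
scores 1.0), while the two unmapped parameters use plain absolute
differences. Under this convention the tuning distance ranges from 0 to 2.

This normalization is a deliberate design choice, fixed by three
convergent observations: (i) the best-tuned-population overlap analysis
(below) reproduces the target ≈83% / ≈32% / 0% overlaps at 5° / 20° / 45°
only under this scaling (an all-axes-wrapped convention with per-axis
maximum 0.5 gives ≈50% at 20°); (ii) the wiring rule's tuning cut-off of
1.1 is described as chosen "from a range 0 to 2", which is the range this
convention produces; and (iii) the feedforward tuning width works out to
≈33° half-width at half-height, matching the intended ≈30° (see below).

### Feedforward input

A stimulus is a point of the same feature space; the default reference
stimulus sits at half maximum on every axis (defined as 0° orientation).
Each cell receives a constant conductance on its distal dendrites,

$$g_{in}(td) = \frac{C}{2\pi\sigma^2} e^{-td^2/2\sigma^2},$$

with σ² = 0.1 and C = 15, i.e. ≈23.9 nS for a perfectly matched cell and a
half-width at half-height of $td = \sqrt{2\sigma^2 \ln 2} \approx 0.372$,
i.e. ≈33° of pure orientation difference. `overlap_curve()` implements the
map-only analysis: the 100 cells best tuned to two stimuli are selected by
tuning distance (ties broken by cell id) and their percentage overlap is
averaged over map seeds.

## 2. Wiring

Every ordered pair of cells is connected independently with probability

$$P = s\left(1 - \frac{pd}{600\,\mu m}\right)_+\left(1 - \frac{td}{1.1}\right)_+,$$

where *pd* is the physical distance on the torus (the sheet wraps around to
avoid edge artifacts; *pd* is floored at 7 µm, the grid pitch) and both
linear factors are clamped at zero — distances beyond 600 µm or tuning
differences beyond 1.1 never connect. Pairs are visited in a fixed
(pre, post) order with one RNG draw per pair, so builds are exactly
reproducible and a brute-force oracle can replay them draw for draw.

The global factor *s* calibrates the expected mean out-degree to a
full-scale-equivalent of 1000 synapses per cell (`target_full_degree`,
Monte-Carlo estimated per map). The unscaled rule yields ≈1800 synapses per
cell in the columnar network and ≈1250 in the non-columnar one, whereas the
documented network statistics of the original model — about 1000 synapses per cell and 2×10⁷
synapses in total (1000 × 20164 = 2.0×10⁷) — indicate the original model
operated at the calibrated density. Calibration also equalizes the edge
counts of the two architectures, making their comparison a comparison of
*arrangement* rather than of synapse count. Passing
`target_full_degree = NULL` samples the raw rule.

## 3. Synaptic amplitudes

For every connected pair i→j the package counts presynaptic common
neighbors (cells projecting to both i and j) and postsynaptic common
neighbors (cells receiving from both) exactly, by bit-set intersection of
adjacency rows. The clustering score of an edge is the product of the two
counts, each normalized by its maximum over all edges of the graph, and the
EPSC amplitude is

$$A = CN \cdot CC \cdot B, \qquad B = 0.5\ \text{nS},$$

where the cluster-connectivity factor
$CC = \tfrac12\left[(\ln \bar n_{pre} + 3) + (\ln \bar n_{post} + 3)\right]$
uses the *target* cell's mean common-neighbor counts over its outgoing
edges, normalized by the network maxima of those means, floored at 0 so
amplitudes remain non-negative conductances. The logarithm captures the
strong saturation of amplitude with cluster connectivity; its effect is
small compared to the CN product. A `hebbian` rule (amplitude ∝ tuning
similarity, $(1 - td/1.1)_+ B$) is provided as the control showing the
results do not hinge on the common-neighbor formulation.

**A documented ambiguity.** The normalizing denominator of the
common-neighbor counts is not stated in the original model description beyond
"normalized to the maximum value". We evaluated the defensible readings
(network-wide maximum; per-cell maximum; per-pair attainable maximum). They
produce indistinguishable wiring but different amplitude *scales*: per-cell
maxima reproduce the original strength-distribution fractions (≈43.5% of
synapses below 20% of maximum, ≈1.6% above 80%) but inflate mean amplitude
enough to push the network into runaway recurrence (connected/unconnected
spike ratio ≈5 rather than ≈2, spiking far beyond 45°); the network-wide
maximum reproduces the dynamic regime — the ratio, the confinement of
spiking, the inhibition sweep — at the cost of a more weak-skewed strength
distribution (≈69% below 0.2, ≈0.006% above 0.8 at full scale). No reading
we found reconciles both. Because essentially every simulated result rests
on the dynamic regime, the package uses the network-wide maximum and
reports its own strength-distribution fractions honestly.

### Synaptic failures

Weak cortical synapses fail often; strong ones are reliable. The default
correction multiplies each amplitude by min(1, s/0.2) of its normalized
strength *s* — synapses above 20% of maximum never fail, reliability falls
linearly to zero below. The control band moves the sloped segment to
s ∈ [0.2, 0.4] with zero transmission below 0.2 (the original control
wording "zero elsewhere" is ambiguous for s ≤ 0.2; we implement it as
stated, zeroing the weakest synapses too, and flag it here). `band = "none"`
disables failures entirely, the manipulation used to show the correction
costs no performance.

### Control networks

`shuffle_amplitudes()` swaps the strengths of random synapse pairs
(default 2 swaps per edge, matching 4×10⁷ swaps on the full-scale graph),
conserving the amplitude multiset exactly. `distance_only_connectivity()`
redraws the wiring from the distance factor alone, analytically rescaled to
the matched edge count. Both controls destroy the alignment between strong
synapses and functionally clustered ensembles while preserving gross
statistics.

## 4. Dynamics

Each pyramidal cell is three equipotential points — soma (input resistance
100 MΩ), proximal dendrites (250 MΩ), distal dendrites (300 MΩ) — coupled
by a 4 MΩ axial resistance, with membrane time constant 20 ms and rest at
−60 mV:

$$\tau_m \frac{dV}{dt} = -(V - V_{rest}) + R_{in}\,(I_{syn} + I_{axial}),
\qquad I_{syn} = g\,(V_{rev} - V).$$

The −V term of the membrane equation is read as leak toward rest (−60 mV
must be a fixed point of the free membrane). Excitation — feedforward,
recurrent, and noise — targets the distal point (reversal 0 mV);
inhibition targets soma and proximal points as *shunting* conductance
(reversal −60 mV = rest), so it divides input efficacy without
hyperpolarizing. Placing excitation distally also yields dendritic
saturation: driving force collapses as the distal point depolarizes, a
built-in brake on recurrence.

Inhibitory interneurons are not explicit: every pyramidal spike delivers,
after 2.5 ms, a 0.01 nS IPSC for 2 ms onto soma *and* proximal point of
every cell (each inhibitory connection effectively makes two synapses), a
summed-activity proxy for dense local inhibition that acts like divisive
normalization. Each spike also delivers its EPSC (the edge's effective
amplitude, rectangular pulse of 0.5 ms after 1.3 ms) to its targets. Where
the original parameter table (EPSC 0.5 ms, IPSC 2 ms) and running text ("duration
1 ms") disagree, the table is used, being the more specific source.

Spiking is threshold-based at −50 mV: the soma is clamped to 0 mV for one
integration step (the action-potential marker), reset to −65 mV
(afterhyperpolarization), and refractory for 3 ms. The AP peak, AHP depth
and refractory period are this package's choices — the original model
states only the threshold — and are exposed through `membrane_params()`.
The equations are integrated with classical RK4 at a 10 µs step,
conductance pulses held piecewise constant within a step; subthreshold
trajectories match closed forms to better than 10⁻⁶ relative error, and the
event queue delivers delays exactly (130 and 250 steps).

### Noise

Two processes, both gated by `noise_relative_amplitude` (trials at
amplitude 0 are fully deterministic):

* **input-specific** — each cell's feedforward conductance is multiplied
  once per trial by 1 ± 0.33·amplitude, sign equiprobable (the original
  description does not give the up/down proportion; we use 1/2);
* **nonspecific** — each cell carries a 5 nS distal conductance switched by
  a telegraph process on a 1 ms grid: on with p = 0.0005/ms, off with
  p = 0.001/ms, hence a stationary on-fraction of 1/3, which is also the
  initialization.

### Reduced-scale convention

Sheets smaller than 142² keep the 1 mm physical extent and the 600 µm
distance cut-off — density drops, distances do not — and, by default,
synaptic conductances (EPSC amplitudes and the IPSC unit) are scaled by
(142/grid_side)², preserving each cell's *aggregate* synaptic drive.
Without this compensation a reduced sheet is simply a sparser, weaker
network and no dynamical claim survives; with it, the full-scale regime
(connected/unconnected spike ratio ≈2, spiking confined to ≈45°, the
inhibition sweep, the noise-robustness ordering) is preserved at grids of
40–64. Reduced sheets still differ from full scale in graininess — single
spikes carry (142/gs)² times more inhibitory weight — so quantitative
values (e.g. the exact spike-increase percentage when failures are removed,
or convergence times) shift by a few points across scales; we treat ordinal
and regime claims as the meaningful reduced-scale outcomes.

## 5. Evaluation

All performance measures are Pearson correlations between per-cell
spike-count vectors over the *whole* network (silent cells included). If
either vector has zero variance the value is undefined and reported `NA`
rather than coerced — a silent network has no similarity, not zero
similarity.

* `discrimination_curve()` — similarity between the response to a reference
  orientation and to test orientations (no noise); lower similarity ⇒
  better discriminability.
* `noise_recovery()` — similarity between the deterministic no-noise
  response and noisy responses to the same stimulus (both noise processes
  on); 1 means total recovery. Curves average plain r over noise seeds
  (default 10).
* `convergence_time()` — similarity of *cumulative* spike counts at
  increasing endpoints from stimulus onset; reports the earliest time
  reaching 95% of the end-of-trial value. Cumulative (nested) windows are
  used because "converging on an asymptote" presupposes nesting; sliding
  windows would measure something else.

The experiment presets (`run_experiment()`) wire these together for the
standard protocols: overlap, response maps, discrimination, inhibition
sweeps (the inverted-U of noise robustness versus inhibition strength),
noise-robustness comparisons across the five network variants, failure-band
manipulations, and convergence. Problem sizes used by the packaged
acceptance runs: map statistics and the strength distribution at full scale
(142²), trial-based quantities at 64² (convergence, failure effects) and
40² (regime and ordering checks) with 5–20 seeds per quantity; a full 142²
build takes ≈20 s and ≈2 GB, a 64² trial ≈8 s.

## 6. Known limitations

* Only local, intralaminar pyramidal–pyramidal circuitry within a single
  layer is modeled; no inter-laminar or long-range input, no explicit
  interneurons, no synaptic plasticity or paired-pulse dynamics within a
  trial.
* The amplitude-normalization ambiguity above means the static strength
  distribution and the dynamic regime could not be reproduced
  simultaneously; we privileged the dynamics and document the residual
  discrepancy rather than split the difference.
* The spike mechanism (AP marker, AHP, refractory period) is a minimal
  integrate-and-fire-style construction; absolute firing rates, and
  quantities sensitive to them, inherit this choice.
* Reduced-scale runs preserve regimes and orderings, not point values;
  full-scale dynamics are feasible but expensive (minutes per trial,
  several GB).
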