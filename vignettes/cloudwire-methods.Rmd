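---
title: "Cloud null models and higher-order connectome structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cloud null models and higher-order connectome structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudwire)
```

## The question the package addresses

A connectome's *first-order* structure is everything a pairwise summary
can capture: how many connections run between each pair of neuron types,
how connection probability falls with distance, how often connections are
reciprocated. Its *higher-order* structure involves three or more neurons
at once: common-neighbour bias, directed cliques (simplices), long-tailed
degree distributions, the polarization of connections into source-like
and sink-like roles. The package implements a null-model construction
that removes higher-order structure while conserving first-order
structure, so the two can be separated and their consequences for spiking
dynamics compared.

The core idea: if connection probabilities are computed from
*type-averaged* axon and dendrite density clouds, every neuron of a type
is statistically exchangeable, and all structure attributable to
individual morphological variation within a type disappears. Comparing a
reference wiring (built from per-neuron morphologies) against its
cloud-based twin (built from type averages, with per-type-pair connection
counts matched exactly) isolates exactly that contribution.

## The cloud construction

For each m-type and component we represent arbour density as mass per bin
on a 2D grid over (signed lateral offset, depth offset) from the soma,
with bin centres on a common lattice. The construction is the four-step
procedure implemented in `build_cloud_connectome()`:

1. `mean_type_density()` — elementwise mean of the instance grids of a
   type (the analogue of averaging reconstructed morphologies).
2. `convolve_clouds()` — the overlap field
   field(Δ) = Σ<sub>u</sub> dend(u) · axon(u − Δ), computed by FFT; the
   field mass equals the product of the cloud masses (checked to 1e-9).
3. `lookup_pair_overlaps()` — nearest-bin lookup of the field at every
   pair's soma offset (no interpolation, matching the grid-resolution
   semantics of the density data). Out-of-range offsets give 0 and are
   counted.
4. `transfer_and_normalize()` + `sample_without_replacement()` — apply
   Õ = O² (the exponent is a config knob, default 2, chosen to conserve
   distance-dependent connectivity), normalise, and draw exactly the
   reference count for the type pair by sequential weighted sampling
   without replacement.

The sampler is implemented as one vectorised pass with exponential sort
keys (`rexp(1)/w`, smallest keys win), which is equal in distribution to
the literal pick–zero–renormalise loop; the literal loop is retained
internally and the equivalence is tested against exact enumeration of the
sequential procedure on small weight vectors (maximum marginal deviation
below 0.02 at 10,000 seeds).

Blocks whose requested count exceeds the number of positive-probability
pairs raise an explicit infeasibility error naming the block; a correctly
generated circuit never encounters this, because targets are capped at
feasibility.

## The synthetic circuit generator

The generator is first-class, tested code: it defines the study
conditions under which every qualitative claim is checked.

* **Geometry.** A cylindrical column, radius 210 µm, depth 0–1000 µm in
  two layers (L2/3: 0–400, L5: 400–1000). These are roughly half-scale
  versions of a juvenile-rat microcircuit column, small enough that every
  stage runs on one CPU.
* **Composition.** Five m-types — two layer-2/3 (pyramidal + basket-like)
  and three layer-5 (two pyramidal classes + Martinotti-like) — at 80%
  excitatory, with Gaussian-mixture clouds whose components encode the
  salient anatomy (descending L2/3 axons, ascending L5 apical dendrites
  and Martinotti axons, compact interneuron arbours). Fractions follow
  largest-remainder rounding so counts sum exactly to `n_neurons`.
* **Within-type diversity.** One knob, η (µm): each neuron's clouds are
  displaced by independent Normal(0, η²) offsets along the lateral and
  depth axes and scaled in total mass by exp(Normal(0, (η/η_ref)²)),
  η_ref = 100 µm. The default η = 20 µm gives ±20 µm positional jitter
  and a 20% log-sd mass factor — the order of within-type variability of
  reconstructed arbours. η = 0 makes every neuron an exact copy of its
  type, and then the reference and cloud probability blocks coincide to
  machine precision (tested at < 1e-12), so the diversity knob is the
  *only* difference between the two wirings.
* **Reference wiring.** The stand-in for an apposition-derived connectome
  samples from squared *instance-level* overlaps: the type-pair field
  evaluated at jitter-displaced offsets and scaled by the two mass
  factors. The selection rule is deliberately symmetric with the cloud
  rule (squared overlap, sampling without replacement), so within-type
  diversity is the isolated variable; we do not claim it reproduces any
  specific apposition algorithm.
* **Connection attributes.** path_length = soma distance × tortuosity
  (default 1.2) + half-normal noise (10 µm), so paths are never shorter
  than the soma distance; synapse_count = 1 + Poisson(mean − 1), default
  mean 5.
* **Targets.** Per-type-pair counts are allocated proportionally to the
  type-level squared-overlap mass of each block, scaled to a mean
  efferent degree of 40 at the default 2,000-neuron scale (≈2%
  density — denser than a full-scale cortical circuit, chosen so simplex
  statistics are rich at desk scale). Targets depend only on neuron
  positions and type clouds, so reference and cloud share them by
  construction.

What the generator does *not* emulate: real reconstructed morphologies
(clouds are smooth mixtures, not arbours), bouton/innervation profiles,
apposition pruning, synapse-level physiology, and the full 31k-neuron,
55-type scale. Passing tests therefore demonstrate that the machinery
isolates within-type diversity under controlled conditions — not that any
specific biological circuit has a particular amount of higher-order
structure.

## Transplant, loss accounting, and the matched control

`transplant()` realises the cloud wiring inside the reference circuit
while inheriting synaptic attributes. Groups are (postsynaptic neuron,
presynaptic m-type); the reference's excitatory afferents of a group are
slots, and the cloud's new sources for that group are matched to slots by
a seeded random bijection (the pairing is not specified by the
construction, so a uniform random bijection is the natural choice).
Demand above the slot count duplicates uniformly chosen slots; demand
against zero slots is dropped and recorded per type pair
(required = placed + lost). Inhibitory connections pass through
unchanged, since reassigning them is not part of the construction. The
matched control (`matched_removal()` then `shuffle_path_length()`)
removes exactly the lost counts per type pair from the reference and
permutes path lengths within the same groups, which reproduces the
transplant's two side effects (slightly fewer excitatory connections;
biologically arbitrary delays) without its rewiring.

## Topology statistics: conventions and numerics

* Directed simplices are ordered tuples; reciprocal connections make
  orderings distinct. Enumeration is by recursive extension on sorted
  out-neighbourhood intersections (C++); an independent
  subset-permutation brute force backs every statistic in the tests.
* A simplex is maximal iff no vertex can be inserted at any position;
  this check is exact even when enumeration is capped at `max_dim`.
* Degree spreads use the population standard deviation (divisor n).
  Hub sets take the top `ceiling(fraction × n)` per direction, ties
  broken towards lower neuron ids; both the in/out union and intersection
  are reported since either reading of "top 0.5%" is defensible.
* Characteristic path length averages over ordered, mutually reachable
  pairs. The classical formula's 1/(N(N−1)) prefactor conflicts with
  restricting to mutually reachable pairs; we normalise by the number of
  such pairs, which reduces to the classical value on strongly connected
  graphs.
* Per-node clustering uses the directed-triangle form
  ((M+Mᵀ)³)ᵢᵢ / (2(dᵗᵒᵗ(dᵗᵒᵗ−1) − 2(M²)ᵢᵢ)); nodes with zero denominator
  (degree ≤ 1, or all neighbours reciprocal partners of a single node)
  get cᵢ = 0 so the network mean stays defined.
* Betti numbers are computed over the two-element field from
  boundary-matrix ranks and guarded at 64 neurons: flag-complex homology
  beyond that needs specialised software and is out of scope. The
  Euler–Poincaré identity against the simplex census is tested on every
  small graph.
* Triad censuses use the 13 connected classes with standard codes
  (030T = transitive triangle, 030C = cycle); counting is delegated to
  igraph and verified against a brute-force classifier.

## The activity stand-in

The simulator is a discrete-time conditional-Bernoulli (GLM-style hazard)
network — a deliberate stand-in for multicompartment simulation, not an
approximation of it. Per bin (default 1 ms), a neuron spikes with
probability 1 − exp(−exp(bias + drive)·Δt); drive is the exponentially
filtered (τ = 5 ms) sum of delayed inputs, each weighted by
w_class · g_class(γ) · synapse_count; delays are path_length / 300 µm·ms⁻¹
quantised to the step (minimum one step); an absolute refractory period
(2 ms) is enforced. Baseline rates are 2 Hz (excitatory) and 5 Hz
(inhibitory); default weights w_E = 0.10 and w_I = −0.30 per synapse give
a stable, balanced spontaneous state at the default excitability.

The calcium-like scalar γ emulates the experimental fact that
extracellular calcium scales excitatory synaptic efficacy more steeply
than inhibitory: g_E(γ) = γ^1.7, g_I(γ) = γ (both monotone, ratio
increasing). The default γ = 1.1 sits near the asynchronous end of the
asynchronous-to-synchronous transition; raising γ moves circuits towards
synchronous, strongly recurrent regimes, and individual circuit
realizations near the transition can tip into a high-rate attractor — the
knob is a one-parameter analogue of the calcium concentration axis, and
no quantitative mapping to mM is claimed. Thalamic input is a grid of
fibers (default 24 at the 1,000-neuron activity scale, mirroring the
~1:100 fiber-to-neuron ratio of a full column) innervating neurons within
80 µm, firing as inhomogeneous Poisson processes with a shared burst
envelope (100 Hz bursts of 80 ms every 400 ms by default) — a periodic
caricature of whisker-evoked thalamic drive. Fiber placement is fixed
across trials; spike draws are per-trial.

Only directional and ordering claims are made about activity: no firing
rate, correlation, or reliability magnitude of any biophysical model is
asserted or matched.

## Activity analytics: conventions

* PSTH correlation matrices use 20 ms bins over concatenated trials;
  neurons with zero PSTH variance are excluded and flagged.
* Trial correlations of the population PSTH use 5 ms bins; within one
  model all K(K−1)/2 unordered pairs of distinct trials are averaged,
  between two models all unordered index pairs including equal indices
  (K(K+1)/2 for equal K; 435 and 465 at K = 30).
* Spike-time reliability follows the correlation-based measure: Gaussian
  kernel σ_S = 5 ms on a 0.5 ms grid, kernel truncated at 5σ; trial pairs
  with an empty train are skipped and neurons with fewer than two
  non-empty trials are undefined rather than zero.
* "Position of a pair in a simplex" means the consecutive pairs
  (v_k, v_{k+1}) of a maximal simplex, position 0 the source pair and
  n − 1 the sink pair, consistent with the definition of source/sink
  connections; non-consecutive pairs are not binned, since no position
  along the simplex is naturally theirs. The summary "sink exceeds
  source for dimensions ≥ 2"
  is evaluated on the count-weighted pooled means across those
  dimensions, which is stable where individual high-dimension classes
  are noisy.
* The exponential distance fit exp(−d/λ) + c uses Levenberg–Marquardt
  least squares with λ₀ = median distance and c₀ = minimum correlation;
  k-means clustering of soma positions uses 10 restarts under a fixed
  seed.

## Problem sizes and determinism

All stochastic entry points take an integer seed, restore the caller's
RNG state, and derive per-stage seeds from the pipeline seed, so a
configuration reproduces its artifacts exactly. The shipped study
conditions are: 2,000 neurons / mean degree 40 for structural
comparisons (simplex censuses to dimension 3), 1,000 neurons / mean
degree 30 / 6 trials of 2 s for evoked-activity comparisons (maximal
simplices to dimension 4), and 20 (structure) or 10 (activity) seeds for
the replicate-level claims. These sizes make the full test suite and the
acceptance script each run in minutes on one CPU while keeping simplex
counts in the hundreds of thousands, large enough for stable ratios.

## Known limitations

* Clouds are rotationally symmetric about the column axis and mirror-
  symmetric in the represented lateral coordinate; laterally biased
  arbours are out of scope.
* The mass-scale + displacement jitter is one concrete mechanism of
  within-type diversity; real diversity also reshapes arbours, which the
  generator does not attempt.
* The hazard simulator has no short-term synaptic plasticity, no
  dendritic filtering, and no conductance dynamics; its correlation
  structure is driven by shared input and recurrence only. Accordingly,
  the robust activity findings at desk scale are the rise of pair
  correlation with maximal-simplex dimension and the positive pooled
  sink-minus-source gap; the finer-grained claim that correlation climbs
  specifically along the sink-participation axis of the 2D-participation
  grid does not replicate reliably under this stand-in (the test suite
  computes and logs it without asserting it).
* Betti numbers are exact but limited to small graphs; simplex censuses
  at the full cortical-column scale require specialised external tools.
* Ingestion of externally published connectome edge lists is supported
  through the TSV/Matrix Market readers, but no analysis in the package
  depends on downloaded data.
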