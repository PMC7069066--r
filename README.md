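# cloudwire

Separating first-order from higher-order structure in cortical
microcircuit connectomes.

Dense cortical wiring diagrams contain structure beyond what pairwise
statistics (type-to-type connection counts, distance-dependent connection
probabilities, reciprocity) can describe: neurons cluster into directed
all-to-all-connected motifs — *directed simplices* — far more often than
matched controls predict, degree distributions are long-tailed, and
connected pairs share more common neighbours than chance. `cloudwire`
implements the null-model construction that isolates this higher-order
structure, the graph-topology statistics that quantify it, and the
spike-train analytics that relate it to network activity, together with a
synthetic-circuit generator so the whole pipeline runs at desk scale
without any external data.

## The method

**Cloud wiring.** For each morphological type (m-type) *m*, average the
axonal and dendritic arbour density clouds of its neurons,
V<sup>axon</sup><sub>m</sub>(x, y) and V<sup>dend</sup><sub>m</sub>(x, y),
on a regular (lateral, depth) grid. For every ordered type pair
*m<sub>i</sub>* → *m<sub>j</sub>* convolve them into an overlap field, look
the field up at the soma offset of every neuron pair to get an overlap
matrix *O*, apply the transfer function *Õ = O²*, normalise *Õ* into
connection probabilities, and draw exactly the reference wiring's number of
connections for that type pair by weighted sampling **without**
replacement (pick, zero, renormalise, repeat). The resulting
*cloud connectome* preserves first-order structure — the macroconnectome is
conserved exactly, distance dependence and reciprocity almost exactly — but
erases structure carried by within-type morphological diversity.

**Controls.** `transplant()` implements the cloud wiring inside an
attribute-carrying reference connectome, reassigning presynaptic sources
within (postsynaptic neuron, presynaptic m-type) groups so that synapse
counts and axonal path lengths are inherited from existing connections
(duplicating or dropping connections where group demands exceed or lack
slots, with full loss accounting), for excitatory connections only.
`matched_removal()` + `shuffle_path_length()` build the matched control
that removes exactly the same per-type-pair connection counts from the
reference and shuffles path lengths within afferent groups, so that losses
and delay scrambling are ruled out as explanations for activity
differences.

**Topology.** Directed simplex and maximal-simplex censuses (a directed
n-simplex is an (n+1)-tuple with an edge from every earlier to every later
member; orderings count separately), higher-order in-degrees, per-connection
source/sink simplex participation and polarity, Euler characteristic, Betti
numbers over GF(2) on small graphs, triad censuses, directed clustering
c<sub>i</sub> = ((M+Mᵀ)³)<sub>ii</sub> / (2(d<sub>i</sub><sup>tot</sup>(d<sub>i</sub><sup>tot</sup>−1) − 2(M²)<sub>ii</sub>)),
characteristic path length over mutually reachable pairs, and the
small-worldness ratio c/l against a matched Erdős–Rényi reference.

**Activity.** A seeded discrete-time hazard (GLM-style) spiking network
stands in for detailed biophysical simulation: per-bin spiking probability
1 − exp(−exp(bias + drive)·Δt) with exponentially filtered, delayed
synaptic input and a calcium-like scalar γ that scales excitatory gain
(γ^1.7) faster than inhibitory (γ), plus a thalamic-fiber stimulus.
Analytics: firing rates, E/I spike ratios, PSTH correlation matrices
R<sub>ij</sub> = C<sub>ij</sub>/√(C<sub>ii</sub>C<sub>jj</sub>),
within/between-model trial correlations, spike-time reliability (Gaussian
kernel, σ<sub>S</sub> = 5 ms), spatial-cluster distance correlations with an
exp(−d/λ) + c fit, and correlation profiles by position of a pair within
maximal simplices.

## Worked example

```r
library(cloudwire)

spec <- circuit_spec(n_neurons = 800, eta = 20, grid_bin = 8, seed = 1)
circ <- build_circuit(spec, mean_degree = 30)          # reference wiring
cloud <- build_cloud_connectome(circ$neurons, circ$morphologies,
                                circ$reference, seed = 2)

degree_summary(circ$reference)
#> <degree_summary: 800 neurons, 24000 edges, sigma_in 17.75, sigma_out 20.66, cor 0.428>
degree_summary(cloud)
#> <degree_summary: 800 neurons, 24000 edges, sigma_in 12.98, sigma_out 16.08, cor 0.550>

count_simplices(circ$reference, max_dim = 3)
#>   dim0   dim1   dim2   dim3
#>    800  24000 160636 632711
count_simplices(cloud, max_dim = 3)
#>   dim0   dim1   dim2   dim3
#>    800  24000 132448 435210

clustering_coefficients(circ$reference)
#> <small_world_stats: c = 0.1681, l = 2.629, c/l = 0.0639>
clustering_coefficients(cloud)
#> <small_world_stats: c = 0.1433, l = 2.589, c/l = 0.0554>

tp <- transplant(cloud, circ$reference, circ$neurons, seed = 3)
tp$loss
#> <loss_report: 16649 excitatory connections required, 194 lost (1.17%), 3619 duplicated>
```

Both wirings have identical edge counts for every m-type pair (the
macroconnectome is conserved by construction), yet the reference — whose
connection probabilities reflect each neuron's individually jittered
morphology — has visibly broader in-/out-degree distributions (σ_in 17.8
vs. 13.0), ~21% more 2D simplices, ~45% more 3D simplices, and a higher
clustering coefficient and small-worldness ratio. That surplus is the
higher-order structure attributable to within-type morphological
diversity. The loss report documents the few cloud connections that cannot
be realised inside the reference circuit (postsynaptic neurons with no
existing afferent of the required m-type), which the matched-removal
control then removes from the reference.

`run_pipeline(default_pipeline_config())` chains all stages — circuit,
wirings, transplant, control, structural comparison, three-variant
simulation, activity analysis — into one seeded, reproducible run.

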