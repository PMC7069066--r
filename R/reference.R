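#' Sample the reference ("apposition-like") connectome
#'
#' The synthetic stand-in for a wiring derived from individual morphologies:
#' identical to the cloud construction except that overlap strengths are
#' evaluated at the instance level — each neuron's clouds carry its own
#' jitter displacement and mass factor — so that within-type morphological
#' diversity is the only difference from the cloud wiring. Selection
#' probabilities are proportional to the squared instance overlap, sampled
#' without replacement; per-m-type-pair edge counts equal `targets` exactly.
#' With `eta = 0` the per-pair probabilities coincide with the cloud block
#' probabilities for the same circuit.
#'
#' @param neurons neuron table.
#' @param morphologies `morphology_set`.
#' @param targets data.frame (`pre_mtype`, `post_mtype`, `count`); see
#'   [default_pair_targets()].
#' @param seed integer seed.
#' @param exponent transfer exponent (default 2, as for the cloud wiring).
#' @return a `connectome`.
#' @export
sample_reference_connectome <- function(neurons, morphologies, targets,
                                        seed = 1L, exponent = 2) {
  sample_block_connectome(neurons, morphologies, targets, seed, exponent,
                          cloud = FALSE)
}

#' Default per-m-type-pair connection targets
#'
#' Allocates `round(mean_degree * n)` connections across m-type
#' combinations proportionally to the total squared type-level overlap mass
#' of each block (largest-remainder rounding, capped at the number of pairs
#' with positive overlap). Targets depend only on the neuron positions and
#' type clouds, not on the jitter draw, so reference and cloud wirings of
#' the same circuit share them.
#'
#' @param neurons neuron table.
#' @param morphologies `morphology_set`.
#' @param mean_degree desired mean number of efferent connections per
#'   neuron (default 40).
#' @param exponent transfer exponent (default 2).
#' @return data.frame with columns `pre_mtype`, `post_mtype`, `count`.
#' @export
default_pair_targets <- function(neurons, morphologies, mean_degree = 40,
                                 exponent = 2) {
  fields <- all_overlap_fields(morphologies, cloud = FALSE)
  types <- morphologies$spec$mtypes$name
  combos <- expand.grid(pre_mtype = types, post_mtype = types,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mass <- numeric(nrow(combos))
  avail <- integer(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    O <- lookup_pair_overlaps(neurons,
                              fields[[block_key(combos$pre_mtype[k],
                                                combos$post_mtype[k])]],
                              combos$pre_mtype[k], combos$post_mtype[k])
    Ot <- O^exponent
    mass[k] <- sum(Ot)
    avail[k] <- sum(Ot > 0)
  }
  total <- round(mean_degree * nrow(neurons))
  q <- total * mass / sum(mass)
  cnt <- floor(q)
  rem <- total - sum(cnt)
  if (rem > 0) {
    extra <- order(q - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  combos$count <- as.integer(pmin(cnt, avail))
  combos
}

#' Assign synapse counts and axonal path lengths to connections
#'
#' `path_length = (Euclidean soma distance) * tortuosity + |Normal(0,
#' noise_sd^2)|` (so `path_length >= soma distance` whenever
#' `tortuosity >= 1`), and `synapse_count = 1 + Poisson(mean_synapses - 1)`.
#'
#' @param conn a `connectome`.
#' @param neurons neuron table.
#' @param tortuosity multiplicative detour factor (>= 1, default 1.2).
#' @param noise_sd scale (um) of the half-normal path-length noise.
#' @param mean_synapses mean synapses per connection (>= 1, default 5).
#' @param seed integer seed.
#' @return the connectome with `synapse_count` and `path_length` columns.
#' @export
assign_connection_attributes <- function(conn, neurons, tortuosity = 1.2,
                                         noise_sd = 10, mean_synapses = 5,
                                         seed = 1L) {
  stopifnot(tortuosity >= 1, mean_synapses >= 1, noise_sd >= 0)
  e <- conn$edges
  d <- sqrt((neurons$x_um[e$pre + 1L] - neurons$x_um[e$post + 1L])^2 +
              (neurons$y_um[e$pre + 1L] - neurons$y_um[e$post + 1L])^2 +
              (neurons$z_um[e$pre + 1L] - neurons$z_um[e$post + 1L])^2)
  with_seed(seed, {
    e$synapse_count <- 1L + rpois(nrow(e), mean_synapses - 1)
    e$path_length <- d * tortuosity + abs(rnorm(nrow(e), 0, noise_sd))
  })
  conn$edges <- e
  conn
}

#' Generate a full synthetic circuit
#'
#' Convenience wrapper running neuron generation, morphology instantiation,
#' target allocation, reference wiring, and attribute assignment.
#'
#' @param spec a [circuit_spec()].
#' @param mean_degree mean efferent degree for [default_pair_targets()].
#' @param ... passed to [assign_connection_attributes()].
#' @return list with elements `spec`, `neurons`, `morphologies`, `targets`,
#'   `reference` (a `connectome` with attributes).
#' @export
build_circuit <- function(spec, mean_degree = 40, ...) {
  neurons <- generate_neurons(spec)
  morph <- instantiate_morphologies(neurons, spec)
  targets <- default_pair_targets(neurons, morph, mean_degree = mean_degree)
  ref <- sample_reference_connectome(neurons, morph, targets,
                                     seed = derive_seed(spec$seed, 7L))
  ref <- assign_connection_attributes(ref, neurons,
                                      seed = derive_seed(spec$seed, 8L), ...)
  list(spec = spec, neurons = neurons, morphologies = morph,
       targets = targets, reference = ref)
}
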