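#' Specification of a synthetic cortical column
#'
#' Describes a layered cylindrical column of neurons partitioned into
#' morphological types (m-types), each with excitatory/inhibitory class, a
#' population fraction, and Gaussian-mixture axon/dendrite density clouds.
#' Within-type morphological diversity is controlled by a single jitter
#' parameter `eta`: each neuron's clouds are displaced by a random offset
#' with standard deviation `eta` um per axis (lateral, depth) and scaled in
#' total mass by a log-normal factor with log-sd `eta / eta_ref`. With
#' `eta = 0` every neuron is an exact copy of its type.
#'
#' @param n_neurons number of neurons.
#' @param mtypes m-type catalog: data.frame with columns `name`, `layer`,
#'   `synapse_class` ("EXC"/"INH"), `fraction`, and list-columns `axon`,
#'   `dendrite` holding Gaussian-mixture data.frames (`weight`, `x`, `y`,
#'   `sd`, um; `y` is the depth offset from the soma, positive = deeper).
#' @param layers data.frame with columns `name`, `y_min`, `y_max` (um);
#'   intervals must be disjoint and tile `[0, depth_max]`.
#' @param column_radius lateral radius of the column (um).
#' @param eta within-type morphological jitter (um, >= 0).
#' @param eta_ref reference scale converting `eta` to the log-sd of the
#'   per-neuron mass factor (`eta / eta_ref`); default 100 um.
#' @param grid_bin density-grid resolution in um (default 2).
#' @param seed integer seed controlling neuron placement and jitter.
#' @return object of class `circuit_spec`.
#' @export
circuit_spec <- function(n_neurons = 2000,
                         mtypes = default_mtype_catalog(),
                         layers = default_layers(),
                         column_radius = 210,
                         eta = 20,
                         eta_ref = 100,
                         grid_bin = 2,
                         seed = 1L) {
  stopifnot(n_neurons >= 1, eta >= 0, grid_bin > 0, column_radius > 0)
  if (nrow(mtypes) == 0) stop("empty m-type catalog")
  if (abs(sum(mtypes$fraction) - 1) > 1e-9) {
    stop("m-type fractions must sum to 1")
  }
  if (!all(mtypes$synapse_class %in% c("EXC", "INH"))) {
    stop("synapse_class must be EXC or INH")
  }
  if (!all(mtypes$layer %in% layers$name)) stop("unknown layer in catalog")
  ly <- layers[order(layers$y_min), ]
  if (ly$y_min[1] != 0 ||
      any(abs(ly$y_min[-1] - ly$y_max[-nrow(ly)]) > 1e-9)) {
    stop("layer intervals must tile [0, depth_max] without gaps")
  }
  structure(list(n_neurons = as.integer(n_neurons), mtypes = mtypes,
                 layers = layers, column_radius = column_radius, eta = eta,
                 eta_ref = eta_ref, grid_bin = grid_bin,
                 seed = as.integer(seed)),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf(
    "<circuit_spec: %d neurons, %d m-types, %d layers, eta = %g um, bin = %g um, seed = %d>\n",
    x$n_neurons, nrow(x$mtypes), nrow(x$layers), x$eta, x$grid_bin, x$seed))
  invisible(x)
}

gm <- function(weight, x, y, sd) data.frame(weight = weight, x = x, y = y, sd = sd)

#' Default two-layer, five-m-type catalog
#'
#' A reduced, desk-scale stand-in for a cortical column: layer 2/3 and layer
#' 5 populations with 80% excitatory neurons. Pyramidal-cell clouds have
#' descending (L2/3) or ascending (L5 apical / Martinotti axon) components;
#' interneuron clouds are compact. All cloud masses are 1 per component.
#'
#' @return m-type catalog data.frame as used by [circuit_spec()].
#' @export
default_mtype_catalog <- function() {
  cat <- data.frame(
    name = c("L23_PC", "L23_NBC", "L5_TTPC", "L5_STPC", "L5_MC"),
    layer = c("L23", "L23", "L5", "L5", "L5"),
    synapse_class = c("EXC", "INH", "EXC", "EXC", "INH"),
    fraction = c(0.35, 0.10, 0.30, 0.15, 0.10)
  )
  cat$dendrite <- list(
    gm(c(0.7, 0.3), 0, c(0, -80), c(60, 80)),
    gm(1, 0, 0, 60),
    gm(c(0.6, 0.4), 0, c(0, -300), c(80, 130)),
    gm(1, 0, 0, 80),
    gm(1, 0, 0, 70)
  )
  cat$axon <- list(
    gm(c(0.5, 0.5), 0, c(0, 300), c(80, 120)),
    gm(1, 0, 0, 70),
    gm(c(0.7, 0.3), 0, c(0, -250), c(100, 120)),
    gm(1, 0, 0, 90),
    gm(c(0.6, 0.4), 0, c(0, -200), c(80, 100))
  )
  cat
}

#' Default layer intervals (um depth)
#' @export
default_layers <- function() {
  data.frame(name = c("L23", "L5"), y_min = c(0, 400), y_max = c(400, 1000))
}

#' Generate neuron identities and soma positions
#'
#' Per-m-type counts follow largest-remainder rounding of
#' `fraction * n_neurons` (floors first, then one extra neuron to the types
#' with the largest fractional remainders, ties by catalog order), so counts
#' sum exactly to `n_neurons`. Somata are uniform in the column's circular
#' cross-section and uniform in depth within the m-type's layer.
#'
#' @param spec a [circuit_spec()].
#' @return neuron table: data.frame with columns `neuron_id` (0-based,
#'   contiguous), `m_type`, `layer`, `synapse_class`, `x_um`, `y_um`
#'   (depth), `z_um`.
#' @export
generate_neurons <- function(spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  q <- spec$mtypes$fraction * spec$n_neurons
  counts <- floor(q)
  rem <- spec$n_neurons - sum(counts)
  if (rem > 0) {
    extra <- order(q - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$mtypes)), function(k) {
      n_k <- counts[k]
      if (n_k == 0) return(NULL)
      ly <- spec$layers[spec$layers$name == spec$mtypes$layer[k], ]
      r <- spec$column_radius * sqrt(runif(n_k))
      th <- runif(n_k, 0, 2 * pi)
      data.frame(m_type = spec$mtypes$name[k], layer = ly$name,
                 synapse_class = spec$mtypes$synapse_class[k],
                 x_um = r * cos(th),
                 y_um = runif(n_k, ly$y_min, ly$y_max),
                 z_um = r * sin(th))
    })
    out <- do.call(rbind, rows)
    out <- cbind(neuron_id = seq_len(nrow(out)) - 1L, out)
    rownames(out) <- NULL
    out
  })
}

#' Instantiate per-neuron jittered morphologies
#'
#' Each neuron's clouds are those of its m-type, displaced by independent
#' Normal(0, eta^2) offsets along the lateral and depth axes and scaled in
#' mass by `exp(Normal(0, (eta/eta_ref)^2))`. With `eta = 0` every neuron's
#' parameters equal its type's exactly.
#'
#' @param neurons a neuron table from [generate_neurons()].
#' @param spec the [circuit_spec()] used to generate it.
#' @return object of class `morphology_set`: the spec plus a per-neuron
#'   table of (`dlat_um`, `ddepth_um`, `scale`).
#' @export
instantiate_morphologies <- function(neurons, spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  n <- nrow(neurons)
  with_seed(derive_seed(spec$seed, 101L), {
    tab <- data.frame(
      neuron_id = neurons$neuron_id,
      m_type = neurons$m_type,
      dlat_um = spec$eta * rnorm(n),
      ddepth_um = spec$eta * rnorm(n),
      scale = exp((spec$eta / spec$eta_ref) * rnorm(n))
    )
  })
  structure(list(spec = spec, table = tab), class = "morphology_set")
}

#' @export
print.morphology_set <- function(x, ...) {
  cat(sprintf("<morphology_set: %d neurons, eta = %g um>\n",
              nrow(x$table), x$spec$eta))
  invisible(x)
}

# Render the type-level cloud of one m-type/component at the spec's bin.
type_density <- function(spec, m_type, component = c("axon", "dendrite")) {
  component <- match.arg(component)
  k <- match(m_type, spec$mtypes$name)
  if (is.na(k)) stop("unknown m-type: ", m_type)
  render_density(spec$mtypes[[component]][[k]], spec$grid_bin,
                 m_type = m_type, component = component)
}

#' Density cloud of a single neuron instance
#'
#' The type cloud displaced by the neuron's jitter offset (quantised to the
#' grid lattice) and scaled by its mass factor.
#'
#' @param morphologies a `morphology_set`.
#' @param neuron_id 0-based neuron id.
#' @param component `"axon"` or `"dendrite"`.
#' @return a `density_grid`.
#' @export
instance_density <- function(morphologies, neuron_id, component) {
  spec <- morphologies$spec
  row <- morphologies$table[neuron_id + 1L, ]
  g <- type_density(spec, row$m_type, component)
  b <- g$bin
  density_grid(g$values * row$scale, b,
               g$x0 + round(row$dlat_um / b) * b,
               g$y0 + round(row$ddepth_um / b) * b,
               m_type = row$m_type, component = component)
}

#' Mean density cloud of an m-type
#'
#' The elementwise arithmetic mean of the instance grids of all neurons of
#' the m-type (the analogue of averaging reconstructed morphologies). Also
#' accepts a plain list of `density_grid`s.
#'
#' @param x a `morphology_set` or a list of `density_grid`s.
#' @param m_type,component required when `x` is a `morphology_set`.
#' @return a `density_grid`.
#' @export
mean_type_density <- function(x, m_type = NULL, component = NULL) {
  if (is.list(x) && !inherits(x, "morphology_set")) {
    return(mean_density_grids(x))
  }
  stopifnot(inherits(x, "morphology_set"))
  idx <- which(x$table$m_type == m_type)
  if (length(idx) == 0) stop("no instances of m-type ", m_type)
  g <- type_density(x$spec, m_type, component)
  b <- g$bin
  ki <- round(x$table$dlat_um[idx] / b)
  kj <- round(x$table$ddepth_um[idx] / b)
  # Mean of shifted/scaled copies == convolution of the type grid with the
  # (mass-weighted) displacement histogram.
  i0 <- min(ki); j0 <- min(kj)
  h <- matrix(0, max(ki) - i0 + 1L, max(kj) - j0 + 1L)
  for (t in seq_along(idx)) {
    h[ki[t] - i0 + 1L, kj[t] - j0 + 1L] <-
      h[ki[t] - i0 + 1L, kj[t] - j0 + 1L] + x$table$scale[idx[t]]
  }
  vals <- if (all(dim(h) == 1L)) {
    g$values * (h[1L, 1L] / length(idx))
  } else {
    conv2_full(g$values, h) / length(idx)
  }
  density_grid(vals, b, g$x0 + i0 * b, g$y0 + j0 * b,
               m_type = m_type, component = component)
}
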