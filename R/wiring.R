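#' Convolve dendrite and axon density clouds into an overlap field
#'
#' Computes `field(offset) = sum_u dendrite(u) * axon(u - offset)`, the
#' expected overlap strength of the two arbours for somata at every relative
#' position. The total field mass equals the product of the two cloud
#' masses.
#'
#' For a connection pre -> post the relevant field is
#' `convolve_clouds(dendrite of post type, axon of pre type)`, evaluated at
#' the offset (pre soma - post soma); see [lookup_pair_overlaps()].
#'
#' @param dendrite,axon `density_grid` objects with equal bin size.
#' @return an object of class `overlap_field` (a `density_grid` with
#'   `pre_mtype`/`post_mtype` labels).
#' @export
convolve_clouds <- function(dendrite, axon) {
  if (abs(dendrite$bin - axon$bin) > 1e-9) {
    stop("mismatched bin sizes: ", dendrite$bin, " vs ", axon$bin)
  }
  ra <- reverse_grid(axon)
  vals <- conv2_full(dendrite$values, ra$values)
  out <- density_grid(vals, dendrite$bin, dendrite$x0 + ra$x0,
                      dendrite$y0 + ra$y0)
  out$pre_mtype <- axon$m_type
  out$post_mtype <- dendrite$m_type
  class(out) <- c("overlap_field", class(out))
  out
}

#' Look up overlap strengths for all neuron pairs of an m-type combination
#'
#' Evaluates the pre -> post overlap field at the soma offset of every
#' (pre, post) pair by nearest-bin lookup. The lateral coordinate is the
#' signed lateral offset `r + dlat_pre - dlat_post` (with `r >= 0` the soma
#' lateral distance), the depth coordinate `y_pre - y_post` (plus jitter
#' offsets when `morphologies` is supplied, in which case entries are also
#' scaled by the product of the two instance mass factors). Offsets outside
#' the field evaluate to 0 and are counted in the `"n_out_of_range"`
#' attribute. Same-neuron entries are set to 0.
#'
#' @param neurons a neuron table.
#' @param field an `overlap_field` from [convolve_clouds()].
#' @param pre_mtype,post_mtype m-type names selecting the block.
#' @param morphologies optional `morphology_set` for instance-level lookup.
#' @return numeric matrix `O` (rows: pre neurons, cols: post neurons, both
#'   in increasing id order, ids in the `"pre_ids"`/`"post_ids"` attributes).
#' @export
lookup_pair_overlaps <- function(neurons, field, pre_mtype, post_mtype,
                                 morphologies = NULL) {
  if (!pre_mtype %in% neurons$m_type) stop("unknown m-type: ", pre_mtype)
  if (!post_mtype %in% neurons$m_type) stop("unknown m-type: ", post_mtype)
  pre <- neurons[neurons$m_type == pre_mtype, ]
  post <- neurons[neurons$m_type == post_mtype, ]
  r <- sqrt(outer(pre$x_um, post$x_um, "-")^2 +
              outer(pre$z_um, post$z_um, "-")^2)
  dy <- outer(pre$y_um, post$y_um, "-")
  scale <- NULL
  if (!is.null(morphologies)) {
    mt <- morphologies$table
    r <- r + outer(mt$dlat_um[pre$neuron_id + 1L],
                   mt$dlat_um[post$neuron_id + 1L], "-")
    dy <- dy + outer(mt$ddepth_um[pre$neuron_id + 1L],
                     mt$ddepth_um[post$neuron_id + 1L], "-")
    scale <- outer(mt$scale[pre$neuron_id + 1L],
                   mt$scale[post$neuron_id + 1L])
  }
  vals <- grid_value_at(field, r, dy)
  oor <- attr(vals, "n_out_of_range")
  O <- matrix(vals, nrow(pre), nrow(post))
  if (!is.null(scale)) O <- O * scale
  if (pre_mtype == post_mtype) {
    O[cbind(seq_len(nrow(pre)), seq_len(nrow(post)))] <- 0
  }
  attr(O, "pre_ids") <- pre$neuron_id
  attr(O, "post_ids") <- post$neuron_id
  attr(O, "n_out_of_range") <- oor
  O
}

#' Transfer and normalize an overlap block into connection probabilities
#'
#' Applies the transfer function `O_tilde = O^exponent` (default exponent 2,
#' which conserves distance-dependent connectivity) and normalizes to a
#' probability matrix `P = O_tilde / sum(O_tilde)`. Zeros in `O` stay zero
#' in `P`; an all-zero block is flagged empty.
#'
#' @param O non-negative overlap matrix from [lookup_pair_overlaps()].
#' @param exponent transfer exponent (default 2).
#' @return object of class `block_probabilities` with elements `O`,
#'   `O_transferred`, `P`, `empty`.
#' @export
transfer_and_normalize <- function(O, exponent = 2) {
  if (any(O < 0)) stop("overlap entries must be non-negative")
  Ot <- O^exponent
  s <- sum(Ot)
  P <- if (s > 0) Ot / s else Ot
  structure(list(O = O, O_transferred = Ot, P = P, empty = s == 0,
                 pre_ids = attr(O, "pre_ids"), post_ids = attr(O, "post_ids")),
            class = "block_probabilities")
}

#' Weighted sampling without replacement by sequential renormalization
#'
#' Draws `n_target` distinct entries with the distribution of the sequential
#' procedure: pick an entry with probability proportional to its weight, set
#' its weight to zero, renormalize, repeat. Implemented as one vectorised
#' pass with exponential sort keys (`rexp(1)/w`, smallest keys win), which
#' is identical in distribution to the sequential loop.
#'
#' @param P numeric matrix or vector of non-negative weights (need not sum
#'   to 1).
#' @param n_target number of entries to draw; must not exceed the number of
#'   positive-weight entries.
#' @param seed optional integer seed.
#' @param label block label used in infeasibility errors.
#' @return integer vector of `n_target` distinct (linear) indices into `P`,
#'   in the order drawn.
#' @export
sample_without_replacement <- function(P, n_target, seed = NULL,
                                       label = "block") {
  w <- as.numeric(P)
  if (any(w < 0)) stop("negative weights")
  pos <- which(w > 0)
  if (n_target > length(pos)) {
    stop(sprintf(
      "infeasible target for %s: %d connections requested but only %d entries have positive probability",
      label, n_target, length(pos)))
  }
  if (n_target == 0) return(integer(0))
  with_seed(seed, {
    keys <- rexp(length(pos)) / w[pos]
    pos[order(keys)[seq_len(n_target)]]
  })
}

# Literal sequential pick-zero-renormalize loop. Slow; retained as an
# independent reference for the vectorised sampler.
sample_sequential <- function(P, n_target, seed = NULL) {
  w <- as.numeric(P)
  with_seed(seed, {
    out <- integer(n_target)
    for (k in seq_len(n_target)) {
      out[k] <- sample.int(length(w), 1L, prob = w)
      w[out[k]] <- 0
    }
    out
  })
}

# Overlap fields for every (pre m-type, post m-type) combination.
# cloud = TRUE uses the mean instance clouds; FALSE the unjittered type
# clouds (the instance-level reference path).
all_overlap_fields <- function(morphologies, cloud = TRUE) {
  spec <- morphologies$spec
  types <- spec$mtypes$name
  ax <- lapply(types, function(m) {
    if (cloud) mean_type_density(morphologies, m, "axon")
    else type_density(spec, m, "axon")
  })
  de <- lapply(types, function(m) {
    if (cloud) mean_type_density(morphologies, m, "dendrite")
    else type_density(spec, m, "dendrite")
  })
  names(ax) <- names(de) <- types
  fields <- list()
  for (a in types) {
    for (b in types) {
      fields[[paste(a, b, sep = "->")]] <- convolve_clouds(de[[b]], ax[[a]])
    }
  }
  fields
}

block_key <- function(pre, post) paste(pre, post, sep = "->")

# Shared block-wise sampling engine for cloud and reference wirings.
sample_block_connectome <- function(neurons, morphologies, targets, seed,
                                    exponent, cloud) {
  fields <- all_overlap_fields(morphologies, cloud = cloud)
  edges <- vector("list", nrow(targets))
  for (k in seq_len(nrow(targets))) {
    tgt <- targets$count[k]
    if (tgt == 0) next
    key <- block_key(targets$pre_mtype[k], targets$post_mtype[k])
    O <- lookup_pair_overlaps(neurons, fields[[key]], targets$pre_mtype[k],
                              targets$post_mtype[k],
                              morphologies = if (cloud) NULL else morphologies)
    bp <- transfer_and_normalize(O, exponent = exponent)
    idx <- sample_without_replacement(bp$P, tgt,
                                      seed = derive_seed(seed, k),
                                      label = key)
    rc <- arrayInd(idx, dim(bp$P))
    edges[[k]] <- data.frame(pre = bp$pre_ids[rc[, 1]],
                             post = bp$post_ids[rc[, 2]])
  }
  out <- do.call(rbind, edges)
  if (is.null(out)) out <- data.frame(pre = integer(0), post = integer(0))
  connectome(out[order(out$pre, out$post), , drop = FALSE], nrow(neurons))
}

#' Build the cloud connectome matched to a reference wiring
#'
#' For every (pre m-type, post m-type) combination, convolves the mean
#' axon/dendrite clouds of the two types, looks up the overlap strengths of
#' all neuron pairs, squares and normalizes them into connection
#' probabilities, and draws exactly as many connections as the reference
#' wiring contains for that combination (sampling without replacement with
#' sequential renormalization). The macroconnectome is therefore conserved
#' exactly; the microconnectome is not.
#'
#' @param neurons neuron table.
#' @param morphologies `morphology_set` (supplies the mean type clouds).
#' @param reference a `connectome` whose per-m-type-pair counts are the
#'   targets; alternatively pass `targets` directly.
#' @param seed integer seed.
#' @param exponent transfer exponent (default 2).
#' @param targets optional data.frame (`pre_mtype`, `post_mtype`, `count`)
#'   overriding the reference counts.
#' @return a `connectome` (without edge attributes).
#' @export
build_cloud_connectome <- function(neurons, morphologies, reference,
                                   seed = 1L, exponent = 2, targets = NULL) {
  if (is.null(targets)) targets <- pair_targets_of(reference, neurons)
  sample_block_connectome(neurons, morphologies, targets, seed, exponent,
                          cloud = TRUE)
}

# Per-pair counts of an existing connectome as a targets data.frame.
pair_targets_of <- function(conn, neurons) {
  m <- macroconnectome(conn, neurons)
  data.frame(pre_mtype = rep(rownames(m), ncol(m)),
             post_mtype = rep(colnames(m), each = nrow(m)),
             count = as.integer(m))
}
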