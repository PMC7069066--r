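#' Distance distribution of connections for a neuron group
#'
#' Histogram of Euclidean soma-to-soma distances of the connections whose
#' postsynaptic (direction `"afferent"`) or presynaptic (`"efferent"`)
#' neuron belongs to `group`, normalised to unit mass.
#'
#' @param conn a `connectome`.
#' @param neurons neuron table.
#' @param direction `"afferent"` or `"efferent"`.
#' @param group integer vector of 0-based neuron ids (e.g. one layer).
#' @param bin bin width in um (default 20).
#' @param max_distance histogram range (default: covers the largest
#'   distance present; pass explicitly to compare wirings on equal bins).
#' @return object of class `distance_distribution`: list with `breaks`,
#'   `mass`, `n_edges`, `direction`, `bin`.
#' @export
connection_distance_distribution <- function(conn, neurons,
                                             direction = c("afferent",
                                                           "efferent"),
                                             group, bin = 20,
                                             max_distance = NULL) {
  direction <- match.arg(direction)
  if (length(group) == 0) stop("empty group")
  stopifnot(bin > 0)
  e <- conn$edges
  sel <- if (direction == "afferent") e$post %in% group else e$pre %in% group
  e <- e[sel, , drop = FALSE]
  if (nrow(e) == 0) stop("no ", direction, " edges for this group")
  d <- sqrt((neurons$x_um[e$pre + 1L] - neurons$x_um[e$post + 1L])^2 +
              (neurons$y_um[e$pre + 1L] - neurons$y_um[e$post + 1L])^2 +
              (neurons$z_um[e$pre + 1L] - neurons$z_um[e$post + 1L])^2)
  if (is.null(max_distance)) max_distance <- max(d)
  breaks <- seq(0, bin * ceiling(max_distance / bin + 1e-9), by = bin)
  counts <- tabulate(pmin(floor(d / bin) + 1L, length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mass = counts / sum(counts),
                 n_edges = nrow(e), direction = direction, bin = bin),
            class = "distance_distribution")
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `D(P || Q) = sum p log(p / q)` in nats, after adding the pseudocount
#' `eps` to every bin of both distributions and renormalising (so empty
#' bins never produce infinities).
#'
#' @param P,Q `distance_distribution` objects or plain numeric mass vectors
#'   on identical binning.
#' @param eps pseudocount (default 1e-9).
#' @return divergence in nats (>= 0).
#' @export
kl_divergence <- function(P, Q, eps = 1e-9) {
  get_mass <- function(x) {
    if (inherits(x, "distance_distribution")) x$mass else as.numeric(x)
  }
  if (inherits(P, "distance_distribution") &&
      inherits(Q, "distance_distribution")) {
    if (abs(P$bin - Q$bin) > 1e-9) stop("binning mismatch")
  }
  p <- get_mass(P)
  q <- get_mass(Q)
  if (length(p) != length(q)) {
    # pad the shorter tail with empty bins
    n <- max(length(p), length(q))
    p <- c(p, rep(0, n - length(p)))
    q <- c(q, rep(0, n - length(q)))
  }
  p <- p + eps
  q <- q + eps
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Overexpression of reciprocal connectivity
#'
#' Within a neuron group, the reciprocal connection probability divided by
#' the square of the (pooled) unidirectional connection probability:
#' `p_rec / p_uni^2`, where `p_uni = E / (n (n - 1))` over ordered pairs and
#' `p_rec` is the fraction of unordered pairs connected in both directions.
#' Independent wiring gives 1. With `pairwise = TRUE` the denominator is
#' instead the product of the two direction-specific probabilities (edge
#' from the lower-id to the higher-id neuron, and the reverse), which
#' differs from the pooled estimator when the two directions are
#' imbalanced.
#'
#' @param conn a `connectome`.
#' @param group integer vector of 0-based ids (>= 2 neurons).
#' @param pairwise use the directional product estimator (default FALSE).
#' @return overexpression ratio.
#' @export
reciprocal_overexpression <- function(conn, group, pairwise = FALSE) {
  if (length(group) < 2) stop("group needs at least two neurons")
  e <- conn$edges
  keep <- e$pre %in% group & e$post %in% group
  e <- e[keep, , drop = FALSE]
  n <- length(group)
  if (nrow(e) == 0) stop("p_uni is zero for this group")
  key <- paste(pmin(e$pre, e$post), pmax(e$pre, e$post))
  n_rec <- sum(table(key) == 2)
  p_rec <- n_rec / (n * (n - 1) / 2)
  if (!pairwise) {
    p_uni <- nrow(e) / (n * (n - 1))
    return(p_rec / p_uni^2)
  }
  n_pairs <- n * (n - 1) / 2
  p_up <- sum(e$pre < e$post) / n_pairs
  p_down <- sum(e$pre > e$post) / n_pairs
  if (p_up == 0 || p_down == 0) stop("p_uni is zero for this group")
  p_rec / (p_up * p_down)
}

#' Common-neighbour bias curve
#'
#' Bins ordered neuron pairs by their number of common neighbours (neurons
#' adjacent, in either direction, to both) and reports the connection
#' probability in each bin normalised by the overall connection
#' probability. With `sample_size = NULL` (default) all ordered pairs are
#' used; otherwise a seeded sample. Bins with fewer than `min_pairs` pairs
#' are omitted and flagged.
#'
#' @param conn a `connectome`.
#' @param sample_size number of ordered pairs to sample, or `NULL` for all.
#' @param seed integer seed (used only when sampling).
#' @param min_pairs minimum pairs per bin (default 10).
#' @return data.frame with columns `k` (common-neighbour count),
#'   `n_pairs`, `p_connected`, `normalized` (ratio to the overall rate);
#'   omitted bins in the `"omitted_k"` attribute.
#' @export
common_neighbor_bias <- function(conn, sample_size = NULL, seed = 1L,
                                 min_pairs = 10) {
  n <- conn$n_neurons
  M <- adjacency_matrix(conn)
  U <- ((M + Matrix::t(M)) > 0) * 1
  if (is.null(sample_size)) {
    # all ordered pairs: common-neighbour counts from U %*% U
    K <- as.matrix(U %*% U)
    off <- upper.tri(K) | lower.tri(K)
    k <- K[off]
    connected <- as.matrix(M)[off] > 0
  } else {
    with_seed(seed, {
      a <- sample.int(n, sample_size, replace = TRUE)
      b <- sample.int(n, sample_size, replace = TRUE)
      ok <- a != b
      a <- a[ok]
      b <- b[ok]
    })
    # common neighbours: row products of the undirected adjacency
    k <- numeric(length(a))
    chunk <- 5000L
    for (s in seq(1, length(a), by = chunk)) {
      i <- s:min(s + chunk - 1L, length(a))
      k[i] <- Matrix::rowSums(U[a[i], , drop = FALSE] *
                                U[b[i], , drop = FALSE])
    }
    connected <- M[cbind(a, b)] > 0
  }
  overall <- mean(connected)
  tab <- split(connected, k)
  ks <- as.integer(names(tab))
  n_pairs <- lengths(tab)
  p <- vapply(tab, mean, numeric(1))
  keep <- n_pairs >= min_pairs
  out <- data.frame(k = ks[keep], n_pairs = as.integer(n_pairs[keep]),
                    p_connected = p[keep],
                    normalized = p[keep] / overall)
  attr(out, "omitted_k") <- ks[!keep]
  attr(out, "overall_p") <- overall
  out
}
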