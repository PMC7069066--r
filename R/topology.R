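# Internal wrapper around the C++ flag-complex enumerator.
flag_complex <- function(conn, max_dim = 30L, maximal = FALSE,
                         store_maximal = FALSE, participation = FALSE,
                         nd_in_degree = FALSE, store_all = FALSE) {
  flag_complex_cpp(conn$n_neurons, conn$edges$pre, conn$edges$post,
                   as.integer(max_dim), maximal, store_maximal,
                   participation, nd_in_degree, store_all)
}

trim_counts <- function(x, max_dim) {
  top <- max(which(x > 0), 1L)
  truncated <- top == max_dim + 1L && x[top] > 0
  out <- x[seq_len(top)]
  names(out) <- paste0("dim", seq_along(out) - 1L)
  attr(out, "truncated") <- truncated
  out
}

#' Count directed simplices per dimension
#'
#' A directed n-simplex is an (n+1)-tuple of neurons with a connection from
#' every earlier to every later member; orderings count separately, so a
#' reciprocally connected triangle contains six 2D simplices. Dimension 0
#' counts neurons, dimension 1 connections.
#'
#' @param conn a `connectome`.
#' @param max_dim largest dimension to enumerate (default 30; the
#'   enumeration stops early at the graph's top dimension). If the top
#'   dimension reaches `max_dim` the result carries attribute
#'   `truncated = TRUE`.
#' @return named numeric vector of counts (`dim0`, `dim1`, ...), trailing
#'   zero dimensions removed.
#' @export
count_simplices <- function(conn, max_dim = 30L) {
  fc <- flag_complex(conn, max_dim = max_dim)
  trim_counts(fc$counts, max_dim)
}

#' Count maximal directed simplices per dimension
#'
#' A simplex is maximal iff it is not a face (ordered sub-tuple) of any
#' higher-dimensional simplex.
#'
#' @inheritParams count_simplices
#' @param store if `TRUE`, also return the maximal simplices themselves.
#' @return named numeric vector of maximal counts; with `store = TRUE` a
#'   list with elements `counts` and `simplices` (per dimension, an integer
#'   matrix with one column per simplex, rows = positions, 0-based ids).
#' @export
count_maximal_simplices <- function(conn, max_dim = 30L, store = FALSE) {
  fc <- flag_complex(conn, max_dim = max_dim, maximal = TRUE,
                     store_maximal = store)
  counts <- trim_counts(fc$maximal_counts, max_dim)
  if (!store) return(counts)
  list(counts = counts, simplices = fc$maximal[seq_along(counts)])
}

#' Higher-order in-degree
#'
#' The ND-in-degree of a neuron is the number of ND-simplices it is the sink
#' of; for N = 1 this is the ordinary in-degree.
#'
#' @param conn a `connectome`.
#' @param N simplex dimension (>= 1).
#' @return numeric vector over neurons (index = id + 1).
#' @export
nd_in_degree <- function(conn, N) {
  stopifnot(N >= 1)
  fc <- flag_complex(conn, max_dim = N, nd_in_degree = TRUE)
  fc$nd_in_degree[[N + 1L]]
}

#' Simplex participation of connections at source and sink
#'
#' For each connection, counts the ND-simplices in which it is the source
#' connection (neurons 0 -> 1) or the sink connection (neurons N-1 -> N),
#' and the polarity `(n_source - n_sink) / (n_source + n_sink)`.
#' Connections participating in no ND-simplex have undefined polarity
#' (`NA`) and are excluded from the mean absolute polarity reported in the
#' `"mean_abs_polarity"` attribute.
#'
#' @param conn a `connectome`.
#' @param N simplex dimension (>= 2).
#' @return data.frame with columns `pre`, `post`, `n_source`, `n_sink`,
#'   `polarity`.
#' @export
connection_participation <- function(conn, N) {
  stopifnot(N >= 2)
  fc <- flag_complex(conn, max_dim = N, participation = TRUE)
  ns <- fc$n_source[[N + 1L]]
  nk <- fc$n_sink[[N + 1L]]
  tot <- ns + nk
  pol <- ifelse(tot > 0, (ns - nk) / tot, NA_real_)
  out <- data.frame(pre = fc$edge_pre, post = fc$edge_post,
                    n_source = ns, n_sink = nk, polarity = pol)
  attr(out, "mean_abs_polarity") <- mean(abs(pol), na.rm = TRUE)
  out
}

#' Euler characteristic of the directed flag complex
#'
#' The alternating sum of the number of simplices in each dimension.
#'
#' @param counts per-dimension counts from [count_simplices()] (or a
#'   `connectome`, which is counted first). A truncated count vector
#'   triggers a warning.
#' @return integer-valued Euler characteristic.
#' @export
euler_characteristic <- function(counts) {
  if (inherits(counts, "connectome")) counts <- count_simplices(counts)
  if (isTRUE(attr(counts, "truncated"))) {
    warning("simplex counts truncated at max_dim; Euler characteristic incomplete")
  }
  sum((-1)^(seq_along(counts) - 1L) * counts)
}

# Rank of a binary matrix over GF(2) by Gaussian elimination.
rank_gf2 <- function(M) {
  if (length(M) == 0 || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2L
  rank <- 0L
  nr <- nrow(M)
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1L & seq_len(nr) > rank)
    if (length(piv) == 0) next
    rank <- rank + 1L
    if (piv[1] != rank) M[c(rank, piv[1]), ] <- M[c(piv[1], rank), ]
    hit <- which(M[, j] == 1L & seq_len(nr) != rank)
    if (length(hit)) M[hit, ] <- (M[hit, , drop = FALSE] +
                                    rep(M[rank, ], each = length(hit))) %% 2L
  }
  rank
}

#' Betti numbers of the directed flag complex (small graphs)
#'
#' Computes simplicial homology over the two-element field from
#' boundary-matrix ranks. Intended for small graphs; graphs larger than
#' `guard` neurons raise an error (large-scale homology needs specialised
#' software and is out of scope).
#'
#' @param conn a `connectome`.
#' @param guard maximum admissible neuron count (default 64).
#' @return named numeric vector `beta0`, `beta1`, ... up to the top
#'   dimension of the complex.
#' @export
betti_numbers <- function(conn, guard = 64L) {
  if (conn$n_neurons > guard) {
    stop(sprintf("graph has %d neurons; Betti computation is guarded at %d",
                 conn$n_neurons, guard))
  }
  fc <- flag_complex(conn, max_dim = 30L, store_all = TRUE)
  counts <- trim_counts(fc$counts, 30L)
  top <- length(counts) - 1L
  simp <- fc$all[seq_len(top + 1L)]
  keys <- lapply(simp, function(m) {
    if (ncol(m) == 0) character(0) else apply(m, 2, paste, collapse = ",")
  })
  ranks <- numeric(top + 2L)  # rank of boundary_k, k = 1 .. top (+ zeros)
  for (k in seq_len(top)) {
    mk <- simp[[k + 1L]]
    B <- matrix(0L, nrow = length(keys[[k]]), ncol = ncol(mk))
    for (cidx in seq_len(ncol(mk))) {
      tup <- mk[, cidx]
      for (drop_i in seq_along(tup)) {
        face <- paste(tup[-drop_i], collapse = ",")
        r <- match(face, keys[[k]])
        B[r, cidx] <- (B[r, cidx] + 1L) %% 2L
      }
    }
    ranks[k + 1L] <- rank_gf2(B)
  }
  beta <- vapply(0:top, function(k) {
    counts[k + 1L] - ranks[k + 1L] - ranks[k + 2L]
  }, numeric(1))
  names(beta) <- paste0("beta", 0:top)
  beta
}

#' Degree summary of a connectome
#'
#' In-/out-degrees, their population standard deviations (divisor n, not
#' n - 1), and the Pearson correlation of in- versus out-degree, computed on
#' the subgraph induced by `population` (default: all neurons).
#'
#' @param conn a `connectome`.
#' @param population optional integer vector of 0-based neuron ids.
#' @return object of class `degree_summary`: list with `degrees` (data.frame
#'   `neuron_id`, `in_degree`, `out_degree`), `sigma_in`, `sigma_out`,
#'   `cor_in_out`, `n_edges`.
#' @export
degree_summary <- function(conn, population = NULL) {
  e <- conn$edges
  if (!is.null(population)) {
    if (length(population) == 0) stop("empty population")
    keep <- e$pre %in% population & e$post %in% population
    e <- e[keep, , drop = FALSE]
    ids <- sort(unique(population))
  } else {
    ids <- seq_len(conn$n_neurons) - 1L
  }
  idx <- function(v) match(v, ids)
  din <- tabulate(idx(e$post), nbins = length(ids))
  dout <- tabulate(idx(e$pre), nbins = length(ids))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  structure(list(
    degrees = data.frame(neuron_id = ids, in_degree = din, out_degree = dout),
    sigma_in = pop_sd(din), sigma_out = pop_sd(dout),
    cor_in_out = if (pop_sd(din) > 0 && pop_sd(dout) > 0) cor(din, dout)
    else NA_real_,
    n_edges = nrow(e)), class = "degree_summary")
}

#' @export
print.degree_summary <- function(x, ...) {
  cat(sprintf(
    "<degree_summary: %d neurons, %d edges, sigma_in %.2f, sigma_out %.2f, cor %.3f>\n",
    nrow(x$degrees), x$n_edges, x$sigma_in, x$sigma_out, x$cor_in_out))
  invisible(x)
}

#' Hub neurons by in- and out-degree
#'
#' The `ceiling(fraction * n)` neurons of highest degree in each direction;
#' ties at the cutoff are broken towards the lowest neuron id, so the sets
#' are deterministic.
#'
#' @param summary a [degree_summary()].
#' @param fraction top fraction (default 0.005, i.e. the top 0.5%).
#' @return list with elements `in_hubs`, `out_hubs` (0-based ids), plus
#'   their union and intersection.
#' @export
hub_set <- function(summary, fraction = 0.005) {
  stopifnot(fraction > 0, fraction <= 1)
  d <- summary$degrees
  k <- ceiling(fraction * nrow(d))
  top <- function(deg) d$neuron_id[order(-deg, d$neuron_id)][seq_len(k)]
  in_hubs <- top(d$in_degree)
  out_hubs <- top(d$out_degree)
  list(in_hubs = in_hubs, out_hubs = out_hubs,
       union = sort(union(in_hubs, out_hubs)),
       intersection = sort(intersect(in_hubs, out_hubs)))
}

#' Census of connected three-neuron motifs
#'
#' Counts unordered neuron triples by the isomorphism class of their induced
#' directed subgraph, for the 13 connected classes, labelled with the
#' standard triad-census codes (e.g. `030T` = transitive triangle, `030C` =
#' cyclic triangle, `300` = complete reciprocal triangle).
#'
#' @param conn a `connectome`.
#' @return named numeric vector of 13 counts.
#' @export
triad_census <- function(conn) {
  g <- as_igraph(conn)
  full <- suppressWarnings(igraph::triad_census(g))
  names(full) <- c("003", "012", "102", "021D", "021U", "021C", "111D",
                   "111U", "030T", "030C", "201", "120D", "120U", "120C",
                   "210", "300")
  full[-(1:3)]
}

#' Characteristic path length of a directed network
#'
#' The mean unweighted shortest directed path length over ordered pairs of
#' distinct, mutually reachable neurons (both directions must admit a path;
#' the normalisation uses the number of such pairs). Exact all-pairs BFS up
#' to `exact_limit` neurons; larger networks are estimated from a seeded
#' sample of source neurons, with a standard error.
#'
#' @param conn a `connectome`.
#' @param exact_limit largest size for the exact computation (default 3000).
#' @param sample_size number of source neurons in the sampled estimate.
#' @param seed integer seed for the sampled estimate.
#' @return list with `l`, `n_pairs`, `method`, and `se` (NA when exact).
#' @export
characteristic_path_length <- function(conn, exact_limit = 3000,
                                       sample_size = 200, seed = 1L) {
  g <- as_igraph(conn)
  n <- conn$n_neurons
  if (n <= exact_limit) {
    D <- igraph::distances(g, mode = "out")
    mutual <- is.finite(D) & is.finite(t(D))
    diag(mutual) <- FALSE
    if (!any(mutual)) stop("no mutually reachable pairs")
    vals <- D[mutual]
    return(list(l = mean(vals), n_pairs = length(vals), method = "exact",
                se = NA_real_))
  }
  with_seed(seed, {
    src <- sample.int(n, min(sample_size, n))
    Dout <- igraph::distances(g, v = src, mode = "out")
    Din <- igraph::distances(g, v = src, mode = "in")
    mutual <- is.finite(Dout) & is.finite(Din)
    mutual[cbind(seq_along(src), src)] <- FALSE
    if (!any(mutual)) stop("no mutually reachable pairs in sample")
    vals <- Dout[mutual]
    list(l = mean(vals), n_pairs = length(vals), method = "sampled",
         se = sd(vals) / sqrt(length(vals)))
  })
}

#' Directed clustering coefficients and small-worldness
#'
#' Per-node directed clustering
#' `c_i = ((M + M^T)^3)_ii / (2 (d_tot (d_tot - 1) - 2 (M^2)_ii))`,
#' the fraction of realised triangles (of any edge orientation) among the
#' node and its neighbours; nodes with zero denominator get `c_i = 0`. The
#' network coefficient `c` is the mean over all nodes, and `c / l` (with
#' `l` from [characteristic_path_length()]) quantifies small-worldness.
#'
#' @param conn a `connectome`.
#' @param path_length optional precomputed [characteristic_path_length()]
#'   result; computed when `NULL`.
#' @return object of class `small_world_stats`: list with `c_i`, `c`, `l`,
#'   `ratio`.
#' @export
clustering_coefficients <- function(conn, path_length = NULL) {
  if (conn$n_neurons == 0) stop("empty graph")
  M <- adjacency_matrix(conn)
  A <- M + Matrix::t(M)
  diag_A3 <- Matrix::rowSums((A %*% A) * A)
  d_tot <- Matrix::rowSums(M) + Matrix::colSums(M)
  recip <- Matrix::rowSums(M * Matrix::t(M))
  denom <- 2 * (d_tot * (d_tot - 1) - 2 * recip)
  c_i <- ifelse(denom > 0, diag_A3 / denom, 0)
  cc <- mean(c_i)
  l <- if (is.null(path_length)) {
    tryCatch(characteristic_path_length(conn), error = function(e) NULL)
  } else {
    path_length
  }
  structure(list(c_i = as.numeric(c_i), c = cc,
                 l = if (is.null(l)) NA_real_ else l$l,
                 ratio = if (is.null(l)) NA_real_ else cc / l$l),
            class = "small_world_stats")
}

#' @export
print.small_world_stats <- function(x, ...) {
  cat(sprintf("<small_world_stats: c = %.4f, l = %.3f, c/l = %.4f>\n",
              x$c, x$l, x$ratio))
  invisible(x)
}

#' Erdos-Renyi reference network of matched size and sparseness
#'
#' Draws a directed G(n, m) graph without self-edges and reports the
#' closed-form degree standard deviation
#' `sigma_ER = sqrt((n - 1) p (1 - p))` with `p = m / (n (n - 1))`.
#'
#' @param n number of nodes.
#' @param m number of edges (0 <= m <= n (n - 1)).
#' @param seed integer seed.
#' @return list with `connectome`, `p`, `sigma_closed_form`.
#' @export
er_reference <- function(n, m, seed = 1L) {
  if (m < 0 || m > n * (n - 1)) stop("m out of range for a simple digraph")
  p <- m / (n * (n - 1))
  conn <- with_seed(seed, {
    g <- igraph::sample_gnm(n, m, directed = TRUE)
    el <- igraph::as_edgelist(g, names = FALSE)
    connectome(data.frame(pre = el[, 1] - 1L, post = el[, 2] - 1L), n)
  })
  list(connectome = conn, p = p,
       sigma_closed_form = sqrt((n - 1) * p * (1 - p)))
}
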