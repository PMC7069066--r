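#' Directed connectome container
#'
#' A `connectome` holds a directed edge list over neurons with contiguous
#' integer ids starting at 0, plus optional per-edge attributes
#' `synapse_count` (integer, >= 1) and `path_length` (um, the axonal path a
#' spike travels from the presynaptic soma to the synapse). Self-edges are
#' forbidden and at most one edge per ordered pair is allowed; connection
#' multiplicity lives in `synapse_count`.
#'
#' @param edges data.frame with integer columns `pre`, `post` (0-based ids)
#'   and optional `synapse_count`, `path_length`.
#' @param n_neurons number of neurons (ids run 0 .. n_neurons - 1).
#' @return an object of class `connectome`.
#' @export
connectome <- function(edges, n_neurons) {
  stopifnot(is.data.frame(edges), all(c("pre", "post") %in% names(edges)))
  edges$pre <- as.integer(edges$pre)
  edges$post <- as.integer(edges$post)
  if (nrow(edges) > 0) {
    if (any(edges$pre == edges$post)) stop("self-edges are forbidden")
    rng <- range(c(edges$pre, edges$post))
    if (rng[1] < 0 || rng[2] >= n_neurons) stop("edge ids out of range")
    if (anyDuplicated(edges$pre * as.double(n_neurons) + edges$post)) {
      stop("duplicate ordered pairs in edge list")
    }
  }
  structure(list(edges = edges, n_neurons = as.integer(n_neurons)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome: %d neurons, %d edges%s>\n", x$n_neurons,
              nrow(x$edges),
              if ("path_length" %in% names(x$edges)) ", with attributes"
              else ""))
  invisible(x)
}

n_edges <- function(conn) nrow(conn$edges)

# m-type of each edge endpoint, given the neuron table.
edge_mtypes <- function(conn, neurons) {
  list(pre = neurons$m_type[conn$edges$pre + 1L],
       post = neurons$m_type[conn$edges$post + 1L])
}

#' Per-(pre m-type, post m-type) connection counts
#'
#' The macroconnectome of a wiring: how many connections run between every
#' ordered pair of m-types. Row names are presynaptic m-types, column names
#' postsynaptic.
#'
#' @param conn a `connectome`.
#' @param neurons a neuron table (see [generate_neurons()]).
#' @param mtype_levels optional character vector fixing the row/column order.
#' @return integer matrix of counts summing to the number of edges.
#' @export
macroconnectome <- function(conn, neurons, mtype_levels = NULL) {
  if (is.null(mtype_levels)) mtype_levels <- sort(unique(neurons$m_type))
  em <- edge_mtypes(conn, neurons)
  tab <- table(factor(em$pre, levels = mtype_levels),
               factor(em$post, levels = mtype_levels))
  m <- matrix(as.integer(tab), nrow = length(mtype_levels),
              dimnames = list(pre = mtype_levels, post = mtype_levels))
  m
}

#' Difference of two macroconnectome matrices
#' @param a,b count matrices with identical dimnames.
#' @return elementwise `a - b`.
#' @export
macroconnectome_diff <- function(a, b) {
  stopifnot(identical(dimnames(a), dimnames(b)))
  a - b
}

# Sparse adjacency (dgCMatrix) of the binary wiring, pre in rows.
adjacency_matrix <- function(conn) {
  Matrix::sparseMatrix(i = conn$edges$pre + 1L, j = conn$edges$post + 1L,
                       x = 1, dims = c(conn$n_neurons, conn$n_neurons))
}

as_igraph <- function(conn) {
  igraph::graph_from_edgelist(cbind(conn$edges$pre, conn$edges$post) + 1L,
                              directed = TRUE) |>
    (\(g) igraph::add_vertices(g, max(0L, conn$n_neurons -
                                        igraph::vcount(g))))()
}
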