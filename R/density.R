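#' Morphology density grids
#'
#' A `density_grid` stores the expected mass of axonal or dendritic arbour
#' per spatial bin, on a 2D grid spanning signed lateral offset (x, um) and
#' depth offset (y, um) relative to the soma. Bin centres lie on multiples of
#' the bin size so that grids of equal bin size share a common lattice.
#'
#' @param values numeric matrix of non-negative bin masses; rows index the
#'   lateral axis, columns the depth axis.
#' @param bin bin size in um (> 0).
#' @param x0,y0 coordinates (um) of the centre of `values[1, 1]`; must be
#'   multiples of `bin`.
#' @param m_type,component optional labels (component is `"axon"` or
#'   `"dendrite"`).
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(values, bin, x0, y0, m_type = NA_character_,
                         component = NA_character_) {
  stopifnot(is.matrix(values), bin > 0)
  if (any(values < 0)) stop("density values must be non-negative")
  if (!all(abs(c(x0, y0) / bin - round(c(x0, y0) / bin)) < 1e-6)) {
    stop("grid origins must lie on the bin lattice")
  }
  structure(
    list(values = values, bin = bin, x0 = x0, y0 = y0,
         m_type = m_type, component = component),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "<density_grid %s/%s: %d x %d bins of %g um, mass %.4g>\n",
    x$m_type, x$component, nrow(x$values), ncol(x$values), x$bin,
    sum(x$values)
  ))
  invisible(x)
}

grid_axes <- function(g) {
  list(x = g$x0 + (seq_len(nrow(g$values)) - 1L) * g$bin,
       y = g$y0 + (seq_len(ncol(g$values)) - 1L) * g$bin)
}

#' Render a Gaussian-mixture arbour cloud onto a density grid
#'
#' Each mixture component is an isotropic 2D Gaussian in (lateral, depth)
#' offset from the soma. Bin masses are exact Gaussian integrals over the bin
#' (product of one-dimensional normal CDF differences), so the grid mass
#' equals the parameterised total up to the tail mass outside the extent.
#'
#' @param mixture data.frame with columns `weight`, `x`, `y`, `sd` (um).
#' @param bin bin size in um.
#' @param extent optional list with elements `x` and `y`, each a length-2
#'   range in um. The default covers every component out to 4.5 standard
#'   deviations; a supplied extent must cover at least 4 sd.
#' @inheritParams density_grid
#' @return a `density_grid` whose total mass is `sum(mixture$weight)` to
#'   within 0.1%.
#' @export
render_density <- function(mixture, bin, extent = NULL,
                           m_type = NA_character_, component = NA_character_) {
  if (bin <= 0) stop("bin size must be positive")
  if (is.null(mixture) || nrow(mixture) == 0) stop("empty mixture")
  stopifnot(all(c("weight", "x", "y", "sd") %in% names(mixture)))
  if (any(mixture$sd <= 0) || any(mixture$weight < 0)) {
    stop("mixture components need sd > 0 and weight >= 0")
  }
  if (is.null(extent)) {
    extent <- list(
      x = range(c(mixture$x - 4.5 * mixture$sd, mixture$x + 4.5 * mixture$sd)),
      y = range(c(mixture$y - 4.5 * mixture$sd, mixture$y + 4.5 * mixture$sd))
    )
  } else {
    cov_x <- extent$x[1] <= mixture$x - 4 * mixture$sd &
      extent$x[2] >= mixture$x + 4 * mixture$sd
    cov_y <- extent$y[1] <= mixture$y - 4 * mixture$sd &
      extent$y[2] >= mixture$y + 4 * mixture$sd
    if (!all(cov_x & cov_y)) {
      stop("extent must cover at least 4 sd of every mixture component")
    }
  }
  ix <- seq.int(floor(extent$x[1] / bin), ceiling(extent$x[2] / bin))
  iy <- seq.int(floor(extent$y[1] / bin), ceiling(extent$y[2] / bin))
  cx <- ix * bin
  cy <- iy * bin
  vals <- matrix(0, length(cx), length(cy))
  for (k in seq_len(nrow(mixture))) {
    px <- pnorm(cx + bin / 2, mixture$x[k], mixture$sd[k]) -
      pnorm(cx - bin / 2, mixture$x[k], mixture$sd[k])
    py <- pnorm(cy + bin / 2, mixture$y[k], mixture$sd[k]) -
      pnorm(cy - bin / 2, mixture$y[k], mixture$sd[k])
    vals <- vals + mixture$weight[k] * outer(px, py)
  }
  density_grid(vals, bin, cx[1], cy[1], m_type = m_type, component = component)
}

# Full 2D linear convolution via FFT. Tiny negative values produced by
# round-off are clamped to zero.
conv2_full <- function(a, b) {
  nr <- nrow(a) + nrow(b) - 1L
  nc <- ncol(a) + ncol(b) - 1L
  nr2 <- stats::nextn(nr, c(2, 3, 5))
  nc2 <- stats::nextn(nc, c(2, 3, 5))
  pa <- matrix(0, nr2, nc2)
  pb <- matrix(0, nr2, nc2)
  pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  out <- Re(stats::fft(stats::fft(pa) * stats::fft(pb), inverse = TRUE)) /
    (nr2 * nc2)
  out <- out[seq_len(nr), seq_len(nc), drop = FALSE]
  out[out < 0] <- 0
  out
}

reverse_grid <- function(g) {
  v <- g$values[rev(seq_len(nrow(g$values))), rev(seq_len(ncol(g$values))),
                drop = FALSE]
  density_grid(v, g$bin,
               -(g$x0 + (nrow(g$values) - 1L) * g$bin),
               -(g$y0 + (ncol(g$values) - 1L) * g$bin),
               m_type = g$m_type, component = g$component)
}

#' Evaluate a grid at arbitrary offsets (nearest-bin lookup)
#'
#' Offsets outside the grid evaluate to 0; the number of out-of-range
#' lookups is returned in the `"n_out_of_range"` attribute.
#'
#' @param grid a `density_grid` or `overlap_field`.
#' @param x,y numeric vectors of offsets in um (recycled to common length).
#' @return numeric vector of grid values.
#' @export
grid_value_at <- function(grid, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  i <- round((x - grid$x0) / grid$bin) + 1
  j <- round((y - grid$y0) / grid$bin) + 1
  ok <- i >= 1 & i <= nrow(grid$values) & j >= 1 & j <= ncol(grid$values)
  out <- numeric(n)
  out[ok] <- grid$values[cbind(i[ok], j[ok])]
  attr(out, "n_out_of_range") <- sum(!ok)
  out
}

#' Overlap score of an axon and a dendrite cloud at a given soma offset
#'
#' The axon grid (soma at the origin) is displaced so that the dendrite's
#' soma sits at `soma_offset` = (position of the dendrite's owner) minus
#' (position of the axon's owner), quantised to the nearest bin, and the two
#' grids are multiplied bin by bin and summed. The score depends only on the
#' relative offset.
#'
#' @param axon,dendrite `density_grid` objects with equal bin size.
#' @param soma_offset length-2 numeric, (lateral, depth) offset in um.
#' @return non-negative overlap score.
#' @export
pairwise_overlap <- function(axon, dendrite, soma_offset) {
  if (abs(axon$bin - dendrite$bin) > 1e-9) {
    stop("mismatched bin sizes: ", axon$bin, " vs ", dendrite$bin)
  }
  b <- axon$bin
  kx <- round(soma_offset[1] / b)
  ky <- round(soma_offset[2] / b)
  # axon cell (i, j) sits at axon$x0 + (i-1) b; dendrite cell (i', j') at
  # dendrite$x0 + (i'-1) b + k b. Equal positions give the index shift below.
  sx <- round((axon$x0 - dendrite$x0) / b) - kx
  sy <- round((axon$y0 - dendrite$y0) / b) - ky
  na <- dim(axon$values)
  nd <- dim(dendrite$values)
  i_lo <- max(1L, 1L - sx)
  i_hi <- min(na[1], nd[1] - sx)
  j_lo <- max(1L, 1L - sy)
  j_hi <- min(na[2], nd[2] - sy)
  if (i_lo > i_hi || j_lo > j_hi) return(0)
  sum(axon$values[i_lo:i_hi, j_lo:j_hi, drop = FALSE] *
        dendrite$values[(i_lo:i_hi) + sx, (j_lo:j_hi) + sy, drop = FALSE])
}

#' Elementwise mean of density grids
#'
#' Grids must share a bin size; extents may differ and are merged on the
#' common lattice.
#'
#' @param grids a non-empty list of `density_grid` objects.
#' @return a `density_grid` over the union extent.
#' @export
mean_density_grids <- function(grids) {
  if (length(grids) == 0) stop("no density grids supplied")
  bins <- vapply(grids, function(g) g$bin, numeric(1))
  if (diff(range(bins)) > 1e-9) stop("grids must share a bin size")
  b <- bins[1]
  ix0 <- min(vapply(grids, function(g) g$x0, numeric(1))) / b
  iy0 <- min(vapply(grids, function(g) g$y0, numeric(1))) / b
  ix1 <- max(vapply(grids, function(g) g$x0 + (nrow(g$values) - 1) * g$bin,
                    numeric(1))) / b
  iy1 <- max(vapply(grids, function(g) g$y0 + (ncol(g$values) - 1) * g$bin,
                    numeric(1))) / b
  acc <- matrix(0, round(ix1 - ix0) + 1L, round(iy1 - iy0) + 1L)
  for (g in grids) {
    ox <- round(g$x0 / b - ix0)
    oy <- round(g$y0 / b - iy0)
    ri <- seq_len(nrow(g$values)) + ox
    ci <- seq_len(ncol(g$values)) + oy
    acc[ri, ci] <- acc[ri, ci] + g$values
  }
  density_grid(acc / length(grids), b, round(ix0) * b, round(iy0) * b,
               m_type = grids[[1]]$m_type, component = grids[[1]]$component)
}
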