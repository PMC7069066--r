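# Per-neuron PSTH over concatenated trials: neurons x (bins * trials).
psth_matrix <- function(spikes, dt, n_neurons) {
  nb <- ceiling(spikes$duration_ms / dt)
  K <- length(spikes$trials)
  X <- matrix(0, n_neurons, nb * K)
  for (k in seq_len(K)) {
    tr <- spikes$trials[[k]]
    if (nrow(tr) == 0) next
    b <- pmin(floor(tr$time_ms / dt) + 1L, nb)
    idx <- (tr$neuron_id) * (nb * K) + (k - 1L) * nb + b
    cnt <- tabulate(idx, nbins = n_neurons * nb * K)
    X <- X + matrix(cnt, n_neurons, nb * K, byrow = TRUE)
  }
  X
}

#' Firing rates
#'
#' The firing rate is the average number of spikes in a time bin of size
#' `dt`, divided by `dt`. Returns the per-neuron mean rate over the whole
#' recording and the population rate histogram (Hz per neuron, averaged
#' over trials).
#'
#' @param spikes a `spike_data`.
#' @param dt bin size (ms).
#' @param population integer vector of 0-based ids (default: all neurons
#'   occurring anywhere; pass explicitly for exact population size).
#' @param n_neurons total neuron count; inferred from `population` if given.
#' @return list with `mean_rate_hz`, `bin_ms`, `rate_hz` (population
#'   histogram), `spike_count`.
#' @export
firing_rates <- function(spikes, dt = 20, population = NULL,
                         n_neurons = NULL) {
  stopifnot(dt > 0)
  if (is.null(population)) {
    if (is.null(n_neurons)) {
      n_neurons <- max(vapply(spikes$trials,
                              function(t) if (nrow(t)) max(t$neuron_id) + 1L
                              else 0L, integer(1)))
    }
    population <- seq_len(n_neurons) - 1L
  }
  if (length(population) == 0) stop("empty population")
  K <- length(spikes$trials)
  nb <- ceiling(spikes$duration_ms / dt)
  counts <- numeric(nb)
  total <- 0
  for (tr in spikes$trials) {
    tr <- tr[tr$neuron_id %in% population, , drop = FALSE]
    total <- total + nrow(tr)
    if (nrow(tr)) {
      counts <- counts + tabulate(pmin(floor(tr$time_ms / dt) + 1L, nb),
                                  nbins = nb)
    }
  }
  list(mean_rate_hz = total /
         (length(population) * K * spikes$duration_ms / 1000),
       bin_ms = (seq_len(nb) - 0.5) * dt,
       rate_hz = counts / (K * length(population) * dt / 1000),
       spike_count = total)
}

#' Excitatory-to-inhibitory spike-count ratio
#'
#' Total spike count of excitatory neurons divided by that of inhibitory
#' neurons, per trial and pooled. Trials with zero inhibitory spikes give
#' `NA` (flagged with a warning).
#'
#' @param spikes a `spike_data`.
#' @param neurons neuron table.
#' @return list with `per_trial` and `pooled`.
#' @export
ei_spike_ratio <- function(spikes, neurons) {
  exc <- neurons$synapse_class == "EXC"
  counts <- vapply(spikes$trials, function(tr) {
    is_e <- exc[tr$neuron_id + 1L]
    c(e = sum(is_e), i = sum(!is_e))
  }, numeric(2))
  if (sum(counts["i", ]) == 0) {
    warning("no inhibitory spikes; E/I ratio undefined")
    return(list(per_trial = rep(NA_real_, ncol(counts)), pooled = NA_real_))
  }
  per_trial <- ifelse(counts["i", ] > 0, counts["e", ] / counts["i", ],
                      NA_real_)
  list(per_trial = per_trial,
       pooled = sum(counts["e", ]) / sum(counts["i", ]))
}

#' Pairwise PSTH correlation matrix
#'
#' Builds each neuron's PSTH over the concatenated trials at bin size `dt`
#' and returns the normalized covariance matrix
#' `R_ij = C_ij / sqrt(C_ii C_jj)` over the active neurons. Neurons with
#' zero PSTH variance are excluded and listed in `excluded`.
#'
#' @param spikes a `spike_data`.
#' @param n_neurons total number of neurons.
#' @param dt bin size in ms (default 20).
#' @return object of class `correlation_matrix`: list with `R`, `ids`
#'   (0-based active ids), `excluded`.
#' @export
pairwise_correlation_matrix <- function(spikes, n_neurons, dt = 20) {
  X <- psth_matrix(spikes, dt, n_neurons)
  v <- apply(X, 1, stats::var)
  active <- which(v > 0)
  if (length(active) < 2) stop("fewer than two active neurons")
  R <- cor(t(X[active, , drop = FALSE]))
  structure(list(R = R, ids = active - 1L,
                 excluded = setdiff(seq_len(n_neurons), active) - 1L),
            class = "correlation_matrix")
}

#' Correlations of population responses between trials (and models)
#'
#' Computes one population PSTH per trial (bin size `dt`, default 5 ms) and
#' correlates them. Within one model the mean is over all `K (K - 1) / 2`
#' unordered pairs of distinct trials; between two models it is over all
#' unordered index pairs including equal indices, `K (K + 1) / 2` pairs for
#' equal trial counts (e.g. 435 within and 465 between for K = 30).
#'
#' @param spikes a `spike_data`.
#' @param other optional second `spike_data` for a between-model comparison.
#' @param dt bin size (ms).
#' @return list with `mean_correlation`, `n_pairs`, `correlations`.
#' @export
population_trial_correlations <- function(spikes, other = NULL, dt = 5) {
  pop_psth <- function(sd_obj) {
    nb <- ceiling(sd_obj$duration_ms / dt)
    vapply(sd_obj$trials, function(tr) {
      if (nrow(tr) == 0) numeric(nb)
      else tabulate(pmin(floor(tr$time_ms / dt) + 1L, nb), nbins = nb)
    }, numeric(ceiling(sd_obj$duration_ms / dt)))
  }
  A <- pop_psth(spikes)
  if (is.null(other)) {
    K <- ncol(A)
    if (K < 2) stop("need at least two trials")
    R <- cor(A)
    vals <- R[upper.tri(R)]
    return(list(mean_correlation = mean(vals), n_pairs = length(vals),
                correlations = vals))
  }
  B <- pop_psth(other)
  if (abs(spikes$duration_ms - other$duration_ms) > 1e-9) {
    stop("trial durations differ between models")
  }
  Ka <- ncol(A)
  Kb <- ncol(B)
  C <- cor(A, B)
  keep <- outer(seq_len(Ka), seq_len(Kb), "<=")
  vals <- C[keep]
  list(mean_correlation = mean(vals), n_pairs = sum(keep),
       correlations = vals)
}

#' Spike-time reliability across trials
#'
#' Each neuron's spike train in each trial is binned at `dt_s` and convolved
#' with a Gaussian kernel of width `sigma_s` (truncated at five standard
#' deviations); the reliability is the mean normalized inner product of the
#' filtered signals over all pairs of trials with at least one spike each.
#' Neurons with fewer than two non-empty trials are undefined (`NA`).
#'
#' @param spikes a `spike_data` with at least two trials.
#' @param sigma_s Gaussian kernel width (ms, default 5).
#' @param dt_s signal resolution (ms, default 0.5).
#' @param n_neurons total number of neurons.
#' @return object of class `reliability_result`: list with `r_spike`
#'   (vector over neurons, `NA` when undefined), `sigma_s`, `dt_s`, `K`,
#'   `undefined` (0-based ids).
#' @export
spike_time_reliability <- function(spikes, sigma_s = 5, dt_s = 0.5,
                                   n_neurons = NULL) {
  K <- length(spikes$trials)
  if (K < 2) stop("reliability needs at least two trials")
  if (is.null(n_neurons)) {
    n_neurons <- max(vapply(spikes$trials,
                            function(t) if (nrow(t)) max(t$neuron_id) + 1L
                            else 0L, integer(1)))
  }
  L <- ceiling(spikes$duration_ms / dt_s)
  half <- ceiling(5 * sigma_s / dt_s)
  kern <- exp(-((-half:half) * dt_s)^2 / (2 * sigma_s^2))
  by_neuron <- lapply(seq_len(K), function(k) {
    tr <- spikes$trials[[k]]
    split(pmin(floor(tr$time_ms / dt_s) + 1L, L), tr$neuron_id)
  })
  r_spike <- rep(NA_real_, n_neurons)
  for (id in as.character(0:(n_neurons - 1L))) {
    sigs <- list()
    for (k in seq_len(K)) {
      b <- by_neuron[[k]][[id]]
      if (is.null(b) || length(b) == 0) next
      s <- numeric(L + 2L * half)
      for (bb in b) s[bb:(bb + 2L * half)] <- s[bb:(bb + 2L * half)] + kern
      sigs[[length(sigs) + 1L]] <- s
    }
    if (length(sigs) < 2) next
    norms <- vapply(sigs, function(s) sqrt(sum(s * s)), numeric(1))
    acc <- 0
    np <- 0L
    for (a in seq_len(length(sigs) - 1L)) {
      for (b2 in (a + 1L):length(sigs)) {
        acc <- acc + sum(sigs[[a]] * sigs[[b2]]) / (norms[a] * norms[b2])
        np <- np + 1L
      }
    }
    r_spike[as.integer(id) + 1L] <- acc / np
  }
  structure(list(r_spike = r_spike, sigma_s = sigma_s, dt_s = dt_s, K = K,
                 undefined = which(is.na(r_spike)) - 1L),
            class = "reliability_result")
}

#' Distance dependence of correlations between spatial clusters
#'
#' Partitions the neurons into `k` spatial clusters (k-means on soma
#' positions, 10 restarts, seeded), computes one pooled PSTH per cluster
#' over the concatenated trials, and returns the correlation of every
#' cluster pair against the Euclidean distance of the cluster centres.
#'
#' @param neurons neuron table.
#' @param spikes a `spike_data`.
#' @param k number of clusters (default 100).
#' @param dt PSTH bin size (ms).
#' @param seed integer seed.
#' @return list with `distance_um`, `correlation` (per cluster pair),
#'   `cluster` (per-neuron assignment), `excluded_clusters`.
#' @export
spatial_cluster_correlations <- function(neurons, spikes, k = 100, dt = 20,
                                         seed = 1L) {
  if (k < 2) stop("need at least two clusters")
  if (k > nrow(neurons)) stop("more clusters than neurons")
  pos <- cbind(neurons$x_um, neurons$y_um, neurons$z_um)
  km <- with_seed(seed, kmeans(pos, centers = k, nstart = 10))
  nb <- ceiling(spikes$duration_ms / dt)
  K <- length(spikes$trials)
  P <- matrix(0, k, nb * K)
  for (tr_i in seq_len(K)) {
    tr <- spikes$trials[[tr_i]]
    if (nrow(tr) == 0) next
    cl <- km$cluster[tr$neuron_id + 1L]
    b <- pmin(floor(tr$time_ms / dt) + 1L, nb)
    idx <- (cl - 1L) * (nb * K) + (tr_i - 1L) * nb + b
    P <- P + matrix(tabulate(idx, nbins = k * nb * K), k, nb * K,
                    byrow = TRUE)
  }
  v <- apply(P, 1, stats::var)
  ok <- which(v > 0)
  if (length(ok) < 2) stop("fewer than two active clusters")
  R <- cor(t(P[ok, , drop = FALSE]))
  D <- as.matrix(dist(km$centers[ok, , drop = FALSE]))
  ut <- upper.tri(R)
  list(distance_um = D[ut], correlation = R[ut],
       cluster = km$cluster, excluded_clusters = setdiff(seq_len(k), ok))
}

#' Fit an exponential distance-correlation decay
#'
#' Unweighted least-squares fit of `r = exp(-d / lambda) + c` via
#' Levenberg-Marquardt, with starting values `lambda = median(d)` and
#' `c = min(r)`.
#'
#' @param d distances (um).
#' @param r correlations.
#' @return object of class `exp_fit`: list with `lambda`, `c_offset`,
#'   `se_lambda`, `se_c`, `fit` (the `nls` object).
#' @export
fit_exponential <- function(d, r) {
  stopifnot(length(d) == length(r), length(d) >= 3)
  df <- data.frame(d = d, r = r)
  fit <- minpack.lm::nlsLM(r ~ exp(-d / lambda) + c0, data = df,
                           start = list(lambda = stats::median(d),
                                        c0 = min(r)),
                           lower = c(1e-6, -Inf))
  est <- summary(fit)$coefficients
  out <- list(lambda = est["lambda", "Estimate"],
              c_offset = est["c0", "Estimate"],
              se_lambda = est["lambda", "Std. Error"],
              se_c = est["c0", "Std. Error"], fit = fit)
  if (out$lambda <= 0) stop("degenerate exponential fit")
  structure(out, class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: lambda = %.1f um (se %.1f), offset = %.4f (se %.4f)>\n",
              x$lambda, x$se_lambda, x$c_offset, x$se_c))
  invisible(x)
}

#' Mean pair correlation by position in maximal simplices
#'
#' For every maximal simplex of dimension n, the consecutive connections
#' `(v_k, v_{k+1})` are binned by position k (0 = source pair, n - 1 = sink
#' pair) and the mean correlation of the connected neurons is reported per
#' (dimension, position), together with the sink-minus-source difference
#' per dimension. Pairs involving neurons without a correlation value
#' (inactive) are skipped and counted.
#'
#' @param R a `correlation_matrix`.
#' @param maximal maximal-simplex list from
#'   `count_maximal_simplices(conn, store = TRUE)$simplices`.
#' @param dims dimensions to include (default: all of dimension >= 1).
#' @return list with `profile` (data.frame `dim`, `position`, `mean_r`,
#'   `n_pairs`), `sink_minus_source` (data.frame `dim`, `difference`),
#'   `n_skipped`.
#' @export
simplex_position_correlations <- function(R, maximal, dims = NULL) {
  stopifnot(inherits(R, "correlation_matrix"))
  idx_of <- rep(NA_integer_, max(R$ids) + 2L)
  idx_of[R$ids + 1L] <- seq_along(R$ids)
  if (is.null(dims)) dims <- seq_len(length(maximal) - 1L)
  rows <- list()
  skipped <- 0L
  for (d in dims) {
    if (d + 1L > length(maximal)) next
    simp <- maximal[[d + 1L]]
    if (is.null(simp) || ncol(simp) == 0) next
    for (pos in seq_len(d)) {
      a <- simp[pos, ]
      b <- simp[pos + 1L, ]
      ia <- idx_of[a + 1L]
      ib <- idx_of[b + 1L]
      ok <- !is.na(ia) & !is.na(ib)
      skipped <- skipped + sum(!ok)
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        dim = d, position = pos - 1L,
        mean_r = mean(R$R[cbind(ia[ok], ib[ok])]),
        n_pairs = sum(ok))
    }
  }
  profile <- do.call(rbind, rows)
  if (is.null(profile)) stop("no maximal simplices of the requested dimensions")
  diffs <- do.call(rbind, lapply(split(profile, profile$dim), function(p) {
    data.frame(dim = p$dim[1],
               difference = p$mean_r[which.max(p$position)] -
                 p$mean_r[which.min(p$position)])
  }))
  rownames(diffs) <- NULL
  list(profile = profile, sink_minus_source = diffs, n_skipped = skipped)
}

#' Mean correlation binned by simplex participation of connections
#'
#' Bins connections by their source- and sink-participation counts in
#' ND-simplices and reports the mean correlation of the connected pair per
#' (source bin, sink bin). Empty bins are `NA`.
#'
#' @param R a `correlation_matrix`.
#' @param participation data.frame from [connection_participation()].
#' @param breaks bin edges applied to both counts (default
#'   `c(0, 1, 2, 4, 8, 16, Inf)`; left-closed).
#' @return list with matrices `mean_r` and `n` (rows: source bins, cols:
#'   sink bins) and `breaks`.
#' @export
correlation_by_participation <- function(R, participation,
                                         breaks = c(0, 1, 2, 4, 8, 16, Inf)) {
  stopifnot(inherits(R, "correlation_matrix"))
  idx_of <- rep(NA_integer_, max(R$ids) + 2L)
  idx_of[R$ids + 1L] <- seq_along(R$ids)
  ia <- idx_of[participation$pre + 1L]
  ib <- idx_of[participation$post + 1L]
  ok <- !is.na(ia) & !is.na(ib)
  r <- R$R[cbind(ia[ok], ib[ok])]
  bs <- cut(participation$n_source[ok], breaks, right = FALSE,
            include.lowest = TRUE)
  bk <- cut(participation$n_sink[ok], breaks, right = FALSE,
            include.lowest = TRUE)
  mean_r <- tapply(r, list(bs, bk), mean)
  n <- tapply(r, list(bs, bk), length)
  n[is.na(n)] <- 0
  list(mean_r = mean_r, n = n, breaks = breaks)
}

#' Depth profile of a per-neuron quantity
#'
#' Bins a per-neuron value by soma depth and reports mean, standard
#' deviation, and standard error per bin, for all neurons and optionally
#' for the excitatory/inhibitory subpopulations.
#'
#' @param values numeric vector aligned with `neurons` (index = id + 1).
#' @param neurons neuron table.
#' @param bin depth bin width (um, default 100).
#' @param by_class also compute E/I sub-profiles (default TRUE).
#' @return data.frame with columns `class` ("ALL", "EXC", "INH"),
#'   `depth_mid`, `n`, `mean`, `sd`, `sem`; empty bins omitted.
#' @export
depth_profile <- function(values, neurons, bin = 100, by_class = TRUE) {
  stopifnot(length(values) == nrow(neurons))
  one <- function(sel, label) {
    if (!any(sel)) return(NULL)
    b <- floor(neurons$y_um[sel] / bin)
    v <- values[sel]
    agg <- split(v, b)
    data.frame(class = label,
               depth_mid = (as.numeric(names(agg)) + 0.5) * bin,
               n = lengths(agg),
               mean = vapply(agg, mean, numeric(1)),
               sd = vapply(agg, sd, numeric(1)),
               sem = vapply(agg, function(x) sd(x) / sqrt(length(x)),
                            numeric(1)))
  }
  out <- one(rep(TRUE, nrow(neurons)), "ALL")
  if (by_class) {
    out <- rbind(out, one(neurons$synapse_class == "EXC", "EXC"),
                 one(neurons$synapse_class == "INH", "INH"))
  }
  rownames(out) <- NULL
  out
}
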