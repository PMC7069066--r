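fake_spikes <- function(trials, duration = 1000, protocol = "spontaneous") {
  structure(list(trials = trials, duration_ms = duration, params = NULL,
                 protocol = protocol), class = "spike_data")
}

one_train <- function(times, id = 0L) {
  data.frame(time_ms = times, neuron_id = rep(id, length(times)))
}

test_that("firing rates count spikes per bin per neuron", {
  sp <- fake_spikes(list(one_train(seq(50, 950, by = 100))), 1000)
  fr <- firing_rates(sp, dt = 100, population = 0L)
  expect_equal(fr$mean_rate_hz, 10)
  expect_equal(sum(fr$rate_hz * 0.1), 10)
  expect_equal(fr$spike_count, 10)
  empty <- fake_spikes(list(one_train(numeric(0))), 1000)
  fr0 <- firing_rates(empty, dt = 100, population = 0:4)
  expect_equal(fr0$mean_rate_hz, 0)
  expect_true(all(fr0$rate_hz == 0))
})

test_that("E/I ratio handles the canonical and degenerate cases", {
  neu <- data.frame(neuron_id = 0:1, m_type = c("E1", "I1"), layer = "L23",
                    synapse_class = c("EXC", "INH"), x_um = 0, y_um = 0,
                    z_um = 0)
  sp <- fake_spikes(list(rbind(one_train(seq_len(800), 0L),
                               one_train(seq_len(200), 1L))))
  expect_equal(ei_spike_ratio(sp, neu)$pooled, 4)
  sp0 <- fake_spikes(list(one_train(1:5, 1L)))
  expect_equal(ei_spike_ratio(sp0, neu)$pooled, 0)
  # pooled ratio equals the count-weighted combination of trials
  sp2 <- fake_spikes(list(rbind(one_train(1:10, 0L), one_train(1:5, 1L)),
                          rbind(one_train(1:30, 0L), one_train(1:10, 1L))))
  out <- ei_spike_ratio(sp2, neu)
  expect_equal(out$pooled, (10 + 30) / (5 + 10))
  expect_warning(ei_spike_ratio(fake_spikes(list(one_train(1:3, 0L))), neu),
                 "undefined")
})

test_that("PSTH correlation matrix is a normalized covariance", {
  set.seed(4)
  trials <- lapply(1:3, function(k) {
    rbind(one_train(sort(runif(30, 0, 1000)), 0L),
          one_train(sort(runif(25, 0, 1000)), 1L),
          one_train(sort(runif(40, 0, 1000)), 2L))
  })
  sp <- fake_spikes(trials)
  R <- pairwise_correlation_matrix(sp, 4, dt = 50)
  expect_equal(diag(R$R), rep(1, 3), ignore_attr = TRUE)
  expect_equal(R$R, t(R$R))
  expect_equal(R$excluded, 3L)  # neuron 3 never spikes
  # direct per-pair recomputation
  X <- cloudwire:::psth_matrix(sp, 50, 4)
  expect_equal(R$R[1, 2], cor(X[1, ], X[2, ]), tolerance = 1e-12)
  # identical trains correlate at exactly 1
  twin <- fake_spikes(lapply(1:2, function(k) {
    rbind(one_train(c(100, 300, 700), 0L), one_train(c(100, 300, 700), 1L))
  }))
  Rt <- pairwise_correlation_matrix(twin, 2, dt = 100)
  expect_equal(Rt$R[1, 2], 1)
})

test_that("trial-correlation pair counts follow the stated combinatorics", {
  mk <- function(K) fake_spikes(lapply(seq_len(K), function(k) {
    one_train(sort(runif(20, 0, 1000)), 0L)
  }))
  set.seed(7)
  w30 <- population_trial_correlations(mk(30))
  expect_equal(w30$n_pairs, 30 * 29 / 2)  # 435
  b30 <- population_trial_correlations(mk(30), mk(30))
  expect_equal(b30$n_pairs, 30 * 31 / 2)  # 465
  expect_equal(population_trial_correlations(mk(3))$n_pairs, 3L)
  # identical trials give mean correlation 1
  tr <- one_train(seq(25, 975, by = 50))
  same <- fake_spikes(list(tr, tr, tr))
  expect_equal(population_trial_correlations(same)$mean_correlation, 1)
  expect_error(population_trial_correlations(mk(1)), "two trials")
})

test_that("spike-time reliability matches its Gaussian closed form", {
  # identical non-empty trains across trials
  tr <- one_train(c(100, 400, 800))
  sp <- fake_spikes(list(tr, tr, tr))
  out <- spike_time_reliability(sp, n_neurons = 1)
  expect_equal(out$r_spike[1], 1, tolerance = 1e-9)
  # two single-spike trials at offset 5 ms with sigma = 5 ms
  sp2 <- fake_spikes(list(one_train(500), one_train(505)))
  out2 <- spike_time_reliability(sp2, sigma_s = 5, dt_s = 0.5,
                                 n_neurons = 1)
  expect_equal(out2$r_spike[1], exp(-25 / 100), tolerance = 1e-3)
  expect_equal(out2$r_spike[1], 0.7788, tolerance = 1e-3)
  # invariance under a joint shift of every trial
  sp3 <- fake_spikes(list(one_train(c(550)), one_train(c(555))))
  out3 <- spike_time_reliability(sp3, n_neurons = 1)
  expect_equal(out3$r_spike[1], out2$r_spike[1], tolerance = 1e-9)
  # empty-train handling: neurons with < 2 non-empty trials are undefined
  sp4 <- fake_spikes(list(one_train(100), one_train(numeric(0)),
                          one_train(numeric(0))))
  out4 <- spike_time_reliability(sp4, n_neurons = 1)
  expect_true(is.na(out4$r_spike[1]))
  expect_equal(out4$undefined, 0L)
  expect_error(spike_time_reliability(fake_spikes(list(one_train(1)))),
               "two trials")
  # bounds on simulated rasters
  set.seed(11)
  sp5 <- fake_spikes(lapply(1:4, function(k) {
    do.call(rbind, lapply(0:5, function(id) {
      one_train(sort(runif(rpois(1, 8), 0, 1000)), id)
    }))
  }))
  out5 <- spike_time_reliability(sp5, n_neurons = 6)
  ok <- !is.na(out5$r_spike)
  expect_true(all(out5$r_spike[ok] >= 0 & out5$r_spike[ok] <= 1 + 1e-12))
})

test_that("k-means clustering separates blobs and the distance matrix is sane", {
  set.seed(5)
  neu <- data.frame(neuron_id = 0:59, m_type = "A", layer = "L23",
                    synapse_class = "EXC",
                    x_um = c(rnorm(30, 0, 5), rnorm(30, 500, 5)),
                    y_um = c(rnorm(30, 0, 5), rnorm(30, 500, 5)),
                    z_um = 0)
  trials <- lapply(1:3, function(k) {
    do.call(rbind, lapply(0:59, function(id) {
      one_train(sort(runif(15, 0, 1000)), id)
    }))
  })
  sp <- fake_spikes(trials)
  out <- spatial_cluster_correlations(neu, sp, k = 2, dt = 50, seed = 3)
  expect_equal(length(unique(out$cluster[1:30])), 1L)
  expect_equal(length(unique(out$cluster[31:60])), 1L)
  expect_true(out$cluster[1] != out$cluster[31])
  expect_error(spatial_cluster_correlations(neu, sp, k = 100, seed = 1),
               "more clusters")
})

test_that("exponential distance-correlation fits recover known parameters", {
  set.seed(9)
  d <- runif(300, 10, 900)
  r <- exp(-d / 150) + 0.1 + rnorm(300, 0, 0.01)
  fit <- fit_exponential(d, r)
  expect_equal(fit$lambda, 150, tolerance = 0.1 * 150)
  expect_equal(fit$c_offset, 0.1, tolerance = 0.02)
  expect_gt(fit$lambda, 0)
})

test_that("simplex-position profiles read a constructed correlation gradient", {
  # one maximal 4-simplex 0->1->2->3->4 with R(v_k, v_{k+1}) = k/10
  R <- diag(5)
  for (k in 1:4) {
    R[k, k + 1] <- R[k + 1, k] <- (k - 1) / 10
  }
  Rm <- structure(list(R = R, ids = 0:4, excluded = integer(0)),
                  class = "correlation_matrix")
  maximal <- c(lapply(1:4, function(d) matrix(integer(0), d, 0)),
               list(matrix(0:4, 5, 1)))
  out <- simplex_position_correlations(Rm, maximal)
  prof <- out$profile[out$profile$dim == 4, ]
  expect_equal(prof$mean_r, (0:3) / 10)
  expect_true(all(diff(prof$mean_r) > 0))
  expect_equal(out$sink_minus_source$difference[
    out$sink_minus_source$dim == 4], 0.3)
  # a 1D maximal simplex has a single position: source pair == sink pair
  maximal1 <- list(matrix(integer(0), 1, 0), matrix(c(0L, 1L), 2, 1))
  out1 <- simplex_position_correlations(Rm, maximal1)
  expect_equal(out1$sink_minus_source$difference, 0)
})

test_that("profile means equal brute-force recomputation on random inputs", {
  conn <- rand_digraph(12, 0.35, seed = 44)
  set.seed(44)
  n <- conn$n_neurons
  S <- matrix(rnorm(n * 30), n)
  R <- cor(t(S))
  Rm <- structure(list(R = R, ids = 0:(n - 1), excluded = integer(0)),
                  class = "correlation_matrix")
  ms <- count_maximal_simplices(conn, store = TRUE)
  out <- simplex_position_correlations(Rm, ms$simplices)
  for (row in seq_len(nrow(out$profile))) {
    d <- out$profile$dim[row]
    pos <- out$profile$position[row]
    simp <- ms$simplices[[d + 1]]
    vals <- R[cbind(simp[pos + 1, ] + 1, simp[pos + 2, ] + 1)]
    expect_equal(out$profile$mean_r[row], mean(vals))
    expect_equal(out$profile$n_pairs[row], ncol(simp))
  }
})

test_that("participation-binned correlations equal group-by recomputation", {
  conn <- rand_digraph(12, 0.35, seed = 45)
  set.seed(45)
  S <- matrix(rnorm(12 * 30), 12)
  R <- cor(t(S))
  Rm <- structure(list(R = R, ids = 0:11, excluded = integer(0)),
                  class = "correlation_matrix")
  part <- connection_participation(conn, 2)
  out <- correlation_by_participation(Rm, part, breaks = c(0, 1, 3, Inf))
  rvals <- R[cbind(part$pre + 1, part$post + 1)]
  bs <- cut(part$n_source, c(0, 1, 3, Inf), right = FALSE,
            include.lowest = TRUE)
  bk <- cut(part$n_sink, c(0, 1, 3, Inf), right = FALSE,
            include.lowest = TRUE)
  expect_equal(out$mean_r, tapply(rvals, list(bs, bk), mean))
  expect_equal(sum(out$n), nrow(part))
  # a flat correlation structure gives a flat grid
  Rf <- Rm
  Rf$R <- matrix(0.2, 12, 12)
  diag(Rf$R) <- 1
  outf <- correlation_by_participation(Rf, part, breaks = c(0, 1, 3, Inf))
  vals <- outf$mean_r[!is.na(outf$mean_r) & outf$n > 0]
  expect_true(all(abs(vals - 0.2) < 1e-12))
})

test_that("depth profiles aggregate correctly and partition by class", {
  set.seed(6)
  neu <- data.frame(neuron_id = 0:99, m_type = "A", layer = "L23",
                    synapse_class = rep(c("EXC", "INH"), 50),
                    x_um = 0, y_um = runif(100, 0, 1000), z_um = 0)
  const <- depth_profile(rep(5, 100), neu, bin = 100)
  allp <- const[const$class == "ALL", ]
  expect_true(all(allp$mean == 5))
  expect_true(all(allp$sd == 0, na.rm = TRUE))
  vals <- rnorm(100)
  prof <- depth_profile(vals, neu, bin = 200)
  for (row in which(prof$class == "ALL")) {
    sel <- floor(neu$y_um / 200) == (prof$depth_mid[row] - 100) / 200
    expect_equal(prof$mean[row], mean(vals[sel]))
    expect_equal(prof$n[row], sum(sel))
  }
  bymid <- split(prof, prof$depth_mid)
  for (b in bymid) {
    expect_equal(sum(b$n[b$class %in% c("EXC", "INH")]),
                 b$n[b$class == "ALL"])
  }
})
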