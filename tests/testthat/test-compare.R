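test_that("connection distance histograms are normalised and partition edges", {
  neu <- data.frame(neuron_id = 0:2, m_type = "A", layer = "L23",
                    synapse_class = "EXC",
                    x_um = c(0, 57, 0), y_um = 0, z_um = 0)
  conn <- make_conn(rbind(c(0, 1)), 3)
  dd <- connection_distance_distribution(conn, neu, "afferent", group = 0:2,
                                         bin = 20)
  expect_equal(sum(dd$mass), 1, tolerance = 1e-12)
  expect_equal(dd$mass[3], 1)  # 57 um lands in [40, 60)
  expect_error(connection_distance_distribution(conn, neu, "afferent",
                                                group = integer(0)),
               "empty")
  expect_error(connection_distance_distribution(conn, neu, "efferent",
                                                group = 2), "no efferent")

  spec <- small_spec(n = 200, seed = 30)
  neus <- generate_neurons(spec)
  m <- instantiate_morphologies(neus, spec)
  ref <- sample_reference_connectome(
    neus, m, default_pair_targets(neus, m, 20), seed = 1)
  groups <- split(neus$neuron_id, neus$layer)
  n_aff <- sum(vapply(groups, function(g) {
    connection_distance_distribution(ref, neus, "afferent", g)$n_edges
  }, numeric(1)))
  expect_equal(n_aff, nrow(ref$edges))
})

test_that("KL divergence has its closed forms and Gibbs positivity", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-3)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.1438,
               tolerance = 1e-3)
  expect_equal(kl_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(6)
    q <- runif(6)
    expect_gte(kl_divergence(p / sum(p), q / sum(q)), 0)
  }
})

test_that("reciprocal overexpression is 1 for complete and 0 for acyclic wiring", {
  recip <- make_conn(rbind(c(0, 1), c(1, 0), c(0, 2), c(2, 0),
                           c(1, 2), c(2, 1)), 3)
  expect_equal(reciprocal_overexpression(recip, 0:2), 1)
  acyc <- make_conn(rbind(c(0, 1), c(0, 2), c(1, 2)), 3)
  expect_equal(reciprocal_overexpression(acyc, 0:2), 0)
  # independent wiring is near 1
  er <- er_reference(800, round(800 * 799 * 0.03), seed = 4)$connectome
  expect_equal(reciprocal_overexpression(er, 0:799), 1, tolerance = 0.15)
  expect_error(reciprocal_overexpression(recip, 0L), "two neurons")
})

test_that("macroconnectome counts sum to the edge count and diffs match losses", {
  spec <- small_spec(n = 200, seed = 31)
  neu <- generate_neurons(spec)
  m <- instantiate_morphologies(neu, spec)
  ref <- sample_reference_connectome(
    neu, m, default_pair_targets(neu, m, 20), seed = 1)
  ref <- assign_connection_attributes(ref, neu, seed = 2)
  cl <- build_cloud_connectome(neu, m, ref, seed = 3)
  expect_equal(sum(macroconnectome(ref, neu)), nrow(ref$edges))
  expect_true(all(macroconnectome_diff(macroconnectome(ref, neu),
                                       macroconnectome(cl, neu)) == 0))
  out <- transplant(cl, ref, neu, seed = 4)
  d <- macroconnectome_diff(macroconnectome(out$hybrid, neu),
                            macroconnectome(ref, neu))
  tab <- out$loss$table
  for (k in which(tab$lost > 0)) {
    expect_equal(d[tab$pre_mtype[k], tab$post_mtype[k]], -tab$lost[k])
  }
})

test_that("cloud wiring preserves distance dependence far better than ER", {
  wins <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    spec <- circuit_spec(n_neurons = 400, eta = 20, grid_bin = 10,
                         seed = 60 + s)
    neu <- generate_neurons(spec)
    m <- instantiate_morphologies(neu, spec)
    ref <- sample_reference_connectome(
      neu, m, default_pair_targets(neu, m, 25), seed = s)
    cl <- build_cloud_connectome(neu, m, ref, seed = s + 100)
    er <- er_reference(400, nrow(ref$edges), seed = s + 200)$connectome
    g <- neu$neuron_id
    d_ref <- connection_distance_distribution(ref, neu, "afferent", g,
                                              max_distance = 1500)
    d_cl <- connection_distance_distribution(cl, neu, "afferent", g,
                                             max_distance = 1500)
    d_er <- connection_distance_distribution(er, neu, "afferent", g,
                                             max_distance = 1500)
    wins <- wins + (kl_divergence(d_ref, d_cl) < kl_divergence(d_ref, d_er))
  }
  expect_equal(wins, n_seeds)
})

test_that("common-neighbour bias is flat on ER and rising on block graphs", {
  er <- er_reference(800, round(800 * 799 * 0.025), seed = 6)$connectome
  curve <- common_neighbor_bias(er)
  big <- curve[curve$n_pairs >= 20000, ]
  expect_gt(nrow(big), 2)
  expect_true(all(abs(big$normalized - 1) < 0.15))
  # two dense blocks: common neighbours predict connectivity
  set.seed(2)
  blocks <- rbind(
    expand.grid(pre = 0:39, post = 0:39),
    expand.grid(pre = 40:79, post = 40:79))
  blocks <- blocks[blocks$pre != blocks$post & runif(nrow(blocks)) < 0.5, ]
  sparse_bg <- expand.grid(pre = 0:79, post = 0:79)
  sparse_bg <- sparse_bg[sparse_bg$pre != sparse_bg$post &
                           runif(nrow(sparse_bg)) < 0.02, ]
  eb <- unique(rbind(blocks, sparse_bg))
  conn <- connectome(eb, 80)
  cb <- common_neighbor_bias(conn, min_pairs = 50)
  # aggregate trend: top-k bins connect far more often than bottom-k bins
  lo <- cb$p_connected[cb$k <= quantile(cb$k, 0.3)]
  hi <- cb$p_connected[cb$k >= quantile(cb$k, 0.7)]
  expect_gt(mean(hi), 2 * mean(lo))
})
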