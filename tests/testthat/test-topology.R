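tri_trans <- make_conn(rbind(c(0, 1), c(0, 2), c(1, 2)), 3)  # A->B->C, A->C
tri_cycle <- make_conn(rbind(c(0, 1), c(1, 2), c(2, 0)), 3)
tri_recip <- make_conn(rbind(c(0, 1), c(1, 0), c(0, 2), c(2, 0),
                             c(1, 2), c(2, 1)), 3)

test_that("simplex counts match the directed-clique definition on canonical graphs", {
  expect_equal(as.numeric(count_simplices(tri_trans)), c(3, 3, 1))
  # all six orderings of a reciprocal triangle are distinct 2D simplices
  expect_equal(as.numeric(count_simplices(tri_recip)), c(3, 6, 6))
  # a directed cycle contains no 2D simplex
  expect_equal(as.numeric(count_simplices(tri_cycle)), c(3, 3))
})

test_that("maximal simplices are those not contained in higher ones", {
  out <- count_maximal_simplices(tri_trans, store = TRUE)
  expect_equal(as.numeric(out$counts), c(0, 0, 1))
  expect_equal(out$simplices[[3]][, 1], c(0L, 1L, 2L))
  single <- make_conn(rbind(c(0, 1)), 3)
  cm <- count_maximal_simplices(single)
  expect_equal(as.numeric(cm), c(1, 1))  # the isolated vertex and the edge
})

test_that("enumeration agrees with brute force on random digraphs", {
  for (s in 1:6) {
    p <- c(0.2, 0.4)[s %% 2 + 1]
    conn <- rand_digraph(10, p, seed = 100 + s)
    all_bf <- bf_all_simplices(conn)
    expect_equal(as.numeric(count_simplices(conn)), bf_counts(all_bf))
    expect_equal(as.numeric(count_maximal_simplices(conn)),
                 bf_maximal_counts(all_bf))
    for (N in 1:3) {
      expect_equal(nd_in_degree(conn, N),
                   bf_nd_in_degree(all_bf, conn$n_neurons, N))
    }
    for (N in 2:3) {
      got <- connection_participation(conn, N)
      want <- bf_participation(all_bf, conn, N)
      m <- merge(got, want, by = c("pre", "post"))
      expect_equal(m$n_source.x, m$n_source.y)
      expect_equal(m$n_sink.x, m$n_sink.y)
    }
  }
})

test_that("1D in-degree is the ordinary in-degree and participation defines polarity", {
  conn <- rand_digraph(12, 0.3, seed = 7)
  ds <- degree_summary(conn)
  expect_equal(nd_in_degree(conn, 1), ds$degrees$in_degree)
  part <- connection_participation(tri_trans, 2)
  src <- part[part$pre == 0 & part$post == 1, ]
  snk <- part[part$pre == 1 & part$post == 2, ]
  expect_equal(src$n_source, 1)
  expect_equal(src$n_sink, 0)
  expect_equal(src$polarity, 1)
  expect_equal(snk$n_source, 0)
  expect_equal(snk$n_sink, 1)
  expect_equal(snk$polarity, -1)
  # polarity formula on explicit counts
  expect_equal((5 - 5) / (5 + 5), 0)
  part_ac <- part[part$pre == 0 & part$post == 2, ]
  expect_true(is.na(part_ac$polarity))  # the shortcut edge is in no position
})

test_that("Euler characteristic is the alternating simplex-count sum", {
  expect_equal(euler_characteristic(tri_cycle), 0)
  expect_equal(euler_characteristic(tri_trans), 1)
  recip4 <- rand_digraph(4, 1.1, seed = 1)  # complete reciprocal digraph
  expect_equal(as.numeric(count_simplices(recip4)), c(4, 12, 24, 24))
  expect_equal(euler_characteristic(recip4), -8)
  trunc <- count_simplices(recip4, max_dim = 2)
  expect_warning(euler_characteristic(trunc), "truncated")
})

test_that("Betti numbers satisfy known cases and the Euler-Poincare identity", {
  b_cycle <- betti_numbers(tri_cycle)
  expect_equal(as.numeric(b_cycle), c(1, 1))
  b_trans <- betti_numbers(tri_trans)
  expect_equal(b_trans[["beta0"]], 1)
  expect_true(all(b_trans[-1] == 0))
  for (s in 1:8) {
    conn <- rand_digraph(8, 0.3, seed = 50 + s)
    beta <- betti_numbers(conn)
    chi <- euler_characteristic(count_simplices(conn))
    expect_equal(sum((-1)^(seq_along(beta) - 1) * beta), chi)
  }
  expect_error(betti_numbers(rand_digraph(70, 0.05, seed = 1)), "guard")
})

test_that("degree summaries match direct recomputation and conserve edges", {
  single <- make_conn(rbind(c(0, 1)), 3)
  ds <- degree_summary(single)
  expect_equal(ds$degrees$in_degree, c(0, 1, 0))
  expect_equal(ds$degrees$out_degree, c(1, 0, 0))
  recip4 <- rand_digraph(4, 1.1, seed = 1)
  ds4 <- degree_summary(recip4)
  expect_true(all(ds4$degrees$in_degree == 3))
  expect_true(all(ds4$degrees$out_degree == 3))
  conn <- rand_digraph(50, 0.1, seed = 3)
  ds50 <- degree_summary(conn)
  din <- tabulate(conn$edges$post + 1L, 50)
  expect_equal(sum(ds50$degrees$in_degree), nrow(conn$edges))
  expect_equal(sum(ds50$degrees$out_degree), nrow(conn$edges))
  expect_equal(ds50$sigma_in, sqrt(mean((din - mean(din))^2)))
})

test_that("hub selection sizes and tie-breaking are deterministic", {
  conn <- rand_digraph(1000, 0.02, seed = 5)
  hubs <- hub_set(degree_summary(conn), 0.005)
  expect_length(hubs$in_hubs, 5L)
  expect_length(hubs$out_hubs, 5L)
  all_h <- hub_set(degree_summary(conn), 1)
  expect_length(all_h$in_hubs, 1000L)
  # tie at the cutoff resolves to the lowest id
  tie <- make_conn(rbind(c(1, 0), c(2, 3)), 5)
  h <- hub_set(degree_summary(tie), 1 / 5)
  expect_equal(h$in_hubs, 0L)  # ids 0 and 3 tie at in-degree 1
})

test_that("triad census matches brute force and canonical examples", {
  tc <- triad_census(tri_trans)
  expect_equal(unname(tc[["030T"]]), 1)
  expect_equal(sum(tc), 1)
  tc2 <- triad_census(tri_cycle)
  expect_equal(unname(tc2[["030C"]]), 1)
  expect_equal(unname(triad_census(tri_recip)[["300"]]), 1)
  for (s in 1:6) {
    conn <- rand_digraph(12, c(0.2, 0.4)[s %% 2 + 1], seed = 200 + s)
    expect_equal(unname(triad_census(conn)), unname(bf_triad_census(conn)))
  }
})

test_that("characteristic path length averages mutually reachable pairs", {
  pair <- make_conn(rbind(c(0, 1), c(1, 0)), 2)
  expect_equal(characteristic_path_length(pair)$l, 1)
  cyc <- characteristic_path_length(tri_cycle)
  expect_equal(cyc$l, 1.5)
  expect_equal(cyc$n_pairs, 6L)
  chain <- make_conn(rbind(c(0, 1), c(1, 2)), 3)
  expect_error(characteristic_path_length(chain), "mutually reachable")
  # sampled estimate agrees with the exact value on a moderate graph
  conn <- rand_digraph(300, 0.03, seed = 9)
  exact <- characteristic_path_length(conn)
  est <- characteristic_path_length(conn, exact_limit = 10,
                                    sample_size = 150, seed = 2)
  expect_lt(abs(est$l - exact$l), 4 * est$se + 0.05)
})

test_that("directed clustering matches the matrix closed forms", {
  cc <- clustering_coefficients(tri_recip)
  expect_equal(cc$c_i, rep(1, 3))
  expect_equal(cc$c, 1)
  cc2 <- clustering_coefficients(tri_cycle)
  expect_equal(cc2$c_i, rep(0.5, 3))
  star <- make_conn(rbind(c(0, 1), c(0, 2), c(0, 3)), 4)
  cc3 <- clustering_coefficients(star)
  expect_equal(cc3$c_i, rep(0, 4))
  expect_equal(cc2$ratio, 0.5 / 1.5)
})

test_that("G(n,m) reference has exact edge count and the closed-form sigma", {
  er0 <- er_reference(10, 0, seed = 1)
  expect_equal(er0$sigma_closed_form, 0)
  expect_equal(nrow(er0$connectome$edges), 0L)
  er <- er_reference(400, 3000, seed = 2)
  expect_equal(nrow(er$connectome$edges), 3000L)
  expect_false(any(er$connectome$edges$pre == er$connectome$edges$post))
  expect_error(er_reference(10, 100, seed = 1), "out of range")
})

test_that("simplex counts are monotone: an empty dimension ends the complex", {
  for (s in 1:5) {
    counts <- count_simplices(rand_digraph(12, 0.25, seed = 300 + s))
    expect_true(all(counts > 0))  # trailing zeros trimmed, none interior
  }
})
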