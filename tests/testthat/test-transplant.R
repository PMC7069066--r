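# A small hand-made circuit: two excitatory m-types (A, B) and one
# inhibitory (I), with full attribute bookkeeping.
toy_neurons <- function() {
  data.frame(neuron_id = 0:5,
             m_type = c("A", "A", "B", "B", "I", "I"),
             layer = "L23",
             synapse_class = c("EXC", "EXC", "EXC", "EXC", "INH", "INH"),
             x_um = c(0, 10, 20, 30, 40, 50), y_um = 0, z_um = 0)
}

with_attrs <- function(edges, n = 6) {
  e <- data.frame(pre = edges[, 1], post = edges[, 2])
  e$synapse_count <- seq_len(nrow(e)) + 1L
  e$path_length <- 100 + 10 * seq_len(nrow(e))
  connectome(e, n)
}

test_that("transplant fills slots, duplicates on demand, and reports losses", {
  neu <- toy_neurons()
  # reference: post 2 has two afferents from m-type A; post 3 has none
  ref <- with_attrs(rbind(c(0, 2), c(1, 2), c(4, 2)))
  # cloud: post 2 demands three A-afferents (impossible without duplication
  # is not needed here: only ids 0,1 exist -> demand 2), post 3 demands one
  cloud <- connectome(data.frame(pre = c(0L, 1L, 0L), post = c(2L, 2L, 3L)),
                      6)
  out <- transplant(cloud, ref, neu, seed = 1)
  tab <- out$loss$table
  ab <- tab[tab$pre_mtype == "A" & tab$post_mtype == "B", ]
  expect_equal(ab$required, 3L)
  expect_equal(ab$placed, 2L)
  expect_equal(ab$lost, 1L)  # post 3 has no A slots
  expect_equal(ab$required, ab$placed + ab$lost)
  # slot attributes preserved as a multiset for post 2
  hyb <- out$hybrid$edges
  h2 <- hyb[hyb$post == 2 & hyb$pre %in% c(0, 1), ]
  r2 <- ref$edges[ref$edges$post == 2 & ref$edges$pre %in% c(0, 1), ]
  expect_setequal(paste(h2$synapse_count, h2$path_length),
                  paste(r2$synapse_count, r2$path_length))
  # inhibitory edge copied bitwise
  hi <- hyb[hyb$pre == 4, ]
  ri <- ref$edges[ref$edges$pre == 4, ]
  expect_equal(hi$synapse_count, ri$synapse_count)
  expect_equal(hi$path_length, ri$path_length)
})

test_that("demand above the slot count duplicates slots", {
  # three demanded A-afferents for post 2, but only two slots
  neu2 <- rbind(toy_neurons(),
                data.frame(neuron_id = 6, m_type = "A", layer = "L23",
                           synapse_class = "EXC", x_um = 60, y_um = 0,
                           z_um = 0))
  cloud3 <- connectome(data.frame(pre = c(0L, 1L, 6L), post = c(2L, 2L, 2L)),
                       7)
  ref2 <- with_attrs(rbind(c(0, 2), c(1, 2)), n = 7)
  out <- transplant(cloud3, ref2, neu2, seed = 2)
  tab <- out$loss$table
  expect_equal(tab$duplicated, 1L)
  expect_equal(tab$placed, 3L)
  expect_equal(tab$lost, 0L)
  # every placed edge carries attributes from the two original slots
  expect_true(all(out$hybrid$edges$synapse_count %in%
                    ref2$edges$synapse_count))
})

test_that("zero-demand-excess groups lose nothing", {
  neu <- toy_neurons()
  ref <- with_attrs(rbind(c(0, 2), c(1, 3)))
  cloud <- connectome(data.frame(pre = c(1L, 0L), post = c(2L, 3L)), 6)
  out <- transplant(cloud, ref, neu, seed = 3)
  expect_equal(sum(out$loss$table$lost), 0L)
  expect_equal(out$loss$exc_loss_fraction, 0)
})

test_that("matched removal removes exactly the lost counts per pair", {
  spec <- small_spec(n = 250, seed = 21)
  neu <- generate_neurons(spec)
  m <- instantiate_morphologies(neu, spec)
  tg <- default_pair_targets(neu, m, mean_degree = 25)
  ref <- sample_reference_connectome(neu, m, tg, seed = 1)
  ref <- assign_connection_attributes(ref, neu, seed = 2)
  cl <- build_cloud_connectome(neu, m, ref, seed = 3)
  out <- transplant(cl, ref, neu, seed = 4)
  ctrl <- matched_removal(ref, out$loss, neu, seed = 5)
  mref <- macroconnectome(ref, neu)
  mctrl <- macroconnectome(ctrl, neu)
  removed <- mref - mctrl
  tab <- out$loss$table
  for (k in seq_len(nrow(tab))) {
    expect_equal(removed[tab$pre_mtype[k], tab$post_mtype[k]], tab$lost[k])
  }
  # the control's per-pair counts equal the hybrid's (the matched-removal
  # contract), and inhibitory rows are untouched
  expect_equal(mctrl, macroconnectome(out$hybrid, neu))
  # zero-loss report leaves the wiring identical
  zero <- out$loss
  zero$table$lost <- 0L
  expect_identical(matched_removal(ref, zero, neu, seed = 6)$edges,
                   ref$edges)
})

test_that("path-length shuffling permutes within groups and spares inhibition", {
  spec <- small_spec(n = 250, seed = 22)
  neu <- generate_neurons(spec)
  m <- instantiate_morphologies(neu, spec)
  tg <- default_pair_targets(neu, m, mean_degree = 25)
  ref <- sample_reference_connectome(neu, m, tg, seed = 1)
  ref <- assign_connection_attributes(ref, neu, seed = 2)
  sh <- shuffle_path_length(ref, neu, seed = 9)
  expect_equal(sh$edges$pre, ref$edges$pre)
  expect_equal(sh$edges$synapse_count, ref$edges$synapse_count)
  # group multisets preserved
  exc <- neu$synapse_class[ref$edges$pre + 1] == "EXC"
  key <- paste(ref$edges$post, neu$m_type[ref$edges$pre + 1])
  for (g in split(which(exc), key[exc])[1:50]) {
    expect_equal(sort(sh$edges$path_length[g]),
                 sort(ref$edges$path_length[g]))
  }
  # inhibitory edges bitwise unchanged
  expect_identical(sh$edges$path_length[!exc], ref$edges$path_length[!exc])
  # something actually moved among the excitatory edges
  expect_gt(sum(sh$edges$path_length[exc] != ref$edges$path_length[exc]), 0)
  # size-1 groups cannot change
  ones <- names(which(table(key[exc]) == 1))
  idx1 <- which(exc & key %in% ones)
  expect_identical(sh$edges$path_length[idx1], ref$edges$path_length[idx1])
})
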