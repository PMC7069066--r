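# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's enumeration strategy: simplices are found by checking
# every permutation of every vertex subset, maximality via explicit face
# sets, triads by matching induced subgraphs against hand-written
# representatives.

make_conn <- function(edges, n) {
  connectome(data.frame(pre = edges[, 1], post = edges[, 2]), n)
}

rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p, n, n)
  diag(A) <- FALSE
  idx <- which(A, arr.ind = TRUE)
  make_conn(cbind(idx[, 1] - 1L, idx[, 2] - 1L), n)
}

adj_of <- function(conn) {
  A <- matrix(FALSE, conn$n_neurons, conn$n_neurons)
  if (nrow(conn$edges)) A[cbind(conn$edges$pre, conn$edges$post) + 1L] <- TRUE
  A
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# All directed simplices by subset + permutation enumeration.
# Returns a list: element d+1 holds a matrix with d+1 rows (0-based ids),
# one column per d-simplex.
bf_all_simplices <- function(conn) {
  n <- conn$n_neurons
  A <- adj_of(conn)
  U <- A | t(A)
  out <- list(matrix(0:(n - 1L), nrow = 1))
  for (d in seq_len(n - 1L)) {
    found <- list()
    for (sub in utils::combn(n, d + 1L, simplify = FALSE)) {
      pairs <- utils::combn(sub, 2L)
      if (!all(U[t(pairs)])) next
      for (perm in perms_of(sub)) {
        ok <- TRUE
        for (i in seq_len(d)) {
          for (j in (i + 1L):(d + 1L)) {
            if (!A[perm[i], perm[j]]) {
              ok <- FALSE
              break
            }
          }
          if (!ok) break
        }
        if (ok) found[[length(found) + 1L]] <- perm - 1L
      }
    }
    if (length(found) == 0) break
    out[[d + 1L]] <- matrix(unlist(found), nrow = d + 1L)
  }
  out
}

bf_counts <- function(all_simplices) {
  vapply(all_simplices, ncol, numeric(1))
}

# Maximal = not obtainable by deleting one vertex of a higher simplex.
bf_maximal_counts <- function(all_simplices) {
  counts <- numeric(length(all_simplices))
  for (d in seq_along(all_simplices) - 1L) {
    simp <- all_simplices[[d + 1L]]
    faces <- character(0)
    if (d + 2L <= length(all_simplices)) {
      higher <- all_simplices[[d + 2L]]
      for (col in seq_len(ncol(higher))) {
        tup <- higher[, col]
        faces <- c(faces, vapply(seq_along(tup), function(i) {
          paste(tup[-i], collapse = ",")
        }, character(1)))
      }
    }
    keys <- apply(simp, 2, paste, collapse = ",")
    counts[d + 1L] <- sum(!(keys %in% faces))
  }
  counts
}

bf_nd_in_degree <- function(all_simplices, n, N) {
  out <- numeric(n)
  if (N + 1L > length(all_simplices)) return(out)
  sinks <- all_simplices[[N + 1L]][N + 1L, ]
  for (s in sinks) out[s + 1L] <- out[s + 1L] + 1
  out
}

bf_participation <- function(all_simplices, conn, N) {
  e <- conn$edges
  key <- paste(e$pre, e$post)
  ns <- nk <- numeric(nrow(e))
  if (N + 1L <= length(all_simplices)) {
    simp <- all_simplices[[N + 1L]]
    for (col in seq_len(ncol(simp))) {
      tup <- simp[, col]
      i_src <- match(paste(tup[1], tup[2]), key)
      i_snk <- match(paste(tup[N], tup[N + 1L]), key)
      ns[i_src] <- ns[i_src] + 1
      nk[i_snk] <- nk[i_snk] + 1
    }
  }
  data.frame(pre = e$pre, post = e$post, n_source = ns, n_sink = nk)
}

# Triad classification against hand-written representatives (standard
# triad-census codes, connected classes only).
triad_reps <- list(
  "021D" = rbind(c(2, 1), c(2, 3)),
  "021U" = rbind(c(1, 2), c(3, 2)),
  "021C" = rbind(c(1, 2), c(2, 3)),
  "111D" = rbind(c(1, 2), c(2, 1), c(3, 2)),
  "111U" = rbind(c(1, 2), c(2, 1), c(2, 3)),
  "030T" = rbind(c(1, 2), c(3, 2), c(1, 3)),
  "030C" = rbind(c(2, 1), c(3, 2), c(1, 3)),
  "201" = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
  "120D" = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
  "120U" = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
  "120C" = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
  "210" = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
  "300" = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1))
)

rep_mats <- lapply(triad_reps, function(e) {
  B <- matrix(FALSE, 3, 3)
  B[e] <- TRUE
  B
})

perm3 <- perms_of(1:3)

bf_triad_census <- function(conn) {
  A <- adj_of(conn)
  n <- conn$n_neurons
  counts <- setNames(numeric(length(rep_mats)), names(rep_mats))
  for (sub in utils::combn(n, 3L, simplify = FALSE)) {
    B <- A[sub, sub]
    U <- B | t(B)
    if (sum(U[upper.tri(U)]) < 2) next  # not connected
    for (lbl in names(rep_mats)) {
      hit <- FALSE
      for (p in perm3) {
        if (identical(B[p, p], rep_mats[[lbl]])) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        counts[lbl] <- counts[lbl] + 1
        break
      }
    }
  }
  counts
}

# Exact inclusion probabilities of the sequential pick-zero-renormalize
# procedure, by full enumeration of pick orders.
incl_exact <- function(w, k) {
  n <- length(w)
  acc <- numeric(n)
  rec <- function(w, k, pr, sel) {
    if (k == 0) {
      acc[sel] <<- acc[sel] + pr
      return()
    }
    s <- sum(w)
    for (i in which(w > 0)) {
      w2 <- w
      w2[i] <- 0
      rec(w2, k - 1, pr * w[i] / s, c(sel, i))
    }
  }
  rec(w, k, 1, integer(0))
  acc
}

# Small, fast circuit specification for wiring tests.
small_spec <- function(n = 300, eta = 20, seed = 1, bin = 10) {
  circuit_spec(n_neurons = n, eta = eta, grid_bin = bin, seed = seed)
}
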