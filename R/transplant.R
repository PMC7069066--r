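#' Transplant a cloud wiring into a reference connectome
#'
#' Re-implements the cloud edge set inside an existing, attribute-carrying
#' reference wiring. For each (postsynaptic neuron, presynaptic m-type)
#' group, the reference's excitatory afferent connections form *slots*
#' carrying their `synapse_count` and `path_length`; the cloud wiring's new
#' presynaptic sources for that group are assigned to slots by a seeded
#' random bijection, preserving each slot's attributes. If a group demands
#' more connections than it has slots, randomly chosen slots are duplicated
#' (drawn uniformly with replacement); if it has no slots at all, the
#' demanded edges are dropped and counted as lost. Inhibitory connections
#' (presynaptic class INH) are copied from the reference unchanged.
#'
#' @param cloud a `connectome` (the cloud wiring; only edges with
#'   excitatory presynaptic neurons are transplanted).
#' @param reference a `connectome` with `synapse_count` and `path_length`.
#' @param neurons neuron table (supplies m-types and E/I classes).
#' @param seed integer seed.
#' @return list with elements `hybrid` (a `connectome`) and `loss` (a
#'   `loss_report`).
#' @export
transplant <- function(cloud, reference, neurons, seed = 1L) {
  if (!all(c("synapse_count", "path_length") %in% names(reference$edges))) {
    stop("reference connectome must carry synapse_count and path_length")
  }
  exc <- neurons$synapse_class == "EXC"
  ref_e <- reference$edges[exc[reference$edges$pre + 1L], , drop = FALSE]
  ref_i <- reference$edges[!exc[reference$edges$pre + 1L], , drop = FALSE]
  cl_e <- cloud$edges[exc[cloud$edges$pre + 1L], , drop = FALSE]

  mt <- neurons$m_type
  key_ref <- paste(ref_e$post, mt[ref_e$pre + 1L])
  key_cl <- paste(cl_e$post, mt[cl_e$pre + 1L])
  slot_groups <- split(seq_len(nrow(ref_e)), key_ref)
  demand_groups <- split(seq_len(nrow(cl_e)), key_cl)

  placed <- vector("list", length(demand_groups))
  lost_edges <- vector("list", length(demand_groups))
  dup_flag <- vector("list", length(demand_groups))
  with_seed(seed, {
    for (g in seq_along(demand_groups)) {
      dem <- demand_groups[[g]]
      slots <- slot_groups[[names(demand_groups)[g]]]
      if (is.null(slots)) {
        lost_edges[[g]] <- dem
        next
      }
      n_dem <- length(dem)
      n_slot <- length(slots)
      if (n_dem <= n_slot) {
        chosen <- slots[sample.int(n_slot, n_dem)]
        dup <- logical(n_dem)
      } else {
        base <- slots[sample.int(n_slot)]
        extra <- slots[sample.int(n_slot, n_dem - n_slot, replace = TRUE)]
        chosen <- c(base, extra)
        dup <- c(logical(n_slot), rep(TRUE, n_dem - n_slot))
      }
      out <- cl_e[dem, c("pre", "post")]
      out$synapse_count <- ref_e$synapse_count[chosen]
      out$path_length <- ref_e$path_length[chosen]
      placed[[g]] <- out
      dup_flag[[g]] <- dup
    }
  })
  hybrid_e <- rbind(do.call(rbind, placed),
                    ref_i[, c("pre", "post", "synapse_count", "path_length")])
  hybrid <- connectome(hybrid_e[order(hybrid_e$pre, hybrid_e$post), ],
                       reference$n_neurons)

  # Loss accounting per (pre m-type, post m-type), excitatory only.
  pair_of <- function(idx) paste(mt[cl_e$pre[idx] + 1L],
                                 mt[cl_e$post[idx] + 1L], sep = "->")
  all_idx <- seq_len(nrow(cl_e))
  req <- table(pair_of(all_idx))
  lost_idx <- unlist(lost_edges)
  lost <- table(factor(pair_of(lost_idx), levels = names(req)))
  placed_idx <- setdiff(all_idx, lost_idx)
  dup_idx <- unlist(lapply(seq_along(placed), function(g) {
    demand_groups[[g]][dup_flag[[g]]]
  }))
  dup <- table(factor(pair_of(dup_idx), levels = names(req)))
  pairs <- do.call(rbind, strsplit(names(req), "->", fixed = TRUE))
  report <- data.frame(pre_mtype = pairs[, 1], post_mtype = pairs[, 2],
                       required = as.integer(req),
                       placed = as.integer(req) - as.integer(lost),
                       duplicated = as.integer(dup),
                       lost = as.integer(lost))
  rownames(report) <- NULL
  loss <- structure(
    list(table = report,
         exc_loss_fraction = sum(report$lost) / max(1L, sum(report$required))),
    class = "loss_report")
  list(hybrid = hybrid, loss = loss)
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    "<loss_report: %d excitatory connections required, %d lost (%.3g%%), %d duplicated>\n",
    sum(x$table$required), sum(x$table$lost), 100 * x$exc_loss_fraction,
    sum(x$table$duplicated)))
  invisible(x)
}

#' Matched removal control
#'
#' Removes from the reference wiring exactly the per-(pre m-type, post
#' m-type) numbers of connections recorded as lost in a transplant's loss
#' report (uniformly at random within each combination; excitatory
#' connections only), so that the control's per-pair counts equal the
#' hybrid's.
#'
#' @param reference a `connectome`.
#' @param loss a `loss_report` from [transplant()].
#' @param neurons neuron table.
#' @param seed integer seed.
#' @return a `connectome`.
#' @export
matched_removal <- function(reference, loss, neurons, seed = 1L) {
  tab <- loss$table[loss$table$lost > 0, , drop = FALSE]
  if (nrow(tab) == 0) return(reference)
  mt <- neurons$m_type
  keep <- rep(TRUE, nrow(reference$edges))
  epre <- mt[reference$edges$pre + 1L]
  epost <- mt[reference$edges$post + 1L]
  with_seed(seed, {
    for (k in seq_len(nrow(tab))) {
      cand <- which(epre == tab$pre_mtype[k] & epost == tab$post_mtype[k])
      if (length(cand) < tab$lost[k]) {
        stop(sprintf("loss for %s->%s exceeds available edges",
                     tab$pre_mtype[k], tab$post_mtype[k]))
      }
      keep[cand[sample.int(length(cand), tab$lost[k])]] <- FALSE
    }
  })
  connectome(reference$edges[keep, , drop = FALSE], reference$n_neurons)
}

#' Shuffle axonal path lengths within afferent groups
#'
#' Permutes the `path_length` attribute among connections sharing the same
#' postsynaptic neuron and presynaptic m-type, for excitatory presynaptic
#' neurons only; all other attributes and all inhibitory edges are
#' untouched. Together with [matched_removal()] this yields the
#' matched-control wiring.
#'
#' @param conn a `connectome` with `path_length`.
#' @param neurons neuron table.
#' @param seed integer seed.
#' @return a `connectome`.
#' @export
shuffle_path_length <- function(conn, neurons, seed = 1L) {
  stopifnot("path_length" %in% names(conn$edges))
  exc <- neurons$synapse_class[conn$edges$pre + 1L] == "EXC"
  key <- paste(conn$edges$post, neurons$m_type[conn$edges$pre + 1L])
  groups <- split(which(exc), key[exc])
  pl <- conn$edges$path_length
  with_seed(seed, {
    for (g in groups) {
      if (length(g) > 1) pl[g] <- pl[g[sample.int(length(g))]]
    }
  })
  conn$edges$path_length <- pl
  conn
}
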