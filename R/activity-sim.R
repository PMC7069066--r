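#' Parameters of the stochastic spiking simulation
#'
#' A discrete-time conditional-Bernoulli (GLM-style hazard) network: in each
#' time bin a neuron spikes with probability
#' `1 - exp(-exp(bias + drive) * step)`, where `drive` is the
#' exponentially filtered sum of delayed synaptic inputs. Synaptic weights
#' are `w_exc * g_E(gamma) * synapse_count` for excitatory presynaptic
#' neurons and `w_inh * g_I(gamma) * synapse_count` for inhibitory ones.
#' The calcium-like scalar `gamma` emulates the differential modulation of
#' excitatory vs. inhibitory synaptic efficacy by extracellular calcium:
#' both gains increase with `gamma`, the excitatory one faster
#' (`g_E(gamma) = gamma^gain_exc_exponent`, `g_I(gamma) = gamma`), moving
#' the network from asynchronous towards synchronous regimes as `gamma`
#' rises. Conduction delays are `path_length / conduction_velocity`,
#' quantised to the step (minimum one step).
#'
#' @param step_ms time step (ms).
#' @param duration_ms trial duration (ms).
#' @param trials number of repeated trials K.
#' @param baseline_rate_exc,baseline_rate_inh baseline hazard rates (Hz) of
#'   the two classes when the synaptic drive is zero.
#' @param w_exc excitatory weight per synapse (> 0, log-hazard units).
#' @param w_inh inhibitory weight per synapse (< 0).
#' @param gamma calcium-like excitability scalar (> 0).
#' @param gain_exc_exponent exponent of the excitatory gain (default 1.7).
#' @param tau_syn_ms synaptic kernel time constant (ms).
#' @param refractory_ms absolute refractory period (ms).
#' @param conduction_velocity um/ms mapping path length to delay.
#' @param stim_weight log-hazard increment per thalamic fiber spike.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(step_ms = 1, duration_ms = 2000, trials = 5,
                       baseline_rate_exc = 2, baseline_rate_inh = 5,
                       w_exc = 0.10, w_inh = -0.30, gamma = 1.25,
                       gain_exc_exponent = 1.7, tau_syn_ms = 5,
                       refractory_ms = 2, conduction_velocity = 300,
                       stim_weight = 1.0) {
  stopifnot(step_ms > 0, duration_ms > 0, trials >= 1, w_exc > 0, w_inh < 0,
            gamma > 0, tau_syn_ms > 0, refractory_ms >= 0,
            conduction_velocity > 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Excitatory and inhibitory gains of the calcium-like knob
#' @param params a [sim_params()].
#' @return named vector with `g_exc` and `g_inh`.
#' @export
calcium_gains <- function(params) {
  c(g_exc = params$gamma^params$gain_exc_exponent, g_inh = params$gamma)
}

#' Default thalamic-like rate envelope
#'
#' A periodic burst envelope standing in for whisker-deflection-driven
#' thalamic input: `burst_rate` Hz for `burst_ms` every `period_ms`,
#' `base_rate` Hz otherwise, one value per time step.
#'
#' @param duration_ms envelope duration (ms).
#' @param step_ms time step (ms).
#' @param burst_rate,base_rate fiber firing rates (Hz).
#' @param burst_ms,period_ms burst duration and period (ms).
#' @return numeric vector of rates per step.
#' @export
default_stim_envelope <- function(duration_ms, step_ms = 1,
                                  burst_rate = 100, base_rate = 2,
                                  burst_ms = 80, period_ms = 400) {
  t <- (seq_len(ceiling(duration_ms / step_ms)) - 1) * step_ms
  ifelse((t %% period_ms) < burst_ms, burst_rate, base_rate)
}

#' Build a thalamic-like stimulus
#'
#' Places `n_fibers` fibers on a regular lateral grid clipped to the column
#' cross-section (taking the cells closest to the axis) and innervates every
#' neuron within `radius` um lateral distance of a fiber. The per-fiber
#' firing-rate envelope (Hz, one value per time step) is shared by all
#' fibers and identical across trials; fiber spike times are drawn per
#' trial.
#'
#' @param neurons neuron table.
#' @param n_fibers number of fibers (>= 1).
#' @param envelope numeric vector of rates (Hz) per time step.
#' @param radius innervation radius (um).
#' @param column_radius lateral extent of the fiber grid (um); default from
#'   the neuron positions.
#' @param seed integer seed (jitters fiber positions within grid cells).
#' @return object of class `stimulus_set`: list with `fibers` (data.frame
#'   `x_um`, `z_um`), `targets` (list of 0-based neuron ids per fiber),
#'   `envelope`.
#' @export
build_stimulus <- function(neurons, n_fibers, envelope, radius = 60,
                           column_radius = NULL, seed = 1L) {
  stopifnot(n_fibers >= 1, all(envelope >= 0))
  if (is.null(column_radius)) {
    column_radius <- max(sqrt(neurons$x_um^2 + neurons$z_um^2))
  }
  k <- ceiling(sqrt(n_fibers))
  spacing <- 2 * column_radius / k
  gx <- rep(seq_len(k), k)
  gz <- rep(seq_len(k), each = k)
  cx <- (gx - (k + 1) / 2) * spacing
  cz <- (gz - (k + 1) / 2) * spacing
  ord <- order(cx^2 + cz^2)[seq_len(n_fibers)]
  with_seed(seed, {
    fib <- data.frame(
      x_um = cx[ord] + runif(n_fibers, -spacing / 4, spacing / 4),
      z_um = cz[ord] + runif(n_fibers, -spacing / 4, spacing / 4))
  })
  targets <- lapply(seq_len(n_fibers), function(f) {
    d2 <- (neurons$x_um - fib$x_um[f])^2 + (neurons$z_um - fib$z_um[f])^2
    neurons$neuron_id[d2 <= radius^2]
  })
  if (all(lengths(targets) == 0)) {
    warning("stimulus innervates no neurons (radius too small?)")
  }
  structure(list(fibers = fib, targets = targets, envelope = envelope),
            class = "stimulus_set")
}

#' Simulate network spiking activity
#'
#' Runs `params$trials` trials of the hazard model on a connectome. Trials
#' share the connectome, parameters, and stimulus layout but draw
#' independent noise; the whole run is deterministic given `seed`.
#'
#' @param conn a `connectome` (edge attributes `synapse_count` and
#'   `path_length` are used when present; otherwise count 1 and delay of
#'   one step).
#' @param neurons neuron table.
#' @param params a [sim_params()].
#' @param stimulus optional [build_stimulus()] result.
#' @param seed integer seed.
#' @return object of class `spike_data`: list with `trials` (each a
#'   data.frame `time_ms`, `neuron_id` sorted by time), `duration_ms`,
#'   `params`, `protocol`.
#' @export
simulate_spikes <- function(conn, neurons, params, stimulus = NULL,
                            seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  n <- conn$n_neurons
  e <- conn$edges
  step <- params$step_ms
  n_steps <- ceiling(params$duration_ms / step)
  gains <- calcium_gains(params)
  exc_pre <- neurons$synapse_class[e$pre + 1L] == "EXC"
  syn <- if ("synapse_count" %in% names(e)) e$synapse_count else rep(1, nrow(e))
  w <- ifelse(exc_pre, params$w_exc * gains["g_exc"],
              params$w_inh * gains["g_inh"]) * syn
  delay <- if ("path_length" %in% names(e)) {
    pmax(1L, as.integer(round(e$path_length / params$conduction_velocity /
                                step)))
  } else {
    rep(1L, nrow(e))
  }
  W <- lapply(split(seq_len(nrow(e)), delay), function(idx) {
    Matrix::sparseMatrix(i = e$post[idx] + 1L, j = e$pre[idx] + 1L,
                         x = w[idx], dims = c(n, n))
  })
  delays <- as.integer(names(W))
  max_delay <- max(c(delays, 1L))
  bias <- ifelse(neurons$synapse_class == "EXC",
                 log(params$baseline_rate_exc / 1000),
                 log(params$baseline_rate_inh / 1000))
  decay <- exp(-step / params$tau_syn_ms)
  refr <- round(params$refractory_ms / step)
  env <- NULL
  if (!is.null(stimulus)) {
    env <- rep_len(stimulus$envelope, n_steps)
  }

  trials <- vector("list", params$trials)
  for (tr in seq_len(params$trials)) {
    trials[[tr]] <- with_seed(derive_seed(seed, 1000L + tr), {
      pending <- matrix(0, n, max_delay + 1L)
      y <- numeric(n)
      last_spike <- rep(-refr - 1L, n)
      fiber_spikes <- NULL
      if (!is.null(stimulus)) {
        nf <- nrow(stimulus$fibers)
        p_f <- pmin(1, env * step / 1000)
        fiber_spikes <- matrix(runif(nf * n_steps) < rep(p_f, each = nf),
                               nf, n_steps)
      }
      times <- integer(0)
      ids <- integer(0)
      for (t in seq_len(n_steps)) {
        col <- (t - 1L) %% (max_delay + 1L) + 1L
        y <- y * decay + pending[, col]
        pending[, col] <- 0
        p <- 1 - exp(-exp(bias + y) * step)
        sp <- which(runif(n) < p & (t - last_spike) > refr)
        if (length(sp)) {
          last_spike[sp] <- t
          times <- c(times, rep.int(t, length(sp)))
          ids <- c(ids, sp - 1L)
          for (di in seq_along(W)) {
            dcol <- (t - 1L + delays[di]) %% (max_delay + 1L) + 1L
            pending[, dcol] <- pending[, dcol] +
              Matrix::rowSums(W[[di]][, sp, drop = FALSE])
          }
        }
        if (!is.null(fiber_spikes)) {
          fsp <- which(fiber_spikes[, t])
          if (length(fsp)) {
            tgt <- unlist(stimulus$targets[fsp])
            if (length(tgt)) {
              dcol <- t %% (max_delay + 1L) + 1L
              add <- tabulate(tgt + 1L, nbins = n) * params$stim_weight
              pending[, dcol] <- pending[, dcol] + add
            }
          }
        }
      }
      data.frame(time_ms = (times - 1L) * step, neuron_id = ids)
    })
  }
  structure(list(trials = trials, duration_ms = n_steps * step,
                 params = params,
                 protocol = if (is.null(stimulus)) "spontaneous" else
                   "evoked"),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  ns <- vapply(x$trials, nrow, integer(1))
  cat(sprintf(
    "<spike_data: %d trials of %g ms (%s), %.0f spikes/trial on average>\n",
    length(x$trials), x$duration_ms, x$protocol, mean(ns)))
  invisible(x)
}
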