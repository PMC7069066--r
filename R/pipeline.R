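#' Default pipeline configuration
#'
#' A desk-scale configuration of the full comparison design: synthetic
#' circuit, reference wiring, cloud wiring, transplant, matched-removal
#' control, structural comparison, activity simulation of the three circuit
#' variants, and activity analysis.
#'
#' @param n_neurons circuit size (default 600, kept small so the whole
#'   pipeline runs in seconds).
#' @param seed global seed; per-stage seeds are derived from it.
#' @return nested configuration list (schema version 1).
#' @export
default_pipeline_config <- function(n_neurons = 600, seed = 1L) {
  list(
    schema_version = 1,
    seed = as.integer(seed),
    circuit = list(n_neurons = n_neurons, eta = 20, eta_ref = 100,
                   grid_bin = 8, column_radius = 210),
    wiring = list(mean_degree = 30, exponent = 2),
    attributes = list(tortuosity = 1.2, noise_sd = 10, mean_synapses = 5),
    simulation = list(step_ms = 1, duration_ms = 1000, trials = 4,
                      gamma = 1.25),
    analysis = list(dt_corr = 20, dt_trial = 5, sigma_s = 5, dt_s = 0.5,
                    max_dim = 4)
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file following the [default_pipeline_config()] schema.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1) {
    stop("unsupported or missing config schema_version (expected 1)")
  }
  base <- default_pipeline_config()
  utils::modifyList(base, cfg)
}

#' Run the full comparison pipeline
#'
#' Stages, in order: circuit generation; reference wiring with attributes;
#' cloud wiring with matched per-m-type-pair counts; transplant into the
#' reference (hybrid) with loss accounting; matched-removal +
#' path-length-shuffle control; structural statistics (degrees, simplex
#' counts, clustering, KL divergences) for reference and cloud; spiking
#' simulation of the three variants (reference, hybrid, control); and
#' activity analysis (rates, E/I ratio, trial correlations). Re-running
#' with the same configuration reproduces all results exactly.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a YAML file.
#' @param out_dir optional directory; when given, artifacts (neuron table,
#'   edge lists, loss report, spike files, report JSON) are written there.
#' @return a `run_report` list with per-stage summaries and the computed
#'   objects in `$artifacts`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed
  report <- list(schema_version = config$schema_version, seed = seed,
                 stages = list())
  stage <- function(name, value) {
    report$stages[[name]] <<- value
  }

  spec <- circuit_spec(
    n_neurons = config$circuit$n_neurons,
    eta = config$circuit$eta, eta_ref = config$circuit$eta_ref,
    grid_bin = config$circuit$grid_bin,
    column_radius = config$circuit$column_radius, seed = seed)
  neurons <- generate_neurons(spec)
  morph <- instantiate_morphologies(neurons, spec)
  stage("generate", list(n_neurons = nrow(neurons),
                         eta = spec$eta, seed = spec$seed))

  targets <- default_pair_targets(neurons, morph,
                                  mean_degree = config$wiring$mean_degree,
                                  exponent = config$wiring$exponent)
  reference <- sample_reference_connectome(neurons, morph, targets,
                                           seed = derive_seed(seed, 7L),
                                           exponent = config$wiring$exponent)
  reference <- assign_connection_attributes(
    reference, neurons, tortuosity = config$attributes$tortuosity,
    noise_sd = config$attributes$noise_sd,
    mean_synapses = config$attributes$mean_synapses,
    seed = derive_seed(seed, 8L))
  stage("wire_reference", list(n_edges = n_edges(reference),
                               seed = derive_seed(seed, 7L)))

  cloud <- build_cloud_connectome(neurons, morph, reference,
                                  seed = derive_seed(seed, 9L),
                                  exponent = config$wiring$exponent)
  stage("wire_cloud", list(n_edges = n_edges(cloud),
                           seed = derive_seed(seed, 9L)))

  tp <- transplant(cloud, reference, neurons,
                   seed = derive_seed(seed, 10L))
  stage("transplant", list(loss_fraction = tp$loss$exc_loss_fraction,
                           duplicated = sum(tp$loss$table$duplicated),
                           seed = derive_seed(seed, 10L)))

  control <- matched_removal(reference, tp$loss, neurons,
                             seed = derive_seed(seed, 11L))
  control <- shuffle_path_length(control, neurons,
                                 seed = derive_seed(seed, 12L))
  stage("control", list(n_edges = n_edges(control),
                        seed = derive_seed(seed, 11L)))

  ds_ref <- degree_summary(reference)
  ds_cloud <- degree_summary(cloud)
  simp_ref <- count_simplices(reference, max_dim = config$analysis$max_dim)
  simp_cloud <- count_simplices(cloud, max_dim = config$analysis$max_dim)
  sw_ref <- clustering_coefficients(reference)
  sw_cloud <- clustering_coefficients(cloud)
  exc_ids <- neurons$neuron_id[neurons$synapse_class == "EXC"]
  dd_ref <- connection_distance_distribution(reference, neurons, "afferent",
                                             exc_ids, max_distance = 1500)
  dd_cloud <- connection_distance_distribution(cloud, neurons, "afferent",
                                               exc_ids, max_distance = 1500)
  # Monte-Carlo standard error of the difference of the two sigma estimates
  se_in <- sqrt(ds_ref$sigma_in^2 + ds_cloud$sigma_in^2) /
    sqrt(2 * (nrow(neurons) - 1))
  se_out <- sqrt(ds_ref$sigma_out^2 + ds_cloud$sigma_out^2) /
    sqrt(2 * (nrow(neurons) - 1))
  identity_regime <-
    abs(ds_ref$sigma_in - ds_cloud$sigma_in) < 2 * se_in &&
    abs(ds_ref$sigma_out - ds_cloud$sigma_out) < 2 * se_out
  stage("topology", list(
    sigma_in = c(reference = ds_ref$sigma_in, cloud = ds_cloud$sigma_in),
    sigma_out = c(reference = ds_ref$sigma_out, cloud = ds_cloud$sigma_out),
    simplices_reference = simp_ref, simplices_cloud = simp_cloud,
    clustering = c(reference = sw_ref$c, cloud = sw_cloud$c),
    kl_afferent = kl_divergence(dd_ref, dd_cloud),
    identity_regime = identity_regime))

  sim_cfg <- config$simulation
  params <- sim_params(step_ms = sim_cfg$step_ms,
                       duration_ms = sim_cfg$duration_ms,
                       trials = sim_cfg$trials, gamma = sim_cfg$gamma)
  variants <- list(reference = reference, hybrid = tp$hybrid,
                   control = control)
  spikes <- lapply(seq_along(variants), function(i) {
    simulate_spikes(variants[[i]], neurons, params,
                    seed = derive_seed(seed, 20L + i))
  })
  names(spikes) <- names(variants)
  activity <- lapply(names(variants), function(v) {
    fr <- firing_rates(spikes[[v]], dt = config$analysis$dt_corr,
                       population = neurons$neuron_id)
    ei <- ei_spike_ratio(spikes[[v]], neurons)
    tc <- if (params$trials >= 2) {
      population_trial_correlations(spikes[[v]],
                                    dt = config$analysis$dt_trial)
    } else {
      NULL
    }
    list(mean_rate_hz = fr$mean_rate_hz, ei_ratio = ei$pooled,
         trial_correlation = tc$mean_correlation %||% NA_real_)
  })
  names(activity) <- names(variants)
  stage("activity", activity)

  artifacts <- list(spec = spec, neurons = neurons, morphologies = morph,
                    targets = targets, reference = reference, cloud = cloud,
                    hybrid = tp$hybrid, loss = tp$loss, control = control,
                    spikes = spikes)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_neuron_table(neurons, file.path(out_dir, "neurons.tsv"))
    write_connectome(reference, file.path(out_dir, "reference.tsv"))
    write_connectome(cloud, file.path(out_dir, "cloud.tsv"))
    write_connectome(tp$hybrid, file.path(out_dir, "hybrid.tsv"))
    write_connectome(control, file.path(out_dir, "control.tsv"))
    write_loss_report(tp$loss, file.path(out_dir, "loss_report.json"))
    for (v in names(spikes)) {
      write_spike_data(spikes[[v]], out_dir, prefix = paste0("spikes_", v))
    }
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report$artifacts <- artifacts
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: seed %d, stages: %s>\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  invisible(x)
}
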