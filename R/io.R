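# File formats: plain TSV with headers for tables, Matrix Market for the
# binary adjacency, JSON for reports, one whitespace-delimited file per
# trial for spike data.

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file '%s' lacks required column(s): %s", what, path,
                 paste(missing, collapse = ", ")))
  }
}

#' Read and write neuron tables
#'
#' TSV with header columns `neuron_id`, `m_type`, `layer`, `synapse_class`,
#' `x_um`, `y_um`, `z_um`.
#'
#' @param neurons a neuron table.
#' @param path file path.
#' @return `read_neuron_table` returns the neuron table.
#' @export
write_neuron_table <- function(neurons, path) {
  write.table(neurons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_neuron_table
#' @export
read_neuron_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("neuron_id", "m_type", "layer", "synapse_class",
                      "x_um", "y_um", "z_um"), "neuron table", path)
  if (!identical(sort(df$neuron_id), seq_len(nrow(df)) - 1L)) {
    stop("neuron table '", path, "': neuron_id must be contiguous from 0")
  }
  df[order(df$neuron_id), , drop = FALSE]
}

#' Read and write connectome edge lists
#'
#' TSV with header `pre_id`, `post_id` and optional `synapse_count`,
#' `path_length_um`, preceded by a `# n_neurons: <N>` comment line.
#'
#' @param conn a `connectome`.
#' @param path file path.
#' @param n_neurons overrides the neuron count recorded in the file.
#' @return `read_connectome` returns a `connectome`.
#' @export
write_connectome <- function(conn, path) {
  e <- conn$edges
  out <- data.frame(pre_id = e$pre, post_id = e$post)
  if ("synapse_count" %in% names(e)) out$synapse_count <- e$synapse_count
  if ("path_length" %in% names(e)) out$path_length_um <- e$path_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_neurons: %d", conn$n_neurons), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, n_neurons = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(n_neurons)) {
    m <- regmatches(first, regexec("^# n_neurons: *([0-9]+)", first))[[1]]
    if (length(m) < 2) {
      stop("connectome file '", path,
           "' lacks the '# n_neurons:' header; pass n_neurons explicitly")
    }
    n_neurons <- as.integer(m[2])
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  check_columns(df, c("pre_id", "post_id"), "connectome", path)
  e <- data.frame(pre = df$pre_id, post = df$post_id)
  if ("synapse_count" %in% names(df)) e$synapse_count <- df$synapse_count
  if ("path_length_um" %in% names(df)) e$path_length <- df$path_length_um
  connectome(e, n_neurons)
}

#' Export the binary adjacency in Matrix Market coordinate format
#' @param conn a `connectome`.
#' @param path destination (.mtx).
#' @export
write_adjacency_mm <- function(conn, path) {
  Matrix::writeMM(adjacency_matrix(conn), path)
  invisible(path)
}

#' Read and write density grids
#'
#' The values go to `<prefix>.tsv` (tab-delimited matrix, rows = lateral
#' bins) and the geometry (`bin`, `x0`, `y0`, `m_type`, `component`) to a
#' `<prefix>.json` sidecar.
#'
#' @param grid a `density_grid`.
#' @param prefix path prefix without extension.
#' @return `read_density_grid` returns a `density_grid`.
#' @export
write_density_grid <- function(grid, prefix) {
  write.table(grid$values, paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(bin = grid$bin, x0 = grid$x0, y0 = grid$y0,
         m_type = grid$m_type, component = grid$component),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(read.delim(paste0(prefix, ".tsv"), header = FALSE))
  dimnames(vals) <- NULL
  density_grid(vals, meta$bin, meta$x0, meta$y0,
               m_type = meta$m_type %||% NA_character_,
               component = meta$component %||% NA_character_)
}

#' Read and write spike data
#'
#' One whitespace-delimited file per trial with columns (time_ms,
#' neuron_id), named `<prefix>_trial<k>.dat`, plus a `<prefix>_meta.json`
#' with duration and protocol.
#'
#' @param spikes a `spike_data`.
#' @param dir output directory.
#' @param prefix file-name prefix (default "spikes").
#' @return `read_spike_data` returns a `spike_data`.
#' @export
write_spike_data <- function(spikes, dir, prefix = "spikes") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(spikes$trials)) {
    write.table(spikes$trials[[k]],
                file.path(dir, sprintf("%s_trial%03d.dat", prefix, k)),
                sep = " ", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  jsonlite::write_json(
    list(duration_ms = spikes$duration_ms, protocol = spikes$protocol,
         trials = length(spikes$trials)),
    file.path(dir, paste0(prefix, "_meta.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

#' @rdname write_spike_data
#' @export
read_spike_data <- function(dir, prefix = "spikes") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, "_meta.json")),
                              simplifyVector = TRUE)
  trials <- lapply(seq_len(meta$trials), function(k) {
    f <- file.path(dir, sprintf("%s_trial%03d.dat", prefix, k))
    if (file.size(f) == 0) {
      return(data.frame(time_ms = numeric(0), neuron_id = integer(0)))
    }
    df <- read.table(f, col.names = c("time_ms", "neuron_id"))
    df$neuron_id <- as.integer(df$neuron_id)
    df
  })
  structure(list(trials = trials, duration_ms = meta$duration_ms,
                 params = NULL, protocol = meta$protocol),
            class = "spike_data")
}

#' Write a transplant loss report as JSON
#' @param loss a `loss_report`.
#' @param path destination (.json).
#' @export
write_loss_report <- function(loss, path) {
  jsonlite::write_json(
    list(table = loss$table, exc_loss_fraction = loss$exc_loss_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_loss_report
#' @export
read_loss_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = x$table, exc_loss_fraction = x$exc_loss_fraction),
            class = "loss_report")
}
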