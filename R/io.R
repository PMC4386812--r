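#' Write a simulated trace to CSV
#'
#' Columns: `time_ms`, `V_soma_mV`, then `V_node_mV`, `d` and `g_syn_nS`
#' where available. `g_syn` must be supplied on the recorded grid.
#'
#' @param sim An `nl_sim` object.
#' @param path Output path.
#' @param g_syn Optional synaptic conductance on the recorded grid (nS).
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path, g_syn = NULL) {
  df <- data.frame(time_ms = sim$times, V_soma_mV = sim$V_soma)
  if (!is.null(sim$V_node)) df$V_node_mV <- sim$V_node
  if (!is.null(sim$d)) df$d <- sim$d
  if (!is.null(g_syn)) {
    stopifnot(length(g_syn) == length(sim$times))
    df$g_syn_nS <- as.numeric(g_syn)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write spike times as plain text
#'
#' One event time per line, in ms with six decimal places.
#'
#' @param times Spike times (ms).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_times <- function(times, path) {
  writeLines(sprintf("%.6f", times), path)
  invisible(path)
}

#' Read spike times written by [write_spike_times()]
#' @param path Input path.
#' @return Numeric vector of times (ms).
#' @export
read_spike_times <- function(path) {
  x <- readLines(path)
  as.numeric(x[nzchar(x)])
}

#' Write spike trains of several fibers as a two-column CSV
#'
#' Columns `fiber_id`, `time_ms`.
#'
#' @param trains List of spike-time vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  df <- data.frame(
    fiber_id = rep(seq_along(trains), lengths(trains)),
    time_ms = unlist(trains, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a conductance trace as CSV
#'
#' Columns `time_ms`, `g_nS`.
#'
#' @param g Conductance trace from [conductance_from_trains()] or
#'   [binaural_conductance()] (carries its `dt` attribute).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conductance_csv <- function(g, path) {
  dt <- attr(g, "dt")
  stopifnot(!is.null(dt))
  df <- data.frame(time_ms = (seq_along(g) - 1) * dt, g_nS = as.numeric(g))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records seed, integration settings and the resolved configuration beside
#' the outputs of a run, so that the run is reproducible from the output
#' directory alone.
#'
#' @param manifest Named list.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}
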