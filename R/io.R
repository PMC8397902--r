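#' Write trial spikes in the neutral columnar format
#'
#' Delimited text with columns (cell_id, trial_id, spike_time_s), plus a YAML
#' sidecar `<path>.meta.yml` holding the trial count, recording span, state
#' epochs, window length and labels.
#'
#' @param ts a [trial_spikes()] object.
#' @param path output file path (the sidecar gets `.meta.yml` appended).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(ts, path) {
  stopifnot(inherits(ts, "trial_spikes"))
  rows <- list()
  for (ci in seq_len(ts$n_cells)) for (tr in seq_len(ts$n_trials)) {
    st <- ts$spikes[[ci]][[tr]]
    if (length(st))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ts$cell_ids[ci], trial_id = tr, spike_time_s = st)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), trial_id = integer(0),
               spike_time_s = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(n_trials = ts$n_trials, t_range = ts$t_range,
               spontaneous = ts$spontaneous, evoked = ts$evoked,
               T_window = ts$T_window, cell_ids = as.list(ts$cell_ids),
               recording = ts$recording, stimulus = ts$stimulus)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' Read trial spikes from the neutral columnar format
#'
#' @param path file written by [write_spikes()] (sidecar expected alongside).
#' @return A [trial_spikes()] object.
#' @export
read_spikes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  cell_ids <- unlist(meta$cell_ids)
  spikes <- lapply(cell_ids, function(cid) {
    lapply(seq_len(meta$n_trials), function(tr) {
      sel <- tab$cell_id == cid & tab$trial_id == tr
      sort(tab$spike_time_s[sel])
    })
  })
  trial_spikes(spikes, t_range = unlist(meta$t_range),
               spontaneous = unlist(meta$spontaneous),
               evoked = unlist(meta$evoked), T_window = meta$T_window,
               cell_ids = cell_ids, recording = meta$recording,
               stimulus = meta$stimulus)
}

#' Write a fitting target as a delimited table
#'
#' Columns: time, psth, variance, covariance, het_psth, het_var, het_cov.
#' The epoch and any ground truth go into a YAML sidecar.
#'
#' @param target an [data_target()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target <- function(target, path) {
  stopifnot(inherits(target, "ob_target"))
  tab <- data.frame(time = target$time, psth = target$psth,
                    variance = target$var, covariance = target$cov,
                    het_psth = target$het_psth, het_var = target$het_var,
                    het_cov = target$het_cov)
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(epoch = target$epoch)
  if (!is.null(target$truth)) meta$truth <- as.list(target$truth)
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}

#' Read a fitting target written by [write_target()]
#'
#' @param path input path.
#' @return An [data_target()].
#' @export
read_target <- function(path) {
  tab <- utils::read.csv(path)
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  truth <- if (!is.null(meta$truth)) unlist(meta$truth) else NULL
  data_target(time = tab$time, psth = tab$psth, var = tab$variance,
              cov = tab$covariance, het_psth = tab$het_psth,
              het_var = tab$het_var, het_cov = tab$het_cov,
              epoch = unlist(meta$epoch), truth = truth)
}

#' Build a network and input regime from a YAML configuration
#'
#' The configuration names the free and fixed couplings, time constants,
#' optional transfer-table files (per cell type), input-correlation overrides,
#' the input regime and its mean/noise parameters, and simulation settings.
#' Unspecified entries fall back to package defaults. Example:
#' \preformatted{
#' couplings: {wMG: 6, wGM: 3, wGc: 1.5, wMP: 1, wPM: 1}
#' tau: {MC: 40, PGC: 20, GC: 30}
#' transfer_tables: {MC: mc.txt, PGC: pgc.txt, GC: gc.txt}
#' input:
#'   regime: small_fixed
#'   mu_base: {MC: 1.0, PGC: 0.8, GC: 0.5}
#'   mu_evoked: {MC: 4.0, PGC: 3.0, GC: 2.0}
#'   sigma_small: {MC: 2.5, PGC: 2.5, GC: 2.5}
#'   sigma_large: {MC: 5.0, PGC: 5.0, GC: 5.0}
#'   tau_rise: 100
#' simulation: {dt: 1, t_start: -2000, t_end: 2000, n_realizations: 1000,
#'              T_window: 100, seed: 1}
#' }
#'
#' @param path path to the YAML file.
#' @return list with `net` ([ob_network()]), `orn` ([orn_regime()]) and
#'   `simulation` (a list of settings, possibly empty).
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cp <- cfg$couplings
  if (is.null(cp$wMG) || is.null(cp$wGM) || is.null(cp$wGc))
    stop("config must provide couplings wMG, wGM, wGc", call. = FALSE)
  net_args <- list(wMG = cp$wMG, wGM = cp$wGM, wGc = cp$wGc)
  if (!is.null(cp$wMP)) net_args$wMP <- cp$wMP
  if (!is.null(cp$wPM)) net_args$wPM <- cp$wPM
  if (!is.null(cfg$tau)) net_args$tau <- unlist(cfg$tau)
  if (!is.null(cfg$transfer_tables)) {
    dir <- dirname(path)
    net_args$transfer <- lapply(cfg$transfer_tables, function(f)
      read_transfer_table(if (file.exists(f)) f else file.path(dir, f)))
  }
  net <- do.call(ob_network, net_args)
  orn_args <- list(net = net)
  inp <- cfg$input
  if (!is.null(inp)) {
    if (!is.null(inp$regime)) orn_args$regime <- inp$regime
    for (nm in c("mu_base", "mu_evoked", "sigma_small", "sigma_large"))
      if (!is.null(inp[[nm]])) orn_args[[nm]] <- unlist(inp[[nm]])
    if (!is.null(inp$tau_rise)) orn_args$tau_rise <- inp$tau_rise
  }
  orn <- do.call(ob_orn_input, orn_args)
  list(net = net, orn = orn,
       simulation = if (is.null(cfg$simulation)) list() else cfg$simulation)
}

#' Write a stat series as a long delimited table
#'
#' Columns: window_center, unit (cell index or `j:k` pair), statistic
#' (`psth`, `var`, `cov`), value.
#'
#' @param stats an [ensemble_stats()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_series <- function(stats, path) {
  stopifnot(inherits(stats, "stat_series"))
  n <- ncol(stats$psth)
  rows <- list(
    data.frame(window_center = rep(stats$centers, n),
               unit = rep(as.character(seq_len(n)), each = length(stats$centers)),
               statistic = "psth", value = as.vector(stats$psth)),
    data.frame(window_center = rep(stats$centers, n),
               unit = rep(as.character(seq_len(n)), each = length(stats$centers)),
               statistic = "var", value = as.vector(stats$var)))
  pair_id <- paste0(stats$pairs[, 1], ":", stats$pairs[, 2])
  rows[[3]] <- data.frame(
    window_center = rep(stats$centers, length(pair_id)),
    unit = rep(pair_id, each = length(stats$centers)),
    statistic = "cov", value = as.vector(stats$cov))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
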