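#' Doubly stochastic trial-structured spike trains
#'
#' Generates trial-aligned spike trains with configurable evoked changes in
#' mean, variance and pairwise covariance. Per trial and epoch, each
#' gain-sharing group draws a common gain `g` with mean 1 and variance `v`
#' (gamma-distributed, shape `1/v`; `v = 0` gives `g = 1`); every cell then
#' fires a Poisson train at `lambda * g` within the epoch, with spike times
#' uniform given the count. Counts in a window of length `T` therefore have
#' mean `lambda T`, variance `lambda T + (lambda T)^2 v`, and co-group cells
#' covariance `lambda_a T lambda_b T v`; `v = 0` recovers Poisson statistics
#' (Fano factor 1, zero correlation).
#'
#' @param n_cells number of cells.
#' @param n_trials number of trials.
#' @param rate_spont,rate_evoked per-cell rates (spikes/s), recycled.
#' @param gain_var_spont,gain_var_evoked shared-gain variances `v`, `>= 0`.
#' @param groups integer vector assigning each cell to a gain-sharing group
#'   (default: all cells share one gain).
#' @param t_range recording span (s), onset at 0.
#' @param seed integer seed, or `NULL`.
#' @param ... passed to [trial_spikes()] (e.g. `T_window`, `mode`).
#' @return A [trial_spikes()] object.
#' @export
generate_trains <- function(n_cells = 30, n_trials = 10,
                            rate_spont = 5, rate_evoked = 10,
                            gain_var_spont = 0.1, gain_var_evoked = 0.3,
                            groups = rep(1L, n_cells), t_range = c(-2, 2),
                            seed = NULL, ...) {
  stopifnot(n_cells >= 1, n_trials >= 1, length(groups) == n_cells)
  rate_spont <- rep_len(rate_spont, n_cells)
  rate_evoked <- rep_len(rate_evoked, n_cells)
  if (any(rate_spont < 0) || any(rate_evoked < 0) ||
      gain_var_spont < 0 || gain_var_evoked < 0)
    stop("rates and gain variances must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_gain <- function(v) if (v == 0) 1 else
    stats::rgamma(1, shape = 1 / v, scale = v)
  epochs <- list(spont = c(t_range[1], 0), evoked = c(0, t_range[2]))
  gvar <- c(spont = gain_var_spont, evoked = gain_var_evoked)
  spikes <- lapply(seq_len(n_cells), function(ci) vector("list", n_trials))
  for (tr in seq_len(n_trials)) {
    for (ep in names(epochs)) {
      span <- epochs[[ep]]
      dur <- diff(span)
      gains <- vapply(sort(unique(groups)), function(g) draw_gain(gvar[ep]), 0)
      names(gains) <- sort(unique(groups))
      for (ci in seq_len(n_cells)) {
        lam <- (if (ep == "spont") rate_spont[ci] else rate_evoked[ci]) *
          gains[as.character(groups[ci])]
        cnt <- stats::rpois(1, lam * dur)
        if (cnt > 0) {
          st <- sort(stats::runif(cnt, span[1], span[2]))
          spikes[[ci]][[tr]] <- c(spikes[[ci]][[tr]], st)
        }
      }
    }
    for (ci in seq_len(n_cells))
      if (is.null(spikes[[ci]][[tr]])) spikes[[ci]][[tr]] <- numeric(0)
  }
  trial_spikes(spikes, t_range = t_range, ...)
}

#' Model-generated target statistics with known ground truth
#'
#' Simulates the olfactory-bulb circuit at a known coupling triple and returns
#' its mitral-cell windowed statistics as a fitting target, carrying the
#' generating couplings for recovery scoring. Heterogeneity series are
#' constant by default (uniform weights).
#'
#' @param wMG,wGM,wGc ground-truth couplings.
#' @param regime input-noise regime.
#' @param n_realizations ensemble size for the target simulation.
#' @param t_span,dt,T_window simulation settings.
#' @param seed integer seed.
#' @param het constant heterogeneity level for all three series.
#' @param net_args,orn_args extra constructor arguments.
#' @return An [data_target()] with `truth` set.
#' @export
generate_targets <- function(wMG, wGM, wGc, regime = "small_fixed",
                             n_realizations = 1000, t_span = c(-2000, 2000),
                             dt = 1, T_window = 100, seed = 1, het = 0,
                             net_args = list(), orn_args = list()) {
  net <- do.call(ob_network, c(list(wMG = wMG, wGM = wGM, wGc = wGc),
                               net_args))
  orn <- do.call(ob_orn_input, c(list(net = net, regime = regime), orn_args))
  ens <- simulate_ensemble(net, orn, t_span = t_span, dt = dt,
                           n_realizations = n_realizations, seed = seed,
                           T_window = T_window)
  ms <- mc_stats(ensemble_stats(ens), net)
  data_target(time = ms$time, psth = ms$psth, var = ms$var, cov = ms$cov,
              het_psth = rep(het, nrow(ms)), het_var = rep(het, nrow(ms)),
              het_cov = rep(het, nrow(ms)),
              epoch = c(t_span[1], t_span[2]) / 1000,
              truth = c(wMG = wMG, wGM = wGM, wGc = wGc))
}
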