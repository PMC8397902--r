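#' Olfactory receptor neuron input regime
#'
#' Time-varying mean and noise amplitude of the feedforward drive to each cell.
#' The mean `mu_j(t)` is a smooth step: baseline before stimulus onset, rising
#' exponentially (time constant `tau_rise`) to an evoked plateau after onset.
#' The noise amplitude `sigma_j(t)` follows one of three regimes:
#' \describe{
#'   \item{`small_fixed`}{`sigma_small` at all times,}
#'   \item{`time_varying`}{steps from `sigma_small` to `sigma_large` at onset,
#'     except for granule cells whose sigma never varies,}
#'   \item{`large_fixed`}{`sigma_large` at all times (granule cells stay at
#'     `sigma_small`, consistent with their sigma never being raised).}
#' }
#' The fixed regimes equal the spontaneous/evoked values of the time-varying
#' regime by construction.
#'
#' @param regime one of `"small_fixed"`, `"time_varying"`, `"large_fixed"`.
#' @param mu_base,mu_evoked numeric vectors (per cell) of baseline and plateau
#'   input means (activity units).
#' @param sigma_small,sigma_large numeric vectors (per cell) of the two noise
#'   amplitudes (activity units * sqrt(ms)), all `>= 0`.
#' @param gc_cells integer indices of granule cells (their sigma is pinned to
#'   `sigma_small`).
#' @param t_on stimulus onset time (ms).
#' @param tau_rise rise time constant of the mean step (ms).
#' @return An object of class `"orn_regime"`.
#' @seealso [ob_orn_input()] for circuit defaults, [orn_eval()] to evaluate.
#' @export
orn_regime <- function(regime = c("small_fixed", "time_varying", "large_fixed"),
                       mu_base, mu_evoked, sigma_small, sigma_large,
                       gc_cells = integer(0), t_on = 0, tau_rise = 100) {
  regime <- match.arg(regime)
  n <- length(mu_base)
  stopifnot(length(mu_evoked) == n, length(sigma_small) == n,
            length(sigma_large) == n)
  if (any(sigma_small < 0) || any(sigma_large < 0))
    stop("noise amplitudes sigma must be >= 0", call. = FALSE)
  if (tau_rise <= 0) stop("tau_rise must be positive", call. = FALSE)
  structure(list(regime = regime, n = n,
                 mu_base = as.numeric(mu_base),
                 mu_evoked = as.numeric(mu_evoked),
                 sigma_small = as.numeric(sigma_small),
                 sigma_large = as.numeric(sigma_large),
                 gc_cells = as.integer(gc_cells),
                 t_on = t_on, tau_rise = tau_rise),
            class = "orn_regime")
}

#' @export
print.orn_regime <- function(x, ...) {
  cat(sprintf("<orn_regime> %s, %d cells, onset %g ms, rise %g ms\n",
              x$regime, x$n, x$t_on, x$tau_rise))
  invisible(x)
}

#' Evaluate an input regime on a time grid
#'
#' @param orn an [orn_regime()].
#' @param t numeric vector of times (ms).
#' @return list with matrices `mu` and `sigma`, dimension `length(t) x n`.
#' @export
orn_eval <- function(orn, t) {
  stopifnot(inherits(orn, "orn_regime"))
  nt <- length(t)
  step <- ifelse(t >= orn$t_on, 1 - exp(-(t - orn$t_on) / orn$tau_rise), 0)
  mu <- outer(step, orn$mu_evoked - orn$mu_base) +
    matrix(orn$mu_base, nt, orn$n, byrow = TRUE)
  sig_lo <- matrix(orn$sigma_small, nt, orn$n, byrow = TRUE)
  sig_hi <- matrix(orn$sigma_large, nt, orn$n, byrow = TRUE)
  if (length(orn$gc_cells))
    sig_hi[, orn$gc_cells] <- sig_lo[, orn$gc_cells]
  sigma <- switch(orn$regime,
    small_fixed = sig_lo,
    large_fixed = sig_hi,
    time_varying = {
      evoked <- t >= orn$t_on
      out <- sig_lo
      out[evoked, ] <- sig_hi[evoked, ]
      out
    })
  list(mu = mu, sigma = sigma)
}

#' Spontaneous / evoked parameter snapshots of an input regime
#'
#' Constant (mu, sigma) vectors representing the spontaneous state (well before
#' onset) and the evoked plateau (well after onset), as used by the
#' steady-state reduction.
#'
#' @param orn an [orn_regime()].
#' @return list with elements `spontaneous` and `evoked`, each a list of
#'   vectors `mu`, `sigma`.
#' @export
orn_states <- function(orn) {
  ev <- orn_eval(orn, orn$t_on + 50 * orn$tau_rise)
  sp <- orn_eval(orn, orn$t_on - 1)
  list(spontaneous = list(mu = drop(sp$mu), sigma = drop(sp$sigma)),
       evoked = list(mu = drop(ev$mu), sigma = drop(ev$sigma)))
}

#' Default circuit input for the 7-cell network
#'
#' Mitral cells receive the strongest mean drive, periglomerular cells less,
#' and granule cells (which get no direct receptor input) a smaller evoked
#' increase standing in for excitation from unmodeled glomeruli.
#'
#' @param net an [ob_network()].
#' @param regime noise regime, see [orn_regime()].
#' @param mu_base,mu_evoked,sigma_small,sigma_large named per-type values.
#' @param ... passed on to [orn_regime()] (e.g. `tau_rise`).
#' @return An `"orn_regime"` for the 7 cells of `net`.
#' @export
ob_orn_input <- function(net, regime = "small_fixed",
                         mu_base = c(MC = 7.0, PGC = 0.8, GC = 1.0),
                         mu_evoked = c(MC = 12.0, PGC = 3.0, GC = 3.0),
                         sigma_small = c(MC = 2.5, PGC = 2.5, GC = 2.5),
                         sigma_large = c(MC = 5.0, PGC = 5.0, GC = 5.0),
                         ...) {
  ct <- net$cell_type
  orn_regime(regime,
             mu_base = unname(mu_base[ct]), mu_evoked = unname(mu_evoked[ct]),
             sigma_small = unname(sigma_small[ct]),
             sigma_large = unname(sigma_large[ct]),
             gc_cells = cells_of_type(net, "GC"), ...)
}

#' Interpolate the evoked noise level between regimes
#'
#' Returns a copy of the input regime whose large-noise value is replaced by
#' `sigma_hat = (j-1)/10 * sigma_small + (1 - (j-1)/10) * sigma_large`,
#' `j = 1..10`, the linear family used to probe robustness of the noise-regime
#' comparison: j = 1 leaves `sigma_large` unchanged, j = 10 brings it within
#' 10 percent of `sigma_small`.
#'
#' @param orn an [orn_regime()].
#' @param j integer in `1:10`.
#' @return An `"orn_regime"`.
#' @export
orn_interp_sigma <- function(orn, j) {
  stopifnot(inherits(orn, "orn_regime"), j %in% 1:10)
  frac <- (j - 1) / 10
  orn$sigma_large <- frac * orn$sigma_small + (1 - frac) * orn$sigma_large
  orn
}
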