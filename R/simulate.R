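#' Cholesky factor with positive-semidefinite fallback
#'
#' Lower-triangular square root of a correlation/covariance matrix. If the
#' matrix is singular (or numerically slightly indefinite), an eigenvalue
#' factorization with negative eigenvalues clipped at 0 is used instead, with
#' a warning; clearly indefinite input is an error.
#'
#' @param C symmetric matrix.
#' @param tol relative tolerance below which negative eigenvalues are treated
#'   as rounding error.
#' @return A matrix `L` with `L %*% t(L) == C` (up to clipping).
#' @export
chol_psd <- function(C, tol = 1e-8) {
  C <- as.matrix(C)
  ok <- try(t(chol(C)), silent = TRUE)
  if (!inherits(ok, "try-error")) return(ok)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("matrix is not positive semidefinite", call. = FALSE)
  warning("singular correlation matrix: using eigenvalue-clipped square root")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
}

#' Correlated white-noise increments
#'
#' Draws Brownian increments for `n_cells` streams with per-step variance `dt`
#' and cross-stream correlation `c`, realized by applying a matrix square root
#' of `c` to independent Gaussian draws.
#'
#' @param c correlation matrix (symmetric PSD, unit diagonal).
#' @param n_steps number of time steps.
#' @param n_cells number of streams; must match `nrow(c)`.
#' @param dt time step (ms).
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return `n_steps x n_cells` matrix of increments.
#' @export
correlated_noise <- function(c, n_steps, n_cells = nrow(c), dt = 1,
                             seed = NULL) {
  c <- as.matrix(c)
  if (nrow(c) != n_cells || ncol(c) != n_cells)
    stop("correlation matrix must be n_cells x n_cells", call. = FALSE)
  if (max(abs(diag(c) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  L <- chol_psd(c)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n_steps * n_cells), n_steps, n_cells)
  sqrt(dt) * z %*% t(L)
}

#' Simulate an ensemble of the stochastic rate network
#'
#' Integrates `tau_j dx_j = (-x_j + mu_j(t) + sum_k w_jk G_k) dt +
#' sigma_j(t) dW_j`, `r_j = F_j(x_j)`, by the explicit Euler-Maruyama scheme
#' with correlated noise increments, over `n_realizations` independent
#' realizations. Gates evolve by `ds/dt = alpha f(r) (1 - s) - beta s` with
#' `f(r) = r / r_bar`; all per-step updates use previous-step values.
#'
#' Windowed spike-count proxies `R_j(t) = integral of r_j over (t - T/2,
#' t + T/2)` (rectangle rule at `dt` resolution) are accumulated for every
#' realization on a grid of half-overlapping windows; full rate trajectories
#' are kept for the first `keep_trajectories` realizations only.
#'
#' @param net a [rate_network()] / [ob_network()].
#' @param orn an [orn_regime()] with one entry per cell.
#' @param t_span simulation interval in ms, default 2 s before to 2 s after
#'   stimulus onset.
#' @param dt time step (ms).
#' @param n_realizations ensemble size, `>= 1`.
#' @param seed integer seed (`NULL` to continue the current RNG stream).
#' @param T_window spike-count window length (ms); must be a multiple of
#'   `2 * dt`. Set to `NULL` to skip count accumulation.
#' @param keep_trajectories how many realizations' rate trajectories to store.
#' @return An object of class `"ob_ensemble"`: fields `time` (s, length
#'   `n_steps`), `psth` (matrix, across-realization mean rate), `sum_r`,
#'   `sumsq_r`, `cross_r` moment accumulators, `counts` (array
#'   `n_windows x n_cells x n_realizations`), `window_centers` (s), `traj`
#'   (array of kept rate trajectories), `gate_range`, plus metadata.
#' @export
simulate_ensemble <- function(net, orn, t_span = c(-2000, 2000), dt = 1,
                              n_realizations = 100, seed = NULL,
                              T_window = 100, keep_trajectories = 0) {
  stopifnot(inherits(net, "rate_network"), inherits(orn, "orn_regime"))
  if (orn$n != net$n) stop("orn and network cell counts differ", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (n_realizations < 1) stop("need at least one realization", call. = FALSE)
  n_steps <- floor(diff(t_span) / dt)
  if (n_steps < 2) stop("t_span too short for this dt", call. = FALSE)
  half_steps <- 0L
  if (!is.null(T_window)) {
    if (T_window < 2 * dt)
      stop("T_window must be at least 2 * dt", call. = FALSE)
    half_steps <- round(T_window / 2 / dt)
    if (abs(half_steps * 2 * dt - T_window) > 1e-9)
      stop("T_window must be a multiple of 2 * dt", call. = FALSE)
  }
  t_grid <- t_span[1] + dt * (seq_len(n_steps) - 1)    # step start times
  inp <- orn_eval(orn, t_grid)
  L <- chol_psd(net$input_correlation)
  rbar <- vapply(net$transfer, max_rate, 0)
  gate_alpha <- lapply(net$kinetics, function(kl)
    if (length(kl)) vapply(kl, `[[`, 0, "alpha") else numeric(0))
  gate_beta <- lapply(net$kinetics, function(kl)
    if (length(kl)) vapply(kl, `[[`, 0, "beta") else numeric(0))
  tf_x <- lapply(net$transfer, `[[`, "input")
  tf_y <- lapply(net$transfer, `[[`, "rate")

  if (!is.null(seed)) set.seed(seed)
  res <- .em_core(as.integer(n_realizations), as.integer(n_steps), dt,
                  net$tau, inp$mu, inp$sigma, L, net$W,
                  gate_alpha, gate_beta, rbar, tf_x, tf_y,
                  as.integer(half_steps), as.integer(keep_trajectories),
                  TRUE)
  n <- net$n
  n_win <- res$n_win
  time_s <- (t_span[1] + dt * seq_len(n_steps)) / 1000   # sample times
  counts <- NULL
  centers <- NULL
  if (n_win > 0) {
    counts <- array(res$counts, dim = c(n_win, n, n_realizations))
    centers <- (t_span[1] + dt * half_steps * seq_len(n_win)) / 1000
  }
  traj <- NULL
  if (keep_trajectories > 0)
    traj <- array(res$traj, dim = c(n_steps, n, keep_trajectories))
  structure(list(
    time = time_s,
    psth = matrix(res$sum_r, n_steps, n) / n_realizations,
    sum_r = matrix(res$sum_r, n_steps, n),
    sumsq_r = matrix(res$sumsq_r, n_steps, n),
    cross_r = matrix(res$cross_r, n_steps, max(n * (n - 1) / 2, 1)),
    counts = counts, window_centers = centers,
    traj = traj, gate_range = c(res$gate_min, res$gate_max),
    n_realizations = n_realizations, n_steps = n_steps, dt = dt,
    t_span = t_span, T_window = T_window, seed = seed,
    cell_type = net$cell_type, n = n), class = "ob_ensemble")
}

#' @export
print.ob_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ob_ensemble> %d cells, %d steps of %g ms, %d realizations, seed %s\n",
    x$n, x$n_steps, x$dt, x$n_realizations,
    if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}

#' Windowed spike-count proxy of a single rate trajectory
#'
#' `R(t) = integral of r over (t - T/2, t + T/2)`, rectangle rule at `dt`
#' resolution, on a grid of half-overlapping windows (centers spaced `T/2`).
#'
#' @param r numeric rate trajectory (spikes/s) sampled every `dt` ms.
#' @param dt sampling step (ms).
#' @param T_window window length (ms), a multiple of `2 * dt` and
#'   `>= 2 * dt`.
#' @return list with `counts` and window `centers` (ms, relative to the first
#'   sample time).
#' @export
windowed_counts <- function(r, dt = 1, T_window = 100) {
  if (T_window < 2 * dt)
    stop("T_window must be at least 2 * dt", call. = FALSE)
  half <- round(T_window / 2 / dt)
  if (abs(half * 2 * dt - T_window) > 1e-9)
    stop("T_window must be a multiple of 2 * dt", call. = FALSE)
  n_blocks <- floor(length(r) / half)
  if (n_blocks < 2) stop("trajectory shorter than one window", call. = FALSE)
  block <- vapply(seq_len(n_blocks), function(b)
    sum(r[((b - 1) * half + 1):(b * half)]), 0)
  counts <- (block[-n_blocks] + block[-1]) * dt / 1000
  list(counts = counts, centers = dt * half * seq_len(n_blocks - 1))
}

#' Ensemble spike-count statistics
#'
#' Across-realization mean rate (PSTH), windowed-count variance per cell and
#' covariance per cell pair, with unbiased (n - 1) normalization, on the
#' half-overlapping window grid of the ensemble.
#'
#' @param ens an [simulate_ensemble()] result that accumulated counts.
#' @return An object of class `"stat_series"`: `centers` (s), `T_window` (s),
#'   `psth` (windows x cells, spikes/s, mean count / T), `var` (windows x
#'   cells), `cov` (windows x pairs), `pairs` (2-column index matrix).
#' @export
ensemble_stats <- function(ens) {
  stopifnot(inherits(ens, "ob_ensemble"))
  if (is.null(ens$counts))
    stop("ensemble was simulated without count accumulation", call. = FALSE)
  if (ens$n_realizations < 2)
    stop("variance undefined for a single realization", call. = FALSE)
  counts <- ens$counts
  n_win <- dim(counts)[1]; n <- dim(counts)[2]; m <- dim(counts)[3]
  T_s <- ens$T_window / 1000
  mean_c <- apply(counts, c(1, 2), mean)
  var_c <- apply(counts, c(1, 2), stats::var)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  cov_c <- matrix(0, n_win, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- counts[, pairs[p, 1], ]; b <- counts[, pairs[p, 2], ]
    cov_c[, p] <- rowSums((a - rowMeans(a)) * (b - rowMeans(b))) / (m - 1)
  }
  structure(list(centers = ens$window_centers, T_window = T_s,
                 psth = mean_c / T_s, var = var_c, cov = cov_c,
                 pairs = pairs, cell_type = ens$cell_type,
                 n_realizations = m), class = "stat_series")
}

#' @export
print.stat_series <- function(x, ...) {
  cat(sprintf("<stat_series> %d windows of %g s, %d cells, %d pairs\n",
              length(x$centers), x$T_window, ncol(x$psth), ncol(x$cov)))
  invisible(x)
}

#' Instantaneous ensemble moments
#'
#' Across-realization mean, variance and pairwise covariance of the rate at
#' every time step (the `dt`-resolution statistics used to calibrate the
#' window-to-instantaneous scaling factors).
#'
#' @param ens an [simulate_ensemble()] result.
#' @return list with `time` (s), `mean`, `var` (steps x cells), `cov`
#'   (steps x pairs), `pairs`.
#' @export
instantaneous_stats <- function(ens) {
  stopifnot(inherits(ens, "ob_ensemble"))
  m <- ens$n_realizations
  if (m < 2) stop("variance undefined for a single realization", call. = FALSE)
  mu <- ens$sum_r / m
  v <- (ens$sumsq_r - m * mu^2) / (m - 1)
  n <- ens$n
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  cv <- matrix(0, ens$n_steps, nrow(pairs))
  for (p in seq_len(nrow(pairs)))
    cv[, p] <- (ens$cross_r[, p] - m * mu[, pairs[p, 1]] * mu[, pairs[p, 2]]) /
      (m - 1)
  list(time = ens$time, mean = mu, var = pmax(v, 0), cov = cv, pairs = pairs)
}

#' Mitral-cell summary statistics of a simulated ensemble
#'
#' The model-versus-data comparison uses the mitral cells only (the recorded
#' population): PSTH and count variance averaged over the two (statistically
#' identical) mitral cells, and the count covariance of the mitral-cell pair.
#'
#' @param stats an [ensemble_stats()] result from an [ob_network()] ensemble.
#' @param net the network that produced it.
#' @return data.frame with columns `time`, `psth`, `var`, `cov`.
#' @export
mc_stats <- function(stats, net) {
  stopifnot(inherits(stats, "stat_series"), inherits(net, "rate_network"))
  mc <- cells_of_type(net, "MC")
  if (length(mc) != 2) stop("expected exactly two mitral cells", call. = FALSE)
  p <- which(stats$pairs[, 1] == mc[1] & stats$pairs[, 2] == mc[2])
  data.frame(time = stats$centers,
             psth = rowMeans(stats$psth[, mc, drop = FALSE]),
             var = rowMeans(stats$var[, mc, drop = FALSE]),
             cov = stats$cov[, p])
}
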