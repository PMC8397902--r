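#' Halton quasi-random samples in a box
#'
#' First `n` points of the Halton low-discrepancy sequence (radical-inverse
#' digits in prime bases 2, 3, 5, ... per dimension, starting at index 1),
#' affinely mapped into the given box. Deterministic: repeated calls give
#' identical output.
#'
#' @param lower,upper numeric vectors of box bounds, `lower < upper`,
#'   elementwise finite.
#' @param n number of points, `>= 1`.
#' @return `n x length(lower)` matrix of points; column names follow `lower`.
#' @examples
#' halton_sample(c(0, 0, 0), c(1, 1, 1), 2)  # (1/2,1/3,1/5), (1/4,2/3,2/5)
#' @export
halton_sample <- function(lower, upper, n) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("need finite bounds with lower < upper", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (d > length(primes)) stop("too many dimensions", call. = FALSE)
  radical_inverse <- function(i, base) {
    f <- 1 / base; r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  u <- vapply(seq_len(d), function(dim)
    vapply(seq_len(n), radical_inverse, 0, base = primes[dim]),
    numeric(n))
  u <- matrix(u, nrow = n)
  out <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(out) <- names(lower)
  out
}

#' Default search box for the free couplings
#'
#' Bounds for the (wMG, wGM, wGc) screen, chosen to contain the best-fit
#' averages reported for all three noise regimes.
#' @return list with `lower` and `upper` named vectors.
#' @export
default_search_box <- function() {
  list(lower = c(wMG = 0, wGM = 0, wGc = 0),
       upper = c(wMG = 10, wGM = 8, wGc = 5))
}

#' Data-uncertainty weight series
#'
#' Builds the weights `W_i(t)` multiplying each model-data mismatch, as a
#' monotone non-increasing function of the across-population heterogeneity
#' (standard deviation) of the corresponding data statistic. Default form:
#' `W(t) = 1 / (1 + s(t) / mean(s))`, so `W = 1/2` where the heterogeneity
#' equals its time average; an all-zero heterogeneity series gives `W == 1`.
#'
#' @param het numeric heterogeneity series (across-cell or across-pair
#'   standard deviation at each time point), `>= 0`.
#' @param form a function of (s, mean_s) returning weights, overriding the
#'   default reciprocal-linear form.
#' @return numeric weight series, same length as `het`.
#' @export
build_weights <- function(het, form = NULL) {
  if (any(het < 0)) stop("heterogeneity must be >= 0", call. = FALSE)
  m <- mean(het)
  if (m == 0) return(rep(1, length(het)))
  if (is.null(form)) 1 / (1 + het / m) else form(het, m)
}

#' Target statistics for model fitting
#'
#' Bundles the data curves the model is fit to: PSTH, spike-count variance and
#' covariance on a common window-center grid, together with their
#' across-population heterogeneity series (from which the weights are built)
#' and the analysis epoch.
#'
#' @param time window centers (s).
#' @param psth,var,cov data statistic curves on that grid.
#' @param het_psth,het_var,het_cov heterogeneity series (default 0: uniform
#'   weights).
#' @param epoch analysis interval (s), default `c(-2, 2)`.
#' @param truth optional named vector of generating couplings (for recovery
#'   experiments).
#' @return An object of class `"ob_target"` with precomputed weights `W1`,
#'   `W2`, `W3`.
#' @export
data_target <- function(time, psth, var, cov, het_psth = 0 * time,
                        het_var = 0 * time, het_cov = 0 * time,
                        epoch = c(-2, 2), truth = NULL) {
  stopifnot(length(psth) == length(time), length(var) == length(time),
            length(cov) == length(time))
  if (any(var < 0)) stop("variance target must be >= 0", call. = FALSE)
  structure(list(time = time, psth = psth, var = var, cov = cov,
                 het_psth = het_psth, het_var = het_var, het_cov = het_cov,
                 W1 = build_weights(het_psth), W2 = build_weights(het_var),
                 W3 = build_weights(het_cov), epoch = epoch, truth = truth),
            class = "ob_target")
}

#' @export
print.ob_target <- function(x, ...) {
  cat(sprintf("<ob_target> %d windows on [%g, %g] s%s\n", length(x$time),
              min(x$time), max(x$time),
              if (is.null(x$truth)) "" else
                paste0(", truth (", paste(signif(x$truth, 3), collapse = ", "), ")")))
  invisible(x)
}

#' Weighted error between a model and a data statistic
#'
#' `integral of W(t) |X(t) - X_data(t)| dt` over the epoch, optionally
#' normalized by `||X_data|| = integral of (W(t) X_data(t))^2 dt` (the squared
#' weighted data integrated over the epoch). Trapezoidal integration on the
#' common grid. Note the error is not invariant to rescaling `W` by a
#' constant: the numerator scales linearly and the norm quadratically.
#'
#' @param model,data statistic series on the common grid.
#' @param time grid (s).
#' @param W weight series on the grid.
#' @param epoch integration interval (s).
#' @param normalize divide by `||data||`; an identically-zero norm is an
#'   error.
#' @return scalar error, `>= 0`.
#' @export
statistic_error <- function(model, data, time, W = rep(1, length(time)),
                            epoch = c(-2, 2), normalize = TRUE) {
  stopifnot(length(model) == length(time), length(data) == length(time),
            length(W) == length(time))
  sel <- time >= epoch[1] & time <= epoch[2]
  if (sum(sel) < 2) stop("fewer than 2 grid points in epoch", call. = FALSE)
  tt <- time[sel]
  num <- pracma::trapz(tt, W[sel] * abs(model[sel] - data[sel]))
  if (!normalize) return(num)
  nrm <- pracma::trapz(tt, (W[sel] * data[sel])^2)
  if (nrm <= 0)
    stop("zero data norm over the epoch: cannot normalize", call. = FALSE)
  num / nrm
}

#' PSTH tolerance gate
#'
#' A parameter set is close to the data if the unnormalized weighted L1
#' mismatch of its PSTH over the epoch is at most `tol` (boundary inclusive).
#'
#' @param psth_error_raw unnormalized weighted PSTH error (from
#'   [statistic_error()] with `normalize = FALSE`).
#' @param tol tolerance, default 1.4.
#' @return logical flag.
#' @export
psth_tolerance <- function(psth_error_raw, tol = 1.4) psth_error_raw <= tol

fit_errors <- function(mstats, target) {
  e1_raw <- statistic_error(mstats$psth, target$psth, target$time, target$W1,
                            target$epoch, normalize = FALSE)
  e1 <- statistic_error(mstats$psth, target$psth, target$time, target$W1,
                        target$epoch)
  e2 <- statistic_error(mstats$var, target$var, target$time, target$W2,
                        target$epoch)
  e3 <- statistic_error(mstats$cov, target$cov, target$time, target$W3,
                        target$epoch)
  c(error_psth_raw = e1_raw, error_psth = e1, error_var = e2, error_cov = e3,
    error_total = e1 + e2 + e3)
}

#' Screen the coupling space against target statistics
#'
#' Two-stage screening of coupling triples, following the fitting protocol:
#' every point is first simulated with a small ensemble
#' (`n_gate_realizations`) and gated on the PSTH tolerance (unnormalized
#' weighted mismatch `<= tol`); points within tolerance advance to
#' variance/covariance scoring with a larger ensemble (`n_realizations`).
#' Records are ranked with gated points first, then by total error, with ties
#' broken by PSTH error and sample index.
#'
#' All points at a given stage share one seed (common random numbers), so
#' Monte-Carlo noise is strongly correlated across points and largely cancels
#' out of their error differences - essential for stable rankings at
#' desk-scale ensemble sizes.
#'
#' @param points matrix of coupling triples (columns wMG, wGM, wGc), e.g. from
#'   [halton_sample()], or `NULL` to draw `n_points` from `box`.
#' @param target an [data_target()].
#' @param regime input-noise regime label, see [orn_regime()].
#' @param box list with `lower`/`upper` (used when `points` is `NULL`).
#' @param n_points number of Halton points when `points` is `NULL`.
#' @param n_realizations ensemble size for scoring gated points.
#' @param n_gate_realizations ensemble size for the PSTH gate stage.
#' @param t_span,dt,T_window simulation settings, see [simulate_ensemble()].
#' @param seed integer master seed (the two stages use `seed` and
#'   `seed + 1`).
#' @param tol PSTH tolerance.
#' @param net_args extra arguments passed to [ob_network()].
#' @param orn_args extra arguments passed to [ob_orn_input()].
#' @return An object of class `"ob_screen"`: a data.frame with one row per
#'   point (couplings, errors, `within_tolerance`, `stage`, `rank`,
#'   `failed`), ordered as sampled, with the settings in attributes.
#' @export
screen_parameter_space <- function(points = NULL, target, regime = "small_fixed",
                                   box = default_search_box(), n_points = 100,
                                   n_realizations = 2000,
                                   n_gate_realizations = 100,
                                   t_span = c(-2000, 2000), dt = 1,
                                   T_window = 100, seed = 1, tol = 1.4,
                                   net_args = list(), orn_args = list()) {
  stopifnot(inherits(target, "ob_target"))
  if (is.null(points)) points <- halton_sample(box$lower, box$upper, n_points)
  points <- as.matrix(points)
  n_pts <- nrow(points)
  eval_point <- function(i, n_real, stage_seed) {
    net <- do.call(ob_network, c(list(wMG = points[i, 1], wGM = points[i, 2],
                                      wGc = points[i, 3]), net_args))
    orn <- do.call(ob_orn_input, c(list(net = net, regime = regime),
                                   orn_args))
    ens <- simulate_ensemble(net, orn, t_span = t_span, dt = dt,
                             n_realizations = n_real,
                             seed = stage_seed, T_window = T_window)
    ms <- mc_stats(ensemble_stats(ens), net)
    ms <- data.frame(psth = stats::approx(ms$time, ms$psth, target$time,
                                          rule = 2)$y,
                     var = stats::approx(ms$time, ms$var, target$time,
                                         rule = 2)$y,
                     cov = stats::approx(ms$time, ms$cov, target$time,
                                         rule = 2)$y)
    fit_errors(ms, target)
  }
  res <- vector("list", n_pts)
  for (i in seq_len(n_pts)) {
    res[[i]] <- tryCatch({
      e <- eval_point(i, n_gate_realizations, seed)
      within <- unname(psth_tolerance(e["error_psth_raw"], tol))
      stage <- 1L
      if (within) {
        e <- eval_point(i, n_realizations, seed + 1)
        stage <- 2L
      }
      data.frame(wMG = points[i, 1], wGM = points[i, 2], wGc = points[i, 3],
                 t(e), within_tolerance = within, stage = stage,
                 failed = FALSE)
    }, error = function(err) {
      data.frame(wMG = points[i, 1], wGM = points[i, 2], wGc = points[i, 3],
                 error_psth_raw = NA_real_, error_psth = NA_real_,
                 error_var = NA_real_, error_cov = NA_real_,
                 error_total = NA_real_, within_tolerance = FALSE,
                 stage = 0L, failed = TRUE)
    })
  }
  out <- do.call(rbind, res)
  out$index <- seq_len(n_pts)
  ok <- !out$failed
  ord <- order(!out$within_tolerance[ok], out$error_total[ok],
               out$error_psth[ok], out$index[ok])
  out$rank <- NA_integer_
  out$rank[which(ok)[ord]] <- seq_len(sum(ok))
  rownames(out) <- NULL
  structure(out, class = c("ob_screen", "data.frame"),
            regime = regime, seed = seed, n_realizations = n_realizations,
            n_gate_realizations = n_gate_realizations,
            T_window = T_window, truth = target$truth)
}

#' Best-k fit records of a screen
#'
#' The `k` screened points with the lowest total error (ties broken by PSTH
#' error then sample index). If fewer than `k` valid records exist, all are
#' returned with a warning.
#'
#' @param screen an [screen_parameter_space()] result.
#' @param k number of records.
#' @return data.frame of the best records, in rank order.
#' @export
select_best <- function(screen, k = 10) {
  ok <- screen[!screen$failed, , drop = FALSE]
  ok <- ok[order(ok$rank), , drop = FALSE]
  if (nrow(ok) < k) {
    warning(sprintf("only %d valid records available (requested %d)",
                    nrow(ok), k))
    k <- nrow(ok)
  }
  utils::head(ok, k)
}

#' Scan for parameter sets with evoked decreases in variability
#'
#' Computes steady spontaneous and evoked mitral-cell statistics for each
#' sampled coupling triple and classifies the evoked changes in rate,
#' spike-count variance and pair covariance. Sets where both variance and
#' covariance decrease while the mean rate still increases are the
#' decreased-variability sets; sets where inhibition is so strong that the
#' mean does not increase are flagged separately.
#'
#' The default backend runs short constant-input Monte-Carlo ensembles at the
#' two states and averages windowed count statistics over the stationary
#' part; the `"reduction"` backend uses [solve_moments()] instead (fast, but
#' the self-consistent equations need not converge deep in the
#' strong-inhibition box).
#'
#' @param points matrix of coupling triples, or `NULL` to draw `n_points`
#'   Halton points from `box` (default: the strong-inhibition box
#'   `10 <= wMG <= 20`, `4 <= wGM <= 8`, `5 <= wGc <= 10`).
#' @param regime input-noise regime.
#' @param box bounds list as in [default_search_box()].
#' @param n_points number of points when `points` is `NULL`.
#' @param backend `"simulation"` or `"reduction"`.
#' @param n_realizations ensemble size per state (simulation backend).
#' @param seed integer seed shared by all points (simulation backend).
#' @param scaling_pair optional pair applied through [window_scale()]
#'   (reduction backend).
#' @param net_args,orn_args extra constructor arguments.
#' @param ... passed to [solve_moments()] (reduction backend).
#' @return data.frame with couplings, spontaneous/evoked mitral rate,
#'   variance, covariance, and logicals `decreased_variability` and
#'   `mean_not_increased`. Points where the backend fails are dropped with a
#'   warning.
#' @export
decreased_variability_scan <- function(points = NULL, regime = "small_fixed",
                                       box = list(lower = c(wMG = 10, wGM = 4, wGc = 5),
                                                  upper = c(wMG = 20, wGM = 8, wGc = 10)),
                                       n_points = 50,
                                       backend = c("simulation", "reduction"),
                                       n_realizations = 200, seed = 1,
                                       scaling_pair = NULL,
                                       net_args = list(), orn_args = list(),
                                       ...) {
  backend <- match.arg(backend)
  if (is.null(points)) points <- halton_sample(box$lower, box$upper, n_points)
  points <- as.matrix(points)
  rows <- vector("list", nrow(points))
  n_failed <- 0L
  for (i in seq_len(nrow(points))) {
    net <- do.call(ob_network, c(list(wMG = points[i, 1], wGM = points[i, 2],
                                      wGc = points[i, 3]), net_args))
    orn <- do.call(ob_orn_input, c(list(net = net, regime = regime), orn_args))
    states <- orn_states(orn)
    mc <- cells_of_type(net, "MC")
    summarize_red <- function(state) {
      sol <- solve_moments(net, state$mu, state$sigma, ...)
      out <- if (is.null(scaling_pair)) {
        list(rate_var = sol$rate_var, rate_cov = sol$rate_cov)
      } else window_scale(sol, scaling_pair)
      c(rate = mean(sol$rates[mc]), var = mean(out$rate_var[mc]),
        cov = out$rate_cov[mc[1], mc[2]])
    }
    summarize_sim <- function(state) {
      orn_c <- orn_regime("small_fixed", mu_base = state$mu,
                          mu_evoked = state$mu, sigma_small = state$sigma,
                          sigma_large = state$sigma)
      ens <- simulate_ensemble(net, orn_c, t_span = c(0, 1600), dt = 1,
                               n_realizations = n_realizations, seed = seed,
                               T_window = 100)
      st <- ensemble_stats(ens)
      sel <- st$centers > 0.5          # past the relaxation transient
      p <- which(st$pairs[, 1] == mc[1] & st$pairs[, 2] == mc[2])
      c(rate = mean(st$psth[sel, mc]), var = mean(st$var[sel, mc]),
        cov = mean(st$cov[sel, p]))
    }
    summarize <- if (backend == "simulation") summarize_sim else summarize_red
    row <- tryCatch({
      sp <- summarize(states$spontaneous)
      ev <- summarize(states$evoked)
      data.frame(
        wMG = points[i, 1], wGM = points[i, 2], wGc = points[i, 3],
        rate_spont = sp[["rate"]], rate_evoked = ev[["rate"]],
        var_spont = sp[["var"]], var_evoked = ev[["var"]],
        cov_spont = sp[["cov"]], cov_evoked = ev[["cov"]])
    }, error = function(e) NULL)
    if (is.null(row)) n_failed <- n_failed + 1L else rows[[i]] <- row
  }
  if (n_failed > 0)
    warning(sprintf("%d of %d points failed and were dropped", n_failed,
                    nrow(points)))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no scan point could be evaluated", call. = FALSE)
  rownames(out) <- NULL
  out$mean_not_increased <- out$rate_evoked <= out$rate_spont
  out$decreased_variability <- !out$mean_not_increased &
    out$var_evoked < out$var_spont & out$cov_evoked < out$cov_spont
  out
}

#' Parameter-recovery experiment with model-generated targets
#'
#' Generates target statistics from the circuit at a known coupling triple,
#' appends that triple to a Halton sample of the search box, screens the
#' whole set with [screen_parameter_space()] and reports the rank of the
#' generating triple. Self-consistency check of the fitting pipeline: with an
#' identifiable truth the generating couplings should rank among the very
#' best of the screened set.
#'
#' @param truth named coupling triple (wMG, wGM, wGc), inside `box`.
#' @param regime input-noise regime used for both target and screen.
#' @param n_points number of Halton points screened alongside the truth.
#' @param seed integer master seed (target and screen seeds derive from it).
#' @param box search box.
#' @param n_target_realizations ensemble size for the target.
#' @param n_realizations,n_gate_realizations screening ensemble sizes, see
#'   [screen_parameter_space()].
#' @param t_span simulation interval (ms).
#' @param ... further arguments to [screen_parameter_space()].
#' @return list with `rank` (rank of the truth among `n_points + 1` records),
#'   `n_screened`, `screen`, `target`.
#' @export
recovery_experiment <- function(truth = c(wMG = 6, wGM = 3.5, wGc = 3),
                                regime = "small_fixed", n_points = 1000,
                                seed = 1, box = default_search_box(),
                                n_target_realizations = 3000,
                                n_realizations = 2500,
                                n_gate_realizations = 80,
                                t_span = c(-1000, 1000), ...) {
  tgt <- generate_targets(truth[[1]], truth[[2]], truth[[3]], regime = regime,
                          n_realizations = n_target_realizations,
                          t_span = t_span, seed = seed * 1009 + 11)
  pts <- rbind(halton_sample(box$lower, box$upper, n_points),
               truth = c(truth[[1]], truth[[2]], truth[[3]]))
  scr <- screen_parameter_space(points = pts, target = tgt, regime = regime,
                                n_realizations = n_realizations,
                                n_gate_realizations = n_gate_realizations,
                                t_span = t_span, seed = seed * 1009 + 211,
                                ...)
  list(rank = scr$rank[n_points + 1], n_screened = nrow(pts),
       screen = scr, target = tgt)
}
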