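#' @useDynLib obvar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    # physicists' rule (weight exp(-x^2)); rescale so it integrates against
    # the standard normal density: E[f(Y)] = sum(w * f(sqrt(2) x)) / sqrt(pi)
    .gh_cache[[key]] <- list(y = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .gh_cache[[key]]
}

gauss_e <- function(f, n_nodes) {
  gh <- gh_rule(n_nodes)
  sum(gh$w * f(gh$y))
}

# E[f(Y1, Y2)] for standard bivariate normals with correlation rho
gauss_e2 <- function(f, rho, n_nodes) {
  gh <- gh_rule(n_nodes)
  y1 <- rep(gh$y, times = n_nodes)
  y2 <- rho * y1 + sqrt(1 - rho^2) * rep(gh$y, each = n_nodes)
  w <- rep(gh$w, times = n_nodes) * rep(gh$w, each = n_nodes)
  sum(w * f(y1, y2))
}

#' Gaussian moments of gate-transfer maps
#'
#' Evaluates the one- and two-cell Gaussian integrals entering the
#' steady-state moment equations, by Gauss-Hermite quadrature (tensor-product
#' in the bivariate cases). With `H` the gate-transfer map of a cell and
#' `Y, Y1, Y2` standard (bivariate) normals with correlation `rho`:
#' \describe{
#'   \item{E1}{`E[H_j(sigma_j Y + mu_j)]`}
#'   \item{E2}{`E[H_j(...)^2]`}
#'   \item{V}{`E2 - E1^2`}
#'   \item{NF}{`E[H_k(sigma_k Y1 + mu_k) * Y2^2]` for distinct cells (note the
#'     argument-order asymmetry: the map of the second cell appears, the
#'     squared variable belongs to the first); for `same_cell = TRUE` the
#'     univariate `E[H_j(sigma_j Y + mu_j) * Y^2]`}
#'   \item{NFC}{the centered noise-function moment `NF - E1`, i.e.
#'     `E[H_k(sigma_k Y1 + mu_k) * (Y2^2 - 1)]`; zero for independent
#'     variables}
#'   \item{NF1}{the first-power noise-function moment
#'     `E[H_k(sigma_k Y1 + mu_k) * Y2]` (`= rho sigma_k E[H_k']` by Stein's
#'     lemma); for `same_cell = TRUE` the univariate `E[H_j(...) * Y]`. Scaled
#'     by `sqrt(tau_j / 2)`, this is the noise-function term entering the
#'     moment equations of [solve_moments()]}
#'   \item{S}{`E[H_j(sigma_j Y1 + mu_j) * H_k(sigma_k Y2 + mu_k)]`; for
#'     `same_cell = TRUE` both maps share the same variable}
#'   \item{CV}{`S - E1(j) E1(k)`}
#' }
#' Whenever the two indices coincide the bivariate density is replaced by the
#' standard normal (`same_cell = TRUE`).
#'
#' @param kind one of `"E1"`, `"E2"`, `"V"`, `"NF"`, `"NFC"`, `"NF1"`,
#'   `"S"`, `"CV"`.
#' @param H_j,H_k vectorized functions (gate-transfer maps).
#' @param mu_j,mu_k,sigma_j,sigma_k effective means and standard deviations of
#'   the cells' activity variables; `sigma >= 0`.
#' @param rho correlation of the bivariate density, `|rho| <= 1`.
#' @param same_cell logical: apply the coincident-index rule.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @param check if `TRUE`, re-evaluate with doubled nodes and warn when the
#'   result moves by more than `1e-6`.
#' @return scalar moment value.
#' @export
gauss_moment <- function(kind = c("E1", "E2", "V", "NF", "NFC", "NF1", "S",
                                  "CV"),
                         H_j, H_k = H_j, mu_j = 0, sigma_j = 1,
                         mu_k = mu_j, sigma_k = sigma_j, rho = 0,
                         same_cell = FALSE, n_nodes = 40, check = FALSE) {
  kind <- match.arg(kind)
  if (sigma_j < 0 || sigma_k < 0) stop("sigma must be >= 0", call. = FALSE)
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  eval_at <- function(nn) {
    switch(kind,
      E1 = gauss_e(function(y) H_j(sigma_j * y + mu_j), nn),
      E2 = gauss_e(function(y) H_j(sigma_j * y + mu_j)^2, nn),
      V = gauss_e(function(y) H_j(sigma_j * y + mu_j)^2, nn) -
        gauss_e(function(y) H_j(sigma_j * y + mu_j), nn)^2,
      NF = if (same_cell)
        gauss_e(function(y) H_j(sigma_j * y + mu_j) * y^2, nn)
      else
        gauss_e2(function(y1, y2) H_k(sigma_k * y1 + mu_k) * y2^2, rho, nn),
      NFC = if (same_cell)
        gauss_e(function(y) H_j(sigma_j * y + mu_j) * (y^2 - 1), nn)
      else
        gauss_e2(function(y1, y2) H_k(sigma_k * y1 + mu_k) * (y2^2 - 1),
                 rho, nn),
      NF1 = if (same_cell)
        gauss_e(function(y) H_j(sigma_j * y + mu_j) * y, nn)
      else
        gauss_e2(function(y1, y2) H_k(sigma_k * y1 + mu_k) * y2, rho, nn),
      S = if (same_cell)
        gauss_e(function(y) H_j(sigma_j * y + mu_j) * H_k(sigma_k * y + mu_k),
                nn)
      else
        gauss_e2(function(y1, y2)
          H_j(sigma_j * y1 + mu_j) * H_k(sigma_k * y2 + mu_k), rho, nn),
      CV = {
        sv <- gauss_moment("S", H_j, H_k, mu_j, sigma_j, mu_k, sigma_k, rho,
                           same_cell, nn)
        e1j <- gauss_e(function(y) H_j(sigma_j * y + mu_j), nn)
        e1k <- gauss_e(function(y) H_k(sigma_k * y + mu_k), nn)
        sv - e1j * e1k
      })
  }
  out <- eval_at(n_nodes)
  if (check) {
    out2 <- eval_at(2 * n_nodes)
    if (abs(out2 - out) > 1e-6)
      warning(sprintf(
        "quadrature not converged for %s: doubling nodes moved result by %.3g",
        kind, abs(out2 - out)))
  }
  out
}

default_H <- function(net) {
  lapply(seq_len(net$n), function(k) gate_transfer_map(net, k))
}

#' Solve the shifted operating point
#'
#' Finds the deterministic fixed point `mu1_j = mu_j + sum_k w_jk H_k(mu1_k)`
#' (with `H_k` the composite gate-transfer map) by damped fixed-point
#' iteration. The moment equations are then written about this operating
#' point, where the network coupling is effectively weak.
#'
#' @param net a [rate_network()].
#' @param mu per-cell input means.
#' @param H optional list of gate-transfer maps overriding the network's own
#'   (mainly for analytically tractable test maps).
#' @param tol absolute convergence tolerance on the iterate.
#' @param damping damping factor in `(0, 1]`.
#' @param max_iter iteration cap.
#' @return An object of class `"ob_operating_point"`: fields `mu1`,
#'   `mu_tilde` (`mu - mu1`), `iterations`, `residual`.
#' @export
solve_operating_point <- function(net, mu, H = NULL, tol = 1e-8,
                                  damping = 0.5, max_iter = 1e4) {
  stopifnot(inherits(net, "rate_network"), length(mu) == net$n)
  if (is.null(H)) H <- default_H(net)
  n <- net$n
  fixed_point <- function(m)
    mu + drop(net$W %*% vapply(seq_len(n), function(k) H[[k]](m[k]), 0))
  mu1 <- as.numeric(mu)
  for (it in seq_len(max_iter)) {
    rhs <- fixed_point(mu1)
    res <- max(abs(rhs - mu1))
    mu1 <- (1 - damping) * mu1 + damping * rhs
    if (res < tol)
      return(structure(list(mu1 = mu1, mu_tilde = as.numeric(mu) - mu1,
                            iterations = it, residual = res),
                       class = "ob_operating_point"))
  }
  # strongly coupled circuits can defeat damped iteration; fall back to a
  # damped Newton root search on F(m) = m - fixed_point(m)
  m <- as.numeric(mu)
  Fm <- m - fixed_point(m)
  h <- 1e-6
  for (it2 in seq_len(200)) {
    if (max(abs(Fm)) < tol)
      return(structure(list(mu1 = m, mu_tilde = as.numeric(mu) - m,
                            iterations = max_iter + it2,
                            residual = max(abs(Fm))),
                       class = "ob_operating_point"))
    J <- vapply(seq_len(n), function(k) {
      mp <- m; mp[k] <- mp[k] + h
      ((mp - fixed_point(mp)) - Fm) / h
    }, numeric(n))
    step <- tryCatch(solve(J, Fm), error = function(e) Fm)
    lambda <- 1
    repeat {
      m_new <- m - lambda * step
      F_new <- m_new - fixed_point(m_new)
      if (max(abs(F_new)) < max(abs(Fm)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    m <- m_new; Fm <- F_new
  }
  stop(sprintf("operating point did not converge: residual %.3g after %d iterations",
               max(abs(Fm)), max_iter + 200), call. = FALSE)
}

#' Self-consistent steady-state moments of the stochastic rate network
#'
#' Solves the coupled fixed-point equations for the effective means
#' `mu_tilde(j)`, variances `sigma2(j)` and pairwise covariances `Cov(j,k)` of
#' the activity variables, by damped iteration about the shifted operating
#' point (see [solve_operating_point()]); then shifts the means back and maps
#' to firing rates and rate covariances through the transfer functions under a
#' Gaussian closure. The update equations per iteration are
#' `mu_tilde(j) = mu_tilde_j + sum_k w_jk E1(k)`,
#' `sigma2(j) tau_j = sigma_j^2/2 + sigma_j sum_k w_jk NF(j,k)
#'   + 1/2 sum_k w_jk^2 V(k) + sum_{k != l} w_jk w_jl CV(k,l)`, and
#' `Cov(j,k) (tau_j+tau_k)/2 = 1/2 c_jk sigma_j sigma_k
#'   + 1/2 sigma_j sum_l w_kl NF(j,l) + 1/2 sigma_k sum_l w_jl NF(k,l)
#'   + 1/2 sum_{l1,l2} w_j,l1 w_k,l2 CV(l1,l2)`,
#' with the Gaussian moments of [gauss_moment()] evaluated about the operating
#' point and the bivariate correlation taken as `Cov(j,k)/(sigma(j) sigma(k))`
#' (clipped to +/-0.999). The noise-function term `NF(j,k)` is taken as
#' `sqrt(tau_j/2) * rho_jk * E[H_k(sigma(k) Y + mu_tilde(k)) Y]` (the
#' first-power Gaussian moment, `NF1` of [gauss_moment()], scaled by
#' `sqrt(tau_j/2)`): this is the unique choice for which the moment equations
#' reproduce the exact stationary covariance of the linearized coupled
#' Ornstein-Uhlenbeck system at first order in the couplings, and it matches
#' Monte-Carlo ensembles where the raw second-power reading does not (see the
#' methods vignette).
#'
#' @param net a [rate_network()].
#' @param mu,sigma per-cell input means and noise amplitudes.
#' @param c input correlation matrix, defaults to the network's.
#' @param H optional list of gate-transfer maps overriding the network's own.
#' @param n_nodes Gauss-Hermite nodes per dimension.
#' @param tol absolute tolerance on the fixed-point residual.
#' @param damping damping factor in `(0, 1]`.
#' @param max_iter iteration cap.
#' @return An object of class `"ob_steady"`: `mu1`, `mu_tilde`, `mu`
#'   (unshifted means), `sigma2`, `cov` (activity covariance matrix with
#'   `sigma2` on the diagonal), `rho`, `rates`, `rate_var`, `rate_cov`
#'   (rate covariance matrix), `iterations`, `residual`.
#' @export
solve_moments <- function(net, mu, sigma, c = net$input_correlation, H = NULL,
                          n_nodes = 40, tol = 1e-8, damping = 0.5,
                          max_iter = 2000) {
  stopifnot(inherits(net, "rate_network"), length(mu) == net$n,
            length(sigma) == net$n)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  n <- net$n; W <- net$W; tau <- net$tau
  if (is.null(H)) H <- default_H(net)
  op <- solve_operating_point(net, mu, H = H, tol = tol, damping = damping,
                              max_iter = max_iter)
  # gate-transfer maps about the operating point
  Hs <- lapply(seq_len(n), function(k) {
    shift <- op$mu1[k]; Hk <- H[[k]]
    function(u) Hk(u + shift)
  })
  mu_t_in <- op$mu_tilde
  mu_t <- rep(0, n)
  s2 <- sigma^2 / (2 * tau)
  Cov <- outer(sigma, sigma) * c / outer(tau, tau, `+`)
  diag(Cov) <- s2
  clipped <- FALSE
  for (it in seq_len(max_iter)) {
    sd_ <- sqrt(pmax(s2, 0))
    rho <- Cov / outer(sd_, sd_)
    rho[!is.finite(rho)] <- 0
    rho <- pmin(pmax(rho, -0.999), 0.999)
    E1 <- vapply(seq_len(n), function(k)
      gauss_e(function(y) Hs[[k]](sd_[k] * y + mu_t[k]), n_nodes), 0)
    Vv <- vapply(seq_len(n), function(k)
      gauss_e(function(y) Hs[[k]](sd_[k] * y + mu_t[k])^2, n_nodes), 0) - E1^2
    # noise-function column: first-power moment rho * sigma(k) * E[H_k'],
    # identical for every j up to the correlation factor
    nf1 <- vapply(seq_len(n), function(k)
      gauss_e(function(y) Hs[[k]](sd_[k] * y + mu_t[k]) * y, n_nodes), 0)
    rho_nf <- rho; diag(rho_nf) <- 1
    # tau-scaled noise-function term: sqrt(tau_j / 2) matches the linearized
    # (Lyapunov) covariance of the coupled OU system exactly at first order
    NF <- sqrt(tau / 2) * rho_nf * matrix(nf1, n, n, byrow = TRUE)
    CVm <- diag(Vv, n)
    if (n > 1) {
      for (k in seq_len(n - 1)) for (l in (k + 1):n) {
        sv <- gauss_e2(function(y1, y2)
          Hs[[k]](sd_[k] * y1 + mu_t[k]) * Hs[[l]](sd_[l] * y2 + mu_t[l]),
          rho[k, l], n_nodes)
        CVm[k, l] <- CVm[l, k] <- sv - E1[k] * E1[l]
      }
    }
    mu_t_new <- mu_t_in + drop(W %*% E1)
    quad <- W %*% CVm %*% t(W)          # sum_{k,l} w_jk w_jl CV(k,l) on diag
    s2_new <- (sigma^2 / 2 + sigma * rowSums(W * NF) +
                 diag(quad) - 0.5 * drop(W^2 %*% Vv)) / tau
    if (any(s2_new < 0)) { clipped <- TRUE; s2_new <- pmax(s2_new, 0) }
    Cov_new <- Cov
    if (n > 1) {
      for (j in seq_len(n - 1)) for (k in (j + 1):n) {
        val <- (0.5 * c[j, k] * sigma[j] * sigma[k] +
                  0.5 * sigma[j] * sum(W[k, ] * NF[j, ]) +
                  0.5 * sigma[k] * sum(W[j, ] * NF[k, ]) +
                  0.5 * quad[j, k]) / ((tau[j] + tau[k]) / 2)
        Cov_new[j, k] <- Cov_new[k, j] <- val
      }
    }
    diag(Cov_new) <- s2_new
    res <- max(abs(mu_t_new - mu_t), abs(s2_new - s2),
               abs(Cov_new - Cov))
    mu_t <- (1 - damping) * mu_t + damping * mu_t_new
    s2 <- pmax((1 - damping) * s2 + damping * s2_new, 0)
    Cov <- (1 - damping) * Cov + damping * Cov_new
    diag(Cov) <- s2
    if (res < tol) break
  }
  if (res >= tol) {
    # oscillatory fixed-point maps (strong inhibition) need heavier damping
    if (damping > 0.05)
      return(solve_moments(net, mu, sigma, c = c, H = H, n_nodes = n_nodes,
                           tol = tol, damping = damping / 4,
                           max_iter = 4 * max_iter))
    stop(sprintf("moment equations did not converge: residual %.3g after %d iterations",
                 res, max_iter), call. = FALSE)
  }
  if (clipped)
    warning("negative variance iterate clipped at 0")
  mu_out <- mu_t + op$mu1
  sd_ <- sqrt(pmax(s2, 0))
  rho <- Cov / outer(sd_, sd_)
  rho[!is.finite(rho)] <- 0
  rho <- pmin(pmax(rho, -0.999), 0.999)
  Fj <- lapply(net$transfer, function(tf) function(x) eval_transfer(tf, x))
  rates <- vapply(seq_len(n), function(j)
    gauss_e(function(y) Fj[[j]](sd_[j] * y + mu_out[j]), n_nodes), 0)
  rate_cov <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rate_cov[j, j] <- gauss_e(function(y)
      Fj[[j]](sd_[j] * y + mu_out[j])^2, n_nodes) - rates[j]^2
    if (j < n) for (k in (j + 1):n) {
      sv <- gauss_e2(function(y1, y2)
        Fj[[j]](sd_[j] * y1 + mu_out[j]) * Fj[[k]](sd_[k] * y2 + mu_out[k]),
        rho[j, k], n_nodes)
      rate_cov[j, k] <- rate_cov[k, j] <- sv - rates[j] * rates[k]
    }
  }
  structure(list(mu1 = op$mu1, mu_tilde = mu_t, mu = mu_out, sigma2 = s2,
                 cov = Cov, rho = rho, rates = rates,
                 rate_var = diag(rate_cov), rate_cov = rate_cov,
                 iterations = it, residual = res), class = "ob_steady")
}

#' @export
print.ob_steady <- function(x, ...) {
  cat(sprintf("<ob_steady> %d cells, converged in %d iterations (residual %.2g)\n",
              length(x$rates), x$iterations, x$residual))
  cat("rates (spikes/s):", paste(sprintf("%.3g", x$rates), collapse = " "), "\n")
  invisible(x)
}

#' Window-to-instantaneous scaling-factor pairs
#'
#' The steady-state reduction yields instantaneous rate variances and
#' covariances, while data statistics live in length-`T` counting windows. The
#' relationship is modeled by a per-cell (or per-pair) scaling factor pair:
#' `variance_ratio = Var(R_T) / (T^2 Var(r))` and
#' `covariance_ratio = Cov(R_T_j, R_T_k) / (T^2 Cov(r_j, r_k))`, sampled
#' across cells, windows and simulations, with each covariance ratio paired
#' with the variance ratio of the pair's first cell (the two are correlated).
#'
#' @param sims list of [simulate_ensemble()] results (with counts).
#' @param n number of pairs to sample; if more than available, sampling is
#'   with replacement and the result carries attribute `replace = TRUE`.
#' @param seed integer seed, or `NULL`.
#' @return data.frame with columns `variance_ratio`, `covariance_ratio`,
#'   `sim`, `window`, `cell_j`, `cell_k`.
#' @export
sample_scaling_pairs <- function(sims, n = 500, seed = NULL) {
  if (inherits(sims, "ob_ensemble")) sims <- list(sims)
  rows <- list()
  for (si in seq_along(sims)) {
    ens <- sims[[si]]
    st <- ensemble_stats(ens)
    inst <- instantaneous_stats(ens)
    idx <- vapply(st$centers, function(tc) which.min(abs(inst$time - tc)), 0L)
    T_s <- st$T_window
    for (p in seq_len(nrow(st$pairs))) {
      j <- st$pairs[p, 1]; k <- st$pairs[p, 2]
      vi <- inst$var[idx, j]; ci <- inst$cov[idx, p]
      vr <- st$var[, j] / (T_s^2 * vi)
      cr <- st$cov[, p] / (T_s^2 * ci)
      keep <- which(is.finite(vr) & is.finite(cr) & vi > 0 & ci != 0)
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          variance_ratio = unname(vr[keep]),
          covariance_ratio = unname(cr[keep]),
          sim = si, window = keep, cell_j = j, cell_k = k)
    }
  }
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0)
    stop("no usable scaling pairs (zero instantaneous variance everywhere)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  replace <- n > nrow(all)
  out <- all[sample.int(nrow(all), n, replace = replace), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replace") <- replace
  out
}

#' Apply a scaling-factor pair to a steady-state solution
#'
#' Multiplies the instantaneous rate variances by `variance_ratio` and the
#' rate covariances by `covariance_ratio`, modeling length-`T` window
#' statistics. The scaled covariance is not guaranteed to satisfy the
#' Cauchy-Schwarz bound of the scaled variances; violations are flagged in the
#' returned `cs_violation` matrix.
#'
#' @param sol an [solve_moments()] result.
#' @param pair list or one-row data.frame with `variance_ratio` and
#'   `covariance_ratio`, both `> 0`.
#' @return list with `rate_var`, `rate_cov` (matrix, scaled off-diagonal,
#'   scaled variances on the diagonal) and logical `cs_violation`.
#' @export
window_scale <- function(sol, pair) {
  stopifnot(inherits(sol, "ob_steady"))
  vr <- pair$variance_ratio; cr <- pair$covariance_ratio
  if (!is.finite(vr) || !is.finite(cr) || vr <= 0 || cr <= 0)
    stop("scaling ratios must be positive", call. = FALSE)
  v <- sol$rate_var * vr
  cv <- sol$rate_cov * cr
  diag(cv) <- v
  viol <- abs(cv) > sqrt(outer(v, v)) + 1e-12
  diag(viol) <- FALSE
  list(rate_var = v, rate_cov = cv, cs_violation = viol)
}

#' Resample coupling triples about the best fits
#'
#' Given the best `k` coupling triples, draws `n_extra` further triples from a
#' multivariate normal with the same mean and a shrunk covariance:
#' `mu + shrink * L Z` with `L` the (lower) Cholesky factor of the sample
#' covariance of the inputs and `Z` standard normal, so the draws have
#' covariance `shrink^2` times the input covariance. The originals are
#' returned first, followed by the draws; negative draws are clipped at 0 with
#' a warning.
#'
#' @param best matrix or data.frame of coupling triples (columns wMG, wGM,
#'   wGc), at least 2 rows.
#' @param n_extra number of new draws (990 gives 1000 sets with the default
#'   10 best).
#' @param shrink scale applied to the Cholesky factor.
#' @param seed integer seed, or `NULL`.
#' @return matrix with `nrow(best) + n_extra` rows and the input columns.
#' @export
resample_couplings <- function(best, n_extra = 990, shrink = 0.7,
                               seed = NULL) {
  best <- as.matrix(best)
  if (nrow(best) < 2)
    stop("need at least 2 coupling samples to resample", call. = FALSE)
  mu <- colMeans(best)
  Cw <- stats::cov(best)
  L <- chol_psd(Cw)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(ncol(best) * n_extra), ncol(best), n_extra)
  draws <- t(mu + shrink * L %*% Z)
  if (any(draws < 0)) {
    warning(sprintf("%d negative coupling draws clipped at 0",
                    sum(draws < 0)))
    draws[draws < 0] <- 0
  }
  out <- rbind(best, draws)
  colnames(out) <- colnames(best)
  rownames(out) <- NULL
  out
}
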