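# Frozen expected values for the Gaussian moments come from closed forms of
# normal moments (E[Y^2] = 1, E[Y^4] = 3) verified by large-sample Monte
# Carlo during development.

test_that("gaussian moments reproduce closed forms", {
  idf <- function(x) x
  sqf <- function(x) x^2
  expect_equal(gauss_moment("E1", idf, mu_j = 2, sigma_j = 1), 2,
               tolerance = 1e-10)
  expect_equal(gauss_moment("V", idf, mu_j = 2, sigma_j = 1), 1,
               tolerance = 1e-10)
  expect_equal(gauss_moment("E1", sqf), 1, tolerance = 1e-10)
  expect_equal(gauss_moment("E2", sqf), 3, tolerance = 1e-10)
  expect_equal(gauss_moment("V", sqf), 2, tolerance = 1e-10)
  # printed noise-function form: identity map, distinct cells -> mu_k for any
  # correlation (E[Y1 Y2^2] = 0); centered form -> 0; first-power form ->
  # rho * sigma_k (Stein's lemma with H' = 1)
  for (rho in c(-0.6, 0, 0.3)) {
    expect_equal(gauss_moment("NF", idf, idf, mu_j = 0, sigma_j = 1,
                              mu_k = 1.5, sigma_k = 2, rho = rho), 1.5,
                 tolerance = 1e-9)
    expect_equal(gauss_moment("NFC", idf, idf, mu_j = 0, sigma_j = 1,
                              mu_k = 1.5, sigma_k = 2, rho = rho), 0,
                 tolerance = 1e-9)
    expect_equal(gauss_moment("NF1", idf, idf, mu_j = 0, sigma_j = 1,
                              mu_k = 1.5, sigma_k = 2, rho = rho), rho * 2,
                 tolerance = 1e-9)
  }
  # S for identity maps is the plain second cross-moment
  expect_equal(gauss_moment("S", idf, idf, mu_j = 1, sigma_j = 2, mu_k = 3,
                            sigma_k = 1, rho = 0.4), 0.4 * 2 * 1 + 1 * 3,
               tolerance = 1e-9)
  expect_equal(gauss_moment("CV", idf, idf, mu_j = 1, sigma_j = 2, mu_k = 3,
                            sigma_k = 1, rho = 0.4), 0.8, tolerance = 1e-9)
  expect_error(gauss_moment("E1", idf, sigma_j = -1), "sigma")
})

test_that("quadrature is converged at the default node count", {
  kinds <- c("E1", "E2", "V", "NF", "NFC", "NF1", "S", "CV")
  # smooth gate-like map: spectral convergence, 1e-8 at 40 nodes
  Hsm <- function(x) 1 / (1 + exp(-(x - 5)))
  for (kind in kinds) {
    a <- gauss_moment(kind, Hsm, Hsm, mu_j = 6, sigma_j = 0.5, mu_k = 5,
                      sigma_k = 0.4, rho = 0.3, n_nodes = 40)
    b <- gauss_moment(kind, Hsm, Hsm, mu_j = 6, sigma_j = 0.5, mu_k = 5,
                      sigma_k = 0.4, rho = 0.3, n_nodes = 80)
    expect_lt(abs(a - b), 1e-8)
  }
  expect_no_warning(gauss_moment("E1", Hsm, mu_j = 6, sigma_j = 0.5,
                                 check = TRUE))
  # tabulated (piecewise-linear) maps have kinks, so convergence is
  # polynomial rather than spectral: documented 2e-4 accuracy at 40 nodes
  H <- gate_transfer_map(ob_network(6, 3, 1.5), 1)
  for (kind in kinds) {
    a <- gauss_moment(kind, H, H, mu_j = 6, sigma_j = 0.5, mu_k = 5,
                      sigma_k = 0.4, rho = 0.3, n_nodes = 40)
    b <- gauss_moment(kind, H, H, mu_j = 6, sigma_j = 0.5, mu_k = 5,
                      sigma_k = 0.4, rho = 0.3, n_nodes = 80)
    expect_lt(abs(a - b), 2e-4)
  }
})

test_that("operating point solves the deterministic fixed point", {
  tf <- identity_transfer()
  # all couplings zero: the fixed point is the input mean itself
  net0 <- ou_network(c(20, 30))
  op0 <- solve_operating_point(net0, c(4, 7))
  expect_equal(op0$mu1, c(4, 7), tolerance = 1e-8)
  expect_equal(op0$mu_tilde, c(0, 0), tolerance = 1e-8)
  # single cell with identity gate map and w = 0.5: mu1 = mu / (1 - w) = 2
  net1 <- rate_network(5, matrix(0.5, 1, 1), list(tf), list(list()))
  op1 <- solve_operating_point(net1, 1, H = list(function(x) x))
  expect_equal(op1$mu1, 2, tolerance = 1e-7)
  # symmetric two-cell network: identical shifts
  W <- matrix(c(0, 0.4, 0.4, 0), 2)
  net2 <- rate_network(c(10, 10), W, rep(list(tf), 2),
                       rep(list(list(synapse_kinetics("AMPA"))), 2))
  op2 <- solve_operating_point(net2, c(3, 3))
  expect_equal(op2$mu1[1], op2$mu1[2], tolerance = 1e-8)
  # a map with no fixed point (identity gate, w = 1) fails with the residual
  netd <- rate_network(5, matrix(1, 1, 1), list(tf), list(list()))
  expect_error(solve_operating_point(netd, 1, H = list(function(x) x),
                                     max_iter = 50), "did not converge")
})

test_that("uncoupled moment solution equals the OU closed forms", {
  tau <- c(20, 30, 40); sig <- c(2, 3, 2.5)
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.2; C[1, 3] <- C[3, 1] <- 0.1
  net <- ou_network(tau, C)
  sol <- solve_moments(net, mu = c(5, 6, 7), sigma = sig)
  expect_equal(sol$sigma2, sig^2 / (2 * tau), tolerance = 1e-8)
  cov_expect <- outer(sig, sig) * C / outer(tau, tau, `+`)
  diag(cov_expect) <- sig^2 / (2 * tau)
  expect_equal(sol$cov, cov_expect, tolerance = 1e-8)
  # shift consistency: mu(j) = mu_tilde(j) + mu1_j recovers the input means
  expect_equal(sol$mu, c(5, 6, 7), tolerance = 1e-8)
  # identity transfer far from the clamp: rates equal the activity means
  expect_equal(sol$rates, c(5, 6, 7), tolerance = 1e-6)
})

test_that("moment solution matches ensemble statistics when weakly coupled", {
  net <- toy_circuit(0.25)
  mu <- c(5, 2, 2); sig <- c(2.5, 2.5, 2.5)
  sol <- solve_moments(net, mu, sig)
  orn <- constant_input(mu, sig)
  # dt = 0.25 ms keeps the integrator discretization bias well below the
  # Monte-Carlo bands
  bm <- blocked_moments(net, orn, t_span = c(0, 2500), dt = 0.25,
                        n_real = 2400, seed = 11, burn_s = 1.2, n_blocks = 16)
  # rates are computed from the rate trajectories, so compare rate moments
  expect_true(all(abs(sol$rates - bm$mean) < 3 * bm$mean_se))
  expect_true(all(abs(sol$rate_var - bm$var) < 3 * bm$var_se))
  rc <- sol$rate_cov[cbind(c(1, 1, 2), c(2, 3, 3))]
  expect_true(all(abs(rc - bm$cov) < 3 * bm$cov_se))
})

test_that("shifted operating point remains accurate at moderate coupling", {
  net <- toy_circuit(1)
  mu <- c(5, 2, 2); sig <- c(2.5, 2.5, 2.5)
  sol <- solve_moments(net, mu, sig)
  orn <- constant_input(mu, sig)
  bm <- blocked_moments(net, orn, t_span = c(0, 2500), dt = 0.5,
                        n_real = 1600, seed = 13, burn_s = 1.2)
  # at w = 1 the closure is approximate: systematic (not Monte-Carlo)
  # deviations of a few percent on rates and O(10%) on variances
  expect_true(all(abs(sol$rates - bm$mean) / bm$mean < 0.1))
  expect_true(all(abs(sol$rate_var - bm$var) / bm$var < 0.2))
})
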