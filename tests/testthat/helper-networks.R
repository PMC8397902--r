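# Small networks and inputs reused across tests.

identity_transfer <- function(top = 100) {
  transfer_function(seq(0, top, length.out = 201),
                    seq(0, top, length.out = 201), "identity")
}

# n uncoupled linear cells: an Ornstein-Uhlenbeck benchmark with known
# stationary mean, variance and cross-correlation.
ou_network <- function(tau, corr = diag(length(tau))) {
  n <- length(tau)
  rate_network(tau = tau, W = matrix(0, n, n),
               transfer = rep(list(identity_transfer()), n),
               kinetics = rep(list(list()), n),
               input_correlation = corr)
}

constant_input <- function(mu, sigma) {
  orn_regime("small_fixed", mu_base = mu, mu_evoked = mu,
             sigma_small = sigma, sigma_large = sigma)
}

# 3-cell toy circuit (MC-like excitor, two inhibitors) with coupling scale w;
# weakly coupled for w well below 1.
toy_circuit <- function(w) {
  tfs <- list(default_transfer("MC"), default_transfer("PGC"),
              default_transfer("GC"))
  kins <- list(list(synapse_kinetics("AMPA"), synapse_kinetics("NMDA")),
               list(synapse_kinetics("GABA_A")),
               list(synapse_kinetics("GABA_A")))
  W <- matrix(0, 3, 3); W[2, 1] <- w; W[3, 1] <- w; W[1, 3] <- -w
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.1
  rate_network(c(20, 30, 40), W, tfs, kins, C, c("MC", "PGC", "GC"))
}

# Across-realization standard errors of time-averaged instantaneous moments,
# estimated by splitting the ensemble into independent realization blocks.
blocked_moments <- function(net, orn, t_span, dt, n_real, seed, n_blocks = 8,
                            burn_s = 1) {
  per_block <- n_real / n_blocks
  stopifnot(per_block == round(per_block))
  ms <- vs <- cs <- NULL
  for (b in seq_len(n_blocks)) {
    ens <- simulate_ensemble(net, orn, t_span = t_span, dt = dt,
                             n_realizations = per_block,
                             seed = seed + 1000 * b, T_window = NULL)
    inst <- instantaneous_stats(ens)
    sel <- inst$time > burn_s
    ms <- rbind(ms, colMeans(inst$mean[sel, , drop = FALSE]))
    vs <- rbind(vs, colMeans(inst$var[sel, , drop = FALSE]))
    cs <- rbind(cs, colMeans(inst$cov[sel, , drop = FALSE]))
  }
  list(mean = colMeans(ms), mean_se = apply(ms, 2, stats::sd) / sqrt(n_blocks),
       var = colMeans(vs), var_se = apply(vs, 2, stats::sd) / sqrt(n_blocks),
       cov = colMeans(cs), cov_se = apply(cs, 2, stats::sd) / sqrt(n_blocks))
}
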