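test_that("the circuit has the documented architecture", {
  net <- ob_network(wMG = 6, wGM = 3, wGc = 1.5, wMP = 1, wPM = 1)
  expect_equal(net$cell_type, c("MC", "PGC", "MC", "PGC", "GC", "GC", "GC"))
  W <- net$W
  # inhibition onto MCs is negative, excitation onto interneurons positive
  expect_equal(W[1, 5], -6); expect_equal(W[3, 6], -6)   # independent GC
  expect_equal(W[1, 7], -1.5); expect_equal(W[3, 7], -1.5) # shared GC
  expect_equal(W[1, 2], -1); expect_equal(W[3, 4], -1)   # own PGC
  expect_equal(W[5, 1], 3); expect_equal(W[6, 3], 3)     # MC -> own GC
  expect_equal(W[7, 1], 3); expect_equal(W[7, 3], 3)     # MC -> shared GC
  expect_equal(W[2, 1], 1); expect_equal(W[4, 3], 1)     # MC -> own PGC
  # glomerular symmetry: swapping the two glomeruli leaves W invariant
  perm <- c(3, 4, 1, 2, 6, 5, 7)
  expect_equal(W[perm, perm], unname(W))
  # no cross-glomerular PGC or direct MC-MC coupling
  expect_equal(W[1, 4], 0); expect_equal(W[1, 3], 0); expect_equal(W[2, 3], 0)
})

test_that("input correlation matrix has the documented structure", {
  C <- ob_input_correlation()
  expect_equal(diag(C), rep(1, 7))
  expect_equal(C, t(C))
  expect_equal(C[1, 2], 0.1)   # MC-PGC within glomerulus
  expect_equal(C[1, 3], 0.05)  # MC-MC
  expect_equal(C[5, 6], 0.05)  # GC-GC
  expect_equal(C[1, 5], 0)     # MC-GC uncorrelated
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("constructor rejects invalid configurations", {
  expect_error(ob_network(-1, 2, 1), ">= 0")
  expect_error(rate_network(c(-5, 10), matrix(0, 2, 2),
                            rep(list(identity_transfer()), 2),
                            rep(list(list()), 2)), "positive")
  bad <- diag(2); bad[1, 2] <- 0.5   # asymmetric
  expect_error(rate_network(c(5, 5), matrix(0, 2, 2),
                            rep(list(identity_transfer()), 2),
                            rep(list(list()), 2), bad), "symmetric")
  neg <- matrix(c(1, 2, 2, 1), 2)    # indefinite
  expect_error(rate_network(c(5, 5), matrix(0, 2, 2),
                            rep(list(identity_transfer()), 2),
                            rep(list(list()), 2), neg), "semidefinite")
})

test_that("composite gate maps reflect each cell's synapse types", {
  net <- ob_network(6, 3, 1.5)
  H_mc <- gate_transfer_map(net, 1)    # AMPA + NMDA: bounded by 2
  H_gc <- gate_transfer_map(net, 5)    # single GABA_A gate: bounded by 1
  x <- seq(-5, 30, by = 0.5)
  expect_true(all(H_mc(x) >= 0 & H_mc(x) < 2))
  expect_true(all(H_gc(x) >= 0 & H_gc(x) < 1))
  expect_true(all(diff(H_mc(x)) >= 0))
  # explicit composition at one point
  r <- eval_transfer(net$transfer[[1]], 8)
  rb <- max_rate(net$transfer[[1]])
  expect_equal(H_mc(8), gate_steady(r, rb, synapse_kinetics("AMPA")) +
                 gate_steady(r, rb, synapse_kinetics("NMDA")))
})

test_that("input regimes follow the three-regime specification", {
  net <- ob_network(6, 3, 1.5)
  gc <- cells_of_type(net, "GC")
  for (reg in c("small_fixed", "time_varying", "large_fixed")) {
    orn <- ob_orn_input(net, reg)
    ev <- orn_eval(orn, c(-1500, -1, 500, 1500))
    # sigma constant in fixed regimes; steps at onset otherwise
    if (reg == "small_fixed") {
      expect_true(all(ev$sigma == ev$sigma[1, 1]))
    } else if (reg == "time_varying") {
      expect_true(all(ev$sigma[3, -gc] > ev$sigma[1, -gc]))
      expect_equal(ev$sigma[3, gc], ev$sigma[1, gc])  # GC sigma never varies
    } else {
      expect_true(all(ev$sigma[, -gc] == ev$sigma[1, 1]))
    }
    # mean rises smoothly after onset toward the plateau, MC above PGC
    expect_true(all(ev$mu[1, ] == ev$mu[2, ]))
    expect_true(all(ev$mu[4, ] > ev$mu[1, ]))
    expect_gt(ev$mu[4, 1], ev$mu[4, 2])
  }
  # fixed regimes equal the spontaneous/evoked values of the time-varying one
  tv <- orn_eval(ob_orn_input(net, "time_varying"), c(-1, 1500))
  sf <- orn_eval(ob_orn_input(net, "small_fixed"), c(-1, 1500))
  lf <- orn_eval(ob_orn_input(net, "large_fixed"), c(-1, 1500))
  expect_equal(sf$sigma[1, ], tv$sigma[1, ])
  expect_equal(lf$sigma[2, ], tv$sigma[2, ])
})

test_that("evoked-noise interpolation is the stated linear family", {
  net <- ob_network(6, 3, 1.5)
  orn <- ob_orn_input(net, "large_fixed")
  expect_equal(orn_interp_sigma(orn, 1)$sigma_large, orn$sigma_large)
  o6 <- orn_interp_sigma(orn, 6)
  expect_equal(o6$sigma_large,
               0.5 * orn$sigma_small + 0.5 * orn$sigma_large)
  o10 <- orn_interp_sigma(orn, 10)
  expect_equal(o10$sigma_large,
               0.9 * orn$sigma_small + 0.1 * orn$sigma_large)
  expect_error(orn_interp_sigma(orn, 11))
})
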