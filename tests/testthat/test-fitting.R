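test_that("halton points match the radical-inverse closed form", {
  # oracle: digit-reversal radical inverse in bases 2, 3, 5
  pts <- halton_sample(c(0, 0, 0), c(1, 1, 1), 4)
  expect_equal(pts[1, ], c(1 / 2, 1 / 3, 1 / 5), ignore_attr = TRUE)
  expect_equal(pts[2, ], c(1 / 4, 2 / 3, 2 / 5), ignore_attr = TRUE)
  expect_equal(pts[3, ], c(3 / 4, 1 / 9, 3 / 5), ignore_attr = TRUE)
  # deterministic and affinely mapped into the box
  box <- default_search_box()
  a <- halton_sample(box$lower, box$upper, 50)
  b <- halton_sample(box$lower, box$upper, 50)
  expect_identical(a, b)
  expect_true(all(sweep(a, 2, box$lower, `>=`)) &&
                all(sweep(a, 2, box$upper, `<=`)))
  expect_error(halton_sample(c(0, 1), c(1, 1), 5), "lower < upper")
})

test_that("uncertainty weights decrease with data heterogeneity", {
  s <- c(1, 1, 1, 1)
  expect_equal(build_weights(s), rep(0.5, 4))   # s = <s> everywhere -> 1/2
  expect_equal(build_weights(rep(0, 4)), rep(1, 4))  # all-zero -> W == 1
  s2 <- c(1, 2, 1, 1)
  w2 <- build_weights(s2)
  expect_lt(w2[2], w2[1])                        # larger spread downweighted
  expect_true(all(diff(build_weights(sort(stats::runif(20)))) <= 0))
  expect_error(build_weights(c(-1, 1)), ">= 0")
})

test_that("the weighted error functional matches hand integration", {
  tt <- seq(-2, 2, by = 0.1)
  W <- rep(1, length(tt))
  dat <- rep(1, length(tt))
  expect_equal(statistic_error(dat, dat, tt, W), 0)
  # model 2, data 1 on [-2, 2]: numerator 4, ||data|| = 4, error 1
  expect_equal(statistic_error(rep(2, length(tt)), dat, tt, W), 1)
  # the printed norm is quadratic in W, so rescaling W does not cancel
  e1 <- statistic_error(rep(2, length(tt)), dat, tt, W)
  e2 <- statistic_error(rep(2, length(tt)), dat, tt, 2 * W)
  expect_equal(e2, e1 / 2)
  expect_error(statistic_error(dat, 0 * dat, tt, W), "zero data norm")
})

test_that("the tolerance gate is inclusive at the printed threshold", {
  expect_true(psth_tolerance(0))
  expect_true(psth_tolerance(1.4))
  expect_false(psth_tolerance(1.41))
})

test_that("best-fit selection ranks by total error with documented ties", {
  scr <- structure(
    data.frame(wMG = 1:4, wGM = 1, wGc = 1,
               error_psth_raw = 1, error_psth = c(2, 1, 1, 5),
               error_var = 0, error_cov = 0,
               error_total = c(3, 3, 3, 9),
               within_tolerance = TRUE, failed = FALSE, index = 1:4),
    class = c("ob_screen", "data.frame"))
  ok <- !scr$failed
  ord <- order(scr$error_total[ok], scr$error_psth[ok], scr$index[ok])
  scr$rank <- NA_integer_; scr$rank[which(ok)[ord]] <- seq_len(sum(ok))
  best <- select_best(scr, 2)
  # equal totals broken by psth error, then by sample index
  expect_equal(best$index, c(2, 3))
  expect_warning(all10 <- select_best(scr, 10), "only 4")
  expect_equal(nrow(all10), 4)
})

test_that("screening one point yields exactly one gated record", {
  tgt_time <- seq(-0.95, 0.95, by = 0.05)
  tgt <- data_target(tgt_time, psth = rep(5, length(tgt_time)),
                     var = rep(0.01, length(tgt_time)),
                     cov = rep(0.001, length(tgt_time)),
                     epoch = c(-1, 1))
  scr <- screen_parameter_space(points = matrix(c(6, 3, 1.5), 1), target = tgt,
                                n_realizations = 60, n_gate_realizations = 30,
                                t_span = c(-1000, 1000), seed = 2)
  expect_equal(nrow(scr), 1)
  expect_false(scr$failed)
  expect_true(is.finite(scr$error_total))
  expect_equal(scr$rank, 1)
})

test_that("strong-inhibition scan flags decreased variability coherently", {
  pts <- rbind(c(12, 5, 7), c(16, 6, 9), c(1, 3, 0.5))
  scan <- decreased_variability_scan(points = pts, n_realizations = 150,
                                     seed = 4)
  expect_equal(nrow(scan), 3)
  # flags follow their definitions
  dv <- scan$decreased_variability
  expect_true(all(scan$rate_evoked[dv] > scan$rate_spont[dv]))
  expect_true(all(scan$var_evoked[dv] < scan$var_spont[dv]))
  expect_true(all(scan$cov_evoked[dv] < scan$cov_spont[dv]))
  expect_true(all(xor(scan$mean_not_increased,
                      scan$rate_evoked > scan$rate_spont)))
  # the weak-inhibition point still shows an evoked rate increase
  expect_gt(scan$rate_evoked[3], scan$rate_spont[3])
})
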