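make_ts <- function(spikes, ...) trial_spikes(spikes, ...)

test_that("windowed trial counts follow the half-open convention", {
  # spikes at 0.01 and 0.06 s: both inside the window centered at 0.05
  ts <- make_ts(list(list(c(0.01, 0.06), numeric(0))), t_range = c(0, 0.4),
                spontaneous = c(0, 0), evoked = c(0, 0.4))
  wc <- windowed_trial_counts(ts, T_window = 0.1)
  w05 <- which(abs(wc$centers - 0.05) < 1e-9)
  expect_equal(wc$counts[w05, 1, 1], 2)
  # a spike exactly on a half-window boundary lands in one block only:
  # total across a non-overlapping tiling equals the raw spike count
  ts2 <- make_ts(list(list(c(0.05, 0.1, 0.15, 0.2), numeric(0))),
                 t_range = c(0, 0.4), spontaneous = c(0, 0),
                 evoked = c(0, 0.4))
  wc2 <- windowed_trial_counts(ts2, T_window = 0.1)
  odd <- seq(1, length(wc2$centers), by = 2)  # disjoint windows
  expect_equal(sum(wc2$counts[odd, 1, 1]), 4)
  # no spikes -> all zeros
  expect_true(all(wc$counts[, 1, 2] == 0))
})

test_that("across-trial statistics match hand computation", {
  # counts {1, 2, 3} across three trials: mean 2, variance 1 (n - 1 norm)
  sp <- list(
    list(c(0.05), c(0.04, 0.06), c(0.03, 0.05, 0.07)),     # 1, 2, 3 spikes
    list(c(0.05), c(0.04, 0.06), c(0.03, 0.05, 0.07)))     # identical cell
  ts <- make_ts(sp, t_range = c(0, 0.1), spontaneous = c(0, 0),
                evoked = c(0, 0.1))
  st <- trial_stats(windowed_trial_counts(ts, T_window = 0.1))
  w <- which(abs(st$centers - 0.05) < 1e-9)
  expect_equal(st$mean_count[w, 1], 2)
  expect_equal(st$var[w, 1], 1)
  expect_equal(st$psth[w, 1], 2 / 0.1)
  # identical cells: covariance equals variance (correlation 1)
  expect_equal(st$cov[w, 1], st$var[w, 1])
  expect_error(trial_stats(windowed_trial_counts(
    make_ts(list(list(c(0.01))), t_range = c(0, 0.1),
            spontaneous = c(0, 0), evoked = c(0, 0.1)), T_window = 0.1)),
    "single trial")
})

test_that("trial shuffling destroys across-trial covariance", {
  set.seed(42)
  ts <- generate_trains(n_cells = 2, n_trials = 200, rate_spont = 20,
                        rate_evoked = 20, gain_var_spont = 0.3,
                        gain_var_evoked = 0.3, seed = 42)
  st <- trial_stats(windowed_trial_counts(ts))
  mean_cov <- mean(st$cov)
  expect_gt(mean_cov, 0.1)   # shared gain induces covariance
  # shuffle cell 2's trials: covariance collapses to ~0
  shuf <- ts$spikes
  shuf[[2]] <- shuf[[2]][sample(length(shuf[[2]]))]
  ts2 <- trial_spikes(shuf, t_range = ts$t_range,
                      spontaneous = ts$spontaneous, evoked = ts$evoked,
                      T_window = ts$T_window)
  st2 <- trial_stats(windowed_trial_counts(ts2))
  expect_lt(abs(mean(st2$cov)), 3 * stats::sd(st2$cov) / sqrt(nrow(st2$cov)) +
              0.05 * mean_cov)
})

test_that("state averages split a step series at onset", {
  # regular trains: 10 spikes/s before onset, 30 spikes/s after
  train <- c(seq(-0.95, -0.05, by = 0.1), seq(0.02, 0.99, by = 1 / 30))
  sp <- lapply(1:2, function(i) lapply(1:3, function(tr) train))
  ts <- make_ts(sp, t_range = c(-1, 1), T_window = 0.2)
  st <- trial_stats(windowed_trial_counts(ts))
  sa <- state_average(st, c(-1, 0), c(0, 1))
  expect_gt(sa$cells$mean_evoked[1], sa$cells$mean_spont[1])
  # constant series: both states give the same constant
  cst <- structure(list(centers = seq(-0.9, 0.9, by = 0.1),
                        mean_count = matrix(2, 19, 1),
                        var = matrix(0.5, 19, 1), psth = matrix(20, 19, 1),
                        cov = matrix(0, 19, 0),
                        pairs = matrix(0L, 0, 2), T_window = 0.1,
                        n_trials = 3), class = "trial_stats")
  sa2 <- state_average(cst, c(-1, 0), c(0, 1))
  expect_equal(sa2$cells$mean_spont, sa2$cells$mean_evoked)
  expect_error(state_average(cst, c(-3, -2.5), c(0, 1)), "no window")
})

test_that("fraction increased uses strict inequality with ties excluded", {
  f <- fraction_increased(c(1, 2, 3), c(2, 1, 3))  # up, down, tie
  expect_equal(f$n_increased, 1)
  expect_equal(f$fraction, 1 / 3)
  expect_equal(fraction_increased(c(1, 1), c(2, 2))$fraction, 1)
})

test_that("origin-constrained regression matches its closed form", {
  # points (1,1), (2,4): slope = sum(xy)/sum(x^2) = 9/5
  fit <- slope_through_origin(c(1, 2), c(1, 4))
  expect_equal(fit$slope, 1.8)
  fit2 <- slope_through_origin(1:10, 2 * (1:10))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$r_squared, 1)
  # independent check against lm with zero intercept
  set.seed(1)
  x <- stats::runif(200, 1, 3); y <- 2 * x + stats::rnorm(200, 0, 0.5)
  fit3 <- slope_through_origin(x, y)
  lmfit <- stats::lm(y ~ 0 + x)
  expect_equal(fit3$slope, unname(stats::coef(lmfit)), tolerance = 1e-12)
  se <- summary(lmfit)$coefficients[1, 2]
  expect_lt(abs(fit3$slope - 2), 3 * se)
  expect_error(slope_through_origin(c(0, 0), c(1, 2)), "zero")
})

test_that("mean matching keeps cells below the largest spontaneous mean", {
  cells <- data.frame(cell = 1:3, mean_spont = c(1, 2, 3),
                      mean_evoked = c(2, 5, 3))
  mm <- mean_match_subset(cells)        # cutoff 3 -> cells 1 and 3 survive
  expect_equal(mm$cell, c(1, 3))
  all_in <- data.frame(cell = 1:2, mean_spont = c(2, 3), mean_evoked = c(1, 2))
  expect_equal(nrow(mean_match_subset(all_in)), 2)
  none <- data.frame(cell = 1:2, mean_spont = c(1, 1), mean_evoked = c(5, 6))
  expect_warning(out <- mean_match_subset(none), "every cell")
  expect_equal(nrow(out), 0)
})

test_that("state test is the Welch two-sample t-test", {
  ht <- state_ttest(c(1, 2, 3), c(4, 5, 6))
  oracle <- stats::t.test(c(4, 5, 6), c(1, 2, 3), var.equal = FALSE)
  expect_equal(ht$t, unname(oracle$statistic))
  expect_equal(ht$p_value, oracle$p.value)
  same <- state_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(state_ttest(1, c(1, 2)), "at least 2")
})

test_that("population summary bands scale with across-unit spread", {
  series <- cbind(rep(0, 5), rep(2, 5))
  ps <- population_summary(series, k = 0.2)
  expect_equal(ps$mean, rep(1, 5))
  expect_equal(ps$upper - ps$mean, rep(0.2 * stats::sd(c(0, 2)), 5))
  expect_equal(population_summary(series, k = 0)$upper, ps$mean)
  ident <- population_summary(cbind(rep(3, 4), rep(3, 4)), k = 0.2)
  expect_equal(ident$lower, ident$upper)
})

test_that("poisson trains calibrate the Fano and correlation measures", {
  # homogeneous Poisson (zero gain variance): Fano slope -> 1, correlation -> 0
  ts <- generate_trains(n_cells = 40, n_trials = 60,
                        rate_spont = seq(4, 16, length.out = 40),
                        rate_evoked = seq(5, 18, length.out = 40),
                        gain_var_spont = 0, gain_var_evoked = 0, seed = 99)
  res <- analyze_trials(ts)
  cells <- res$states$cells
  fano <- slope_through_origin(c(cells$mean_spont, cells$mean_evoked),
                               c(cells$var_spont, cells$var_evoked))
  # 3-SE band from the zero-intercept regression residuals
  x <- c(cells$mean_spont, cells$mean_evoked)
  y <- c(cells$var_spont, cells$var_evoked)
  se <- sqrt(sum((y - fano$slope * x)^2) / (length(x) - 1) / sum(x^2))
  expect_lt(abs(fano$slope - 1), 3 * se)
  prs <- res$states$pairs
  corr <- mean(c(prs$cov_spont, prs$cov_evoked))
  corr_se <- stats::sd(c(prs$cov_spont, prs$cov_evoked)) /
    sqrt(2 * nrow(prs))
  expect_lt(abs(corr), 3 * corr_se)
})

test_that("the pipeline is deterministic for identical inputs", {
  ts <- generate_trains(n_cells = 6, n_trials = 8,
                        rate_spont = c(3, 5, 7, 9, 11, 13),
                        rate_evoked = c(6, 8, 10, 12, 14, 16), seed = 5)
  r1 <- analyze_trials(ts)
  r2 <- analyze_trials(ts)
  expect_identical(r1$fractions, r2$fractions)
  expect_identical(r1$slopes, r2$slopes)
  ts_b <- generate_trains(n_cells = 6, n_trials = 8,
                          rate_spont = c(3, 5, 7, 9, 11, 13),
                          rate_evoked = c(6, 8, 10, 12, 14, 16), seed = 5)
  expect_identical(ts$spikes, ts_b$spikes)
})
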