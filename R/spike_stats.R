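#' Trial-structured spike data
#'
#' Neutral container for trial-aligned spike times: one list entry per cell,
#' each a list of per-trial numeric spike-time vectors (seconds, stimulus
#' onset at `t = 0`). Analysis-mode presets set the window length and state
#' epochs: anesthetized odor data use 100 ms windows on `[-2, 2]` s, awake
#' data 20 ms windows with 200 ms epochs around inhalation, optogenetic data
#' 100 ms windows, and anterior-piriform data 200 ms windows.
#'
#' @param spikes list (cells) of lists (trials) of numeric spike times (s).
#' @param t_range recording span (s) relative to onset.
#' @param spontaneous,evoked state epochs (s); spontaneous must end by 0 and
#'   evoked start at or after 0.
#' @param T_window analysis window length (s).
#' @param mode optional preset: `"anesthetized"`, `"awake"`, `"opto"`,
#'   `"aPC"`; overrides `T_window` and the epochs.
#' @param cell_ids,recording,stimulus metadata labels.
#' @return An object of class `"trial_spikes"`.
#' @export
trial_spikes <- function(spikes, t_range = c(-2, 2), spontaneous = NULL,
                         evoked = NULL, T_window = 0.1, mode = NULL,
                         cell_ids = NULL, recording = "rec1",
                         stimulus = "stim") {
  if (!length(spikes)) stop("no cells provided", call. = FALSE)
  n_trials <- unique(vapply(spikes, length, 0L))
  if (length(n_trials) != 1L)
    stop("all cells must have the same number of trials", call. = FALSE)
  if (n_trials == 0L) stop("empty trial list", call. = FALSE)
  for (cl in spikes) for (tr in cl)
    if (length(tr) && (any(!is.finite(tr)) || any(tr < t_range[1] - 1e-9) ||
                       any(tr > t_range[2] + 1e-9)))
      stop("spike times must be finite and within t_range", call. = FALSE)
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("anesthetized", "awake", "opto", "aPC"))
    preset <- switch(mode,
      anesthetized = list(T = 0.1, sp = c(t_range[1], 0), ev = c(0, t_range[2])),
      awake = list(T = 0.02, sp = c(-0.2, 0), ev = c(0, 0.2)),
      opto = list(T = 0.1, sp = c(t_range[1], 0), ev = c(0, t_range[2])),
      aPC = list(T = 0.2, sp = c(t_range[1], 0), ev = c(0, t_range[2])))
    T_window <- preset$T
    if (is.null(spontaneous)) spontaneous <- preset$sp
    if (is.null(evoked)) evoked <- preset$ev
  }
  if (is.null(spontaneous)) spontaneous <- c(t_range[1], 0)
  if (is.null(evoked)) evoked <- c(0, t_range[2])
  if (spontaneous[2] > 0 || evoked[1] < 0)
    stop("spontaneous epoch must precede onset, evoked must follow",
         call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_along(spikes))
  structure(list(spikes = spikes, n_cells = length(spikes),
                 n_trials = n_trials, t_range = t_range,
                 spontaneous = spontaneous, evoked = evoked,
                 T_window = T_window, cell_ids = cell_ids,
                 recording = recording, stimulus = stimulus),
            class = "trial_spikes")
}

#' @export
print.trial_spikes <- function(x, ...) {
  cat(sprintf(
    "<trial_spikes> %s: %d cells x %d trials on [%g, %g] s, T = %g s\n",
    x$recording, x$n_cells, x$n_trials, x$t_range[1], x$t_range[2],
    x$T_window))
  invisible(x)
}

#' Spike counts in half-overlapping windows
#'
#' Counts spikes per cell, trial and window. Windows have length `T`, centers
#' spaced `T/2` on a common grid spanning the recording; each window is
#' half-open `[lo, hi)`, so a spike on a boundary is counted exactly once.
#'
#' @param ts a [trial_spikes()] object.
#' @param T_window window length (s); defaults to the object's.
#' @return list with `counts` (array windows x cells x trials) and `centers`
#'   (s).
#' @export
windowed_trial_counts <- function(ts, T_window = ts$T_window) {
  stopifnot(inherits(ts, "trial_spikes"))
  half <- T_window / 2
  n_blocks <- floor((ts$t_range[2] - ts$t_range[1]) / half + 1e-9)
  if (n_blocks < 2) stop("recording shorter than one window", call. = FALSE)
  edges <- ts$t_range[1] + half * (0:n_blocks)
  n_win <- n_blocks - 1
  centers <- ts$t_range[1] + half * seq_len(n_win)
  counts <- array(0L, dim = c(n_win, ts$n_cells, ts$n_trials))
  for (ci in seq_len(ts$n_cells)) for (tr in seq_len(ts$n_trials)) {
    st <- ts$spikes[[ci]][[tr]]
    if (!length(st)) next
    # half-open [edge_b, edge_{b+1}) block membership, then adjacent-sum
    b <- findInterval(st, edges, left.open = FALSE, rightmost.closed = FALSE)
    b <- b[b >= 1 & b <= n_blocks]
    blk <- tabulate(b, nbins = n_blocks)
    counts[, ci, tr] <- blk[-n_blocks] + blk[-1]
  }
  list(counts = counts, centers = centers, T_window = T_window)
}

#' Across-trial statistics per window
#'
#' Trial mean (as a PSTH in spikes/s), spike-count variance per cell, and
#' spike-count covariance per simultaneously recorded pair, per window, with
#' unbiased (n - 1) normalization.
#'
#' @param wc a [windowed_trial_counts()] result.
#' @return An object of class `"trial_stats"`: `centers`, `T_window`, `psth`
#'   (windows x cells, spikes/s), `mean_count`, `var` (windows x cells),
#'   `cov` (windows x pairs), `pairs`.
#' @export
trial_stats <- function(wc) {
  counts <- wc$counts
  n_win <- dim(counts)[1]; n_cells <- dim(counts)[2]; n_tr <- dim(counts)[3]
  if (n_tr < 2)
    stop("across-trial variance undefined with a single trial", call. = FALSE)
  mean_c <- apply(counts, c(1, 2), mean)
  var_c <- apply(counts, c(1, 2), stats::var)
  pairs <- which(upper.tri(diag(n_cells)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- NULL
  cov_c <- matrix(0, n_win, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    a <- matrix(counts[, pairs[p, 1], ], n_win)
    b <- matrix(counts[, pairs[p, 2], ], n_win)
    cov_c[, p] <- rowSums((a - rowMeans(a)) * (b - rowMeans(b))) / (n_tr - 1)
  }
  structure(list(centers = wc$centers, T_window = wc$T_window,
                 psth = mean_c / wc$T_window, mean_count = mean_c,
                 var = var_c, cov = cov_c, pairs = pairs, n_trials = n_tr),
            class = "trial_stats")
}

#' Time-averaged statistics per state
#'
#' Averages each cell's (and pair's) windowed statistic over the windows whose
#' centers fall in the spontaneous and evoked epochs.
#'
#' @param st a [trial_stats()] result.
#' @param spontaneous,evoked epochs (s).
#' @return list with data.frames `cells` (`mean_spont`, `mean_evoked`,
#'   `var_spont`, `var_evoked` per cell) and `pairs` (`cov_spont`,
#'   `cov_evoked` plus member indices).
#' @export
state_average <- function(st, spontaneous, evoked) {
  stopifnot(inherits(st, "trial_stats"))
  sel_sp <- st$centers >= spontaneous[1] & st$centers < spontaneous[2]
  sel_ev <- st$centers >= evoked[1] & st$centers < evoked[2]
  if (!any(sel_sp) || !any(sel_ev))
    stop("a state epoch contains no window centers", call. = FALSE)
  cells <- data.frame(
    cell = seq_len(ncol(st$psth)),
    mean_spont = colMeans(st$mean_count[sel_sp, , drop = FALSE]),
    mean_evoked = colMeans(st$mean_count[sel_ev, , drop = FALSE]),
    var_spont = colMeans(st$var[sel_sp, , drop = FALSE]),
    var_evoked = colMeans(st$var[sel_ev, , drop = FALSE]))
  pairs <- data.frame(
    cell_j = st$pairs[, 1], cell_k = st$pairs[, 2],
    cov_spont = colMeans(st$cov[sel_sp, , drop = FALSE]),
    cov_evoked = colMeans(st$cov[sel_ev, , drop = FALSE]))
  list(cells = cells, pairs = pairs)
}

#' Count and fraction of units with evoked increases
#'
#' Strict inequality; ties count as not increased.
#'
#' @param spont,evoked numeric vectors of state-averaged values.
#' @return list with `n_increased`, `n_total`, `fraction`.
#' @export
fraction_increased <- function(spont, evoked) {
  stopifnot(length(spont) == length(evoked), length(spont) > 0)
  n_inc <- sum(evoked > spont)
  list(n_increased = n_inc, n_total = length(spont),
       fraction = n_inc / length(spont))
}

#' Least-squares slope through the origin
#'
#' `slope = sum(x y) / sum(x^2)`, the zero-intercept regression used as a
#' population-level Fano factor (variance vs mean) or correlation (covariance
#' vs product of standard deviations). The reported R-squared is for the
#' zero-intercept model, with the total sum of squares about zero
#' (uncentered).
#'
#' @param x,y numeric vectors.
#' @return list with `slope` and `r_squared`.
#' @export
slope_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y))
  sxx <- sum(x^2)
  if (sxx == 0) stop("x is identically zero", call. = FALSE)
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  list(slope = slope,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Mean-matched subset of cells
#'
#' Keeps the cells whose evoked mean count does not exceed the largest
#' spontaneous mean count across all cells, a conservative control for evoked
#' rate increases when comparing Fano slopes between states.
#'
#' @param cells data.frame with columns `mean_spont`, `mean_evoked` (as from
#'   [state_average()]).
#' @return the subset data.frame (possibly empty, with a warning).
#' @export
mean_match_subset <- function(cells) {
  stopifnot(nrow(cells) > 0)
  cutoff <- max(cells$mean_spont)
  out <- cells[cells$mean_evoked <= cutoff, , drop = FALSE]
  if (nrow(out) == 0)
    warning("mean matching removed every cell")
  out
}

#' Welch test for evoked changes
#'
#' Two-sided two-sample t-test not assuming equal variances, applied to the
#' per-cell (or per-pair) state-averaged statistics.
#'
#' @param spont,evoked numeric vectors, each of length `>= 2`.
#' @return list with `t`, `p_value`, `df`.
#' @export
state_ttest <- function(spont, evoked) {
  if (length(spont) < 2 || length(evoked) < 2)
    stop("need at least 2 values per group", call. = FALSE)
  ht <- stats::t.test(evoked, spont, var.equal = FALSE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Population mean curves with heterogeneity bands
#'
#' Across-population mean of a per-cell (or per-pair) windowed statistic with
#' a `mean +/- k * sd` band, `sd` taken across the population after
#' trial-averaging (display scales of 0.2 or 0.05 are typical).
#'
#' @param series matrix, windows x units.
#' @param k band scale, `>= 0`.
#' @return data.frame with `mean`, `lower`, `upper` per window.
#' @export
population_summary <- function(series, k = 0.2) {
  stopifnot(is.matrix(series), k >= 0)
  m <- rowMeans(series)
  s <- apply(series, 1, stats::sd)
  data.frame(mean = m, lower = m - k * s, upper = m + k * s)
}

#' Full spontaneous-versus-evoked analysis of one recording
#'
#' Runs the whole pipeline: windowed counts, across-trial statistics, state
#' averages, fractions increased, origin-constrained Fano and correlation
#' slopes (with the mean-matched evoked variants), and Welch tests.
#'
#' @param ts a [trial_spikes()] object.
#' @return list with elements `stats` ([trial_stats()]), `states`
#'   ([state_average()]), `fractions`, `slopes`, `tests`.
#' @export
analyze_trials <- function(ts) {
  stopifnot(inherits(ts, "trial_spikes"))
  st <- trial_stats(windowed_trial_counts(ts))
  sa <- state_average(st, ts$spontaneous, ts$evoked)
  cells <- sa$cells; prs <- sa$pairs
  fractions <- list(
    rate = fraction_increased(cells$mean_spont, cells$mean_evoked),
    var = fraction_increased(cells$var_spont, cells$var_evoked),
    cov = fraction_increased(prs$cov_spont, prs$cov_evoked))
  sd_sp <- sqrt(cells$var_spont); sd_ev <- sqrt(cells$var_evoked)
  prod_sp <- sd_sp[prs$cell_j] * sd_sp[prs$cell_k]
  prod_ev <- sd_ev[prs$cell_j] * sd_ev[prs$cell_k]
  mm <- mean_match_subset(cells)
  mm_pairs <- prs[prs$cell_j %in% mm$cell & prs$cell_k %in% mm$cell, ,
                  drop = FALSE]
  slopes <- list(
    fano_spont = slope_through_origin(cells$mean_spont, cells$var_spont),
    fano_evoked = slope_through_origin(cells$mean_evoked, cells$var_evoked),
    fano_evoked_matched = if (nrow(mm))
      slope_through_origin(mm$mean_evoked, mm$var_evoked) else NULL,
    corr_spont = slope_through_origin(prod_sp, prs$cov_spont),
    corr_evoked = slope_through_origin(prod_ev, prs$cov_evoked),
    corr_evoked_matched = if (nrow(mm_pairs))
      slope_through_origin(prod_ev[as.integer(rownames(mm_pairs))],
                           mm_pairs$cov_evoked) else NULL)
  tests <- list(
    rate = state_ttest(cells$mean_spont, cells$mean_evoked),
    var = state_ttest(cells$var_spont, cells$var_evoked),
    cov = if (nrow(prs) >= 2)
      state_ttest(prs$cov_spont, prs$cov_evoked) else NULL)
  list(stats = st, states = sa, fractions = fractions, slopes = slopes,
       tests = tests)
}
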