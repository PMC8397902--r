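#' Tabulated transfer function
#'
#' A static input-to-rate map for one cell type, given as a monotone table.
#' These tables stand in for the rate response of detailed multi-compartment
#' biophysical cell models; the firing-rate network only ever sees the table.
#' Inputs below the tabulated range give zero firing; inputs above it are
#' capped at the maximum tabulated rate.
#'
#' @param input numeric, strictly increasing grid of input (activity) values.
#' @param rate numeric, non-decreasing firing rates (spikes/s), same length,
#'   all `>= 0`.
#' @param cell_type label, e.g. `"MC"`, `"PGC"`, `"GC"`.
#' @return An object of class `"ob_transfer"`.
#' @examples
#' tf <- transfer_function(c(0, 1), c(0, 10))
#' eval_transfer(tf, c(-1, 0.5, 2))   # 0, 5, 10
#' @export
transfer_function <- function(input, rate, cell_type = "generic") {
  input <- as.numeric(input)
  rate <- as.numeric(rate)
  if (length(input) < 2L || length(input) != length(rate))
    stop("transfer table needs >= 2 matching (input, rate) rows", call. = FALSE)
  if (any(!is.finite(input)) || any(!is.finite(rate)))
    stop("transfer table entries must be finite", call. = FALSE)
  if (any(diff(input) <= 0))
    stop("transfer input grid must be strictly increasing", call. = FALSE)
  if (any(rate < 0) || any(diff(rate) < 0))
    stop("transfer rates must be non-negative and non-decreasing", call. = FALSE)
  structure(list(input = input, rate = rate, cell_type = cell_type),
            class = "ob_transfer")
}

#' Evaluate a transfer function
#'
#' Piecewise-linear interpolation on the table; clamped to 0 below the grid
#' and to the maximum rate above it.
#'
#' @param tf an [transfer_function()] object.
#' @param x numeric input values.
#' @return firing rates (spikes/s), same length as `x`.
#' @export
eval_transfer <- function(tf, x) {
  stopifnot(inherits(tf, "ob_transfer"))
  stats::approx(tf$input, tf$rate, xout = x, method = "linear",
                yleft = 0, yright = tf$rate[length(tf$rate)])$y
}

#' @export
print.ob_transfer <- function(x, ...) {
  cat(sprintf("<ob_transfer> %s: %d points, input [%g, %g], rate [0, %g] sp/s\n",
              x$cell_type, length(x$input), min(x$input), max(x$input),
              max(x$rate)))
  invisible(x)
}

#' Maximum tabulated rate of a transfer function
#' @param tf an [transfer_function()] object.
#' @return scalar, spikes/s.
#' @export
max_rate <- function(tf) max(tf$rate)

#' Read a transfer table from a two-column delimited file
#'
#' @param path path to a whitespace- or comma-delimited file with columns
#'   (input, rate); lines starting with `#` are ignored.
#' @param cell_type label attached to the table.
#' @return An `"ob_transfer"` object.
#' @export
read_transfer_table <- function(path, cell_type = "generic") {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", col.names = c("input", "rate"))
  transfer_function(tab$input, tab$rate, cell_type = cell_type)
}

#' Default transfer tables shipped with the package
#'
#' Monotone saturating tables, one per olfactory-bulb cell type. These are
#' synthetic stand-ins with the qualitative shape of transfer curves extracted
#' from coupled biophysical cell models (threshold, quasi-linear rise,
#' saturation; mitral and periglomerular cells reach higher maximal rates than
#' granule cells). Users fitting real data should supply their own tables via
#' [read_transfer_table()].
#'
#' @param cell_type one of `"MC"`, `"PGC"`, `"GC"`.
#' @return An `"ob_transfer"` object.
#' @export
default_transfer <- function(cell_type = c("MC", "PGC", "GC")) {
  cell_type <- match.arg(cell_type)
  path <- system.file("extdata",
                      sprintf("synthetic_transfer_%s.txt", tolower(cell_type)),
                      package = "obvar", mustWork = TRUE)
  read_transfer_table(path, cell_type = cell_type)
}
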