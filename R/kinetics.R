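#' Synapse kinetics
#'
#' Rise/decay rate constants of the synaptic gate for one synapse type.
#' The gate s of a presynaptic cell obeys ds/dt = alpha f(r) (1 - s) - beta s
#' with drive f(r) = r / r_bar, so alpha sets activation speed and beta decay.
#' Defaults are the biophysical-model constants:
#' 1/alpha = 1.25 (GABA_A), 1 (AMPA), 52 (NMDA) ms and
#' 1/beta = 18 (GABA_A), 5.5 (AMPA), 343 (NMDA) ms.
#' GABA_A synapses are inhibitory (sign -1), AMPA/NMDA excitatory (+1).
#'
#' @param synapse_type one of `"GABA_A"`, `"AMPA"`, `"NMDA"`.
#' @param alpha,beta rate constants (1/ms), both `> 0`; defaults as above.
#' @return An object of class `"ob_kinetics"` with fields `synapse_type`,
#'   `alpha`, `beta`, `sign`.
#' @export
synapse_kinetics <- function(synapse_type = c("GABA_A", "AMPA", "NMDA"),
                             alpha = NULL, beta = NULL) {
  synapse_type <- match.arg(synapse_type)
  defaults <- list(
    GABA_A = c(alpha = 1 / 1.25, beta = 1 / 18),
    AMPA   = c(alpha = 1 / 1,    beta = 1 / 5.5),
    NMDA   = c(alpha = 1 / 52,   beta = 1 / 343))
  d <- defaults[[synapse_type]]
  if (is.null(alpha)) alpha <- unname(d["alpha"])
  if (is.null(beta)) beta <- unname(d["beta"])
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("synapse rate constants alpha, beta must be positive", call. = FALSE)
  structure(list(synapse_type = synapse_type, alpha = alpha, beta = beta,
                 sign = if (synapse_type == "GABA_A") -1 else +1),
            class = "ob_kinetics")
}

#' @export
print.ob_kinetics <- function(x, ...) {
  cat(sprintf("<ob_kinetics> %s: 1/alpha = %g ms, 1/beta = %g ms, sign %+d\n",
              x$synapse_type, 1 / x$alpha, 1 / x$beta, x$sign))
  invisible(x)
}

#' Steady-state synaptic gate
#'
#' Long-time limit of the gate at constant presynaptic rate `r`:
#' `alpha * (r/r_bar) / (beta + alpha * (r/r_bar))`, a value in `[0, 1)`.
#'
#' @param r presynaptic firing rate (spikes/s), `0 <= r <= r_bar`.
#' @param r_bar maximal rate used to normalize the drive, `> 0`.
#' @param kin an [synapse_kinetics()] object.
#' @return gate value(s) in `[0, 1]`.
#' @examples
#' gate_steady(0, 40, synapse_kinetics("AMPA"))        # 0
#' gate_steady(40, 40, synapse_kinetics("AMPA"))       # ~0.846
#' @export
gate_steady <- function(r, r_bar, kin) {
  stopifnot(inherits(kin, "ob_kinetics"))
  if (!is.numeric(r_bar) || r_bar <= 0)
    stop("r_bar must be positive", call. = FALSE)
  f <- r / r_bar
  kin$alpha * f / (kin$beta + kin$alpha * f)
}

#' Simulate the gate ODE at constant presynaptic rate
#'
#' Explicit-Euler integration of ds/dt = alpha f(r) (1 - s) - beta s, used to
#' check relaxation to [gate_steady()].
#'
#' @param kin an [synapse_kinetics()] object.
#' @param r constant presynaptic rate (spikes/s).
#' @param r_bar maximal rate, `> 0`.
#' @param dt time step (ms).
#' @param t_end total integration time (ms).
#' @param s0 initial gate value.
#' @return numeric vector of gate values at `seq(dt, t_end, by = dt)`.
#' @export
simulate_gate <- function(kin, r, r_bar, dt = 1, t_end = 2000, s0 = 0) {
  stopifnot(inherits(kin, "ob_kinetics"))
  f <- r / r_bar
  n <- floor(t_end / dt)
  out <- numeric(n)
  s <- s0
  for (i in seq_len(n)) {
    s <- s + dt * (kin$alpha * f * (1 - s) - kin$beta * s)
    out[i] <- s
  }
  out
}
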