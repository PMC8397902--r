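#' General stochastic firing-rate network
#'
#' Container for a network of rate units obeying
#' `tau_j dx_j = (-x_j + mu_j(t) + sum_k w_jk G_k) dt + sigma_j(t) dW_j`,
#' `r_j = F_j(x_j)`, where each presynaptic cell k filters its rate through
#' one or more synaptic gates (see [synapse_kinetics()]) and `G_k` is the sum
#' of that cell's gate variables. Weights are stored signed: negative for
#' GABA_A presynaptic cells, positive for AMPA/NMDA.
#'
#' @param tau numeric vector of membrane time constants (ms), all `> 0`.
#' @param W signed weight matrix, `W[j, k]` the weight from presynaptic cell k
#'   onto postsynaptic cell j.
#' @param transfer list of [transfer_function()] objects, one per cell.
#' @param kinetics list (one entry per cell) of lists of [synapse_kinetics()]
#'   objects: the synapse types through which that cell transmits. Cells with
#'   no outgoing edges may have an empty list.
#' @param input_correlation symmetric positive-semidefinite matrix with unit
#'   diagonal: correlations of the input noise increments.
#' @param cell_type character vector of labels, one per cell.
#' @return An object of class `"rate_network"`.
#' @seealso [ob_network()] for the 7-cell olfactory-bulb circuit.
#' @export
rate_network <- function(tau, W, transfer, kinetics,
                         input_correlation = diag(length(tau)),
                         cell_type = rep("generic", length(tau))) {
  n <- length(tau)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("membrane time constants tau must be positive", call. = FALSE)
  W <- as.matrix(W)
  if (!all(dim(W) == n))
    stop("W must be an n x n matrix", call. = FALSE)
  if (length(transfer) != n || !all(vapply(transfer, inherits, TRUE, "ob_transfer")))
    stop("transfer must be a list of n ob_transfer objects", call. = FALSE)
  if (length(kinetics) != n)
    stop("kinetics must be a list with one entry per cell", call. = FALSE)
  kinetics <- lapply(kinetics, function(kl) {
    if (inherits(kl, "ob_kinetics")) kl <- list(kl)
    stopifnot(all(vapply(kl, inherits, TRUE, "ob_kinetics")))
    kl
  })
  C <- as.matrix(input_correlation)
  if (!all(dim(C) == n) || max(abs(C - t(C))) > 1e-12 ||
      max(abs(diag(C) - 1)) > 1e-12)
    stop("input_correlation must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("input_correlation must be positive semidefinite", call. = FALSE)
  structure(list(n = n, tau = as.numeric(tau), W = W, transfer = transfer,
                 kinetics = kinetics, input_correlation = C,
                 cell_type = as.character(cell_type)),
            class = "rate_network")
}

#' @export
print.rate_network <- function(x, ...) {
  cat(sprintf("<rate_network> %d cells (%s), %d edges\n", x$n,
              paste(unique(x$cell_type), collapse = "/"), sum(x$W != 0)))
  invisible(x)
}

#' Composite gate-transfer map of one cell
#'
#' Returns the function `H_k(x) = sum_types gate_steady(F_k(x))`, the summed
#' steady-state gate drive a presynaptic cell contributes per unit weight.
#' Mitral cells transmit through both AMPA and NMDA gates, so their composite
#' gate takes values in `[0, 2)`; inhibitory cells have a single GABA_A gate
#' in `[0, 1)` (the inhibitory sign lives in the weight matrix).
#'
#' @param net a [rate_network()].
#' @param k cell index.
#' @return a vectorized function of the activity variable x.
#' @export
gate_transfer_map <- function(net, k) {
  tf <- net$transfer[[k]]
  kins <- net$kinetics[[k]]
  rb <- max_rate(tf)
  if (length(kins) == 0L) return(function(x) rep(0, length(x)))
  function(x) {
    r <- eval_transfer(tf, x)
    out <- 0
    for (kin in kins) out <- out + gate_steady(r, rb, kin)
    out
  }
}

#' Default olfactory-bulb input-noise correlation matrix
#'
#' Unit diagonal; 0.1 between a mitral cell and the periglomerular cell of the
#' same glomerulus (shared receptor-neuron input), 0.05 between the two mitral
#' cells, and 0.05 between granule cells; zero otherwise.
#'
#' @return 7 x 7 correlation matrix in the cell order of [ob_network()].
#' @export
ob_input_correlation <- function() {
  C <- diag(7)
  C[1, 2] <- C[2, 1] <- 0.1   # MC1 - PGC1
  C[3, 4] <- C[4, 3] <- 0.1   # MC2 - PGC2
  C[1, 3] <- C[3, 1] <- 0.05  # MC1 - MC2
  gc <- 5:7
  C[gc, gc] <- 0.05
  diag(C) <- 1
  C
}

#' The 7-cell olfactory-bulb circuit
#'
#' Builds the minimal mitral/periglomerular/granule sub-network: two glomeruli,
#' each with one mitral cell (MC) and one periglomerular cell (PGC), plus three
#' granule cells (GC) - one providing independent inhibition to each MC and one
#' shared GC inhibiting both. Cell order: MC1, PGC1, MC2, PGC2, GC1, GC2, GCc.
#' Couplings are symmetric between the two glomeruli. The three free couplings
#' are the ones systematically varied when fitting:
#' `wMG` (independent GC inhibition onto MC), `wGM` (MC excitation onto GC,
#' through both AMPA and NMDA gates), and `wGc` (shared-GC inhibition onto MC).
#' PGC couplings are held fixed at `wMP` (PGC inhibition onto MC) and `wPM`
#' (MC excitation onto PGC).
#'
#' @param wMG,wGM,wGc free coupling magnitudes, all `>= 0`.
#' @param wMP,wPM fixed intra-glomerular couplings, `>= 0`.
#' @param tau named vector of time constants (ms) per cell type.
#' @param transfer named list of [transfer_function()] objects per cell type;
#'   defaults to the shipped tables.
#' @param input_correlation 7 x 7 matrix, defaults to [ob_input_correlation()].
#' @return A `"rate_network"` with extra fields `free_couplings` and subclass
#'   `"ob_network"`.
#' @examples
#' net <- ob_network(wMG = 6, wGM = 3, wGc = 1.5)
#' net$free_couplings
#' @export
ob_network <- function(wMG, wGM, wGc, wMP = 1, wPM = 1,
                       tau = c(MC = 40, PGC = 20, GC = 30),
                       transfer = NULL,
                       input_correlation = ob_input_correlation()) {
  w <- c(wMG = wMG, wGM = wGM, wGc = wGc, wMP = wMP, wPM = wPM)
  if (any(!is.finite(w)) || any(w < 0))
    stop("coupling magnitudes must be finite and >= 0", call. = FALSE)
  if (is.null(transfer))
    transfer <- list(MC = default_transfer("MC"), PGC = default_transfer("PGC"),
                     GC = default_transfer("GC"))
  ctype <- c("MC", "PGC", "MC", "PGC", "GC", "GC", "GC")
  tfs <- transfer[ctype]
  kin_by_type <- list(
    MC = list(synapse_kinetics("AMPA"), synapse_kinetics("NMDA")),
    PGC = list(synapse_kinetics("GABA_A")),
    GC = list(synapse_kinetics("GABA_A")))
  kins <- kin_by_type[ctype]
  W <- matrix(0, 7, 7)
  # inhibition onto MCs (signed negative)
  W[1, 2] <- W[3, 4] <- -wMP   # own PGC
  W[1, 5] <- W[3, 6] <- -wMG   # independent GC
  W[1, 7] <- W[3, 7] <- -wGc   # shared GC
  # MC excitation (AMPA + NMDA, positive)
  W[2, 1] <- W[4, 3] <- wPM    # onto own PGC
  W[5, 1] <- W[6, 3] <- wGM    # onto independent GC
  W[7, 1] <- W[7, 3] <- wGM    # onto shared GC
  net <- rate_network(tau = unname(tau[ctype]), W = W, transfer = tfs,
                      kinetics = kins, input_correlation = input_correlation,
                      cell_type = ctype)
  net$free_couplings <- c(wMG = wMG, wGM = wGM, wGc = wGc)
  net$fixed_couplings <- c(wMP = wMP, wPM = wPM)
  class(net) <- c("ob_network", class(net))
  net
}

#' Indices of cells of a given type
#' @param net a [rate_network()].
#' @param type cell-type label.
#' @return integer vector of cell indices.
#' @export
cells_of_type <- function(net, type) which(net$cell_type == type)
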