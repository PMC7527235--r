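## The stochastic energy-minimization engine.
##
## A map is a bijection of N source neurons onto N collicular positions
## (axon competition). Its energy is
##   E = E_chem + E_act
##   E_chem = alpha * sum_i R(i) * L(t_i)          (forward-signaling repulsion)
##   E_act  = -(gamma/2) * sum_{i != j} C_ij U(t_i, t_j)   (correlated activity)
## with C_ij = exp(-|x_i - x_j| / (b N)) the activity correlation of two
## source neurons and U(r') = exp(-r'^2 / (2 d^2)) the collicular overlap.
## The dynamics proposes swaps of two random axons' termination zones,
## accepted with probability 1 / (1 + exp(beta * dE)), beta = 4.

#' Energy-model parameters
#'
#' @param alpha Chemical (forward signaling) strength; default 200.
#' @param gamma Correlated-activity strength; default 1.
#' @param d Collicular interaction distance (SC units); default 3.
#' @param b Retinal correlation distance as a fraction of the axis; the
#'   correlation length is `R = b * n_neurons`. Default 0.11.
#' @param n_neurons Number of neurons per structure; default 100.
#' @param beta Acceptance steepness of the swap probability
#'   `1/(1 + exp(beta * dE))`; default 4.
#' @param iterations Swap proposals per run; default `1e7`.
#' @return An object of class `"energy_params"`.
#' @export
energy_params <- function(alpha = 200, gamma = 1, d = 3, b = 0.11,
                          n_neurons = 100, beta = 4, iterations = 1e7) {
  stopifnot(d > 0, b > 0, beta > 0, n_neurons >= 2, iterations >= 0,
            alpha >= 0, gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma, d = d, b = b,
                 n_neurons = n_neurons, beta = beta,
                 iterations = as.numeric(iterations)),
            class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "Energy parameters: alpha = %g, gamma = %g, d = %g, b = %g (R = %g), N = %d, beta = %g, %g proposals\n",
    x$alpha, x$gamma, x$d, x$b, x$b * x$n_neurons, x$n_neurons, x$beta, x$iterations))
  invisible(x)
}

#' Construct a map state
#'
#' A map state binds each source neuron (retinal ganglion cell or V1 neuron)
#' to its collicular termination zone, together with the receptor levels it
#' carries and the ligand field it reads.
#'
#' @param target_of_source Integer vector: termination position of each
#'   source neuron. For simulated maps this must be a permutation of `1..N`
#'   (competition: no two axons share a target).
#' @param source_positions Axis positions of the source neurons (default
#'   `1..N`).
#' @param source_receptor,target_ligand Optional receptor/ligand vectors.
#' @param isl2 Optional logical Isl2 mask over source neurons.
#' @param type `"RC"` (retino-collicular) or `"CC"` (cortico-collicular).
#' @param simulated Logical; enforce the bijection invariant (default TRUE).
#'   Experimental or synthetic map tables may be sparse/non-bijective.
#' @return An object of class `"map_state"`.
#' @export
map_state <- function(target_of_source,
                      source_positions = seq_along(target_of_source),
                      source_receptor = NULL, target_ligand = NULL,
                      isl2 = NULL, type = c("RC", "CC"), simulated = TRUE) {
  type <- match.arg(type)
  n <- length(target_of_source)
  if (length(source_positions) != n) {
    stop("source_positions must match target_of_source in length", call. = FALSE)
  }
  if (simulated &&
      !identical(sort(as.integer(target_of_source)), seq_len(n))) {
    stop("simulated map is not a bijection onto 1..N", call. = FALSE)
  }
  for (v in list(source_receptor, target_ligand, isl2)) {
    if (!is.null(v) && length(v) != n) {
      stop("all map_state fields must have length N", call. = FALSE)
    }
  }
  structure(list(target_of_source = target_of_source,
                 source_positions = source_positions,
                 source_receptor = source_receptor,
                 target_ligand = target_ligand,
                 isl2 = isl2, type = type, simulated = simulated),
            class = "map_state")
}

#' @export
print.map_state <- function(x, ...) {
  n <- length(x$target_of_source)
  cat(sprintf("%s map state: %d %s, %s\n", x$type, n,
              if (x$type == "RC") "RGC axons" else "V1 axons",
              if (x$simulated) "bijective (simulated)" else "free-form"))
  invisible(x)
}

#' Activity correlation between two source neurons
#'
#' `C = exp(-r / (b N))` with `r` the source-axis distance.
#'
#' @param xi,xj Source axis positions.
#' @param params An [energy_params()].
#' @return Correlation value(s) in (0, 1].
#' @export
activity_correlation <- function(xi, xj, params = energy_params()) {
  exp(-abs(xi - xj) / (params$b * params$n_neurons))
}

#' Collicular overlap between two termination zones
#'
#' `U = exp(-r'^2 / (2 d^2))` with `r'` the SC distance.
#'
#' @param ti,tj Collicular positions.
#' @inheritParams activity_correlation
#' @return Overlap value(s) in (0, 1].
#' @export
sc_overlap <- function(ti, tj, params = energy_params()) {
  exp(-(ti - tj)^2 / (2 * params$d^2))
}

.energy_matrices <- function(source_positions, params) {
  n <- length(source_positions)
  Cm <- exp(-abs(outer(source_positions, source_positions, "-")) /
              (params$b * params$n_neurons))
  p <- seq_len(n)
  Um <- exp(-outer(p, p, "-")^2 / (2 * params$d^2))
  list(C = Cm, U = Um)
}

#' Total energy of a map state
#'
#' @param state A [map_state()] carrying `source_receptor` and
#'   `target_ligand`.
#' @inheritParams activity_correlation
#' @return A list with components `total`, `chem` and `act`.
#' @export
total_energy <- function(state, params = energy_params()) {
  stopifnot(inherits(state, "map_state"),
            !is.null(state$source_receptor), !is.null(state$target_ligand))
  t <- state$target_of_source
  chem <- params$alpha * sum(state$source_receptor * state$target_ligand[t])
  m <- .energy_matrices(state$source_positions, params)
  Upos <- m$U[t, t]
  act <- -(params$gamma / 2) * (sum(m$C * Upos) - sum(diag(m$C * Upos)))
  list(total = chem + act, chem = chem, act = act)
}

#' Energy change of swapping two axons' termination zones
#'
#' Incremental form: the chemical part is
#' `alpha (R(i) - R(j)) (L(t_j) - L(t_i))` and the activity part sums over
#' all other partners; equals the brute-force difference of [total_energy()]
#' before and after the swap.
#'
#' @param state A [map_state()].
#' @param i,j Distinct source-neuron indices.
#' @inheritParams activity_correlation
#' @return The energy change `dE`.
#' @export
swap_delta <- function(state, i, j, params = energy_params()) {
  if (i == j) stop("i and j must differ", call. = FALSE)
  t <- state$target_of_source
  R <- state$source_receptor
  L <- state$target_ligand
  dchem <- params$alpha * (R[i] - R[j]) * (L[t[j]] - L[t[i]])
  m <- .energy_matrices(state$source_positions, params)
  k <- setdiff(seq_along(t), c(i, j))
  dact <- -params$gamma *
    sum((m$C[i, k] - m$C[j, k]) * (m$U[t[j], t[k]] - m$U[t[i], t[k]]))
  dchem + dact
}

#' Swap acceptance probability
#'
#' `p = 1 / (1 + exp(beta * dE))`: 1/2 for an energy-neutral swap,
#' approaching 1 for strongly energy-decreasing swaps. Numerically stable
#' for large `|dE|`.
#'
#' @param delta Energy change of the proposed swap.
#' @param beta Steepness (default 4).
#' @return Acceptance probability in (0, 1).
#' @export
swap_probability <- function(delta, beta = 4) {
  z <- beta * delta
  ifelse(z > 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Accept or reject a proposed swap
#'
#' Draws from the current RNG stream.
#'
#' @inheritParams swap_probability
#' @return Logical.
#' @export
accept_swap <- function(delta, beta = 4) {
  stats::runif(length(delta)) < swap_probability(delta, beta)
}

#' Run the swap dynamics to form one map
#'
#' Starting from a random permutation drawn from the current RNG stream,
#' proposes `params$iterations` random axon-pair swaps, accepting each with
#' the logistic probability, and returns the final map. The bijection is
#' preserved throughout. All randomness (initial permutation and proposal
#' stream) comes from R's RNG, so a preceding `set.seed()` makes the run
#' fully reproducible.
#'
#' @param source_receptor Receptor level per source neuron (length N).
#' @param target_ligand Ligand level per collicular position (length N).
#' @param params An [energy_params()].
#' @param source_positions Source axis positions (default `1..N`).
#' @param isl2 Optional Isl2 mask carried into the returned state.
#' @param type Map type label, `"RC"` or `"CC"`.
#' @param trace Number of evenly spaced energy samples to record along the
#'   trajectory (0 = none).
#' @return A [map_state()]; when `trace > 0` the energy trajectory is
#'   attached as attribute `"energy_trace"`.
#' @export
run_mapping <- function(source_receptor, target_ligand,
                        params = energy_params(),
                        source_positions = seq_along(source_receptor),
                        isl2 = NULL, type = c("RC", "CC"), trace = 0) {
  type <- match.arg(type)
  n <- length(source_receptor)
  if (length(target_ligand) != n) {
    stop("receptor array and ligand curve must have the same length", call. = FALSE)
  }
  m <- .energy_matrices(source_positions, params)
  init <- sample.int(n)
  res <- engine_run(init - 1L, source_receptor, target_ligand, m$C, m$U,
                    params$alpha, params$gamma, params$beta,
                    params$iterations, as.integer(trace))
  st <- map_state(res$perm + 1L, source_positions = source_positions,
                  source_receptor = source_receptor,
                  target_ligand = target_ligand, isl2 = isl2, type = type)
  if (trace > 0) attr(st, "energy_trace") <- res$trace
  st
}
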