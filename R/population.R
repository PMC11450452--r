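# Population dynamics: membrane integration, hypercolumn-wise softmax,
# spike sampling, and the pixel-intensity input-current encoding.

#' Population shape
#'
#' @param n_hyper Number of hypercolumn modules (>= 1).
#' @param n_mini  Minicolumn units per hypercolumn (>= 2).
#' @return A `bcpnn_population_shape`.
#' @export
population_shape <- function(n_hyper, n_mini) {
  stopifnot(n_hyper >= 1, n_mini >= 2)
  structure(list(n_hyper = as.integer(n_hyper), n_mini = as.integer(n_mini),
                 n_units = as.integer(n_hyper * n_mini)),
            class = "bcpnn_population_shape")
}

#' Initial population state
#'
#' Membrane voltages start at 0; the softmax of zeros gives the uniform
#' posterior `1/M` per unit within each hypercolumn.
#'
#' @param shape A [population_shape()].
#' @return A `bcpnn_population_state` with fields `v`, `pi`, `s`, `I_ext`.
#' @export
population_state <- function(shape) {
  n <- shape$n_units
  structure(list(shape = shape, v = numeric(n),
                 pi = rep(1 / shape$n_mini, n),
                 s = numeric(n), I_ext = numeric(n)),
            class = "bcpnn_population_state")
}

#' Activation variant
#'
#' @param mode `"rate"` (the communicated signal is the softmax posterior
#'   itself) or `"spiking"` (independent Bernoulli samples with success
#'   probability `pi * f_max * dt`).
#' @param f_max Maximum firing rate in Hz; ignored in rate mode.
#' @export
activation_variant <- function(mode = c("spiking", "rate"), f_max = 100) {
  mode <- match.arg(mode)
  structure(list(mode = mode, f_max = f_max), class = "bcpnn_activation_variant")
}

#' Membrane integration step
#'
#' The total input of unit `j` is
#' `u_j = I_ext_j + sum over gated projections of (b_j + sum_i z_i w_ij c_ij)`
#' and the voltage follows a first-order filter
#' `v <- v + (dt/tau_m)(u - v)`.  A projection whose gate is off
#' contributes nothing, including its bias.
#'
#' @param state A `bcpnn_population_state` (its `I_ext` field is used).
#' @param inputs List of incoming projections, each a list with elements
#'   `z` (pre-synaptic z-trace vector), `weights`
#'   (a [projection_weights()]), and `gate` (logical).
#' @param tau_m Membrane time constant (s).
#' @param dt Timestep (s).
#' @return The updated state (with `v` advanced; `pi`/`s` untouched).
#' @export
step_membrane <- function(state, inputs = list(), tau_m, dt) {
  stopifnot(tau_m >= dt)
  u <- state$I_ext
  for (inp in inputs) {
    if (!isTRUE(inp$gate)) next
    w <- inp$weights
    if (length(inp$z) != nrow(w$weight) ||
        length(w$bias) != length(state$v))
      stop("projection shape does not match population")
    u <- u + w$bias + drop(crossprod(w$weight * w$conn, inp$z))
  }
  state$v <- state$v + (dt / tau_m) * (u - state$v)
  state
}

#' Hypercolumn-wise softmax
#'
#' Within each block of `n_mini` consecutive units,
#' `pi_j = exp(v_j) / sum_j' exp(v_j')`, stabilized by subtracting the
#' block maximum before exponentiation.
#'
#' @param v Finite voltage vector of length `n_hyper * n_mini`.
#' @param shape A [population_shape()].
#' @return Probability vector; each hypercolumn block sums to 1.
#' @export
softmax_by_hypercolumn <- function(v, shape) {
  if (length(v) != shape$n_units) stop("voltage length does not match shape")
  if (any(!is.finite(v))) stop("voltages must be finite")
  m <- matrix(v, nrow = shape$n_mini)
  m <- exp(sweep(m, 2, apply(m, 2, max)))
  as.vector(sweep(m, 2, colSums(m), "/"))
}

#' Sample spikes from the posterior
#'
#' Rate mode returns `pi` unchanged (the unit communicates its posterior
#' belief).  Spiking mode draws independent Bernoulli samples with
#' success probability `pi_j * f_max * dt`.
#'
#' @param pi Probability vector (softmax output).
#' @param variant An [activation_variant()].
#' @param dt Timestep (s).
#' @return Activity vector: probabilities (rate) or a 0/1 vector (spiking).
#' @export
sample_spikes <- function(pi, variant, dt) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  if (variant$mode == "rate") return(pi)
  mu <- variant$f_max * dt
  stopifnot(mu > 0, mu <= 1)
  as.numeric(runif(length(pi)) < pi * mu)
}

#' Simulate spike counts over many timesteps
#'
#' Repeatedly samples spikes from a fixed posterior `pi` and accumulates
#' per-unit counts; the long-run workhorse behind firing-statistics
#' measurements.  The per-step Bernoulli draws use the same generator
#' call order as [sample_spikes()].
#'
#' @param pi Fixed probability vector.
#' @param variant An [activation_variant()] (must be spiking).
#' @param dt Timestep (s).
#' @param n_steps Number of timesteps to simulate.
#' @return Integer vector of spike counts per unit.
#' @export
simulate_spike_counts <- function(pi, variant, dt, n_steps) {
  stopifnot(variant$mode == "spiking", n_steps >= 1)
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  mu <- variant$f_max * dt
  stopifnot(mu > 0, mu <= 1)
  cpp_spike_counts(pi * mu, as.integer(n_steps))
}

#' Encode pixel intensities as external input currents
#'
#' Each pixel `u_j` in `[0, 1]` drives a 2-minicolumn hypercolumn (ON and
#' OFF units) with the log of the intensity:
#' `I_on = log(max(u, clip))`, `I_off = log(max(1 - u, clip))`.  After a
#' softmax with `tau_m = dt` and no other input this recovers
#' `pi = (u, 1 - u)` up to clipping; `u = 0.5` turns the pixel on at
#' chance level.
#'
#' @param u Pixel-intensity vector in `[0, 1]`.
#' @param clip Floor applied before the log (default `1e-10`).
#' @param base Log base: `"natural"` (default) or `"10"`.
#' @return Current vector of length `2 * length(u)`, interleaved ON/OFF.
#' @export
encode_input_current <- function(u, clip = 1e-10, base = c("natural", "10")) {
  base <- match.arg(base)
  if (any(u < 0 | u > 1)) stop("pixel intensities must lie in [0, 1]")
  lg <- if (base == "natural") log else log10
  out <- numeric(2 * length(u))
  out[seq(1, length(out), by = 2)] <- lg(pmax(u, clip))
  out[seq(2, length(out), by = 2)] <- lg(pmax(1 - u, clip))
  out
}
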