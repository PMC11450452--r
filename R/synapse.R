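# BCPNN synapse: z-trace / p-trace cascade and bias/weight transform for
# one projection between a pre- and a post-synaptic population.

#' Synapse (trace) parameters for one projection
#'
#' Bundles the time constants and the spike scaling factor used by the
#' trace cascade.  The spike scaling factor `mu_spk = f_max * dt` converts
#' a posterior probability into a per-timestep Bernoulli spike probability
#' and normalizes the z-trace increment so that the time-averaged z-trace
#' of a unit firing at probability `pi * mu_spk` per step recovers `pi`.
#'
#' @param tau_zi Pre-synaptic z-trace time constant (s).
#' @param tau_zj Post-synaptic z-trace time constant (s).
#' @param tau_p  P-trace time constant (s); the slow learning filter.
#' @param f_max  Maximum firing rate (Hz).  For rate-coded (non-spiking)
#'   projections use `f_max = 1/dt` so `mu_spk = 1` and the communicated
#'   signal is the posterior probability itself.
#' @param dt     Simulation timestep (s).
#' @param eps    Probability floor applied before the log transform; must
#'   be below `1/M` for every hypercolumn size `M` in the network.
#' @return An object of class `bcpnn_synapse_params`.
#' @export
synapse_params <- function(tau_zi = 0.020, tau_zj = 0.020, tau_p = 5,
                           f_max = 100, dt = 0.001, eps = 1e-4) {
  stopifnot(dt > 0, tau_zi >= dt, tau_zj >= dt, tau_p >= tau_zi,
            f_max > 0, eps > 0, eps < 1)
  mu_spk <- f_max * dt
  if (mu_spk > 1 + 1e-12)
    stop("f_max * dt must be <= 1 (spike probability cannot exceed 1)")
  structure(list(tau_zi = tau_zi, tau_zj = tau_zj, tau_p = tau_p,
                 f_max = f_max, dt = dt, mu_spk = mu_spk, eps = eps),
            class = "bcpnn_synapse_params")
}

#' Initial trace state for a projection
#'
#' z-traces start at zero; p-traces start at the uniform prior
#' (`1/M_pre`, `1/M_post`, and their product for the joint), so the
#' initial weights are exactly zero and the initial bias is `log(1/M)`.
#'
#' @param n_pre,n_post Number of pre-/post-synaptic minicolumn units.
#' @param m_pre,m_post Minicolumns per hypercolumn on each side (sets the
#'   uniform prior).
#' @return An object of class `bcpnn_trace_state` with fields `z_pre`,
#'   `z_post`, `p_pre`, `p_post` and the `n_pre x n_post` matrix `p_joint`.
#' @export
trace_state <- function(n_pre, n_post, m_pre, m_post) {
  stopifnot(n_pre >= 1, n_post >= 1, m_pre >= 2, m_post >= 2)
  structure(list(
    z_pre  = numeric(n_pre),
    z_post = numeric(n_post),
    p_pre  = rep(1 / m_pre, n_pre),
    p_post = rep(1 / m_post, n_post),
    p_joint = matrix(1 / (m_pre * m_post), n_pre, n_post)
  ), class = "bcpnn_trace_state")
}

check_spikes <- function(s, n, rate_mode = FALSE) {
  if (length(s) != n) stop("spike vector has wrong length")
  if (rate_mode) {
    if (any(s < 0 | s > 1)) stop("rate signal must lie in [0, 1]")
  } else if (any(s != 0 & s != 1)) {
    stop("spike input must be binary 0/1")
  }
  invisible(TRUE)
}

#' Advance the z-traces by one timestep
#'
#' Forward-Euler update of the short-term filters of the pre- and
#' post-synaptic spike trains:
#' `z <- z + (dt/tau_z) * (s/mu_spk - z)`, applied elementwise.
#'
#' @param state A `bcpnn_trace_state`.
#' @param s_pre,s_post Binary 0/1 spike vectors (or, for rate-coded
#'   signals with `mu_spk = 1`, probabilities in `[0,1]` with
#'   `rate_mode = TRUE`).
#' @param params A `bcpnn_synapse_params`.
#' @param rate_mode Accept continuous signals in `[0,1]` instead of 0/1.
#' @return The updated state.
#' @export
step_z_traces <- function(state, s_pre, s_post, params, rate_mode = FALSE) {
  check_spikes(s_pre, length(state$z_pre), rate_mode)
  check_spikes(s_post, length(state$z_post), rate_mode)
  ai <- params$dt / params$tau_zi
  aj <- params$dt / params$tau_zj
  state$z_pre  <- state$z_pre  + ai * (s_pre  / params$mu_spk - state$z_pre)
  state$z_post <- state$z_post + aj * (s_post / params$mu_spk - state$z_post)
  state
}

#' Advance the p-traces by one timestep
#'
#' Slow filters of the z-traces and of their outer product:
#' `p_i <- p_i + (dt/tau_p)(z_i - p_i)` and
#' `p_ij <- p_ij + (dt/tau_p)(z_i z_j - p_ij)`.  Call after
#' [step_z_traces()] so the p-traces see the current-step z-values.
#'
#' @inheritParams step_z_traces
#' @return The updated state.
#' @export
step_p_traces <- function(state, params) {
  a <- params$dt / params$tau_p
  state$p_pre  <- state$p_pre  + a * (state$z_pre  - state$p_pre)
  state$p_post <- state$p_post + a * (state$z_post - state$p_post)
  state$p_joint <- state$p_joint +
    a * (outer(state$z_pre, state$z_post) - state$p_joint)
  state
}

#' Bias and weight from the p-traces
#'
#' The bias is the log prior of the post-synaptic unit and the weight the
#' point-wise mutual information between pre- and post-synaptic units:
#' `b_j = log p_j`, `w_ij = log(p_ij / (p_i p_j))` (natural log).
#' Probabilities are floored at `eps` (the joint at `eps^2`) so every
#' entry is finite.
#'
#' @inheritParams step_z_traces
#' @return A list with `bias` (length `n_post`) and `weight`
#'   (`n_pre x n_post`), both in nats.
#' @export
compute_bias_weight <- function(state, params) {
  eps <- params$eps
  pi_ <- pmax(state$p_pre, eps)
  pj  <- pmax(state$p_post, eps)
  pij <- pmax(state$p_joint, eps^2)
  list(bias = log(pj),
       weight = log(pij / outer(pi_, pj)))
}

#' Projection weights container
#'
#' Couples the learned `bias`/`weight` with the binary minicolumn-level
#' connectivity `conn` (the patch-level mask expanded so that every
#' minicolumn pair of an active hypercolumn patch is connected).
#'
#' @param bias Numeric vector over post-synaptic units (nats).
#' @param weight Numeric `n_pre x n_post` matrix (nats).
#' @param conn Binary `n_pre x n_post` matrix; silent entries transmit no
#'   current but their traces keep updating ("Hebbian probes").
#' @return An object of class `bcpnn_projection_weights`.
#' @export
projection_weights <- function(bias, weight, conn = NULL) {
  if (is.null(conn)) conn <- matrix(1, nrow(weight), ncol(weight))
  stopifnot(length(bias) == ncol(weight),
            all(dim(conn) == dim(weight)),
            all(conn %in% c(0, 1)))
  structure(list(bias = bias, weight = weight, conn = conn),
            class = "bcpnn_projection_weights")
}
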