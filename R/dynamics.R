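# Single-neuron dynamics: conductance-based leaky integrate-and-fire solved
# by exact integration (closed-form propagator of the linear membrane ODE
# with conductances frozen over the update interval), with sub-cycling.
#
#   tau_m dv/dt = (v_rest - v) + g_e^(E_e - v) + g_i^(E_i - v) + i^
#
# where g^ = g * tau_m / cm is the dimensionless normalized conductance and
# i^ = i_offset * tau_m / cm is in mV. With g^ frozen over an interval h the
# exact update is
#
#   v_inf  = (v_rest + g_e^ E_e + g_i^ E_i + i^) / (1 + g_e^ + g_i^)
#   tau_ef = tau_m / (1 + g_e^ + g_i^)
#   v     <- v_inf + (v - v_inf) exp(-h / tau_ef)
#
# Conductances decay as g <- g exp(-h / tau_syn) each sub-cycle, before the
# membrane propagator. Spikes are resolved once per full timestep dt.
#
# These R functions are the reference, scalar formulation; the network engine
# (src/engine.cpp) applies the identical update order.

#' Simulation configuration
#'
#' @param dt timestep (ms); spikes are emitted at this resolution
#' @param n_sc sub-cycles per timestep: the state is advanced `n_sc` times by
#'   `dt/n_sc` within each timestep, keeping the frozen-conductance
#'   assumption accurate under fast transients
#' @param arithmetic `"float64"` (double-precision reference) or `"fixed"`
#'   (emulated s16.15 state arithmetic with 16-bit coded weights)
#' @return list of class `sim_config`
#' @export
sim_config <- function(dt = 0.1, n_sc = 2L, arithmetic = c("float64", "fixed")) {
  arithmetic <- match.arg(arithmetic)
  stopifnot(dt > 0, n_sc >= 1)
  structure(list(dt = dt, n_sc = as.integer(n_sc), arithmetic = arithmetic),
            class = "sim_config")
}

#' Initial state of one neuron
#'
#' @param params [cell_params()]
#' @return list with `v` (mV, at rest), `g_exc`, `g_inh` (uS) and
#'   `refract_left` (timesteps)
#' @export
neuron_state <- function(params) {
  list(v = params$v_rest, g_exc = 0, g_inh = 0, refract_left = 0L)
}

#' Exponential decay factor over an interval
#'
#' `exp(-h / tau)`: the exact-integration propagator of a first-order linear
#' decay with time constant `tau` over an interval `h`.
#'
#' @param tau time constant (ms), positive
#' @param h interval (ms), non-negative
#' @return factor in (0, 1]
#' @export
decay_factor <- function(tau, h) {
  if (any(tau <= 0)) stop("decay_factor: tau must be positive")
  if (any(h < 0)) stop("decay_factor: h must be non-negative")
  exp(-h / tau)
}

#' Decay synaptic conductances over an interval
#'
#' Applies the exact exponential decay independently to the excitatory and
#' inhibitory conductance with their respective time constants. Spike
#' contributions for a timestep are added by the engine before the first
#' decay of that timestep.
#'
#' @param state neuron state (see [neuron_state()])
#' @param params [cell_params()]
#' @param h interval (ms)
#' @return updated state
#' @export
decay_conductance <- function(state, params, h) {
  state$g_exc <- state$g_exc * decay_factor(params$tau_syn_e, h)
  state$g_inh <- state$g_inh * decay_factor(params$tau_syn_i, h)
  state
}

#' Advance the membrane potential over an interval (exact propagator)
#'
#' Applies the closed-form solution of the membrane equation with the current
#' conductances frozen over `h`. Threshold, reset and refractory handling are
#' resolved by the caller once per full timestep (see [step_subcycled()]);
#' this function only advances the sub-threshold voltage, and leaves the
#' voltage clamped while the neuron is refractory.
#'
#' @inheritParams decay_conductance
#' @return updated state
#' @export
step_membrane <- function(state, params, h) {
  if (state$refract_left > 0L) {
    state$v <- params$v_reset
    return(state)
  }
  gl <- params$cm / params$tau_m
  ge <- state$g_exc / gl
  gi <- state$g_inh / gl
  ih <- params$i_offset / gl
  den <- 1 + ge + gi
  v_inf <- (params$v_rest + ge * params$e_rev_e + gi * params$e_rev_i + ih) / den
  state$v <- v_inf + (state$v - v_inf) * exp(-h * den / params$tau_m)
  state
}

#' Advance one full timestep with sub-cycling
#'
#' Applies `n_sc` sequential (conductance decay; membrane propagator) pairs
#' with `h = dt/n_sc`, then resolves threshold crossing once at timestep
#' resolution: if `v >= v_thresh`, a spike is emitted, `v` is reset and the
#' neuron becomes refractory for `round(tau_refract/dt)` timesteps (ties
#' round up). While refractory the voltage stays clamped at `v_reset` and
#' conductances continue to decay (and accumulate).
#'
#' @inheritParams decay_conductance
#' @param dt full timestep (ms)
#' @param n_sc sub-cycles
#' @return list `(state, spiked)`
#' @export
step_subcycled <- function(state, params, dt, n_sc = 1L) {
  stopifnot(n_sc >= 1)
  h <- dt / n_sc
  refractory <- state$refract_left > 0L
  for (k in seq_len(n_sc)) {
    state <- decay_conductance(state, params, h)
    state <- step_membrane(state, params, h)
  }
  spiked <- FALSE
  if (refractory) {
    state$refract_left <- state$refract_left - 1L
    state$v <- params$v_reset
  } else if (state$v >= params$v_thresh) {
    spiked <- TRUE
    state$v <- params$v_reset
    state$refract_left <- refractory_steps(params$tau_refract, dt)
  }
  list(state = state, spiked = spiked)
}

# round(tau_refract/dt) with ties rounding up (floor(x + 0.5))
refractory_steps <- function(tau_refract, dt) {
  as.integer(floor(tau_refract / dt + 0.5))
}

#' Intrinsic tonic firing rate of a cell under constant current
#'
#' Closed-form leaky integrate-and-fire period under the offset current
#' alone: `tau_refract + tau_m * log((v_inf - v_reset)/(v_inf - v_thresh))`,
#' where `v_inf = v_rest + i_offset * tau_m / cm`. Returns 0 if the cell
#' never reaches threshold. Used as an analytic cross-check of the solver.
#'
#' @param params [cell_params()]
#' @return firing rate (Hz)
#' @export
intrinsic_rate <- function(params) {
  v_inf <- params$v_rest + params$i_offset * params$tau_m / params$cm
  if (v_inf <= params$v_thresh) return(0)
  period <- params$tau_refract +
    params$tau_m * log((v_inf - params$v_reset) / (v_inf - params$v_thresh))
  1000 / period
}
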