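#' Create a single-synapse state
#'
#' Reference (pure-R) representation of one synapse's dynamic state, used
#' to document and test the conductance model that the compiled network
#' engine implements in aggregated form.
#'
#' @param s HSP scaling factor (multiplies the initial peak conductance).
#' @return List with conductance `g` (AMPA or GABA), NMDA components
#'   `x_fast`/`x_slow`, depression efficacy `D`, and scaling factor `s`.
#' @export
synapse_state <- function(s = 1) {
  list(g = 0, x_fast = 0, x_slow = 0, D = 1, s = s)
}

#' Presynaptic spike update for one synapse
#'
#' On a presynaptic spike the conductance rises instantaneously by
#' `ghat * s * D` (AMPA and both NMDA components for excitatory kinds;
#' GABA uses D = 1) and, for excitatory kinds, the depression efficacy is
#' then reduced: `D <- (1 - d) * D`.
#'
#' @param state a [synapse_state()].
#' @param synapse synapse parameter list (see [default_params()]`$synapse`).
#' @param kind `"PP"`, `"IP"`, `"PI"`, or `"II"` (presynaptic type first).
#' @param ghat initial peak conductance; defaults to the kind's entry.
#' @return Updated state.
#' @export
on_presyn_spike <- function(state, synapse, kind = "PP", ghat = NULL) {
  if (is.null(ghat))
    ghat <- synapse[[c(PP = "ghat_pp", IP = "ghat_ip",
                       PI = "ghat_pi", II = "ghat_ii")[[kind]]]]
  excit <- kind %in% c("PP", "PI")
  inc <- ghat * state$s * (if (excit) state$D else 1)
  state$g <- state$g + inc
  if (excit && kind == "PP") {
    state$x_fast <- state$x_fast + inc
    state$x_slow <- state$x_slow + inc
  }
  if (excit) state$D <- (1 - synapse$d) * state$D
  state
}

#' Exponential decay step for one synapse
#'
#' Conductances decay with their time constants and the depression
#' efficacy recovers toward 1 with `tau_d`.
#'
#' @inheritParams on_presyn_spike
#' @param dt time step, ms.
#' @param kind synapse kind (selects the AMPA or GABA decay constant).
#' @return Updated state.
#' @export
decay_step <- function(state, synapse, dt, kind = "PP") {
  stopifnot(dt > 0)
  tau_g <- if (kind %in% c("PP", "PI")) synapse$tau_ampa else synapse$tau_gaba
  state$g <- state$g * exp(-dt / tau_g)
  state$x_fast <- state$x_fast * exp(-dt / synapse$tau_nmda_fast)
  state$x_slow <- state$x_slow * exp(-dt / synapse$tau_nmda_slow)
  state$D <- 1 - (1 - state$D) * exp(-dt / synapse$tau_d)
  state
}

#' Synaptic current through one synapse
#'
#' `I = sum_components g_c * (V_post - E_c)`, outward positive; the NMDA
#' conductance is `nmda_scale * (x_slow - x_fast)` where the scale
#' normalizes the dual-exponential peak to `nmda_frac` of the AMPA peak.
#'
#' @inheritParams on_presyn_spike
#' @param V_post postsynaptic membrane potential, mV.
#' @return Current (same sign convention as [ml_derivatives()]).
#' @export
synaptic_current <- function(state, V_post, synapse, kind = "PP") {
  E <- if (kind %in% c("PP", "PI")) synapse$e_exc else synapse$e_gaba
  I <- state$g * (V_post - E)
  if (kind == "PP") {
    I <- I + nmda_scale(synapse) * max(0, state$x_slow - state$x_fast) *
      (V_post - synapse$e_exc)
  }
  I
}

# peak of exp(-t/ts) - exp(-t/tf) for unit increments
nmda_peak_value <- function(synapse) {
  tf <- synapse$tau_nmda_fast; ts <- synapse$tau_nmda_slow
  tpk <- log(ts / tf) * ts * tf / (ts - tf)
  exp(-tpk / ts) - exp(-tpk / tf)
}

nmda_scale <- function(synapse) synapse$nmda_frac / nmda_peak_value(synapse)

#' Homogeneous Poisson afferent event times
#'
#' Draws the event times of the afferent (external) drive for one neuron
#' over `[t0, t1)` at a constant rate.
#'
#' @param rate event rate, Hz.
#' @param t0,t1 window bounds, ms.
#' @return Sorted numeric vector of event times in ms.
#' @export
afferent_events <- function(rate, t0 = 0, t1 = 1000) {
  stopifnot(t1 > t0, rate >= 0)
  n <- stats::rpois(1, rate * (t1 - t0) / 1000)
  sort(stats::runif(n, t0, t1))
}

#' Steady-state pre-spike depression under periodic firing
#'
#' Closed-form fixed point of the per-spike map
#' `D_next = 1 - (1 - (1 - d) D) exp(-T / tau_d)` for inter-spike
#' interval `T`:
#' `D* = (1 - exp(-T/tau_d)) / (1 - (1 - d) exp(-T/tau_d))`.
#'
#' @param T_ms inter-spike interval, ms.
#' @param synapse synapse parameter list.
#' @return The steady-state pre-spike efficacy.
#' @export
depression_fixed_point <- function(T_ms, synapse) {
  e <- exp(-T_ms / synapse$tau_d)
  (1 - e) / (1 - (1 - synapse$d) * e)
}
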