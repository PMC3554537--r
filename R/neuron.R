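#' Morris--Lecar derivatives (reference implementation)
#'
#' Right-hand side of the single-compartment Morris--Lecar equations with
#' instantaneous fast activation, a sigmoidal recovery steady state, a
#' cosh-shaped recovery time scale, and a spike-triggered adaptation
#' current `g_ahp * z * (V - E_K)`:
#' \deqn{C \, dV/dt = -g_{Na} m_\infty(V)(V - E_{Na}) - g_K w (V - E_K)
#'   - g_L (V - E_L) - g_{AHP} z (V - E_K) - I_{total}}
#' \deqn{dw/dt = \phi \cosh\!\big((V - V_3)/(2 V_4)\big)\,(w_\infty(V) - w)}
#' with \eqn{m_\infty(V) = (1 + \tanh((V - V_1)/V_2))/2} and
#' \eqn{w_\infty(V) = (1 + \tanh((V - V_3)/V_4))/2}. `I_total` uses the
#' outward-positive convention, so an excitatory synaptic current
#' `g (V - E_exc)` is negative (depolarizing) below its reversal.
#'
#' This pure-R form is the reference against which the compiled network
#' stepper is verified; use [simulate_network()] for actual simulations.
#'
#' @param V membrane potential, mV.
#' @param w recovery gate in `[0, 1]`.
#' @param z adaptation gate in `[0, 1]` (ignored when `g_ahp = 0`).
#' @param neuron list of membrane parameters (see [default_params()]`$neuron`).
#' @param I_total total synaptic plus injected current, outward positive.
#' @return Named vector `c(dV = , dw = )`.
#' @export
ml_derivatives <- function(V, w, z, neuron, I_total = 0) {
  if (!all(is.finite(c(V, w, z, I_total)))) stop("non-finite state or input")
  p <- neuron
  minf <- 0.5 * (1 + tanh((V - p$v1) / p$v2))
  winf <- 0.5 * (1 + tanh((V - p$v3) / p$v4))
  lamw <- p$phi * cosh((V - p$v3) / (2 * p$v4))
  dV <- (-p$g_na * minf * (V - p$e_na) - p$g_k * w * (V - p$e_k) -
           p$g_l * (V - p$e_l) - p$g_ahp * z * (V - p$e_k) - I_total) / p$C
  c(dV = unname(dV), dw = unname(lamw * (winf - w)))
}

#' Adaptation gate update
#'
#' The adaptation gate decays exponentially with time constant `tau_z` and
#' jumps by `delta_z` on each spike, clipped at 1.
#'
#' @param z current gate value.
#' @param neuron parameter list with `tau_z`, `delta_z`.
#' @param dt time step, ms.
#' @param spiked logical; did the neuron spike in this step?
#' @return Updated gate value.
#' @export
adaptation_step <- function(z, neuron, dt, spiked = FALSE) {
  stopifnot(dt > 0)
  z <- z * exp(-dt / neuron$tau_z)
  if (spiked) z <- min(1, z + neuron$delta_z)
  z
}

#' Firing rate of an isolated neuron under constant current (f-I point)
#'
#' Runs a single neuron with constant injected (depolarizing) current and
#' no synaptic input, discarding an initial transient.
#'
#' @param I_depol depolarizing current amplitude (positive values excite).
#' @param params full parameter list from [default_params()].
#' @param duration_ms,transient_ms simulated and discarded time, ms.
#' @param adapt include the adaptation current?
#' @return Firing rate in Hz.
#' @export
fi_point <- function(I_depol, params = default_params(),
                     duration_ms = 2000, transient_ms = 500, adapt = TRUE) {
  if (!adapt) params$neuron$g_ahp <- 0
  net <- single_neuron_input(params, I_inj = -I_depol)
  st <- init_state(1L, net$ndom, params)
  res <- run_core(net, params, st, total_ms = duration_ms + transient_ms,
                  hsp_on = FALSE)
  sum(res$spike_t > transient_ms) / (duration_ms / 1000)
}

# engine input for one synapse-free neuron (type PY)
single_neuron_input <- function(params, I_inj = 0, aff_rate = 0, type = "PY") {
  list(ntype = if (type == "PY") 0L else 1L,
       syn_post = integer(0), syn_kind = integer(0), syn_dom = integer(0),
       out_ptr = c(0L, 0L), out_syn = integer(0),
       aff_rate = aff_rate, I_inj = I_inj,
       ndom = 1L, dom_active = FALSE,
       dom_ptr = c(0L, 0L), dom_pre = integer(0), dom_post = 0L)
}

#' Calibrate afferent drive to the intact-network firing rates
#'
#' Searches the per-type afferent peak conductances until the intact
#' network's time-averaged PY rate is within `tol_py` of `target_py` and
#' the IN rate is within `tol_in` of `target_in`, by alternating bisection
#' on `ghat_aff_py` (driving the PY rate) and `ghat_aff_in` (driving the
#' IN rate) on a reduced lattice. Rates are monotone in their own drive
#' over the bracket, so each 1D search converges.
#'
#' @param params parameter list; the returned copy carries the calibrated
#'   `afferent$ghat_aff_py` / `ghat_aff_in`.
#' @param side_length lattice side of the calibration network.
#' @param duration_ms simulated time per rate evaluation, ms.
#' @param target_py,target_in target rates, Hz.
#' @param tol_py,tol_in acceptance tolerances, Hz.
#' @param bracket multiplicative search bracket around the current values.
#' @param max_rounds alternation rounds.
#' @param seed RNG seed.
#' @return `params` with calibrated afferent conductances and an attribute
#'   `"calibration"` recording the measured rates.
#' @export
calibrate_intact_rates <- function(params = default_params(),
                                   side_length = 20L, duration_ms = 10000,
                                   target_py = 5, target_in = 10,
                                   tol_py = 0.5, tol_in = 1,
                                   bracket = c(0.1, 4), max_rounds = 4,
                                   seed = 1L) {
  cfg <- lattice_config(side_length = side_length, seed = seed)
  net <- build_network(cfg)
  rates <- function(p) {
    set.seed(seed + 1L)
    sim <- simulate_network(net, params = p, total_ms = duration_ms,
                            hsp_on = FALSE, transient_ms = 1000)
    c(py = sim$rates$py, inh = sim$rates$inh)
  }
  measure <- function(gp, gi) {
    p <- params
    p$afferent$ghat_aff_py <- gp; p$afferent$ghat_aff_in <- gi
    rates(p)
  }
  gp <- params$afferent$ghat_aff_py; gi <- params$afferent$ghat_aff_in
  r <- measure(gp, gi)
  for (round in seq_len(max_rounds)) {
    if (abs(r[["py"]] - target_py) <= tol_py &&
        abs(r[["inh"]] - target_in) <= tol_in) break
    # bisection on the PY drive
    lo <- gp * bracket[1]; hi <- gp * bracket[2]
    r_lo <- measure(lo, gi); r_hi <- measure(hi, gi)
    if (r_lo[["py"]] > target_py || r_hi[["py"]] < target_py)
      stop("calibration failed to bracket the PY target rate (",
           sprintf("rate(%.3g) = %.2f, rate(%.3g) = %.2f", lo, r_lo[["py"]],
                   hi, r_hi[["py"]]), ")")
    for (it in 1:10) {
      mid <- (lo + hi) / 2
      rm <- measure(mid, gi)
      if (rm[["py"]] > target_py) hi <- mid else lo <- mid
      if (abs(rm[["py"]] - target_py) <= tol_py / 2) break
    }
    gp <- (lo + hi) / 2
    # bisection on the IN drive
    lo <- gi * bracket[1]; hi <- gi * bracket[2]
    r_lo <- measure(gp, lo); r_hi <- measure(gp, hi)
    if (r_lo[["inh"]] > target_in || r_hi[["inh"]] < target_in)
      stop("calibration failed to bracket the IN target rate")
    for (it in 1:10) {
      mid <- (lo + hi) / 2
      rm <- measure(gp, mid)
      if (rm[["inh"]] > target_in) hi <- mid else lo <- mid
      if (abs(rm[["inh"]] - target_in) <= tol_in / 2) break
    }
    gi <- (lo + hi) / 2
    r <- measure(gp, gi)
  }
  params$afferent$ghat_aff_py <- gp
  params$afferent$ghat_aff_in <- gi
  attr(params, "calibration") <- list(rates = r, side_length = side_length,
                                      duration_ms = duration_ms)
  params
}
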