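#' Trauma (deafferentation) configuration
#'
#' @param pattern `"focal"` (contiguous block of whole columns anchored at
#'   the left lattice edge) or `"diffuse"` (uniform random subset).
#' @param f_d fraction of neurons deafferented ("trauma volume"), in
#'   `[0, 1]`.
#' @param deaff_rate_factor afferent rate multiplier for deafferented
#'   neurons (default 0.1: rate drops from 100 Hz to 10 Hz).
#' @param seed RNG seed for the diffuse pattern.
#' @return An object of class `trauma_config`.
#' @export
trauma_config <- function(pattern = c("focal", "diffuse"), f_d = 0.5,
                          deaff_rate_factor = 0.1, seed = 1L) {
  pattern <- match.arg(pattern)
  if (f_d < 0 || f_d > 1) stop("f_d must lie in [0, 1]")
  if (deaff_rate_factor < 0 || deaff_rate_factor > 1)
    stop("deaff_rate_factor must lie in [0, 1]")
  structure(list(pattern = pattern, f_d = f_d,
                 deaff_rate_factor = deaff_rate_factor,
                 seed = as.integer(seed)),
            class = "trauma_config")
}

#' Select the deafferented neuron set
#'
#' Focal trauma deafferents the smallest block of whole left-edge columns
#' holding at least `f_d * N` neurons; diffuse trauma draws a uniform
#' random subset of size `ceiling(f_d * N)`. Both PY and IN neurons are
#' included.
#'
#' @param network an `ml_network`.
#' @param config a [trauma_config()].
#' @return Integer vector of deafferented neuron indices (1-based).
#' @export
apply_trauma <- function(network, config) {
  stopifnot(inherits(config, "trauma_config"))
  nn <- network$neurons
  N <- nrow(nn)
  n_target <- ceiling(config$f_d * N)
  if (n_target == 0L) return(integer(0))
  if (config$pattern == "focal") {
    L <- network$config$side_length
    ncols <- ceiling(n_target / L)
    nn$index[nn$x < ncols]
  } else {
    set.seed(config$seed)
    sort(sample.int(N, n_target))
  }
}

#' Exponential-moving-average firing-rate estimate
#'
#' Evaluates, at time `t_end`, the exponentially weighted rate estimator
#' `r(t) = sum_k (1/tau) exp(-(t - t_k)/tau)` over each neuron's spike
#' times, in Hz. This is the same estimator the simulation engine updates
#' online to drive the HSP rule.
#'
#' @param spikes data frame with columns `t` (ms) and `neuron` (1-based).
#' @param n_neurons number of neurons.
#' @param tau_rate estimator time constant, seconds.
#' @param t_end evaluation time, ms (default: last spike time).
#' @return Numeric vector of per-neuron rate estimates, Hz.
#' @export
estimate_rates <- function(spikes, n_neurons, tau_rate = 2,
                           t_end = max(spikes$t, 0)) {
  stopifnot(tau_rate > 0)
  tau_ms <- tau_rate * 1000
  r <- numeric(n_neurons)
  if (nrow(spikes)) {
    wt <- exp(-(t_end - spikes$t) / tau_ms) * (1000 / tau_ms)
    acc <- tapply(wt, spikes$neuron, sum)
    r[as.integer(names(acc))] <- acc
  }
  r
}

#' Random equal partition of a PY neuron's inputs into microdomains
#'
#' Deals a random permutation of the incoming synapse rows round-robin
#' into `M` groups, so group sizes differ by at most one.
#'
#' @param n_synapses number of incoming synapses of the neuron.
#' @param M number of microdomains.
#' @return Integer vector of domain indices in `1..M`, one per synapse.
#' @export
partition_round_robin <- function(n_synapses, M) {
  stopifnot(M >= 1)
  if (n_synapses == 0L) return(integer(0))
  dom <- rep_len(seq_len(M), n_synapses)
  dom[sample.int(n_synapses)] <- dom
  dom
}

#' Microdomain maps over a network
#'
#' `partition_random()` assigns every incoming synapse of every PY neuron
#' (excitatory and inhibitory alike) to exactly one of `M` microdomains,
#' randomly and as equally as possible. `partition_segregated()` builds
#' the two-domain map keyed by presynaptic deafferentation status: domain
#' 1 holds synapses from intact presynaptic neurons, domain 2 those from
#' deafferented ones. Domains without any glutamatergic (PY->PY) synapse
#' are inactive: they take no part in HSP.
#'
#' @param network a connected `ml_network`.
#' @param M number of microdomains per PY neuron.
#' @return An object of class `microdomain_map`: `domain` (integer per
#'   synapse row, `NA` for synapses onto IN neurons), `M_of` (domain count
#'   per neuron), and `M`.
#' @export
partition_random <- function(network, M = 1L) {
  M <- as.integer(M)
  stopifnot(M >= 1L)
  nn <- network$neurons
  syn <- network$synapses
  onto_py <- nn$type[syn$post] == "PY"
  domain <- rep(NA_integer_, nrow(syn))
  rows_by_post <- split(which(onto_py), syn$post[onto_py])
  for (rows in rows_by_post)
    domain[rows] <- partition_round_robin(length(rows), M)
  M_of <- ifelse(nn$type == "PY", M, 0L)
  structure(list(domain = domain, M_of = M_of, M = M, segregated = FALSE),
            class = "microdomain_map")
}

#' @rdname partition_random
#' @param deaff deafferented neuron indices from [apply_trauma()].
#' @export
partition_segregated <- function(network, deaff) {
  nn <- network$neurons
  syn <- network$synapses
  is_deaff <- rep(FALSE, nrow(nn)); is_deaff[deaff] <- TRUE
  onto_py <- nn$type[syn$post] == "PY"
  domain <- rep(NA_integer_, nrow(syn))
  domain[onto_py] <- ifelse(is_deaff[syn$pre[onto_py]], 2L, 1L)
  M_of <- ifelse(nn$type == "PY", 2L, 0L)
  structure(list(domain = domain, M_of = M_of, M = 2L, segregated = TRUE),
            class = "microdomain_map")
}

#' One homeostatic update step (reference implementation)
#'
#' The per-domain update of the excitatory and inhibitory scaling factors:
#' with `u` the upregulating drive and `v` the downregulating drive,
#' \deqn{ds_{exc}/dt = \kappa [\max(0, 1 - u/r_t) - \max(0, v/r_t - 1)]}
#' and the GABA factor moves with the opposite sign. The drives per
#' scheme: `local` uses the domain's presynaptic-set mean for `u` and the
#' postsynaptic neuron's own rate for `v`; `global` uses the network PY
#' mean for both; `global_up_local_down` uses the global mean for `u` and
#' the neuron's own rate for `v`; `global_up_no_down` drops the `v` term.
#' Factors are clipped to `[s_min, s_max]`.
#'
#' This mirrors the engine's compiled update and is used to verify it.
#'
#' @param s_exc,s_inh current scaling factors (per domain).
#' @param u,v drive rates, Hz.
#' @param hsp HSP parameter list (see [default_params()]`$hsp`).
#' @param dt_s elapsed time, seconds.
#' @param no_down drop the downregulating term?
#' @return List with updated `s_exc`, `s_inh`.
#' @export
hsp_step <- function(s_exc, s_inh, u, v, hsp, dt_s, no_down = FALSE) {
  up <- pmax(0, 1 - u / hsp$r_target)
  down <- if (no_down) 0 else pmax(0, v / hsp$r_target - 1)
  ds <- hsp$kappa * (up - down) * dt_s
  list(s_exc = pmin(hsp$s_max, pmax(hsp$s_min, s_exc + ds)),
       s_inh = pmin(hsp$s_max, pmax(hsp$s_min, s_inh - ds)))
}

#' Percent change of a conductance relative to its intact value
#'
#' @param g current conductance.
#' @param g_intact conductance in the corresponding intact model (> 0).
#' @return `100 * (g - g_intact) / g_intact`.
#' @export
scaling_percentage <- function(g, g_intact) {
  if (any(g_intact <= 0)) stop("intact conductance must be positive")
  100 * (g - g_intact) / g_intact
}

#' Per-synapse HSP scaling factors from a simulation
#'
#' Expands the engine's per-domain scaling factors back to one value per
#' synapse row of the network (NA for synapses onto IN neurons, which are
#' not scaled).
#'
#' @param sim an `ml_sim` from [simulate_network()] or a phase of
#'   [run_simulation()].
#' @return List with numeric vectors `s_exc`, `s_inh` (per synapse row;
#'   the applicable one is non-NA depending on synapse kind), and the
#'   per-domain vectors.
#' @export
synapse_scaling <- function(sim) {
  eng <- sim$engine
  dom <- eng$syn_dom
  s_exc <- s_inh <- rep(NA_real_, length(dom))
  has <- dom >= 0L
  s_exc[has & eng$syn_kind == 0L] <- sim$state$s_exc[dom[has & eng$syn_kind == 0L] + 1L]
  s_inh[has & eng$syn_kind == 1L] <- sim$state$s_inh[dom[has & eng$syn_kind == 1L] + 1L]
  list(s_exc = s_exc, s_inh = s_inh,
       dom_s_exc = sim$state$s_exc, dom_s_inh = sim$state$s_inh,
       dom_active = eng$dom_active)
}

#' Per-domain presynaptic rate averages
#'
#' For every microdomain of every PY neuron, the mean firing rate of the
#' distinct PY neurons presynaptic to that domain (each presynaptic
#' neuron weighted equally), plus the global PY mean — the drive terms of
#' the homeostatic rule.
#'
#' @param network a connected `ml_network`.
#' @param rates per-neuron firing rates, Hz (see [estimate_rates()]).
#' @param map a microdomain map, or `NULL` for one domain per neuron.
#' @return Data frame with `post`, `domain`, `n_pre` (distinct
#'   presynaptic PY partners), and `r_pre` (their mean rate; `NA` for
#'   domains without glutamatergic input), with the global PY mean rate
#'   in attribute `"r_glob"`.
#' @export
domain_presyn_rates <- function(network, rates, map = NULL) {
  nn <- network$neurons
  syn <- network$synapses
  onto_py <- nn$type[syn$post] == "PY"
  glut <- onto_py & nn$type[syn$pre] == "PY"
  dom <- if (is.null(map)) rep(1L, nrow(syn)) else map$domain
  key <- paste(syn$post[glut], dom[glut], sep = ".")
  pre_sets <- lapply(split(syn$pre[glut], key), unique)
  parts <- strsplit(names(pre_sets), ".", fixed = TRUE)
  out <- data.frame(
    post = vapply(parts, function(x) as.integer(x[1]), integer(1)),
    domain = vapply(parts, function(x) as.integer(x[2]), integer(1)),
    n_pre = vapply(pre_sets, length, integer(1)),
    r_pre = vapply(pre_sets, function(v) mean(rates[v]), numeric(1)))
  out <- out[order(out$post, out$domain), ]
  rownames(out) <- NULL
  attr(out, "r_glob") <- mean(rates[nn$index[nn$type == "PY"]])
  out
}
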