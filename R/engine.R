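# Glue between the R-level network / trauma / microdomain objects and the
# compiled integration core.

kind_code <- c(PP = 0L, IP = 1L, PI = 2L, II = 3L)

# Build the flat input list consumed by sim_core_cpp.
#   network : ml_network with synapses
#   deaff   : integer vector of deafferented neuron indices (1-based)
#   map     : microdomain_map or NULL (one domain per PY neuron)
#   deaff_rate_factor : afferent rate multiplier for deafferented neurons
sim_engine_input <- function(network, params, deaff = integer(0), map = NULL,
                             deaff_rate_factor = 0.1, I_inj = NULL) {
  nn <- network$neurons
  syn <- network$synapses
  N <- nrow(nn)
  ntype <- ifelse(nn$type == "IN", 1L, 0L)
  nsyn <- nrow(syn)
  kind <- unname(kind_code[syn$kind])
  if (nsyn > 0 && anyNA(kind)) stop("unknown synapse kind")

  # --- microdomains: global domain ids for synapses onto PY neurons ---
  py_idx <- which(ntype == 0L)
  onto_py <- if (nsyn > 0) ntype[syn$post] == 0L else logical(0)
  if (is.null(map)) {
    dom_local <- rep(1L, nsyn)         # single domain per PY
    M_of <- rep(1L, N); M_of[ntype == 1L] <- 0L
  } else {
    dom_local <- map$domain
    M_of <- map$M_of
  }
  offs <- integer(N)                    # global offset per neuron
  offs[py_idx] <- cumsum(c(0L, M_of[py_idx]))[seq_along(py_idx)]
  ndom <- sum(M_of[py_idx])
  syn_dom <- rep(-1L, nsyn)
  if (nsyn > 0 && any(onto_py)) {
    syn_dom[onto_py] <- offs[syn$post[onto_py]] + dom_local[onto_py] - 1L
    if (anyNA(syn_dom[onto_py])) stop("microdomain map does not cover all synapses onto PY neurons")
  }
  dom_post <- integer(ndom)
  for (i in py_idx) dom_post[offs[i] + seq_len(M_of[i])] <- i - 1L
  # presynaptic PY sets per domain (unique presyn neurons, equally weighted)
  dom_active <- rep(FALSE, ndom)
  dom_ptr <- integer(ndom + 1L)
  dom_pre <- integer(0)
  if (nsyn > 0) {
    glut <- which(onto_py & kind == 0L)   # PY->PY synapses
    if (length(glut)) {
      key <- split(syn$pre[glut] - 1L, syn_dom[glut])
      sets <- lapply(key, function(v) sort(unique(v)))
      lens <- integer(ndom)
      ids <- as.integer(names(sets)) + 1L  # 1-based into domain arrays
      lens[ids] <- vapply(sets, length, integer(1))
      dom_ptr <- cumsum(c(0L, lens))
      dom_pre <- integer(dom_ptr[ndom + 1L])
      for (k in seq_along(sets)) {
        m <- ids[k]
        if (lens[m] > 0) dom_pre[(dom_ptr[m] + 1L):dom_ptr[m + 1L]] <- sets[[k]]
      }
      dom_active[ids] <- TRUE
    }
  }

  # outgoing CSR over presynaptic neuron
  if (nsyn > 0) {
    ord <- order(syn$pre)
    out_syn <- ord - 1L
    out_ptr <- cumsum(c(0L, tabulate(syn$pre, nbins = N)))
  } else {
    out_syn <- integer(0); out_ptr <- integer(N + 1L)
  }

  aff_rate <- rep(params$afferent$rate, N)
  if (length(deaff)) aff_rate[deaff] <- aff_rate[deaff] * deaff_rate_factor
  if (is.null(I_inj)) I_inj <- numeric(N)

  list(ntype = ntype,
       syn_post = syn$post - 1L, syn_kind = kind, syn_dom = syn_dom,
       out_ptr = as.integer(out_ptr), out_syn = out_syn,
       aff_rate = aff_rate, I_inj = I_inj,
       ndom = as.integer(ndom), dom_active = dom_active,
       dom_ptr = as.integer(dom_ptr), dom_pre = as.integer(dom_pre),
       dom_post = as.integer(dom_post))
}

# Fresh state: rest at E_L with the recovery gate at its fixed point there.
init_state <- function(N, ndom, params) {
  p <- params$neuron
  winf <- 0.5 * (1 + tanh((p$e_l - p$v3) / p$v4))
  list(V = rep(p$e_l, N), w = rep(winf, N), z = numeric(N),
       D = rep(1, N), r = numeric(N),
       g_ampa = numeric(N), g_gaba = numeric(N),
       x_fast = numeric(N), x_slow = numeric(N), g_aff = numeric(N),
       s_exc = rep(1, max(ndom, 1L)), s_inh = rep(1, max(ndom, 1L)),
       in_spike = rep(FALSE, N))
}

flat_params <- function(params, hsp_on) {
  p <- params
  list(C = p$neuron$C, g_na = p$neuron$g_na, g_k = p$neuron$g_k,
       g_l = p$neuron$g_l, g_ahp = p$neuron$g_ahp,
       e_na = p$neuron$e_na, e_k = p$neuron$e_k, e_l = p$neuron$e_l,
       v1 = p$neuron$v1, v2 = p$neuron$v2, v3 = p$neuron$v3,
       v4 = p$neuron$v4, phi = p$neuron$phi,
       spike_threshold = p$neuron$spike_threshold,
       tau_z = p$neuron$tau_z, delta_z = p$neuron$delta_z,
       tau_ampa = p$synapse$tau_ampa, tau_gaba = p$synapse$tau_gaba,
       tau_nmda_fast = p$synapse$tau_nmda_fast,
       tau_nmda_slow = p$synapse$tau_nmda_slow,
       tau_d = p$synapse$tau_d, d = p$synapse$d,
       e_exc = p$synapse$e_exc, e_gaba = p$synapse$e_gaba,
       ghat_pp = p$synapse$ghat_pp, ghat_ip = p$synapse$ghat_ip,
       ghat_pi = p$synapse$ghat_pi, ghat_ii = p$synapse$ghat_ii,
       nmda_frac = p$synapse$nmda_frac,
       ghat_aff_py = p$afferent$ghat_aff_py,
       ghat_aff_in = p$afferent$ghat_aff_in,
       tau_aff = p$afferent$tau_aff, e_aff = p$afferent$e_aff,
       kappa = p$hsp$kappa, r_target = p$hsp$r_target,
       tau_rate_ms = p$hsp$tau_rate * 1000,
       s_min = p$hsp$s_min, s_max = p$hsp$s_max,
       dt_hsp_ms = p$hsp$dt_hsp,
       scheme = hsp_scheme_code(p$hsp$scheme),
       hsp_on = isTRUE(hsp_on))
}

run_core <- function(net, params, state, total_ms, hsp_on = FALSE,
                     dt = params$integrator$dt, t_offset = 0,
                     record_v_idx = integer(0), record_stride = 20L,
                     collect_spikes = TRUE, ts_stride = 0L) {
  ctrl <- list(dt = dt, total_ms = total_ms,
               record_v_idx = as.integer(record_v_idx),
               record_stride = as.integer(record_stride),
               collect_spikes = collect_spikes,
               ts_stride = as.integer(ts_stride), t_offset = t_offset)
  sim_core_cpp(net, flat_params(params, hsp_on), state, ctrl)
}

#' Simulate a network for a fixed duration
#'
#' Low-level single-phase driver: integrates the whole network for
#' `total_ms` milliseconds from a fresh (or supplied) state and returns the
#' spike raster plus summary rates. For the full intact -> trauma -> HSP ->
#' measurement pipeline use [run_simulation()].
#'
#' @param network a connected `ml_network`.
#' @param params parameter list from [default_params()].
#' @param total_ms simulated duration, ms.
#' @param deaff deafferented neuron indices (1-based).
#' @param map optional microdomain map (see [partition_random()]).
#' @param hsp_on enable homeostatic updates?
#' @param transient_ms initial window excluded from the rate summaries.
#' @param state optional state list to continue from.
#' @param deaff_rate_factor afferent rate multiplier for `deaff` neurons.
#' @param ts_stride steps between time-series samples (0 = none).
#' @param dt integration step, ms.
#' @return A list of class `ml_sim`: `spikes` (data frame `t`, `neuron`),
#'   `rates` (`py`, `inh` mean rates in Hz over the post-transient window,
#'   plus `per_neuron`), final `state`, `ts` time-series matrix, `network`
#'   dimensions, and bookkeeping fields.
#' @export
simulate_network <- function(network, params = default_params(),
                             total_ms = 10000, deaff = integer(0),
                             map = NULL, hsp_on = FALSE, transient_ms = 0,
                             state = NULL, deaff_rate_factor = 0.1,
                             ts_stride = 0L, dt = params$integrator$dt) {
  net <- sim_engine_input(network, params, deaff = deaff, map = map,
                          deaff_rate_factor = deaff_rate_factor)
  N <- nrow(network$neurons)
  if (is.null(state)) state <- init_state(N, net$ndom, params)
  res <- run_core(net, params, state, total_ms = total_ms, hsp_on = hsp_on,
                  dt = dt, ts_stride = ts_stride)
  spikes <- data.frame(t = res$spike_t, neuron = res$spike_i + 1L)
  win <- total_ms - transient_ms
  keep <- spikes$t > transient_ms
  per_neuron <- tabulate(spikes$neuron[keep], nbins = N) / (win / 1000)
  is_py <- network$neurons$type == "PY"
  structure(list(spikes = spikes,
                 rates = list(py = mean(per_neuron[is_py]),
                              inh = mean(per_neuron[!is_py]),
                              per_neuron = per_neuron),
                 state = res$state, ts = res$ts,
                 clip_events = res$clip_events,
                 total_ms = total_ms, transient_ms = transient_ms,
                 n_neurons = N, engine = net),
            class = "ml_sim")
}

#' @export
print.ml_sim <- function(x, ...) {
  cat(sprintf("ml_sim: %d neurons, %.1f s simulated, %d spikes (PY %.2f Hz, IN %.2f Hz)\n",
              x$n_neurons, x$total_ms / 1000, nrow(x$spikes),
              x$rates$py, x$rates$inh))
  invisible(x)
}
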