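#' Run the full trauma experiment pipeline
#'
#' Executes the standard phases: build the network, run the calibrated
#' intact network to equilibrium, apply trauma at `t = 0`, evolve under
#' the homeostatic rule until the steady-state criterion is met (network
#' PY rate within `steady_tol` Hz of the target for `steady_window_ms`,
#' or `max_hsp_ms` elapsed), then record a measurement window and analyze
#' it (burst detection over the pattern's sampling region, rate summaries,
#' scaling-factor statistics).
#'
#' @param lattice a [lattice_config()] (or a prebuilt `ml_network`).
#' @param trauma a [trauma_config()].
#' @param params parameter list from [default_params()]; `params$hsp`
#'   selects the HSP scheme and microdomain count `M` (with
#'   `segregated = TRUE` the two-domain status-keyed partition is used and
#'   `M` is ignored).
#' @param intact_ms intact equilibration time, ms.
#' @param max_hsp_ms cap on the HSP evolution phase, ms.
#' @param measure_ms measurement window, ms.
#' @param steady_tol,steady_window_ms steady-state criterion.
#' @param seed seed for all phase randomness.
#' @param sever destroy intact<->deafferented synapses before the
#'   post-trauma phases (control condition)?
#' @param keep_spikes keep the measurement raster in the result?
#' @return A list of class `trauma_run`: `summary` (burst rate, counts,
#'   rates, scaling statistics), `events`, `measure` (the measurement
#'   `ml_sim`), `network`, `deaff`, `map`, `hsp_converged`, `phases`.
#' @export
run_simulation <- function(lattice = lattice_config(side_length = 40L),
                           trauma = trauma_config(),
                           params = default_params(),
                           intact_ms = 5000, max_hsp_ms = 120000,
                           measure_ms = 50000,
                           steady_tol = 1, steady_window_ms = 10000,
                           seed = 1L, sever = FALSE, keep_spikes = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  if (inherits(lattice, "ml_network")) {
    network <- lattice
  } else {
    lattice$seed <- seed
    network <- build_network(lattice)
  }
  trauma$seed <- seed + 1L
  deaff <- apply_trauma(network, trauma)
  if (sever) network <- sever_boundary_connections(network, deaff)
  set.seed(seed + 2L)
  map <- if (isTRUE(params$hsp$segregated)) {
    partition_segregated(network, deaff)
  } else if (params$hsp$M > 1L) {
    partition_random(network, params$hsp$M)
  } else NULL

  # phase 1: intact equilibration (no trauma, no HSP)
  set.seed(seed + 3L)
  intact <- simulate_network(network, params, total_ms = intact_ms,
                             hsp_on = FALSE, map = map)
  # phase 2: trauma + HSP evolution, chunked for the steady-state check
  st <- intact$state
  chunk_ms <- max(steady_window_ms, 5000)
  elapsed <- 0; converged <- FALSE
  rate_trace <- numeric(0)
  while (elapsed < max_hsp_ms) {
    run_ms <- min(chunk_ms, max_hsp_ms - elapsed)
    ph <- simulate_network(network, params, total_ms = run_ms,
                           deaff = deaff, map = map, hsp_on = TRUE,
                           state = st,
                           deaff_rate_factor = trauma$deaff_rate_factor)
    st <- ph$state
    elapsed <- elapsed + run_ms
    rate_trace <- c(rate_trace, ph$rates$py)
    if (elapsed >= steady_window_ms &&
        abs(ph$rates$py - params$hsp$r_target) <= steady_tol) {
      converged <- TRUE
      break
    }
  }
  # phase 3: measurement (HSP stays on, as in the steady-state condition)
  measure <- simulate_network(network, params, total_ms = measure_ms,
                              deaff = deaff, map = map, hsp_on = TRUE,
                              state = st,
                              deaff_rate_factor = trauma$deaff_rate_factor)
  # analysis
  crit <- do.call(burst_criteria, params$analysis)
  recorded <- sampling_region(trauma$pattern, network)
  counts <- bin_raster(measure$spikes, crit$bin_ms, recorded,
                       t_start = 0, t_end = measure_ms)
  events <- detect_bursts(counts, crit)
  types <- network$neurons$type[recorded]
  ib <- intra_burst_stats(events, counts, types, crit$bin_ms)
  sc <- synapse_scaling(measure)
  is_deaff_pre <- rep(FALSE, nrow(network$neurons)); is_deaff_pre[deaff] <- TRUE
  pp <- which(measure$engine$syn_kind == 0L)
  s_pp <- sc$s_exc[pp]
  pre_deaff <- is_deaff_pre[network$synapses$pre[pp]]
  summary <- list(
    burst_rate_hz = burst_rate(events, measure_ms / 1000),
    n_bursts = nrow(events),
    py_rate_hz = measure$rates$py, in_rate_hz = measure$rates$inh,
    intact_py_rate_hz = intact$rates$py, intact_in_rate_hz = intact$rates$inh,
    intra_burst = ib,
    s_pp_mean = mean(s_pp, na.rm = TRUE),
    s_pp_sd = stats::sd(s_pp),
    s_pp_mean_deaff_pre = if (any(pre_deaff)) mean(s_pp[pre_deaff]) else NA_real_,
    s_pp_mean_intact_pre = if (any(!pre_deaff)) mean(s_pp[!pre_deaff]) else NA_real_,
    hsp_converged = converged,
    elapsed_s = proc.time()[["elapsed"]] - t_start)
  if (!keep_spikes) measure$spikes <- measure$spikes[0, ]
  structure(list(summary = summary, events = events, measure = measure,
                 network = network, deaff = deaff, map = map,
                 recorded = recorded, counts = counts,
                 rate_trace = rate_trace, hsp_converged = converged,
                 phases = list(intact_ms = intact_ms, hsp_ms = elapsed,
                               measure_ms = measure_ms),
                 seed = seed),
            class = "trauma_run")
}

#' @export
print.trauma_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("trauma_run: burst rate %.3f Hz (%d bursts), PY %.2f Hz,",
                     " IN %.2f Hz, HSP %s\n"),
              s$burst_rate_hz, s$n_bursts, s$py_rate_hz, s$in_rate_hz,
              if (x$hsp_converged) "converged" else "not converged"))
  invisible(x)
}

#' Sweep a grid of experiment conditions
#'
#' Runs [run_simulation()] over the Cartesian product of the supplied
#' axes with `replicates` independent seeds per point and collects the
#' summary metrics into one data frame. Individual-point failures are
#' isolated and reported as NA rows.
#'
#' @param f_d,scheme,M,pattern,footprint_half,segregated sweep axes
#'   (vectors; scalars fix the condition).
#' @param replicates seeds per grid point.
#' @param seed base seed; point `k`, replicate `j` uses
#'   `seed + 1000 * k + j`.
#' @param side_length lattice side for every point.
#' @param params base parameter list.
#' @param ... forwarded to [run_simulation()] (e.g. `measure_ms`,
#'   `max_hsp_ms`).
#' @return Data frame of per-run metrics, one row per (point, replicate).
#' @export
sweep_simulations <- function(f_d = 0.5, scheme = "local", M = 1L,
                              pattern = "focal", footprint_half = 5L,
                              segregated = FALSE, replicates = 1L,
                              seed = 1L, side_length = 40L,
                              params = default_params(), ...) {
  grid <- expand.grid(f_d = f_d, scheme = scheme, M = M, pattern = pattern,
                      footprint_half = footprint_half,
                      segregated = segregated,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    p <- params
    p$hsp$scheme <- g$scheme; p$hsp$M <- as.integer(g$M)
    p$hsp$segregated <- g$segregated
    res <- tryCatch({
      run <- run_simulation(
        lattice = lattice_config(side_length = side_length,
                                 footprint_half = g$footprint_half),
        trauma = trauma_config(pattern = g$pattern, f_d = g$f_d),
        params = p, seed = seed + 1000L * k + g$replicate,
        keep_spikes = FALSE, ...)
      s <- run$summary
      data.frame(g, burst_rate_hz = s$burst_rate_hz, n_bursts = s$n_bursts,
                 py_rate_hz = s$py_rate_hz, in_rate_hz = s$in_rate_hz,
                 spikes_per_burst_py =
                   if (s$n_bursts > 0) s$intra_burst$PY$spikes_per_neuron else NA,
                 s_pp_mean = s$s_pp_mean, s_pp_sd = s$s_pp_sd,
                 s_pp_mean_deaff_pre = s$s_pp_mean_deaff_pre,
                 s_pp_mean_intact_pre = s$s_pp_mean_intact_pre,
                 converged = run$hsp_converged, error = NA_character_)
    }, error = function(e) {
      data.frame(g, burst_rate_hz = NA, n_bursts = NA, py_rate_hz = NA,
                 in_rate_hz = NA, spikes_per_burst_py = NA, s_pp_mean = NA,
                 s_pp_sd = NA, s_pp_mean_deaff_pre = NA,
                 s_pp_mean_intact_pre = NA, converged = NA,
                 error = conditionMessage(e))
    })
    rows[[k]] <- res
  }
  do.call(rbind, rows)
}

#' Serialize / parse a configuration as JSON
#'
#' Round-trippable flat JSON document with sections for the lattice,
#' trauma, and model parameters.
#'
#' @param lattice a [lattice_config()].
#' @param trauma a [trauma_config()].
#' @param params a [default_params()] list.
#' @param path file path; `NULL` returns the JSON string.
#' @return `write_config`: the path or JSON string; `read_config`: a list
#'   with `lattice`, `trauma`, `params` reconstructed with their classes.
#' @export
write_config <- function(lattice, trauma, params, path = NULL) {
  doc <- list(network = unclass(lattice), trauma = unclass(trauma),
              params = params)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname write_config
#' @param x path to a JSON config, or a JSON string.
#' @export
read_config <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  lat <- do.call(lattice_config, doc$network)
  tra <- do.call(trauma_config, doc$trauma)
  par <- do.call(default_params, doc$params)
  list(lattice = lat, trauma = tra, params = par)
}

#' Deterministic tiny fixtures for the analysis layer
#'
#' Builds a small fixed-seed network and hand-constructed spike rasters
#' with known burst content, for testing the analysis operations without
#' running the simulator.
#'
#' @param seed RNG seed.
#' @return List: `network` (10x10), `burst_raster` (spike data frame over
#'   10 recorded neurons containing exactly 3 constructed bursts under the
#'   default criteria at `bin_ms = 100`, `f_min = 0.5`, `r_min = 20`),
#'   `recorded`, `silent_raster`, and `criteria`.
#' @export
make_fixtures <- function(seed = 42L) {
  net <- build_network(lattice_config(side_length = 10L, seed = seed))
  recorded <- 1:10
  crit <- burst_criteria()
  # three supra-threshold bins (2, 5, 9): 8/10 neurons fire 3 spikes each
  # (30 Hz mean); separated by sub-threshold bins.
  mk_bin <- function(bin, n_active, n_spikes) {
    t0 <- (bin - 1) * 100
    data.frame(t = rep(t0 + seq(5, 95, length.out = n_spikes), n_active),
               neuron = rep(seq_len(n_active), each = n_spikes))
  }
  burst_raster <- rbind(mk_bin(2, 8, 3), mk_bin(5, 8, 3), mk_bin(9, 8, 3),
                        mk_bin(3, 2, 1), mk_bin(7, 4, 5))
  burst_raster <- burst_raster[order(burst_raster$t), ]
  rownames(burst_raster) <- NULL
  list(network = net, burst_raster = burst_raster, recorded = recorded,
       silent_raster = data.frame(t = numeric(), neuron = integer()),
       criteria = crit, n_bursts = 3L, total_bins = 10L)
}

#' Write / read a spike raster as CSV
#'
#' Plain-text records `(time_ms, neuron_index)`, one spike per row.
#'
#' @param spikes data frame with columns `t` and `neuron` (e.g.
#'   `sim$spikes` from [simulate_network()]).
#' @param path CSV file path.
#' @return `write_raster` returns the path invisibly; `read_raster`
#'   returns the spikes data frame.
#' @export
write_raster <- function(spikes, path) {
  utils::write.csv(data.frame(time_ms = spikes$t, neuron_index = spikes$neuron),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  d <- utils::read.csv(path)
  data.frame(t = d$time_ms, neuron = d$neuron_index)
}
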