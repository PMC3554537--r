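#' Burst-detection criteria
#'
#' @param bin_ms bin width, ms (default 100).
#' @param f_min minimal fraction of recorded neurons active in a bin.
#' @param r_min minimal mean firing rate (Hz) of the active neurons in the
#'   bin.
#' @param merge_adjacent merge runs of consecutive supra-threshold bins
#'   into single events?
#' @return An object of class `burst_criteria`.
#' @export
burst_criteria <- function(bin_ms = 100, f_min = 0.5, r_min = 20,
                           merge_adjacent = TRUE) {
  if (bin_ms <= 0) stop("bin_ms must be positive")
  if (f_min <= 0 || f_min > 1) stop("f_min must lie in (0, 1]")
  if (r_min < 0) stop("r_min must be >= 0")
  structure(list(bin_ms = bin_ms, f_min = f_min, r_min = r_min,
                 merge_adjacent = isTRUE(merge_adjacent)),
            class = "burst_criteria")
}

#' Bin a spike raster into per-neuron counts
#'
#' Partitions time into non-overlapping left-closed bins `[t, t + bin)`
#' and counts spikes per recorded neuron and bin.
#'
#' @param spikes data frame with columns `t` (ms) and `neuron`.
#' @param bin_ms bin width, ms.
#' @param recorded integer vector of recorded neuron indices.
#' @param t_start,t_end window bounds, ms; `t_end` defaults to the last
#'   spike rounded up to a whole bin.
#' @return Integer matrix `[neuron, bin]` with rownames the recorded
#'   indices.
#' @export
bin_raster <- function(spikes, bin_ms = 100, recorded,
                       t_start = 0, t_end = NULL) {
  if (is.null(t_end))
    t_end <- if (nrow(spikes)) ceiling(max(spikes$t) / bin_ms) * bin_ms else bin_ms
  nbin <- max(1L, as.integer(ceiling((t_end - t_start) / bin_ms)))
  sel <- spikes$neuron %in% recorded & spikes$t >= t_start & spikes$t < t_end
  counts <- matrix(0L, nrow = length(recorded), ncol = nbin,
                   dimnames = list(recorded, NULL))
  if (any(sel)) {
    b <- floor((spikes$t[sel] - t_start) / bin_ms) + 1L
    n <- match(spikes$neuron[sel], recorded)
    tab <- table(factor(n, levels = seq_along(recorded)),
                 factor(b, levels = seq_len(nbin)))
    counts[] <- as.integer(tab)
  }
  counts
}

#' Detect paroxysmal bursting events
#'
#' A bin is supra-threshold iff at least `f_min` of the recorded neurons
#' fired in it AND the mean firing rate of those active neurons
#' (their counts divided by the bin duration) exceeds `r_min`. Runs of
#' consecutive supra-threshold bins are merged into one event when
#' `merge_adjacent` is set.
#'
#' @param counts matrix from [bin_raster()].
#' @param criteria a [burst_criteria()].
#' @return Data frame with one row per event: `start_bin`, `end_bin`
#'   (1-based, inclusive), `n_bins`, `n_participants`, `total_spikes`.
#' @export
detect_bursts <- function(counts, criteria) {
  stopifnot(inherits(criteria, "burst_criteria"))
  n_rec <- nrow(counts)
  active <- counts > 0L
  n_active <- colSums(active)
  mean_rate <- ifelse(n_active > 0,
                      colSums(counts) / n_active / (criteria$bin_ms / 1000), 0)
  supra <- (n_active >= criteria$f_min * n_rec) & (mean_rate > criteria$r_min)
  if (!any(supra))
    return(data.frame(start_bin = integer(), end_bin = integer(),
                      n_bins = integer(), n_participants = integer(),
                      total_spikes = integer()))
  if (criteria$merge_adjacent) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    starts <- ends <- which(supra)
  }
  part <- mapply(function(s, e) sum(rowSums(counts[, s:e, drop = FALSE]) > 0),
                 starts, ends)
  tot <- mapply(function(s, e) sum(counts[, s:e, drop = FALSE]), starts, ends)
  data.frame(start_bin = starts, end_bin = ends,
             n_bins = ends - starts + 1L,
             n_participants = as.integer(part),
             total_spikes = as.integer(tot))
}

#' Burst rate
#'
#' @param events data frame from [detect_bursts()].
#' @param total_time_s total recorded time, seconds.
#' @return Events per second (Hz).
#' @export
burst_rate <- function(events, total_time_s) {
  stopifnot(total_time_s > 0)
  nrow(events) / total_time_s
}

#' Intra-burst spiking statistics per neuron type
#'
#' Averages, over all bursts and all neurons participating in each burst,
#' the number of spikes fired per neuron per burst and the corresponding
#' firing rate (spikes divided by the burst duration), separately for PY
#' and IN neurons. Silent recorded neurons do not dilute the averages.
#'
#' @param events data frame from [detect_bursts()].
#' @param counts matrix from [bin_raster()].
#' @param types character vector of neuron types aligned with
#'   `rownames(counts)`.
#' @param bin_ms bin width used for `counts`, ms.
#' @return List with `PY` and `IN` components (each `spikes_per_neuron`,
#'   `rate_hz`), or an empty flagged result when there are no events.
#' @export
intra_burst_stats <- function(events, counts, types, bin_ms = 100) {
  if (nrow(events) == 0L)
    return(structure(list(PY = NULL, IN = NULL, n_bursts = 0L), empty = TRUE))
  acc <- list(PY = c(), IN = c(), PY_r = c(), IN_r = c())
  for (k in seq_len(nrow(events))) {
    cs <- rowSums(counts[, events$start_bin[k]:events$end_bin[k], drop = FALSE])
    dur_s <- events$n_bins[k] * bin_ms / 1000
    for (tt in c("PY", "IN")) {
      v <- cs[types == tt & cs > 0]
      if (length(v)) {
        acc[[tt]] <- c(acc[[tt]], v)
        acc[[paste0(tt, "_r")]] <- c(acc[[paste0(tt, "_r")]], v / dur_s)
      }
    }
  }
  list(PY = list(spikes_per_neuron = mean(acc$PY), rate_hz = mean(acc$PY_r)),
       IN = list(spikes_per_neuron = mean(acc$IN), rate_hz = mean(acc$IN_r)),
       n_bursts = nrow(events))
}

#' Averaged normalized cross-covariance between binned spike trains
#'
#' For each sampled pair, computes the correlation-coefficient-normalized
#' cross-covariance of the mean-subtracted binned counts at lags
#' `-max_lag..max_lag` (in bins), then averages over pairs. A positive
#' lag `l` correlates the first train at bin `t` with the second at
#' `t + l`, so a second train delayed by one bin peaks at lag 1. Pairs
#' containing a zero-variance train are skipped.
#'
#' @param counts matrix from [bin_raster()].
#' @param pairs two-column matrix of row indices into `counts`; defaults
#'   to up to `max_pairs` random distinct pairs.
#' @param max_lag maximum lag in bins.
#' @param max_pairs cap on sampled pairs.
#' @return List with `lags`, the averaged covariance `cov` per lag, and
#'   `n_pairs` used.
#' @export
cross_covariance <- function(counts, pairs = NULL, max_lag = 5,
                             max_pairs = 2000) {
  n <- nrow(counts)
  if (n < 2) stop("need at least two neurons")
  if (is.null(pairs)) {
    all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    if (nrow(all_pairs) > max_pairs)
      all_pairs <- all_pairs[sample.int(nrow(all_pairs), max_pairs), ,
                             drop = FALSE]
    pairs <- all_pairs
  }
  lags <- -max_lag:max_lag
  nb <- ncol(counts)
  acc <- numeric(length(lags)); used <- 0L
  x <- sweep(counts, 1, rowMeans(counts))
  sds <- sqrt(rowMeans(x^2))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (sds[i] == 0 || sds[j] == 0) next
    cc <- vapply(lags, function(l) {
      if (l >= 0) {
        a <- x[i, 1:(nb - l)]; b <- x[j, (1 + l):nb]
      } else {
        a <- x[i, (1 - l):nb]; b <- x[j, 1:(nb + l)]
      }
      mean(a * b) / (sds[i] * sds[j])
    }, numeric(1))
    acc <- acc + cc; used <- used + 1L
  }
  list(lags = lags, cov = if (used > 0) acc / used else rep(NA_real_, length(lags)),
       n_pairs = used)
}

#' Intact neurons at the trauma boundary
#'
#' A deafferented neuron is a *boundary deafferented* neuron if its
#' footprint contains at least one intact neuron. The boundary set is the
#' set of intact neurons whose footprint contains at least one boundary
#' deafferented neuron.
#'
#' @param network an `ml_network`.
#' @param deaff deafferented neuron indices.
#' @return Integer vector of intact boundary neuron indices.
#' @export
boundary_neurons <- function(network, deaff) {
  if (length(deaff) == 0L) return(integer(0))
  nn <- network$neurons
  L <- network$config$side_length
  a <- network$config$footprint_half
  is_deaff <- rep(FALSE, nrow(nn)); is_deaff[deaff] <- TRUE
  in_fp <- function(i) {
    sites <- footprint_sites(c(nn$x[i], nn$y[i]), a, L)
    sites[, 2] * L + sites[, 1] + 1L
  }
  bdry_deaff <- deaff[vapply(deaff, function(i) any(!is_deaff[in_fp(i)]),
                             logical(1))]
  if (length(bdry_deaff) == 0L) return(integer(0))
  is_bd <- rep(FALSE, nrow(nn)); is_bd[bdry_deaff] <- TRUE
  intact <- nn$index[!is_deaff]
  intact[vapply(intact, function(i) any(is_bd[in_fp(i)]), logical(1))]
}

#' Recorded-neuron sampling region
#'
#' Focal trauma: 5 adjacent full lines perpendicular to the trauma
#' boundary (spanning the propagation axis), centered on the lattice
#' midline. Diffuse trauma: a centered square block.
#'
#' @param pattern `"focal"` or `"diffuse"`.
#' @param network an `ml_network`.
#' @param n_lines number of adjacent lines (focal).
#' @param block_side side of the square block (diffuse); defaults to 20,
#'   clipped to the lattice.
#' @return Integer vector of recorded neuron indices.
#' @export
sampling_region <- function(pattern = c("focal", "diffuse"), network,
                            n_lines = 5L, block_side = 20L) {
  pattern <- match.arg(pattern)
  nn <- network$neurons
  L <- network$config$side_length
  if (pattern == "focal") {
    if (n_lines > L) stop("sampling region exceeds lattice")
    y0 <- (L - n_lines) %/% 2
    nn$index[nn$y >= y0 & nn$y < y0 + n_lines]
  } else {
    if (block_side > L) stop("sampling region exceeds lattice")
    x0 <- (L - block_side) %/% 2
    nn$index[nn$x >= x0 & nn$x < x0 + block_side &
             nn$y >= x0 & nn$y < x0 + block_side]
  }
}

#' Spatial firing-rate profile along the trauma axis
#'
#' Averages per-PY-neuron firing rates over a center-symmetric strip
#' (half-width `strip_half_width` rows about the lattice midline) at each
#' x position; also returns the full 2D time-averaged rate map.
#'
#' @param rates per-neuron firing rates, Hz (e.g. `sim$rates$per_neuron`).
#' @param network an `ml_network`.
#' @param strip_half_width half-width of the strip cross-section, rows.
#' @return List with `x` (0-based positions), `rate` (strip-averaged PY
#'   rate per position), and `map` (L x L matrix of rates, all neurons).
#' @export
spatial_rate_profile <- function(rates, network, strip_half_width = 5L) {
  nn <- network$neurons
  L <- network$config$side_length
  mid <- L / 2
  strip <- nn$type == "PY" & abs(nn$y + 0.5 - mid) <= strip_half_width
  prof <- vapply(0:(L - 1L), function(xx) {
    sel <- strip & nn$x == xx
    if (any(sel)) mean(rates[nn$index[sel]]) else NA_real_
  }, numeric(1))
  map <- matrix(NA_real_, L, L)
  map[cbind(nn$x + 1L, nn$y + 1L)] <- rates[nn$index]
  list(x = 0:(L - 1L), rate = prof, map = map)
}

#' Sever synapses crossing the intact/deafferented boundary
#'
#' Removes every synapse whose pre- and postsynaptic neurons differ in
#' deafferentation status (in both directions); within-group synapses are
#' untouched.
#'
#' @param network an `ml_network`.
#' @param deaff deafferented neuron indices.
#' @return The modified network.
#' @export
sever_boundary_connections <- function(network, deaff) {
  is_deaff <- rep(FALSE, nrow(network$neurons)); is_deaff[deaff] <- TRUE
  syn <- network$synapses
  keep <- is_deaff[syn$pre] == is_deaff[syn$post]
  network$synapses <- syn[keep, , drop = FALSE]
  rownames(network$synapses) <- NULL
  network
}
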