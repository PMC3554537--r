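#' Lattice network configuration
#'
#' Configuration for the 2D square-lattice network. Neurons occupy every
#' site of a `side_length` x `side_length` grid; every `in_stride`-th site
#' (row-major index `i` with `i %% in_stride == in_stride - 1`, 0-based) is
#' an inhibitory interneuron (IN), the rest are pyramidal (PY) neurons.
#' Each neuron may connect to peers inside its synaptic footprint, the
#' neuron-centered `(2 * footprint_half)^2` site block with per-dimension
#' offsets `[-footprint_half, footprint_half - 1]`, clipped at the lattice
#' edges (no wrap-around).
#'
#' The default connection probabilities are back-derived from the target
#' interior in-degrees of 55 incoming PY and 12 incoming IN synapses per
#' interior PY neuron (79 PY and 20 IN candidates inside a default 10x10
#' footprint). When `footprint_half` differs from the default of 5, the
#' probabilities are rescaled by the ratio of default to current interior
#' candidate counts per type, keeping the expected in-degree invariant to
#' footprint size.
#'
#' @param side_length integer lattice side (default 80).
#' @param in_stride every `in_stride`-th site is inhibitory (default 5).
#' @param footprint_half half-length `a` of the `(2a) x (2a)` footprint.
#' @param p_exc,p_inh per-candidate connection probabilities; defaults
#'   55/79 and 12/20.
#' @param max_exc_per_py cap on incoming PY->PY synapses per PY neuron.
#' @param seed RNG seed used by [build_network()].
#' @param rescale apply the footprint-size probability renormalization
#'   when `footprint_half` differs from 5? Disable for small fixture
#'   networks whose probabilities are meant per candidate as given.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(side_length = 80L, in_stride = 5L,
                           footprint_half = 5L,
                           p_exc = 55 / 79, p_inh = 12 / 20,
                           max_exc_per_py = 75L, seed = 1L,
                           rescale = TRUE) {
  side_length <- as.integer(side_length)
  in_stride <- as.integer(in_stride)
  footprint_half <- as.integer(footprint_half)
  if (side_length < 2L) stop("side_length must be >= 2")
  if (in_stride < 2L) stop("in_stride must be >= 2")
  if (footprint_half < 1L || footprint_half > side_length)
    stop("footprint_half must be in [1, side_length]")
  if (p_exc < 0 || p_exc > 1 || p_inh < 0 || p_inh > 1)
    stop("connection probabilities must lie in [0, 1]")
  if (max_exc_per_py < 0L) stop("max_exc_per_py must be >= 0")
  structure(list(side_length = side_length, in_stride = in_stride,
                 footprint_half = footprint_half,
                 p_exc = p_exc, p_inh = p_inh,
                 max_exc_per_py = as.integer(max_exc_per_py),
                 seed = as.integer(seed), rescale = isTRUE(rescale)),
            class = "lattice_config")
}

#' Lay neurons on the lattice
#'
#' Creates the neuron table (no synapses): row-major site `i` (0-based) has
#' coordinates `x = i %% side`, `y = i %/% side` and is IN iff
#' `i %% in_stride == in_stride - 1`.
#'
#' @param config a [lattice_config()].
#' @return An object of class `ml_network` with a `neurons` data frame
#'   (`index` 1-based, `x`, `y` 0-based, `type` "PY"/"IN") and an empty
#'   synapse table.
#' @export
build_lattice <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  n <- config$side_length^2
  i0 <- seq_len(n) - 1L
  neurons <- data.frame(
    index = seq_len(n),
    x = i0 %% config$side_length,
    y = i0 %/% config$side_length,
    type = ifelse(i0 %% config$in_stride == config$in_stride - 1L, "IN", "PY"),
    stringsAsFactors = FALSE)
  structure(list(neurons = neurons,
                 synapses = data.frame(pre = integer(), post = integer(),
                                       kind = character(),
                                       stringsAsFactors = FALSE),
                 config = config),
            class = "ml_network")
}

#' Candidate partner sites within a neuron's footprint
#'
#' Enumerates the lattice sites in the `(2 * half)^2` block centered on
#' `coord` with per-dimension offsets `[-half, half - 1]`, clipped at the
#' lattice edges and excluding the neuron's own site.
#'
#' @param coord length-2 integer vector `c(x, y)`, 0-based.
#' @param half footprint half-length.
#' @param side lattice side length.
#' @return A two-column matrix of candidate `(x, y)` coordinates.
#' @export
footprint_sites <- function(coord, half, side) {
  x <- coord[[1]]; y <- coord[[2]]
  if (x < 0 || x >= side || y < 0 || y >= side) stop("coord not on lattice")
  off <- seq.int(-half, half - 1L)
  xs <- x + off; xs <- xs[xs >= 0 & xs < side]
  ys <- y + off; ys <- ys[ys >= 0 & ys < side]
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  g <- g[!(g$x == x & g$y == y), , drop = FALSE]
  as.matrix(g)
}

# Directed candidate pairs (pre, post): pre lies in post's footprint.
# Returns a data.frame(pre, post) of 1-based neuron indices.
candidate_pairs <- function(config) {
  L <- config$side_length; a <- config$footprint_half
  off <- seq.int(-a, a - 1L)
  offs <- expand.grid(dx = off, dy = off, KEEP.OUT.ATTRS = FALSE)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  i0 <- seq_len(L^2) - 1L
  px <- i0 %% L; py <- i0 %/% L
  pre <- post <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    qx <- px + offs$dx[k]; qy <- py + offs$dy[k]
    ok <- qx >= 0 & qx < L & qy >= 0 & qy < L
    post[[k]] <- i0[ok] + 1L
    pre[[k]] <- (qy[ok] * L + qx[ok]) + 1L
  }
  data.frame(pre = unlist(pre), post = unlist(post))
}

# Counts of PY / IN candidates in the footprint of a reference interior
# site, used for footprint-size probability renormalization. Falls back to
# the unclipped modular pattern when the lattice has no interior site.
interior_candidate_counts <- function(config) {
  L <- config$side_length; a <- config$footprint_half
  ctr <- c(min(max(a, L %/% 2), L - a), min(max(a, L %/% 2), L - a))
  sites <- footprint_sites(ctr, a, L)
  idx <- sites[, 2] * L + sites[, 1]
  n_in <- sum(idx %% config$in_stride == config$in_stride - 1L)
  c(py = nrow(sites) - n_in, inh = n_in)
}

#' Sample footprint-limited random connectivity
#'
#' Connects every directed candidate pair independently with probability
#' `p_exc` (PY presynaptic) or `p_inh` (IN presynaptic). When
#' `footprint_half` differs from `default_half`, probabilities are rescaled
#' by (default interior candidate count of that type) / (current interior
#' candidate count) so the expected in-degree is footprint-size invariant.
#' Incoming PY->PY synapses above `max_exc_per_py` are pruned at random.
#'
#' @param network an `ml_network` from [build_lattice()].
#' @param config the [lattice_config()] (defaults to the network's own).
#' @param default_half footprint half-length at which `p_exc`/`p_inh` are
#'   defined (default 5).
#' @return The network with its `synapses` data frame filled in
#'   (`pre`, `post` 1-based, `kind` one of "PP", "IP", "PI", "II"; the
#'   first letter is the presynaptic type).
#' @export
sample_connections <- function(network, config = network$config,
                               default_half = 5L) {
  stopifnot(inherits(network, "ml_network"))
  p_exc <- config$p_exc; p_inh <- config$p_inh
  if (!isFALSE(config$rescale) && config$footprint_half != default_half) {
    cur <- interior_candidate_counts(config)
    ref <- interior_candidate_counts(
      lattice_config(side_length = max(config$side_length, 4L * default_half),
                     in_stride = config$in_stride,
                     footprint_half = default_half))
    p_exc <- p_exc * ref[["py"]] / cur[["py"]]
    p_inh <- p_inh * ref[["inh"]] / cur[["inh"]]
    if (p_exc > 1 || p_inh > 1)
      stop("footprint rescaling pushed a connection probability above 1")
  }
  cand <- candidate_pairs(config)
  pre_in <- network$neurons$type[cand$pre] == "IN"
  p <- ifelse(pre_in, p_inh, p_exc)
  keep <- stats::runif(nrow(cand)) < p
  syn <- cand[keep, , drop = FALSE]
  pre_t <- network$neurons$type[syn$pre]
  post_t <- network$neurons$type[syn$post]
  syn$kind <- paste0(substr(pre_t, 1, 1), substr(post_t, 1, 1))
  # cap incoming PY->PY synapses per PY neuron by random pruning
  is_pp <- syn$kind == "PP"
  if (any(is_pp)) {
    pp_rows <- which(is_pp)
    cnt <- tabulate(syn$post[pp_rows], nbins = nrow(network$neurons))
    over <- which(cnt > config$max_exc_per_py)
    drop_rows <- integer(0)
    for (i in over) {
      rows <- pp_rows[syn$post[pp_rows] == i]
      drop_rows <- c(drop_rows,
                     rows[sample.int(length(rows),
                                     length(rows) - config$max_exc_per_py)])
    }
    if (length(drop_rows)) syn <- syn[-drop_rows, , drop = FALSE]
  }
  rownames(syn) <- NULL
  network$synapses <- syn
  network$config <- config
  network
}

#' Build a complete network
#'
#' Convenience wrapper: seeds the RNG from `config$seed`, lays the lattice,
#' and samples connectivity.
#'
#' @inheritParams sample_connections
#' @return A connected `ml_network`.
#' @export
build_network <- function(config = lattice_config()) {
  set.seed(config$seed)
  sample_connections(build_lattice(config), config)
}

# Interior neurons: those whose footprint is not clipped by a lattice edge.
interior_indices <- function(network) {
  a <- network$config$footprint_half
  L <- network$config$side_length
  nn <- network$neurons
  nn$index[nn$x >= a & nn$x <= L - a & nn$y >= a & nn$y <= L - a]
}

#' In-degree statistics per presynaptic type
#'
#' @param network a connected `ml_network`.
#' @param subset `"all_py"` (every PY neuron) or `"interior_py"` (PY
#'   neurons with unclipped footprints).
#' @return A list with per-presynaptic-type (`PY`, `IN`) components, each
#'   holding `mean`, `sd`, `max`, and a named histogram of in-degrees over
#'   the subset.
#' @export
degree_stats <- function(network, subset = c("interior_py", "all_py")) {
  subset <- match.arg(subset)
  nn <- network$neurons
  idx <- if (subset == "interior_py") {
    intersect(interior_indices(network), nn$index[nn$type == "PY"])
  } else nn$index[nn$type == "PY"]
  if (length(idx) == 0L) stop("empty neuron subset")
  syn <- network$synapses
  out <- list()
  for (tt in c("PY", "IN")) {
    rows <- syn$pre %in% nn$index[nn$type == tt] & syn$post %in% idx
    deg <- tabulate(syn$post[rows], nbins = nrow(nn))[idx]
    h <- table(deg)
    out[[tt]] <- list(mean = mean(deg), sd = stats::sd(deg), max = max(deg),
                      histogram = h)
  }
  out$n <- length(idx)
  out
}

#' @export
print.ml_network <- function(x, ...) {
  nn <- x$neurons
  cat(sprintf("ml_network: %d x %d lattice, %d neurons (%d PY, %d IN), %d synapses\n",
              x$config$side_length, x$config$side_length, nrow(nn),
              sum(nn$type == "PY"), sum(nn$type == "IN"), nrow(x$synapses)))
  invisible(x)
}

#' @export
summary.ml_network <- function(object, ...) {
  print(object)
  if (nrow(object$synapses) > 0) {
    cat("synapses by kind:\n")
    print(table(object$synapses$kind))
  }
  invisible(object)
}

#' Write / read a network as plain-text tables
#'
#' Serializes the neuron table and directed edge list as two CSV files.
#'
#' @param network an `ml_network`.
#' @param neurons_file,synapses_file CSV paths.
#' @return `write_network` returns the paths invisibly; `read_network`
#'   returns a partial `ml_network` (tables only, no config).
#' @export
write_network <- function(network, neurons_file, synapses_file) {
  utils::write.csv(network$neurons, neurons_file, row.names = FALSE)
  utils::write.csv(network$synapses, synapses_file, row.names = FALSE)
  invisible(c(neurons_file, synapses_file))
}

#' @rdname write_network
#' @export
read_network <- function(neurons_file, synapses_file) {
  structure(list(neurons = utils::read.csv(neurons_file,
                                           stringsAsFactors = FALSE),
                 synapses = utils::read.csv(synapses_file,
                                            stringsAsFactors = FALSE),
                 config = NULL),
            class = "ml_network")
}
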