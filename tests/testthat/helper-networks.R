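# Small fixture builders shared across test files.

tiny_net <- function(side = 12L, seed = 7L, half = 3L, ...) {
  build_network(lattice_config(side_length = side, footprint_half = half,
                               seed = seed, rescale = FALSE, ...))
}

# Brute-force burst re-evaluation, independent of detect_bursts()'s
# vectorized path: explicit per-bin loop over the two-part criterion.
brute_bursts <- function(counts, crit) {
  n <- nrow(counts)
  supra <- logical(ncol(counts))
  for (b in seq_len(ncol(counts))) {
    col <- counts[, b]
    na <- sum(col > 0)
    ok_f <- na >= crit$f_min * n
    ok_r <- na > 0 && (sum(col) / na / (crit$bin_ms / 1000)) > crit$r_min
    supra[b] <- ok_f && ok_r
  }
  if (!crit$merge_adjacent) return(sum(supra))
  sum(diff(c(FALSE, supra)) == 1)
}

# Brute-force boundary set via explicit offset loops.
brute_boundary <- function(network, deaff) {
  nn <- network$neurons
  L <- network$config$side_length
  a <- network$config$footprint_half
  is_d <- rep(FALSE, nrow(nn)); is_d[deaff] <- TRUE
  fp <- function(i) {
    out <- integer(0)
    for (dx in -a:(a - 1)) for (dy in -a:(a - 1)) {
      if (dx == 0 && dy == 0) next
      x <- nn$x[i] + dx; y <- nn$y[i] + dy
      if (x >= 0 && x < L && y >= 0 && y < L) out <- c(out, y * L + x + 1L)
    }
    out
  }
  bd <- deaff[vapply(deaff, function(i) any(!is_d[fp(i)]), logical(1))]
  is_bd <- rep(FALSE, nrow(nn)); is_bd[bd] <- TRUE
  intact <- nn$index[!is_d]
  sort(intact[vapply(intact, function(i) any(is_bd[fp(i)]), logical(1))])
}
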