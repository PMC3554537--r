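test_that("binning conserves spikes and uses half-open bins", {
  empty <- data.frame(t = numeric(), neuron = integer())
  m <- bin_raster(empty, 100, recorded = 1:4)
  expect_true(all(m == 0))
  # a spike at exactly t = bin_ms belongs to bin 2
  sp <- data.frame(t = c(0, 100, 199.999), neuron = c(1, 1, 2))
  m <- bin_raster(sp, 100, recorded = 1:2, t_end = 200)
  expect_equal(m["1", ], c(1L, 1L))
  expect_equal(m["2", ], c(0L, 1L))
  # conservation on a random raster
  set.seed(1)
  sp <- data.frame(t = runif(500, 0, 1000), neuron = sample(1:10, 500, TRUE))
  m <- bin_raster(sp, 100, recorded = 1:10, t_end = 1000)
  expect_equal(sum(m), 500)
})

test_that("burst detection applies the two-part criterion", {
  crit <- burst_criteria(f_min = 0.5, r_min = 20)
  # 6 of 10 neurons fire 3 spikes each in one bin: fraction 0.6, rate 30 Hz
  counts <- matrix(0L, 10, 5)
  counts[1:6, 3] <- 3L
  ev <- detect_bursts(counts, crit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_bin, 3)
  expect_equal(ev$n_participants, 6)
  # only 4 active: fraction test fails
  counts2 <- matrix(0L, 10, 5); counts2[1:4, 3] <- 3L
  expect_equal(nrow(detect_bursts(counts2, crit)), 0)
  # rate exactly at threshold fails (strict inequality)
  counts3 <- matrix(0L, 10, 5); counts3[1:6, 3] <- 2L
  expect_equal(nrow(detect_bursts(counts3, crit)), 0)
  # three consecutive supra bins merge into one 3-bin event
  counts4 <- matrix(0L, 10, 6); counts4[1:6, 2:4] <- 3L
  ev4 <- detect_bursts(counts4, crit)
  expect_equal(nrow(ev4), 1)
  expect_equal(ev4$n_bins, 3)
  crit_nm <- burst_criteria(f_min = 0.5, r_min = 20, merge_adjacent = FALSE)
  expect_equal(nrow(detect_bursts(counts4, crit_nm)), 3)
})

test_that("burst detection agrees with brute-force re-evaluation", {
  set.seed(99)
  crit <- burst_criteria(f_min = 0.4, r_min = 15)
  for (k in 1:1000) {
    counts <- matrix(rpois(8 * 12, lambda = sample(c(0.2, 1, 3), 1)), 8, 12)
    expect_equal(nrow(detect_bursts(counts, crit)), brute_bursts(counts, crit))
  }
})

test_that("burst rate is events per second", {
  ev <- data.frame(start_bin = 1:30, end_bin = 1:30)
  expect_equal(burst_rate(ev, 100), 0.3)
  expect_equal(burst_rate(ev[0, ], 100), 0)
  expect_equal(burst_rate(ev, 200), 0.15)
})

test_that("intra-burst statistics average over participants only", {
  counts <- matrix(0L, 10, 4)
  counts[1:6, 2] <- 2L  # one burst bin, participants fire 2 spikes
  types <- rep(c("PY", "IN"), each = 5)
  crit <- burst_criteria(r_min = 15)
  ev <- detect_bursts(counts, crit)
  st <- intra_burst_stats(ev, counts, types, bin_ms = 100)
  expect_equal(st$PY$spikes_per_neuron, 2)
  expect_equal(st$PY$rate_hz, 20)
  expect_equal(st$IN$spikes_per_neuron, 2)
  # duplicated burst leaves the per-burst means unchanged
  counts2 <- cbind(counts, counts)
  ev2 <- detect_bursts(counts2, crit)
  expect_equal(nrow(ev2), 2)
  st2 <- intra_burst_stats(ev2, counts2, types, bin_ms = 100)
  expect_equal(st2$PY$spikes_per_neuron, st$PY$spikes_per_neuron)
  # no events: flagged empty result
  st0 <- intra_burst_stats(ev[0, ], counts, types)
  expect_true(attr(st0, "empty"))
})

test_that("cross-covariance is normalized and localizes shifts", {
  set.seed(2)
  x <- rpois(200, 2)
  counts <- rbind(x, x)
  cc <- cross_covariance(counts, pairs = cbind(1, 2), max_lag = 3)
  expect_equal(cc$cov[cc$lags == 0], 1)
  # independent trains: near zero at lag 0
  y <- rpois(200, 2)
  cc2 <- cross_covariance(rbind(x, y), pairs = cbind(1, 2), max_lag = 0)
  expect_lt(abs(cc2$cov), 3 / sqrt(200))
  # copy delayed by one bin peaks at lag 1, not 0
  xs <- c(rpois(1, 2), x[-200])
  cc3 <- cross_covariance(rbind(x, xs), pairs = cbind(1, 2), max_lag = 3)
  expect_equal(cc3$lags[which.max(cc3$cov)], 1)
  # zero-variance train: pair skipped
  cc4 <- cross_covariance(rbind(x, rep(1, 200)), pairs = cbind(1, 2))
  expect_equal(cc4$n_pairs, 0)
})

test_that("boundary sets match brute-force scans", {
  net <- tiny_net(side = 10L, half = 2L)
  expect_length(boundary_neurons(net, integer(0)), 0)
  # left 5 columns deafferented: with offsets [-2, 1], intact boundary is
  # columns 5 and 6
  deaff <- net$neurons$index[net$neurons$x < 5]
  b <- boundary_neurons(net, deaff)
  expect_setequal(unique(net$neurons$x[b]), c(5, 6))
  expect_equal(sort(b), brute_boundary(net, deaff))
  # diffuse sparse trauma: oracle equivalence
  set.seed(13)
  for (k in 1:5) {
    d <- sample(net$neurons$index, 20)
    expect_equal(sort(boundary_neurons(net, d)), brute_boundary(net, d))
  }
})

test_that("sampling regions have the documented sizes", {
  net80 <- build_lattice(lattice_config(side_length = 80L))
  net80$config <- lattice_config(side_length = 80L)
  expect_length(sampling_region("focal", net80), 400)
  expect_length(sampling_region("diffuse", net80), 400)
  net40 <- build_lattice(lattice_config(side_length = 40L))
  expect_length(sampling_region("focal", net40), 200)
  expect_error(sampling_region("diffuse", tiny_net(side = 10L),
                               block_side = 20L), "lattice")
})

test_that("spatial profiles are flat for homogeneous rates", {
  net <- tiny_net(side = 16L, half = 3L)
  rates <- rep(5, 256)
  pr <- spatial_rate_profile(rates, net, strip_half_width = 3L)
  expect_length(pr$x, 16)
  expect_true(all(abs(pr$rate - 5) < 1e-12))
  expect_equal(dim(pr$map), c(16, 16))
})

test_that("severing removes exactly the status-crossing synapses", {
  net <- tiny_net(side = 10L, half = 2L)
  expect_equal(nrow(sever_boundary_connections(net, integer(0))$synapses),
               nrow(net$synapses))
  deaff <- apply_trauma(net, trauma_config("focal", f_d = 0.4))
  cut <- sever_boundary_connections(net, deaff)
  is_d <- rep(FALSE, 100); is_d[deaff] <- TRUE
  crossing <- sum(is_d[net$synapses$pre] != is_d[net$synapses$post])
  expect_equal(nrow(net$synapses) - nrow(cut$synapses), crossing)
  expect_true(all(is_d[cut$synapses$pre] == is_d[cut$synapses$post]))
})
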