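test_that("trauma patterns select the specified neuron sets", {
  net <- tiny_net(side = 20L, half = 5L)
  expect_length(apply_trauma(net, trauma_config("focal", f_d = 0)), 0)
  expect_length(apply_trauma(net, trauma_config("focal", f_d = 1)), 400)
  # focal 0.5 on 20x20: 10 whole columns
  d <- apply_trauma(net, trauma_config("focal", f_d = 0.5))
  expect_length(d, 200)
  expect_true(all(net$neurons$x[d] < 10))
  # whole-column rounding: f_d just above 10 columns' worth adds a column
  d2 <- apply_trauma(net, trauma_config("focal", f_d = 0.51))
  expect_length(d2, 220)
  expect_error(trauma_config(f_d = 1.2), "f_d")
})

test_that("diffuse trauma draws the right size and type composition", {
  net <- tiny_net(side = 20L, half = 5L)
  sizes <- frac_in <- numeric(20)
  for (k in 1:20) {
    d <- apply_trauma(net, trauma_config("diffuse", f_d = 0.25, seed = k))
    sizes[k] <- length(d)
    frac_in[k] <- mean(net$neurons$type[d] == "IN")
  }
  expect_true(all(sizes == 100))
  expect_lt(abs(mean(frac_in) - 0.2), 3 * sqrt(0.2 * 0.8 / (100 * 20)))
})

test_that("EMA rate estimator converges and decays correctly", {
  # stationary Poisson trains: pooled estimate near the true rate
  set.seed(5)
  lambda <- 10; tau <- 2
  spikes <- do.call(rbind, lapply(1:50, function(i) {
    data.frame(t = afferent_events(lambda, 0, 30000), neuron = i)
  }))
  r <- estimate_rates(spikes, 50, tau_rate = tau, t_end = 30000)
  # var of one EMA estimate is lambda/(2 tau); 50 independent neurons
  expect_lt(abs(mean(r) - lambda), 3 * sqrt(lambda / (2 * tau) / 50))
  # silent neuron decays to zero
  r2 <- estimate_rates(data.frame(t = 100, neuron = 1), 1, tau_rate = 0.1,
                       t_end = 5000)
  expect_lt(r2[1], 1e-6)
  # uniform rates: presynaptic means equal the global mean
  rr <- rep(7, 10)
  expect_equal(mean(rr[1:4]), mean(rr))
})

test_that("round-robin partition sizes differ by at most one", {
  set.seed(3)
  expect_equal(partition_round_robin(67, 1), rep(1L, 67))
  d <- partition_round_robin(67, 100)
  expect_true(all(table(d) <= 1))
  d5 <- partition_round_robin(67, 5)
  expect_equal(sort(as.integer(table(d5))), c(13L, 13L, 13L, 14L, 14L))
})

test_that("random microdomain maps exactly partition every PY neuron's inputs", {
  net <- tiny_net(side = 10L, half = 3L)
  set.seed(8)
  for (M in c(1L, 3L, 40L)) {
    map <- partition_random(net, M)
    onto_py <- net$neurons$type[net$synapses$post] == "PY"
    expect_true(all(!is.na(map$domain[onto_py])))
    expect_true(all(is.na(map$domain[!onto_py])))
    expect_true(all(map$domain[onto_py] >= 1 & map$domain[onto_py] <= M))
    # per-neuron balance
    for (i in unique(net$synapses$post[onto_py])[1:5]) {
      sz <- table(map$domain[onto_py & net$synapses$post == i])
      expect_lte(max(sz) - min(sz), 1)
    }
  }
})

test_that("segregated partition matches presynaptic deafferentation status", {
  net <- tiny_net(side = 9L, half = 2L)
  deaff <- apply_trauma(net, trauma_config("focal", f_d = 1 / 3))
  map <- partition_segregated(net, deaff)
  syn <- net$synapses
  onto_py <- net$neurons$type[syn$post] == "PY"
  is_d <- rep(FALSE, 81); is_d[deaff] <- TRUE
  expect_equal(map$domain[onto_py],
               ifelse(is_d[syn$pre[onto_py]], 2L, 1L))
  # a neuron with all-intact inputs has an empty deafferented domain
  far <- net$neurons$index[net$neurons$x == 8 & net$neurons$type == "PY"][1]
  rows <- onto_py & syn$post == far
  expect_true(all(map$domain[rows] == 1L))
  # a boundary neuron with mixed inputs covers both domains
  mid <- net$neurons$index[net$neurons$x == 3 & net$neurons$y == 3 &
                             net$neurons$type == "PY"][1]
  rows <- onto_py & syn$post == mid
  expect_setequal(unique(map$domain[rows]), c(1L, 2L))
})

test_that("hsp_step implements the rectified up/down rule", {
  hsp <- default_params()$hsp
  rt <- hsp$r_target
  # fixed point
  s <- hsp_step(1, 1, u = rt, v = rt, hsp, dt_s = 1)
  expect_equal(s$s_exc, 1); expect_equal(s$s_inh, 1)
  # silent presynaptic pool: full-speed up for AMPA, down for GABA
  s <- hsp_step(1, 1, u = 0, v = rt / 2, hsp, dt_s = 1)
  expect_equal(s$s_exc, 1 + hsp$kappa)
  expect_equal(s$s_inh, 1 - hsp$kappa)
  # hyperactive postsynaptic neuron with saturated presyn drive
  s <- hsp_step(1, 1, u = 2 * rt, v = 2 * rt, hsp, dt_s = 1)
  expect_equal(s$s_exc, 1 - hsp$kappa)
  expect_equal(s$s_inh, 1 + hsp$kappa)
  # clipping at the bounds
  s <- hsp_step(hsp$s_max, hsp$s_min, u = 0, v = 0, hsp, dt_s = 100)
  expect_equal(s$s_exc, hsp$s_max)
  expect_equal(s$s_inh, hsp$s_min)
})

test_that("scaling percentage is relative to the intact conductance", {
  expect_equal(scaling_percentage(1, 1), 0)
  expect_equal(scaling_percentage(2, 1), 100)
  expect_equal(scaling_percentage(0.5, 1), -50)
  expect_error(scaling_percentage(1, 0), "positive")
})

test_that("kappa = 0 freezes all scaling factors", {
  net <- tiny_net(side = 8L, half = 2L)
  p <- default_params(hsp = list(kappa = 0))
  set.seed(2)
  sim <- simulate_network(net, p, total_ms = 2000, hsp_on = TRUE)
  expect_true(all(sim$state$s_exc == 1))
  expect_true(all(sim$state$s_inh == 1))
})

test_that("a silent deafferented network upregulates at rate kappa", {
  # no afferent drive and no spikes: u = v = 0, so ds_exc/dt = +kappa and
  # ds_inh/dt = -kappa until the bounds are hit
  net <- tiny_net(side = 6L, half = 2L)
  p <- default_params(afferent = list(rate = 0), hsp = list(kappa = 0.05))
  sim <- simulate_network(net, p, total_ms = 10000, hsp_on = TRUE)
  act <- sim$engine$dom_active
  expect_equal(unname(sim$state$s_exc[act]),
               rep(1 + 0.05 * 10, sum(act)), tolerance = 1e-6)
  expect_equal(unname(sim$state$s_inh[act]),
               rep(max(0, 1 - 0.05 * 10), sum(act)), tolerance = 1e-6)
  # inactive domains (no glutamatergic synapses) stay frozen
  if (any(!act)) expect_true(all(sim$state$s_exc[!act] == 1))
})

test_that("dense-network presynaptic averages approach the global mean", {
  # footprint covering the whole lattice at p = 1: every PY's presynaptic
  # set is (almost) the full PY population
  net <- build_network(lattice_config(side_length = 6L, footprint_half = 6L,
                                      p_exc = 1, p_inh = 0, seed = 4L,
                                      rescale = FALSE))
  set.seed(6)
  sim <- simulate_network(net, total_ms = 3000)
  r <- estimate_rates(sim$spikes, 36, tau_rate = 1, t_end = 3000)
  py <- net$neurons$index[net$neurons$type == "PY"]
  rglob <- mean(r[py])
  syn <- net$synapses
  for (i in py[1:6]) {
    pre <- unique(syn$pre[syn$post == i & syn$kind == "PP"])
    expect_lt(abs(mean(r[pre]) - rglob), 0.15 * max(rglob, 1))
  }
})

test_that("the four HSP schemes wire the correct drive terms", {
  # symmetric all-to-all network, every neuron driven identically above
  # the target rate, no afferent noise: the presynaptic-set mean, the
  # global mean, and each neuron's own rate then coincide exactly, so the
  # local, global, and global_up_local_down schemes must produce
  # identical downscaling, while global_up_no_down (no downregulating
  # arm) must leave the factors at 1.
  net <- build_network(lattice_config(side_length = 6L, footprint_half = 6L,
                                      p_exc = 1, p_inh = 1, seed = 11L,
                                      rescale = FALSE))
  s_for <- function(scheme) {
    p <- default_params(afferent = list(rate = 0),
                        hsp = list(scheme = scheme, kappa = 0.2))
    eng <- traumanet:::sim_engine_input(net, p)
    eng$I_inj <- rep(-80, 36)
    st <- traumanet:::init_state(36L, eng$ndom, p)
    # let the rate estimator equilibrate before enabling plasticity, so
    # the drives reflect the stationary rates rather than the EMA ramp
    warm <- traumanet:::run_core(eng, p, st, total_ms = 15000, hsp_on = FALSE)
    res <- traumanet:::run_core(eng, p, warm$state, total_ms = 4000,
                                hsp_on = TRUE)
    list(s = res$state$s_exc, rate = length(res$spike_t) / 36 / 4)
  }
  out <- lapply(c("local", "global", "global_up_local_down",
                  "global_up_no_down"), s_for)
  expect_gt(out[[1]]$rate, default_params()$hsp$r_target)  # above target
  expect_identical(out[[1]]$s, out[[2]]$s)
  expect_identical(out[[1]]$s, out[[3]]$s)
  expect_true(all(out[[1]]$s < 1))           # down-arm engaged
  expect_true(all(out[[4]]$s == 1))          # no down-arm
})

test_that("domain presynaptic averages weight each partner once", {
  net <- tiny_net(side = 8L, half = 2L)
  rates <- seq_len(64) / 10
  set.seed(12)
  map <- partition_random(net, 3L)
  tab <- domain_presyn_rates(net, rates, map)
  # oracle: recompute one (post, domain) cell directly
  row <- tab[which.max(tab$n_pre), ]
  syn <- net$synapses
  sel <- syn$post == row$post & map$domain == row$domain &
    net$neurons$type[syn$pre] == "PY"
  expect_equal(row$r_pre, mean(rates[unique(syn$pre[sel])]))
  expect_equal(attr(tab, "r_glob"),
               mean(rates[net$neurons$type == "PY"]))
})
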