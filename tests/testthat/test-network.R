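# Lorentzian in-degree sampling, wiring, Euler simulation, per-neuron currents.

test_that("Lorentzian in-degree sampler: degenerate width, range, median", {
  expect_identical(sample_lorentzian_indegrees(50, 10, 0),
                   rep.int(10L, 50))
  k <- sample_lorentzian_indegrees(1e5, 1000, 0.3, seed = 4)
  expect_true(all(k >= 1 & k <= 1e5 - 1))
  # median of the Lorentzian equals its centre; binomial CI half-width at 1e5
  # draws is ~ 1.5 * IQR / sqrt(N) << 10
  expect_true(median(k) >= 990 && median(k) <= 1010)
  expect_error(sample_lorentzian_indegrees(10, 20, 0.3), "N > K")
  # HWHM scales as delta0 * sqrt(K): half the mass within K +/- HWHM
  expect_equal(mean(abs(k - 1000) <= 0.3 * sqrt(1000)), 0.5, tolerance = 0.02)
})

test_that("sampler is deterministic given a seed", {
  a <- sample_lorentzian_indegrees(1000, 50, 1, seed = 7)
  b <- sample_lorentzian_indegrees(1000, 50, 1, seed = 7)
  c <- sample_lorentzian_indegrees(1000, 50, 1, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("connectivity: exact cross in-degrees, realized draws, no self/duplicates", {
  conn <- build_connectivity(120, 60, 20, delta0_ee = 1.5, delta0_ii = 0.5,
                             seed = 3)
  expect_true(all(lengths(conn$ei$pre) == 20))   # every e-neuron: exactly K inhibitory inputs
  expect_true(all(lengths(conn$ie$pre) == 20))
  expect_identical(lengths(conn$ee$pre), as.integer(conn$ee$indeg))
  for (j in seq_len(120)) {
    expect_false(j %in% conn$ee$pre[[j]])
    expect_false(anyDuplicated(conn$ee$pre[[j]]) > 0)
  }
  for (j in seq_len(60)) expect_false(j %in% conn$ii$pre[[j]])
  conn2 <- build_connectivity(120, 60, 20, 1.5, 0.5, seed = 3)
  expect_identical(conn, conn2)
  conn3 <- build_connectivity(120, 60, 20, 1.5, 0.5, seed = 4)
  expect_false(identical(conn$ee$pre, conn3$ee$pre))
})

test_that("uncoupled QIF: silent below threshold, closed-form rate above", {
  conn <- build_connectivity(4, 4, 2, 0, 0, seed = 1)
  p0 <- model_params(g0_ee = 1e-14, g0_ei = 1e-14, g0_ie = 1e-14, g0_ii = 1e-14,
                     I0_e = -0.1, I0_i = -0.1, K = 2)
  # sub-threshold drive: no spikes after the transient flushes initial conditions
  sim <- simulate_network(conn, p0, dt = 1e-3, T = 2000, transient = 500, seed = 2)
  expect_identical(nrow(sim$raster), 0L)
  # supra-threshold: rate = sqrt(c)/(pi tau_m), c = sqrt(K) I0
  p1 <- model_params(g0_ee = 1e-14, g0_ei = 1e-14, g0_ie = 1e-14, g0_ii = 1e-14,
                     I0_e = 0.2, I0_i = 0.2, K = 2)
  sim1 <- simulate_network(conn, p1, dt = 1e-3, T = 20000, transient = 1000, seed = 2)
  expected <- sqrt(sqrt(2) * 0.2) / (pi * 20) * 1000
  expect_equal(mean(sim1$rates_Hz), expected, tolerance = 0.01)
})

test_that("spike conservation and determinism of the simulator", {
  p <- model_params(I0_e = 0.2, K = 20, delta0_ee = 1, delta0_ii = 0.5)
  conn <- build_connectivity(200, 50, 20, 1, 0.5, seed = 6)
  sim <- simulate_network(conn, p, dt = 1e-3, T = 3000, transient = 500,
                          seed = 9, trace_bin = 1)
  expect_identical(nrow(sim$raster), as.integer(sum(sim$counts)))
  # rate-trace integral recovers the spike count (binning-exact)
  e_cnt <- sum(sim$trace$R_e_Hz) / 1000 * 1 * 200
  i_cnt <- sum(sim$trace$R_i_Hz) / 1000 * 1 * 50
  expect_equal(e_cnt + i_cnt, sum(sim$counts))
  sim2 <- simulate_network(conn, p, dt = 1e-3, T = 3000, transient = 500,
                           seed = 9, trace_bin = 1)
  expect_identical(sim$raster, sim2$raster)    # bit-identical
  expect_warning(simulate_network(conn, p, dt = 0.05, T = 10, seed = 1),
                 "dt is large")
})

test_that("per-neuron effective currents: uncoupled limit and summation oracle", {
  conn <- build_connectivity(60, 30, 10, 1, 0.5, seed = 2)
  p0 <- model_params(g0_ee = 1e-14, g0_ei = 1e-14, g0_ie = 1e-14, g0_ii = 1e-14,
                     I0_e = 0.2, I0_i = 0.1, K = 10)
  sim0 <- simulate_network(conn, p0, dt = 1e-3, T = 5000, transient = 500, seed = 3)
  st0 <- measure_neuron_effective_currents(sim0)
  expect_equal(st0$i_eff[st0$pop == "e"], rep(sqrt(10) * 0.2, 60), tolerance = 1e-6)
  expect_equal(st0$i_eff[st0$pop == "i"], rep(sqrt(10) * 0.1, 30), tolerance = 1e-6)

  p <- model_params(I0_e = 0.2, K = 10, delta0_ee = 1, delta0_ii = 0.5)
  sim <- simulate_network(conn, p, dt = 1e-3, T = 5000, transient = 500, seed = 3)
  st <- measure_neuron_effective_currents(sim)
  # brute-force double-summation oracle for a handful of neurons
  r <- tabulate(sim$raster$neuron, nbins = 90) / sim$settings$T
  for (j in c(1, 17, 60)) {
    oracle <- sqrt(10) * p$I0_e + p$tau_m_e / sqrt(10) *
      (p$g0_ee * sum(r[conn$ee$pre[[j]]]) - p$g0_ei * sum(r[conn$ei$pre[[j]] + 60]))
    expect_equal(st$i_eff[j], oracle, tolerance = 1e-10)
  }
  for (j in c(1, 30)) {
    oracle <- sqrt(10) * p$I0_i + p$tau_m_i / sqrt(10) *
      (p$g0_ie * sum(r[conn$ie$pre[[j]]]) - p$g0_ii * sum(r[conn$ii$pre[[j]] + 60]))
    expect_equal(st$i_eff[60 + j], oracle, tolerance = 1e-10)
  }
  # silence threshold tagging
  expect_true(all(st$class[st$rate_Hz < 0.01] == "silent"))
  expect_true(all(st$class %in% c("silent", "mean-driven", "fluctuation-driven")))
})

test_that("population-mean effective current matches the rate formula on a
           homogeneous fixed-in-degree network", {
  # with delta0 = 0 every in-degree is exactly K, so the population average of
  # per-neuron currents equals the K-scaled rate expression algebraically
  conn <- build_connectivity(80, 40, 8, 0, 0, seed = 5)
  p <- model_params(I0_e = 0.05, K = 8, delta0_ee = 0, delta0_ii = 0)
  sim <- simulate_network(conn, p, dt = 1e-3, T = 4000, transient = 500, seed = 4)
  st <- measure_neuron_effective_currents(sim)
  # edge-weighted mean presynaptic rates
  r <- tabulate(sim$raster$neuron, nbins = 120) / sim$settings$T
  w_ee <- mean(vapply(conn$ee$pre, function(ix) mean(r[ix]), 1)) * 1000
  w_ei <- mean(vapply(conn$ei$pre, function(ix) mean(r[ix + 80]), 1)) * 1000
  pred <- sqrt(8) * (p$I0_e + p$tau_m_e * 8 / 8 *
                       (p$g0_ee * w_ee - p$g0_ei * w_ei) / 1000)
  expect_equal(mean(st$i_eff[1:80]), pred, tolerance = 1e-10)
})
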