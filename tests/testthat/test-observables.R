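# Diagnostics: coherence, ISI variability, rate traces, spectra,
# fundamental frequencies, rate distributions, burst delays.

test_that("coherence: identical traces give 1, independent noise gives ~1/sqrt(N)", {
  set.seed(42)
  common <- sin(2 * pi * (1:500) / 50)
  v_same <- matrix(rep(common, 40), ncol = 40)
  expect_equal(coherence_rho(v_same), 1, tolerance = 1e-12)
  N <- 1000; Tn <- 10000
  v_noise <- matrix(rnorm(Tn * N), Tn, N)
  rho <- coherence_rho(v_noise)
  # var of the mean of N iid signals is 1/N; allow 3 standard errors
  se <- sqrt(2 / (Tn - 1)) / (2 * sqrt(N))   # delta-method SE of sqrt(chi2 mean)
  expect_lt(abs(rho - 1 / sqrt(N)), 3 * se)
  expect_error(coherence_rho(matrix(1, 5, 5)), "degenerate")
})

test_that("coherence: common sinusoid plus equal-variance noise gives sqrt(1/2)", {
  set.seed(7)
  n <- 20000; N <- 200
  s <- sqrt(2) * sin(2 * pi * (1:n) / 100)    # variance 1
  v <- matrix(s, n, N) + matrix(rnorm(n * N), n, N)
  expect_equal(coherence_rho(v), sqrt(1 / 2), tolerance = 0.05 / sqrt(0.5))
})

test_that("ISI cv: periodic -> 0, Poisson -> 1, sparse neurons excluded", {
  raster <- data.frame(t_ms = seq(10, 1000, by = 10), neuron = 1L)
  raster$pop <- "e"
  r <- isi_cv(raster)
  expect_equal(r$cv[1], 0)
  set.seed(3)
  tp <- cumsum(rexp(10000, rate = 0.1))
  raster2 <- data.frame(t_ms = c(tp, 1, 2), neuron = c(rep(1L, 10000), 2L, 2L))
  r2 <- isi_cv(raster2)
  expect_equal(r2$cv[1], 1, tolerance = 0.03)
  expect_true(is.na(r2$cv[2]))            # 2 spikes -> undefined
  expect_equal(r2$CV, r2$cv[1])           # population CV averages defined ones only
})

test_that("ISI cv of gamma-shaped renewal trains recovers 1/sqrt(shape)", {
  set.seed(11)
  for (shape in c(2, 4)) {
    tg <- cumsum(rgamma(8000, shape = shape, rate = 1))
    r <- isi_cv(data.frame(t_ms = tg, neuron = 1L))
    expect_equal(r$cv[1], 1 / sqrt(shape), tolerance = 0.05)
  }
})

test_that("rate trace conserves spike counts and recovers a Poisson rate", {
  expect_equal(sum(population_rate_trace(data.frame(t_ms = numeric(0),
                                                    neuron = integer(0),
                                                    pop = character(0)),
                                         5, 100, 10, 10)$R_e_Hz), 0)
  set.seed(5)
  N <- 1000; T_ms <- 10000; rate <- 10  # Hz
  n_sp <- rpois(1, N * rate * T_ms / 1000)
  raster <- data.frame(t_ms = runif(n_sp, 0, T_ms),
                       neuron = sample.int(N, n_sp, replace = TRUE))
  raster$pop <- "e"
  tr <- population_rate_trace(raster, 10, T_ms, N, 1)
  # exact conservation: integral * N * bin = total count
  expect_equal(sum(tr$R_e_Hz) / 1000 * 10 * N, n_sp)
  expect_lt(abs(mean(tr$R_e_Hz) - rate), 0.3)
})

test_that("power spectrum finds a pure tone and satisfies Parseval", {
  dt_s <- 0.01                  # 10 ms
  t <- (0:9999) * dt_s
  x <- sin(2 * pi * 3 * t)
  sp <- power_spectrum(x, 10, 10000)
  expect_equal(attr(sp, "delta_nu_Hz"), 0.01)
  expect_equal(sp$freq_Hz[which.max(sp$power)], 3.00, tolerance = 1e-9)
  expect_equal(sum(sp$power), mean((x - mean(x))^2), tolerance = 1e-8)
  expect_error(power_spectrum(x[1:100], 10, 10000), "shorter")
})

test_that("white-noise spectrum is flat across decades", {
  set.seed(9)
  sp <- power_spectrum(replicate(5, rnorm(10000), simplify = FALSE), 10, 10000)
  b1 <- mean(sp$power[sp$freq_Hz > 0.1 & sp$freq_Hz <= 1])
  b2 <- mean(sp$power[sp$freq_Hz > 1 & sp$freq_Hz <= 10])
  expect_lt(max(b1, b2) / min(b1, b2), 2)
})

test_that("quadratically mixed two-tone signal yields both fundamentals and combinations", {
  dt_s <- 0.01
  t <- (0:49999) * dt_s
  base <- sin(2 * pi * 1.30 * t) + 0.8 * sin(2 * pi * 0.40 * t)
  x <- base + 0.15 * base^2
  f <- fundamental_frequencies(power_spectrum(x, 10, 10000))
  expect_equal(f$nu_1, 1.30, tolerance = 1e-6)
  expect_equal(f$nu_2, 0.40, tolerance = 1e-6)
  expect_gt(f$validated_fraction, 0.9)
})

test_that("locking detection: 4:1 ratio locks as 1:4, golden ratio does not lock", {
  dt_s <- 0.01
  t <- (0:49999) * dt_s
  mk <- function(f2) sin(2 * pi * 1.6 * t) + 0.6 * sin(2 * pi * f2 * t) +
    0.1 * sin(2 * pi * (1.6 + f2) * t)
  lock <- fundamental_frequencies(power_spectrum(mk(0.4), 10, 10000))
  expect_true(lock$locked)
  expect_identical(lock$locking_order, "1:4")
  gold <- fundamental_frequencies(power_spectrum(mk(1.6 / 1.618034), 10, 10000))
  expect_false(gold$locked)
})

test_that("single periodic signal degenerates to one fundamental", {
  t <- (0:9999) * 0.01
  f <- fundamental_frequencies(power_spectrum(sin(2 * pi * 2 * t), 10, 10000))
  expect_equal(f$nu_1, 2)
  expect_true(is.na(f$nu_2))
  expect_error(fundamental_frequencies(power_spectrum(rep(0, 10000), 10, 10000)),
               "no oscillation")
})

test_that("rate distribution: parameter recovery, silent handling", {
  set.seed(21)
  mu <- log(5); sg <- 0.6
  rates <- exp(rnorm(1e4, mu, sg))
  fit <- rate_distribution(rates)
  expect_lt(abs(fit$mu_log - mu), 3 * sg / sqrt(1e4))
  expect_lt(abs(fit$sigma_log - sg), 3 * sg / sqrt(2e4))
  expect_equal(fit$mean_Hz, exp(mu + sg^2 / 2), tolerance = 0.05)
  allsilent <- rate_distribution(rep(0, 50))
  expect_equal(allsilent$silent_fraction, 1)
  expect_true(is.na(allsilent$mu_log))
  mix <- rate_distribution(c(rep(0.001, 30), rates))
  expect_equal(mix$silent_fraction, 30 / (30 + 1e4))
})

test_that("burst delay: zero for identical traces, recovers shifts, antisymmetric", {
  t <- seq(0, 5000, by = 1)
  x <- pmax(sin(2 * pi * t / 250), 0)^4
  expect_equal(burst_delay(x, x, t)$delay_ms, 0)
  shift <- function(x, k) x[((seq_along(x) - 1 - k) %% length(x)) + 1]
  y <- shift(x, 7)
  d <- burst_delay(x, y, t)
  expect_equal(d$delay_ms, 7, tolerance = 1)
  expect_equal(burst_delay(y, x, t)$delay_ms, -d$delay_ms, tolerance = 0.1)
  # near-simultaneous bursts: sub-sample shift is indistinguishable from zero
  set.seed(2)
  xn <- x + rnorm(length(x), 0, 0.01)
  yn <- x + rnorm(length(x), 0, 0.01)
  dn <- burst_delay(xn, yn, t)
  expect_lt(abs(dn$delay_ms), 2 * max(dn$sd_ms / sqrt(dn$n_cycles), 1))
  expect_error(burst_delay(rep(0:1, 3), rep(0:1, 3), 1:6), "not oscillatory")
})
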