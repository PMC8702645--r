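# Stationary solutions, expansions, effective currents and fluctuations.

test_that("balance feasibility follows the inequality chains", {
  expect_true(is_balance_feasible(params_async()))
  # I0_e/I0_i = 1.02 > g_ei/g_ii = 1.00935... > g_ee/g_ie = 0.9
  p <- params_async()
  expect_gt(p$I0_e / p$I0_i, p$g0_ei / p$g0_ii)
  expect_gt(p$g0_ei / p$g0_ii, p$g0_ee / p$g0_ie)
  # reversing the current ratio breaks the first chain and the second cannot hold
  expect_false(is_balance_feasible(model_params(I0_e = 0.2, I0_i = 0.2)))
})

test_that("parameter validation rejects non-physical values", {
  expect_error(model_params(tau_m_e = -1), "positive")
  expect_error(model_params(K = 0), "positive")
  expect_error(model_params(delta0_ee = -0.1), "non-negative")
})

test_that("derivative vanishes on the rate-zero manifold and at V-bar", {
  p <- params_async()
  d <- mf_derivative(macro_state(0, 0.3, 0, -0.2), p)
  expect_identical(unname(d[c(1, 3)]), c(0, 0))
  # R_e equation's bracket vanishes at V_e = -g_ee d_ee / (2 pi) for any R_e
  Vb_e <- -p$g0_ee * p$delta0_ee / (2 * pi)
  d2 <- mf_derivative(macro_state(7, Vb_e, 0, 0), p)
  expect_equal(unname(d2[1]), 0, tolerance = 1e-14)
  expect_error(mf_derivative(c(NaN, 0, 0, 0), p), "non-finite")
})

test_that("exact fixed point zeroes the vector field (self-consistency)", {
  for (K in c(100, 1000, 1e6)) {
    p <- params_async(K)
    fp <- stationary_state(p)
    expect_lt(fp$residual, 1e-12)
    d <- mf_derivative(macro_state(fp$R_bar_e, fp$V_bar_e, fp$R_bar_i, fp$V_bar_i), p)
    expect_lt(max(abs(d)), 1e-10)
    expect_true(fp$R_bar_e >= 0 && fp$R_bar_i >= 0)
  }
})

test_that("stationary mean potentials follow the heterogeneity widths", {
  p <- params_async()
  fp <- stationary_state(p)
  expect_equal(fp$V_bar_e, -0.27 * 2.5 / (2 * pi), tolerance = 1e-12)  # -0.10743
  expect_equal(fp$V_bar_i, -0.953939 * 1 / (2 * pi), tolerance = 1e-12)
})

test_that("zeroth-order balanced rates reproduce the asynchronous-set values", {
  ex <- rate_expansion(params_async(), 0)
  expect_equal(unname(ex$R_k_Hz[1, "e"]), 3.18, tolerance = 0.005 / 3.18)
  expect_equal(unname(ex$R_k_Hz[1, "i"]), 11.28, tolerance = 0.005 / 11.28)
})

test_that("first-order expansion satisfies the order-matching identity", {
  p <- params_async()
  ex <- rate_expansion(p, 1)
  x0 <- ex$x_k[1, ]; x1 <- ex$x_k[2, ]
  # tau (g_ee R1_e - g_ei R1_i) = (pi R0_e tau)^2 - V_bar_e^2, same for i
  expect_equal(p$g0_ee * x1[["e"]] - p$g0_ei * x1[["i"]],
               (pi * x0[["e"]])^2 - ex$V_bar[["e"]]^2, tolerance = 1e-12)
  expect_equal(p$g0_ie * x1[["e"]] - p$g0_ii * x1[["i"]],
               (pi * x0[["i"]])^2 - ex$V_bar[["i"]]^2, tolerance = 1e-12)
})

test_that("expansion partial sums improve order by order toward the exact solve", {
  for (K in c(1e4, 1e6)) {
    p <- params_async(K)
    exact_e <- stationary_state(p)$R_bar_e
    ex <- rate_expansion(p, 2)
    err <- abs(ex$partial_sums_Hz[, "e"] - exact_e)
    expect_lt(err[2], err[1])
    expect_lt(err[3], err[2])
  }
  # error contraction ~ factor eps per added order once K is deep enough in
  # the asymptotic regime (K = 1e6, eps = 1e-3); the series is asymptotic, so
  # the gains come pairwise and we check odd-order steps
  e_of <- function(K, ord) {
    p <- params_async(K)
    abs(rate_expansion(p, ord)$partial_sums_Hz[ord + 1, "e"] -
          stationary_state(p)$R_bar_e)
  }
  eps <- 1e-3
  expect_lt(e_of(1e6, 1) / e_of(1e6, 0), 10 * eps)
  expect_lt(e_of(1e6, 3) / e_of(1e6, 2), 10 * eps)
  # fixed order, growing K: order-0 error shrinks like eps
  expect_lt(e_of(1e6, 0) / e_of(1e4, 0), 10 * sqrt(1e4 / 1e6))
  expect_error(rate_expansion(model_params(g0_ee = 1, g0_ei = 1, g0_ie = 1,
                                           g0_ii = 1), 1),
               "degenerate coupling matrix")
})

test_that("effective currents: uncoupled limit and large-K convergence to Ia", {
  p <- params_async()
  # with (numerically) vanishing couplings I_eff = sqrt(K) I0
  p0 <- model_params(g0_ee = 1e-14, g0_ei = 1e-14, g0_ie = 1e-14, g0_ii = 2e-14,
                     I0_e = 0.2, K = 400)
  expect_equal(unname(effective_currents(p0, 5, 10)),
               unname(sqrt(400) * c(p0$I0_e, p0$I0_i)), tolerance = 1e-9)
  Ia <- asymptotic_effective_currents(p)
  expect_equal(unname(Ia), c(0.0284, 0.4791), tolerance = 2e-3)
  # identity: Ia_a = (pi R0_a tau)^2 - V_bar_a^2
  ex <- rate_expansion(p, 1)
  expect_equal(unname(Ia[[1]]), unname((pi * ex$x_k[1, "e"])^2 - ex$V_bar[["e"]]^2),
               tolerance = 1e-12)
  expect_equal(unname(Ia[[2]]), unname((pi * ex$x_k[1, "i"])^2 - ex$V_bar[["i"]]^2),
               tolerance = 1e-12)
  # I_eff at the truncated expansion R0 + eps R1 equals Ia identically (the
  # order-0 drive cancels and sqrt(K) eps = 1); at the exact rates the
  # difference decays as O(eps)
  s1 <- rate_expansion(p, 1)$partial_sums_Hz[2, ]
  expect_equal(unname(effective_currents(p, s1[["e"]], s1[["i"]])), unname(Ia),
               tolerance = 1e-9)
  dev <- sapply(c(1e4, 1e6, 1e8), function(K) {
    pK <- params_async(K)
    fp <- stationary_state(pK)
    max(abs(effective_currents(pK, fp$R_bar_e, fp$R_bar_i) - Ia))
  })
  expect_lt(dev[2], dev[1] * 0.15)
  expect_lt(dev[3], dev[2] * 0.15)
})

test_that("current fluctuations: zero rates, sqrt-homogeneity, asynchronous values", {
  p <- params_async()
  expect_equal(unname(current_fluctuations(p, 0, 0)), c(0, 0))
  d1 <- current_fluctuations(p, 4, 9)
  d2 <- current_fluctuations(p, 8, 18)
  expect_equal(unname(d2), unname(d1) * sqrt(2), tolerance = 1e-12)
  r0 <- rate_expansion(p, 0)$R_k_Hz[1, ]
  expect_equal(unname(current_fluctuations(p, r0[["e"]], r0[["i"]])),
               c(0.4623, 0.4593), tolerance = 2e-4)
})

test_that("expansion requires equal time constants; exact solve does not", {
  p <- model_params(I0_e = 0.2, tau_m_i = 25)
  expect_error(rate_expansion(p, 1), "equal membrane time constants")
  fp <- stationary_state(p)
  expect_lt(fp$residual, 1e-12)
})
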