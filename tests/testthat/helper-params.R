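# canonical parameter sets used throughout the tests

# asynchronous-regime set (heterogeneity widths 2.5 / 1.0, I0_e = 0.2)
params_async <- function(K = 1000) model_params(I0_e = 0.2, K = K)

# period-doubling cut: delta0_ee = 2.0, delta0_ii = 0.3, K = 1000
params_pd_cut <- function(I0e, tau_m_i = 20) {
  model_params(I0_e = I0e, I0_i = I0e / 1.02, K = 1000,
               delta0_ee = 2.0, delta0_ii = 0.3, tau_m_i = tau_m_i)
}

# subcritical-Hopf cut: delta0_ee = 1.58, delta0_ii = 0.3, K = 1000
params_subhopf_cut <- function(I0e) {
  model_params(I0_e = I0e, I0_i = I0e / 1.02, K = 1000,
               delta0_ee = 1.58, delta0_ii = 0.3)
}

TAU_M <- 20  # ms; printed Lyapunov/eigenvalue figures are exponents per tau_m
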