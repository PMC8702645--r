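#' Time derivative of the neural mass model
#'
#' Evaluates the vector field of the four-dimensional neural mass model. For
#' population \eqn{\alpha} (with its own membrane time constant
#' \eqn{\tau_m^{(\alpha)}}):
#' \deqn{\tau_m \dot R = R (2 V + g_0 \Delta_0 / \pi)}
#' \deqn{\tau_m \dot V = V^2 - (\pi R \tau_m)^2 +
#'   \sqrt{K}\,[I_0 + (g_{0,exc} R^{(e)} - g_{0,inh} R^{(i)}) \tau_m]}
#'
#' @param state a [macro_state()] (rates in Hz) or numeric 4-vector
#'   `(R_e, V_e, R_i, V_i)` with rates in Hz.
#' @param params a [model_params()] object.
#' @return named numeric 4-vector `(dR_e, dV_e, dR_i, dV_i)` in internal units
#'   (rates in 1/ms, time in ms).
#' @export
mf_derivative <- function(state, params) {
  validate_params(params)
  s <- state_vector(state)
  if (!all(is.finite(s))) stop("non-finite state")
  d <- cpp_mf_derivative(s, pars_vector(params))$deriv
  names(d) <- c("dR_e", "dV_e", "dR_i", "dV_i")
  d
}

#' Finite-in-degree expansion of the balanced stationary rates
#'
#' Expands the stationary population rates in powers of
#' \eqn{\varepsilon = 1/\sqrt{K}},
#' \eqn{\bar R^{(\alpha)} = \sum_k \varepsilon^k \bar R_k^{(\alpha)}}. At every
#' order the coefficients solve the same 2x2 linear system with inhomogeneity
#' \eqn{N_k^{(\alpha)}}: \eqn{N_0 = I_0}, \eqn{N_1 = \bar V^2 - (\pi \bar R_0
#' \tau_m)^2}, and higher orders are convolutions of lower-order rates. The
#' zeroth order is the classic balanced-state rate solution and is independent
#' of the structural heterogeneity; heterogeneity enters from order one through
#' \eqn{\bar V}.
#'
#' Defined for equal membrane time constants in the two populations.
#'
#' @param params a [model_params()] object (requires `tau_m_e == tau_m_i`).
#' @param max_order highest order kept (>= 0).
#' @return object of class `qif_expansion`: list with `eps`, matrices
#'   `R_k_Hz` (rows = orders 0..max_order, columns e/i) and `partial_sums_Hz`.
#' @examples
#' ex <- rate_expansion(model_params(I0_e = 0.2, K = 1000), 2)
#' ex$R_k_Hz[1, ]   # zeroth-order balanced rates, Hz
#' @export
rate_expansion <- function(params, max_order = 2) {
  validate_params(params)
  if (max_order < 0) stop("max_order must be >= 0")
  if (params$tau_m_e != params$tau_m_i)
    stop("the rate expansion is defined for equal membrane time constants")
  tau <- params$tau_m_e
  D <- params$g0_ei * params$g0_ie - params$g0_ee * params$g0_ii
  if (abs(D) < 1e-14) stop("degenerate coupling matrix")
  Vb <- c(e = -params$g0_ee * params$delta0_ee / (2 * pi),
          i = -params$g0_ii * params$delta0_ii / (2 * pi))
  m <- max_order
  xe <- numeric(m + 1); xi <- numeric(m + 1)  # x_k = R_k * tau (dimensionless)
  solve_order <- function(Ne, Ni) {
    c((Ne * params$g0_ii - Ni * params$g0_ei) / D,
      (Ne * params$g0_ie - Ni * params$g0_ee) / D)
  }
  x0 <- solve_order(params$I0_e, params$I0_i)
  xe[1] <- x0[1]; xi[1] <- x0[2]
  if (m >= 1) {
    N1e <- Vb[["e"]]^2 - (pi * xe[1])^2
    N1i <- Vb[["i"]]^2 - (pi * xi[1])^2
    x1 <- solve_order(N1e, N1i)
    xe[2] <- x1[1]; xi[2] <- x1[2]
  }
  if (m >= 2) {
    for (k in 2:m) {
      conv <- function(x) {
        if (k %% 2 == 0) {
          j <- k / 2
          -2 * pi^2 * sum(x[seq_len(j)] * x[k - seq_len(j) + 1])
        } else {
          j <- (k - 1) / 2
          -2 * pi^2 * (sum(x[seq_len(j)] * x[k - seq_len(j) + 1]) + 0.5 * x[j + 1]^2)
        }
      }
      xk <- solve_order(conv(xe), conv(xi))
      xe[k + 1] <- xk[1]; xi[k + 1] <- xk[2]
    }
  }
  eps <- 1 / sqrt(params$K)
  R_k <- cbind(e = xe, i = xi) / tau * 1000       # Hz
  rownames(R_k) <- paste0("order", 0:m)
  partial <- apply(R_k * eps^(0:m), 2, cumsum)
  if (m == 0) partial <- matrix(R_k * 1, 1, 2, dimnames = list("order0", c("e", "i")))
  structure(list(eps = eps, R_k_Hz = R_k, partial_sums_Hz = partial,
                 x_k = cbind(e = xe, i = xi), V_bar = Vb, params = params),
            class = "qif_expansion")
}

#' @export
print.qif_expansion <- function(x, ...) {
  cat(sprintf("Rate expansion in eps = 1/sqrt(K) = %.4g (orders 0..%d)\n",
              x$eps, nrow(x$R_k_Hz) - 1))
  print(round(x$R_k_Hz, 4))
  cat("partial sums (Hz):\n"); print(round(x$partial_sums_Hz, 4))
  invisible(x)
}

# order-0 rates in 1/ms for general (possibly unequal) tau_m:
# I0_a + tau_a (g_ae R_e - g_ai R_i) = 0 for a in {e,i}
order0_rates <- function(p) {
  A <- rbind(c(p$g0_ee * p$tau_m_e, -p$g0_ei * p$tau_m_e),
             c(p$g0_ie * p$tau_m_i, -p$g0_ii * p$tau_m_i))
  if (abs(det(A)) < 1e-14) stop("degenerate coupling matrix")
  drop(solve(A, -c(p$I0_e, p$I0_i)))
}

#' Stationary state of the neural mass model
#'
#' The stationary mean membrane potentials are fixed by the heterogeneity,
#' \eqn{\bar V^{(\alpha)} = -g_0^{(\alpha\alpha)} \Delta_0^{(\alpha\alpha)} /
#' (2\pi)}; the rates solve a quadratic 2x2 system. `method = "exact"` solves
#' that system by damped Newton iteration initialised at the zeroth-order
#' balanced solution (tolerance 1e-12 on the max-norm residual);
#' `method = "expansion"` returns the partial sum of [rate_expansion()] at the
#' requested order.
#'
#' @param params a [model_params()] object.
#' @param method `"exact"` or `"expansion"`.
#' @param order expansion order when `method = "expansion"`.
#' @param tol Newton tolerance on the residual max-norm.
#' @return object of class `qif_fixed_point`: `R_bar_e`, `R_bar_i` (Hz),
#'   `V_bar_e`, `V_bar_i`, `method`, `residual`, `balance_warning`.
#' @examples
#' stationary_state(model_params(I0_e = 0.2, K = 1000))
#' @export
stationary_state <- function(params, method = c("exact", "expansion"),
                             order = 1, tol = 1e-12) {
  validate_params(params)
  method <- match.arg(method)
  p <- params
  Vb_e <- -p$g0_ee * p$delta0_ee / (2 * pi)
  Vb_i <- -p$g0_ii * p$delta0_ii / (2 * pi)
  bal_warn <- !is_balance_feasible(p)
  if (method == "expansion") {
    ex <- rate_expansion(p, order)
    r <- ex$partial_sums_Hz[order + 1, ] / 1000
    if (any(r < 0)) stop("no physical fixed point")
    res <- max(abs(stationary_residual(c(r[1], r[2]), p)))
    fp <- list(R_bar_e = r[[1]] * 1000, R_bar_i = r[[2]] * 1000,
               V_bar_e = Vb_e, V_bar_i = Vb_i,
               method = sprintf("expansion(order %d)", order),
               residual = res, balance_warning = bal_warn, params = p)
    return(structure(fp, class = "qif_fixed_point"))
  }
  r <- pmax(order0_rates(p), 1e-12)
  G <- stationary_residual(r, p)
  for (iter in seq_len(300)) {
    if (max(abs(G)) < tol) break
    eps <- 1 / sqrt(p$K)
    J <- rbind(c(p$tau_m_e * p$g0_ee - 2 * eps * pi^2 * p$tau_m_e^2 * r[1],
                 -p$tau_m_e * p$g0_ei),
               c(p$tau_m_i * p$g0_ie,
                 -p$tau_m_i * p$g0_ii - 2 * eps * pi^2 * p$tau_m_i^2 * r[2]))
    step <- tryCatch(solve(J, -G), error = function(e) stop("no physical fixed point"))
    lam <- 1
    repeat {
      r_new <- r + lam * step
      G_new <- stationary_residual(r_new, p)
      if (sum(G_new^2) < sum(G^2) || lam < 1e-10) break
      lam <- lam / 2
    }
    r <- r_new; G <- G_new
  }
  if (max(abs(G)) > sqrt(tol)) stop("no physical fixed point")
  if (any(r < -1e-9)) stop("no physical fixed point")
  r <- pmax(r, 0)
  structure(list(R_bar_e = r[1] * 1000, R_bar_i = r[2] * 1000,
                 V_bar_e = Vb_e, V_bar_i = Vb_i, method = "exact-solve",
                 residual = max(abs(G)), balance_warning = bal_warn, params = p),
            class = "qif_fixed_point")
}

# residual of the stationary rate system at rates r (1/ms):
# G_a = I0_a + tau_a (g_ae r_e - g_ai r_i) + eps [Vb_a^2 - (pi r_a tau_a)^2]
stationary_residual <- function(r, p) {
  eps <- 1 / sqrt(p$K)
  Vb_e <- -p$g0_ee * p$delta0_ee / (2 * pi)
  Vb_i <- -p$g0_ii * p$delta0_ii / (2 * pi)
  c(p$I0_e + p$tau_m_e * (p$g0_ee * r[1] - p$g0_ei * r[2]) +
      eps * (Vb_e^2 - (pi * r[1] * p$tau_m_e)^2),
    p$I0_i + p$tau_m_i * (p$g0_ie * r[1] - p$g0_ii * r[2]) +
      eps * (Vb_i^2 - (pi * r[2] * p$tau_m_i)^2))
}

#' @export
print.qif_fixed_point <- function(x, ...) {
  cat(sprintf("Neural mass fixed point (%s), residual %.3g\n", x$method, x$residual))
  cat(sprintf("  R_bar = (%.4f, %.4f) Hz   V_bar = (%.5f, %.5f)\n",
              x$R_bar_e, x$R_bar_i, x$V_bar_e, x$V_bar_i))
  if (isTRUE(x$balance_warning))
    cat("  note: zeroth-order balance inequalities violated\n")
  invisible(x)
}

as_macro_state <- function(fp) {
  macro_state(fp$R_bar_e, fp$V_bar_e, fp$R_bar_i, fp$V_bar_i)
}

#' Effective input currents at the population level
#'
#' \eqn{I_{eff}^{(\alpha)} = \sqrt{K} [I_0^{(\alpha)} +
#' \tau_m^{(\alpha)} (g_0^{(\alpha e)} R^{(e)} - g_0^{(\alpha i)} R^{(i)})]}.
#' In a balanced state these stay finite as \eqn{K} grows.
#'
#' @param params a [model_params()] object.
#' @param R_e,R_i population rates in Hz (>= 0).
#' @return named vector `c(I_eff_e, I_eff_i)`.
#' @export
effective_currents <- function(params, R_e, R_i) {
  validate_params(params)
  if (R_e < 0 || R_i < 0) stop("rates must be non-negative")
  re <- R_e / 1000; ri <- R_i / 1000
  sK <- sqrt(params$K)
  c(I_eff_e = sK * (params$I0_e + params$tau_m_e *
                      (params$g0_ee * re - params$g0_ei * ri)),
    I_eff_i = sK * (params$I0_i + params$tau_m_i *
                      (params$g0_ie * re - params$g0_ii * ri)))
}

#' Asymptotic effective currents in the large-K limit
#'
#' The \eqn{K \to \infty} limits of the effective currents, determined by the
#' first-order coefficients of the balanced-rate expansion:
#' \eqn{I_a^{(\alpha)} = \tau_m (g_0^{(\alpha e)} \bar R_1^{(e)} -
#' g_0^{(\alpha i)} \bar R_1^{(i)})}. Equivalently
#' \eqn{I_a^{(\alpha)} = (\pi \bar R_0^{(\alpha)} \tau_m)^2 -
#' (\bar V^{(\alpha)})^2}.
#'
#' @param params a [model_params()] object (equal time constants).
#' @return named vector `c(Ia_e, Ia_i)`.
#' @export
asymptotic_effective_currents <- function(params) {
  ex <- rate_expansion(params, 1)
  x1 <- ex$x_k[2, ]
  c(Ia_e = params$g0_ee * x1[["e"]] - params$g0_ei * x1[["i"]],
    Ia_i = params$g0_ie * x1[["e"]] - params$g0_ii * x1[["i"]])
}

#' Poissonian amplitude of the input-current fluctuations
#'
#' Assuming each neuron receives K independent Poisson trains per population at
#' the given rates, the fluctuation amplitude of the effective input current is
#' \deqn{\Delta I^{(\alpha)} = \sqrt{\tau_m [ (g_0^{(\alpha e)})^2 R^{(e)} +
#'   (g_0^{(\alpha i)})^2 R^{(i)} ]},}
#' independent of K. Monotone non-decreasing in each rate; homogeneous of
#' degree 1/2 (doubling both rates scales both amplitudes by sqrt(2)).
#'
#' @param params a [model_params()] object.
#' @param R_e,R_i population rates in Hz (>= 0).
#' @return named vector `c(dI_e, dI_i)`.
#' @export
current_fluctuations <- function(params, R_e, R_i) {
  validate_params(params)
  if (R_e < 0 || R_i < 0) stop("rates must be non-negative")
  re <- R_e / 1000; ri <- R_i / 1000
  c(dI_e = sqrt(params$tau_m_e * (params$g0_ee^2 * re + params$g0_ei^2 * ri)),
    dI_i = sqrt(params$tau_m_i * (params$g0_ie^2 * re + params$g0_ii^2 * ri)))
}
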