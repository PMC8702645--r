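# Linear stability of neural mass fixed points: Jacobian eigenvalues,
# large-K reduced spectrum, and Hopf location by eigenvalue bisection.

# analytic 4x4 Jacobian of the vector field at a state (internal units)
mf_jacobian_matrix <- function(s, p) {
  Re <- s[1]; Ve <- s[2]; Ri <- s[3]; Vi <- s[4]
  sK <- sqrt(p$K)
  J <- matrix(0, 4, 4)
  J[1, 1] <- (2 * Ve + p$g0_ee * p$delta0_ee / pi) / p$tau_m_e
  J[1, 2] <- 2 * Re / p$tau_m_e
  J[2, 1] <- -2 * pi^2 * p$tau_m_e * Re + sK * p$g0_ee
  J[2, 2] <- 2 * Ve / p$tau_m_e
  J[2, 3] <- -sK * p$g0_ei
  J[3, 3] <- (2 * Vi + p$g0_ii * p$delta0_ii / pi) / p$tau_m_i
  J[3, 4] <- 2 * Ri / p$tau_m_i
  J[4, 1] <- sK * p$g0_ie
  J[4, 3] <- -2 * pi^2 * p$tau_m_i * Ri - sK * p$g0_ii
  J[4, 4] <- 2 * Vi / p$tau_m_i
  J
}

classify_spectrum <- function(ev) {
  re <- Re(ev); im <- Im(ev)
  lead <- which(re > max(re) - 1e-12)
  lead_complex <- any(abs(im[lead]) > 1e-9)
  if (max(re) < 0) {
    if (lead_complex) "stable focus" else "stable node"
  } else {
    if (lead_complex) "unstable focus" else "saddle-like"
  }
}

#' Eigenvalues of the neural mass Jacobian at a fixed point
#'
#' Linearises the neural mass model at a stationary solution and returns the
#' four eigenvalues (units 1/ms), the fixed-point class, and the relaxation
#' frequencies \eqn{\nu_k = \mathrm{Im}\,\Lambda^{(k)} / (2\pi)} in Hz. For a
#' stable focus these frequencies predict the frequencies of the
#' fluctuation-driven collective oscillations seen in the network.
#'
#' @param params a [model_params()] object.
#' @param fp a `qif_fixed_point` from [stationary_state()]; computed if `NULL`.
#' @param tol residual tolerance above which `fp` is rejected.
#' @return object of class `qif_eigen`: `values` (complex, 1/ms, ordered by
#'   decreasing real part), `class`, `nu_Hz`, `max_re`.
#' @examples
#' p <- model_params(I0_e = 0.006, delta0_ee = 2, delta0_ii = 0.3, K = 1000,
#'                   I0_i = 0.006 / 1.02)
#' jacobian_eigenvalues(p)
#' @export
jacobian_eigenvalues <- function(params, fp = NULL, tol = 1e-8) {
  validate_params(params)
  if (is.null(fp)) fp <- stationary_state(params)
  s <- state_vector(as_macro_state(fp))
  d <- cpp_mf_derivative(s, pars_vector(params))$deriv
  if (max(abs(d)) > tol) stop("not a fixed point")
  ev <- eigen(mf_jacobian_matrix(s, params), only.values = TRUE)$values
  ev <- ev[order(-Re(ev), -Im(ev))]
  structure(list(values = ev, class = classify_spectrum(ev),
                 nu_Hz = Im(ev) / (2 * pi) * 1000, max_re = max(Re(ev)),
                 fixed_point = fp),
            class = "qif_eigen")
}

#' @export
print.qif_eigen <- function(x, ...) {
  cat(sprintf("Fixed-point spectrum (%s), max Re = %.5g 1/ms\n", x$class, x$max_re))
  for (k in seq_along(x$values))
    cat(sprintf("  L%d = %+.5g %+.5g i  (nu = %.4g Hz)\n", k,
                Re(x$values[k]), Im(x$values[k]), abs(x$nu_Hz[k])))
  invisible(x)
}

#' Large-K approximation of the fixed-point spectrum
#'
#' In the limit of large median in-degree the linearisation reduces to a 4x4
#' system with zero trace in which only the zeroth-order rates enter; its
#' eigenvalues scale as \eqn{K^{1/4}} and (with both DC currents proportional)
#' as \eqn{\sqrt{I_0^{(e)}}}. The eigenvalues are computed numerically from the
#' reduced matrix.
#'
#' @param params a [model_params()] object.
#' @return object of class `qif_eigen` (reduced-system eigenvalues).
#' @export
largeK_eigenvalues <- function(params) {
  validate_params(params)
  r0 <- order0_rates(params)
  if (any(r0 <= 0)) stop("order-0 rates non-physical")
  sK <- sqrt(params$K)
  M <- matrix(0, 4, 4)
  M[1, 2] <- 2 * r0[1] / params$tau_m_e
  M[2, 1] <- sK * params$g0_ee
  M[2, 3] <- -sK * params$g0_ei
  M[3, 4] <- 2 * r0[2] / params$tau_m_i
  M[4, 1] <- sK * params$g0_ie
  M[4, 3] <- -sK * params$g0_ii
  ev <- eigen(M, only.values = TRUE)$values
  ev <- ev[order(-Re(ev), -Im(ev))]
  structure(list(values = ev, class = classify_spectrum(ev),
                 nu_Hz = Im(ev) / (2 * pi) * 1000, max_re = max(Re(ev)),
                 fixed_point = NULL),
            class = "qif_eigen")
}

set_control <- function(params, control, value) {
  p <- unclass(params)
  switch(control,
    I0 = {   # move I0_e, preserving the I0_e / I0_i ratio of `params`
      ratio <- params$I0_e / params$I0_i
      p$I0_e <- value; p$I0_i <- value / ratio
    },
    I0_e = p$I0_e <- value,
    I0_i = p$I0_i <- value,
    delta0_ee = p$delta0_ee <- value,
    delta0_ii = p$delta0_ii <- value,
    K = p$K <- value,
    stop(sprintf("unknown control parameter '%s'", control))
  )
  structure(p, class = "qif_params")
}

#' Locate a Hopf bifurcation by eigenvalue bisection
#'
#' Bisects a control parameter on the sign of the maximal real part of the
#' fixed-point Jacobian eigenvalues, re-solving the stationary state at each
#' step. A Hopf point is confirmed when the crossing eigenvalue pair has a
#' nonzero imaginary part; the crossing frequency
#' \eqn{\mathrm{Im}\,\Lambda/(2\pi)} is reported in Hz.
#'
#' @param params a [model_params()] object (values at the bracket ends are
#'   overridden by `control`).
#' @param control one of `"I0"` (moves `I0_e` preserving the `I0_e/I0_i`
#'   ratio), `"I0_e"`, `"I0_i"`, `"delta0_ee"`, `"delta0_ii"`, `"K"`.
#' @param bracket numeric `c(low, high)` with opposite stability at the ends.
#' @param tol relative tolerance on the control parameter.
#' @param max_iter bisection iteration cap.
#' @return list with `value` (critical control value), `frequency_Hz`,
#'   `is_hopf`, `iterations`, `control`.
#' @export
find_hopf <- function(params, control = "I0", bracket, tol = 1e-6,
                      max_iter = 60) {
  validate_params(params)
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  f <- function(v) {
    p <- set_control(params, control, v)
    fp <- tryCatch(stationary_state(p), error = function(e) NULL)
    if (is.null(fp)) stop("fixed point vanished")
    jacobian_eigenvalues(p, fp)
  }
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- f(lo); e_hi <- f(hi)
  if (sign(e_lo$max_re) == sign(e_hi$max_re)) stop("no crossing")
  it <- 0
  while (it < max_iter && (hi - lo) > tol * abs(hi)) {
    mid <- 0.5 * (lo + hi)
    e_mid <- f(mid)
    if (sign(e_mid$max_re) == sign(e_lo$max_re)) {
      lo <- mid; e_lo <- e_mid
    } else {
      hi <- mid; e_hi <- e_mid
    }
    it <- it + 1
  }
  crit <- 0.5 * (lo + hi)
  e_c <- f(crit)
  lead <- e_c$values[which.max(Re(e_c$values))]
  is_hopf <- abs(Im(lead)) > 1e-6
  if (!is_hopf) warning("non-Hopf crossing")
  list(value = crit, frequency_Hz = abs(Im(lead)) / (2 * pi) * 1000,
       is_hopf = is_hopf, iterations = it, control = control)
}
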