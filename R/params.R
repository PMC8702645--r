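#' Model parameters for the balanced E-I QIF network and its neural mass model
#'
#' Collects the rescaled synaptic couplings \eqn{g_0^{(\alpha\beta)}}, rescaled
#' DC currents \eqn{I_0^{(\alpha)}}, the median in-degree \eqn{K}, the
#' structural-heterogeneity widths \eqn{\Delta_0^{(\alpha\alpha)}} and the
#' membrane time constants. The physical (unrescaled) quantities are
#' \eqn{I^{(\alpha)} = \sqrt{K} I_0^{(\alpha)}} and
#' \eqn{g^{(\alpha\beta)} = g_0^{(\alpha\beta)}/\sqrt{K}}; the in-degree
#' distribution half-width is \eqn{\Delta_k = \Delta_0 \sqrt{K}}.
#'
#' The defaults are the canonical coupling set used throughout the analyses
#' (\eqn{g_0^{(ee)}=0.27}, \eqn{g_0^{(ii)}=0.953939}, \eqn{g_0^{(ie)}=0.3},
#' \eqn{g_0^{(ei)}=0.96286}, \eqn{I_0^{(i)} = I_0^{(e)}/1.02}).
#'
#' @param g0_ee,g0_ei,g0_ie,g0_ii coupling magnitudes (dimensionless, > 0);
#'   first index is the postsynaptic population.
#' @param I0_e,I0_i rescaled DC currents (dimensionless).
#' @param K median in-degree (> 0; real-valued in the mean field, integer when
#'   used to build a network).
#' @param delta0_ee,delta0_ii heterogeneity widths \eqn{\Delta_0} (>= 0).
#' @param tau_m_e,tau_m_i membrane time constants in ms (> 0).
#' @return an object of class `qif_params` (named list).
#' @examples
#' p <- model_params(I0_e = 0.2, K = 1000)
#' is_balance_feasible(p)
#' @export
model_params <- function(g0_ee = 0.27, g0_ei = 0.96286, g0_ie = 0.3,
                         g0_ii = 0.953939, I0_e = 0.2, I0_i = I0_e / 1.02,
                         K = 1000, delta0_ee = 2.5, delta0_ii = 1,
                         tau_m_e = 20, tau_m_i = 20) {
  p <- list(g0_ee = g0_ee, g0_ei = g0_ei, g0_ie = g0_ie, g0_ii = g0_ii,
            I0_e = I0_e, I0_i = I0_i, K = K,
            delta0_ee = delta0_ee, delta0_ii = delta0_ii,
            tau_m_e = tau_m_e, tau_m_i = tau_m_i)
  validate_params(p)
  structure(p, class = "qif_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("g0_ee", "g0_ei", "g0_ie", "g0_ii", "K", "tau_m_e", "tau_m_i")) {
    if (!num1(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", f))
  }
  for (f in c("delta0_ee", "delta0_ii")) {
    if (!num1(p[[f]]) || p[[f]] < 0)
      stop(sprintf("parameter '%s' must be a single non-negative number", f))
  }
  for (f in c("I0_e", "I0_i")) {
    if (!num1(p[[f]])) stop(sprintf("parameter '%s' must be a single finite number", f))
  }
  invisible(p)
}

#' Balanced-state feasibility of the zeroth-order solution
#'
#' Evaluates the inequality chains that guarantee non-negative zeroth-order
#' (\eqn{K \to \infty}) balanced rates: either
#' \eqn{I_0^{(e)}/I_0^{(i)} > g_0^{(ei)}/g_0^{(ii)} > g_0^{(ee)}/g_0^{(ie)}}
#' or the fully reversed chain.
#'
#' @param params a [model_params()] object.
#' @return `TRUE` if either chain holds.
#' @export
is_balance_feasible <- function(params) {
  validate_params(params)
  ratio <- params$I0_e / params$I0_i
  c1 <- params$g0_ei / params$g0_ii
  c2 <- params$g0_ee / params$g0_ie
  (ratio > c1 && c1 > c2) || (ratio < c1 && c1 < c2)
}

# named numeric vector handed to the compiled integrators
pars_vector <- function(p) {
  c(g0_ee = p$g0_ee, g0_ei = p$g0_ei, g0_ie = p$g0_ie, g0_ii = p$g0_ii,
    I0_e = p$I0_e, I0_i = p$I0_i, K = p$K,
    delta0_ee = p$delta0_ee, delta0_ii = p$delta0_ii,
    tau_m_e = p$tau_m_e, tau_m_i = p$tau_m_i)
}

#' @export
print.qif_params <- function(x, ...) {
  cat("QIF balanced-network parameters\n")
  cat(sprintf("  couplings  g0: ee=%.6g ei=%.6g ie=%.6g ii=%.6g\n",
              x$g0_ee, x$g0_ei, x$g0_ie, x$g0_ii))
  cat(sprintf("  DC currents I0: e=%.6g i=%.6g   median in-degree K=%g\n",
              x$I0_e, x$I0_i, x$K))
  cat(sprintf("  heterogeneity Delta0: ee=%.4g ii=%.4g   tau_m: e=%g ms i=%g ms\n",
              x$delta0_ee, x$delta0_ii, x$tau_m_e, x$tau_m_i))
  cat(sprintf("  zeroth-order balance feasible: %s\n", is_balance_feasible(x)))
  invisible(x)
}

#' Macroscopic state of the neural mass model
#'
#' A point \eqn{(R^{(e)}, V^{(e)}, R^{(i)}, V^{(i)})} of the four-dimensional
#' neural mass phase space. Rates are given in Hz at the interface and stored
#' internally in 1/ms; mean membrane potentials are dimensionless.
#'
#' @param R_e,R_i population rates in Hz (>= 0).
#' @param V_e,V_i mean membrane potentials.
#' @return object of class `qif_state` with fields in Hz.
#' @export
macro_state <- function(R_e, V_e, R_i, V_i) {
  v <- c(R_e = R_e, V_e = V_e, R_i = R_i, V_i = V_i)
  if (!all(is.finite(v))) stop("non-finite state")
  if (R_e < 0 || R_i < 0) stop("rates must be non-negative")
  structure(as.list(v), class = "qif_state")
}

# internal-unit vector (R in 1/ms) from a qif_state / 4-vector (Hz convention)
state_vector <- function(state) {
  if (inherits(state, "qif_state"))
    c(state$R_e / 1000, state$V_e, state$R_i / 1000, state$V_i)
  else if (is.numeric(state) && length(state) == 4L)
    c(state[1] / 1000, state[2], state[3] / 1000, state[4])
  else stop("state must be a qif_state or a numeric 4-vector (R_e, V_e, R_i, V_i) with rates in Hz")
}

#' @export
print.qif_state <- function(x, ...) {
  cat(sprintf("qif_state: R_e=%.4g Hz  V_e=%.4g  R_i=%.4g Hz  V_i=%.4g\n",
              x$R_e, x$V_e, x$R_i, x$V_i))
  invisible(x)
}
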