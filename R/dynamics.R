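# Time-domain analysis of the neural mass model: RK4 integration, Benettin
# Lyapunov spectra, peak-map bifurcation diagrams, PING delay, regime labels.

escape_error <- function(t_escape) {
  stop(structure(class = c("qif_escape", "error", "condition"),
                 list(message = sprintf("trajectory escaped at t = %.6g ms", t_escape),
                      call = sys.call(-1), t_escape = t_escape)))
}

default_init <- function(params) {
  fp <- tryCatch(stationary_state(params), error = function(e) NULL)
  if (is.null(fp)) {
    r0 <- pmax(order0_rates(params), 1e-4) * 1000
    macro_state(r0[1] * 1.01, -params$g0_ee * params$delta0_ee / (2 * pi),
                r0[2] * 1.01, -params$g0_ii * params$delta0_ii / (2 * pi))
  } else {
    macro_state(fp$R_bar_e * 1.01 + 0.01, fp$V_bar_e,
                fp$R_bar_i * 1.01 + 0.01, fp$V_bar_i)
  }
}

#' Integrate the neural mass model (RK4)
#'
#' Fixed-step 4th-order Runge-Kutta integration of the four-dimensional neural
#' mass model. Rates are clipped at zero when round-off drives them negative
#' (counted; more than 0.1% of steps is treated as a too-large step size and
#' raises an error). Trajectories whose potentials or dimensionless rates
#' exceed an overflow guard are declared escaped (condition class
#' `qif_escape`), the expected outcome in the unstable-focus regime.
#'
#' @param params a [model_params()] object.
#' @param init initial [macro_state()] (default: slightly perturbed fixed
#'   point).
#' @param dt integration step, ms (default 0.01).
#' @param T integrated time after the transient, ms.
#' @param transient discarded initial time, ms.
#' @param stride sampling stride in steps for the returned trace.
#' @param guard overflow guard on `|V|` and `tau_m * R`.
#' @return a `data.frame` of class `qif_trace` with columns
#'   `t_ms, R_e_Hz, V_e, R_i_Hz, V_i`; attributes `n_clip`, `final_state`.
#' @export
integrate_mf <- function(params, init = NULL, dt = 0.01, T = 1000,
                         transient = 0, stride = 10L, guard = 1e6) {
  validate_params(params)
  stopifnot(dt > 0, T > 0, transient >= 0)
  if (is.null(init)) init <- default_init(params)
  s0 <- state_vector(init)
  if (any(s0[c(1, 3)] < 0)) stop("initial rates must be non-negative")
  n_tr <- round(transient / dt); n_st <- round(T / dt)
  out <- cpp_integrate_mf(s0, pars_vector(params), dt, n_tr, n_st,
                          as.integer(stride), guard)
  if (isTRUE(out$escaped)) escape_error(out$t_escape)
  if (out$n_clip > 0.001 * (n_tr + n_st))
    stop("negative-rate clipping exceeded 0.1% of steps; reduce dt")
  tr <- out$trace
  df <- data.frame(t_ms = tr[, 1], R_e_Hz = tr[, 2] * 1000, V_e = tr[, 3],
                   R_i_Hz = tr[, 4] * 1000, V_i = tr[, 5])
  attr(df, "n_clip") <- out$n_clip
  attr(df, "final_state") <- macro_state(out$final[1] * 1000, out$final[2],
                                         out$final[3] * 1000, out$final[4])
  class(df) <- c("qif_trace", "data.frame")
  df
}

#' Lyapunov spectrum of the neural mass model (Benettin algorithm)
#'
#' Propagates the reference trajectory together with four tangent vectors
#' (linearised dynamics evaluated along the orbit) and re-orthonormalises the
#' tangent frame by modified Gram-Schmidt at a fixed step interval; the
#' Lyapunov exponents are the time-averaged logarithmic stretching factors.
#' At a stable focus the spectrum equals the multiset of eigenvalue real
#' parts; a limit cycle has \eqn{\lambda_1 = 0}; chaos has
#' \eqn{\lambda_1 > 0} with \eqn{\lambda_2 = 0}.
#'
#' @inheritParams integrate_mf
#' @param T averaging time after the transient, ms (default 200 s).
#' @param transient discarded time, ms (default 10 s).
#' @param renorm_every re-orthonormalisation interval in steps.
#' @param seed seed for the random initial orthonormal tangent frame.
#' @return object of class `qif_lyapunov`: `lambda` (sorted, 1/ms),
#'   `trace` (running estimates), `settings`.
#' @export
lyapunov_spectrum <- function(params, init = NULL, dt = 0.01, T = 200000,
                              transient = 10000, renorm_every = 10L,
                              seed = 1L, guard = 1e6) {
  validate_params(params)
  stopifnot(dt > 0, T > transient || transient >= 0)
  if (is.null(init)) init <- default_init(params)
  s0 <- state_vector(init)
  set.seed(seed)
  Q0 <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  n_tr <- round(transient / dt); n_st <- round(T / dt)
  out <- cpp_lyapunov(s0, pars_vector(params), dt, n_tr, n_st,
                      as.integer(renorm_every), Q0, guard, 200L)
  if (isTRUE(out$escaped)) escape_error(out$t_escape)
  lam <- sort(out$lambda, decreasing = TRUE)
  tr <- out$trace
  colnames(tr) <- c("t_ms", paste0("lambda", 1:4))
  structure(list(lambda = lam, trace = tr,
                 settings = list(dt = dt, T = T, transient = transient,
                                 renorm_every = renorm_every, seed = seed)),
            class = "qif_lyapunov")
}

#' @export
print.qif_lyapunov <- function(x, ...) {
  cat("Lyapunov spectrum (1/ms):",
      paste(sprintf("%+.5g", x$lambda), collapse = "  "), "\n")
  cat(sprintf("  dt = %g ms, T = %g s, transient = %g s\n",
              x$settings$dt, x$settings$T / 1000, x$settings$transient / 1000))
  invisible(x)
}

# group sorted maxima into clusters: a new cluster starts when the relative
# gap to the previous value exceeds `tol`
cluster_peaks <- function(v, tol = 0.005) {
  if (length(v) == 0) return(list(centers = numeric(0), sizes = integer(0)))
  v <- sort(v)
  scale <- pmax(abs(v[-1]), 1e-12)
  breaks <- which(diff(v) / scale > tol)
  idx <- cumsum(c(1, seq_along(v)[-1] %in% (breaks + 1)))
  centers <- tapply(v, idx, mean)
  sizes <- tapply(v, idx, length)
  list(centers = as.numeric(centers), sizes = as.integer(sizes))
}

#' Peak-map bifurcation diagram
#'
#' For each value of the control parameter, integrates the neural mass model
#' and collects the local maxima of the excitatory rate after the transient.
#' Maxima are grouped into clusters at a relative tolerance; the number of
#' distinct clusters identifies period-1/2/4 bands and chaotic bands. At least
#' `min_peaks` post-transient maxima are required before clusters are counted.
#' Control values whose trajectory escapes are flagged (`escaped = TRUE`) and
#' excluded from clustering.
#'
#' @inheritParams find_hopf
#' @param control_values numeric vector of control-parameter values.
#' @param dt,T,transient integration settings, ms.
#' @param cluster_tol relative distance for grouping maxima.
#' @param min_peaks minimum number of maxima required to count bands.
#' @return object of class `qif_peak_map`: `summary` data.frame (columns
#'   `value, n_peaks, n_clusters, escaped`) and `detail` list (per value:
#'   `peaks_Hz`, `times_ms`, `clusters_Hz`).
#' @export
peak_map <- function(params, control = "I0", control_values, dt = 0.01,
                     T = 60000, transient = 20000, cluster_tol = 0.005,
                     min_peaks = 200L, guard = 1e6) {
  validate_params(params)
  detail <- vector("list", length(control_values))
  summary <- data.frame(value = control_values, n_peaks = NA_integer_,
                        n_clusters = NA_integer_, escaped = FALSE)
  for (j in seq_along(control_values)) {
    p <- set_control(params, control, control_values[j])
    init <- default_init(p)
    out <- cpp_mf_peaks(state_vector(init), pars_vector(p), dt,
                        round(transient / dt), round(T / dt), guard, 100000L)
    if (isTRUE(out$escaped)) {
      summary$escaped[j] <- TRUE
      detail[[j]] <- list(escaped = TRUE)
      next
    }
    pk <- out$peaks_e * 1000
    cl <- cluster_peaks(pk, cluster_tol)
    summary$n_peaks[j] <- length(pk)
    summary$n_clusters[j] <- if (length(pk) >= min_peaks)
      length(cl$centers) else NA_integer_
    detail[[j]] <- list(peaks_Hz = pk, times_ms = out$times_e,
                        clusters_Hz = cl$centers, escaped = FALSE)
  }
  structure(list(summary = summary, detail = detail, control = control),
            class = "qif_peak_map")
}

#' @export
print.qif_peak_map <- function(x, ...) {
  cat(sprintf("Peak map over %s (%d values)\n", x$control, nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' Excitatory-to-inhibitory burst delay in the neural mass model
#'
#' In the oscillatory (PING-like) regime the excitatory rate peak precedes the
#' inhibitory one by a delay \eqn{\Delta t}. Integrates the model (each
#' population uses its own membrane time constant) and measures the circular
#' mean over cycles of the time from each inhibitory rate peak back to the
#' preceding excitatory peak.
#'
#' @inheritParams integrate_mf
#' @param T,transient integration settings, ms.
#' @return list with `delay_ms`, `sd_ms`, `n_cycles`, `period_ms`.
#' @export
ping_delay_mf <- function(params, dt = 0.01, T = 20000, transient = 10000,
                          guard = 1e6) {
  validate_params(params)
  tr <- integrate_mf(params, dt = dt, T = T, transient = transient,
                     stride = 10L, guard = guard)
  # a genuine collective oscillation, not residual ringing around a focus
  amp <- diff(range(tr$R_e_Hz))
  if (amp < 0.01 * max(tr$R_e_Hz, 1e-12)) stop("not oscillatory")
  burst_delay(tr$R_e_Hz, tr$R_i_Hz, tr$t_ms)
}

# circular mean of (inhibitory peak time - preceding excitatory peak time),
# delays mapped into (-period/2, period/2]
delay_between_peaks <- function(t_e, t_i) {
  period <- median(diff(t_e))
  d <- vapply(t_i, function(ti) {
    prev <- t_e[t_e <= ti]
    if (length(prev) == 0) return(NA_real_)
    ti - max(prev)
  }, numeric(1))
  d <- d[!is.na(d)] %% period
  d[d > period / 2] <- d[d > period / 2] - period
  if (length(d) < 5) stop("not oscillatory")
  list(delay_ms = mean(d), sd_ms = sd(d), n_cycles = length(d),
       period_ms = period)
}

#' Classify the dynamical regime of the neural mass model
#'
#' Decision tree over the fixed-point spectrum and, when the fixed point is
#' unstable or absent, the Lyapunov spectrum of the attractor:
#' stable fixed point with real leading eigenvalue -> III (stable node);
#' stable with complex leading pair -> II (stable focus); unstable with a
#' bounded attractor: \eqn{|\lambda_1|} below `lam_tol` -> IV (stable limit
#' cycle), \eqn{\lambda_1 >} `lam_tol` -> V (chaos); trajectory escape -> I
#' (unstable focus, no bounded collective solution). The unstable limit cycle
#' coexisting with the stable focus of region II is not searched for.
#'
#' @inheritParams lyapunov_spectrum
#' @param T,transient Lyapunov averaging settings, ms.
#' @param lam_tol tolerance on a zero Lyapunov exponent, 1/ms.
#' @return object of class `qif_regime`: `label` in
#'   `c("I_unstable_focus","II_stable_focus","III_stable_node",
#'     "IV_stable_LC","V_chaotic","indeterminate")`, `co_class` in
#'   `c("O_P","O_F","O_S","none")`, plus `details`.
#' @export
classify_regime <- function(params, dt = 0.01, T = 50000, transient = 10000,
                            lam_tol = 1e-3, seed = 1L) {
  validate_params(params)
  eig <- tryCatch(jacobian_eigenvalues(params), error = function(e) NULL)
  if (!is.null(eig) && eig$max_re < 0) {
    lab <- if (eig$class == "stable node") "III_stable_node" else "II_stable_focus"
    return(structure(list(label = lab, co_class = "O_F",
                          details = list(eigen = eig,
                                         note = "coexisting unstable LC in II not searched for")),
                     class = "qif_regime"))
  }
  ly <- tryCatch(
    lyapunov_spectrum(params, dt = dt, T = T, transient = transient, seed = seed),
    qif_escape = function(e) e)
  if (inherits(ly, "qif_escape"))
    return(structure(list(label = "I_unstable_focus", co_class = "O_S",
                          details = list(eigen = eig, escape = ly$t_escape)),
                     class = "qif_regime"))
  l1 <- ly$lambda[1]
  lab <- if (abs(l1) < lam_tol) "IV_stable_LC"
         else if (l1 > lam_tol) "V_chaotic"
         else "indeterminate"
  structure(list(label = lab, co_class = if (lab == "indeterminate") "none" else "O_P",
                 details = list(eigen = eig, lyapunov = ly)),
            class = "qif_regime")
}

#' @export
print.qif_regime <- function(x, ...) {
  cat(sprintf("Neural mass regime: %s (collective-oscillation class %s)\n",
              x$label, x$co_class))
  invisible(x)
}
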