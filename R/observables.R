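# Macroscopic and microscopic diagnostics: coherence, ISI variability,
# binned rates, power spectra, fundamental frequencies, rate distributions,
# burst delays.

#' Coherence indicator of a neural population
#'
#' \deqn{\rho = \left( \sigma_V^2 \Big/ \frac{1}{N}\sum_i \sigma_i^2
#' \right)^{1/2},} the ratio of the variance of the mean membrane potential to
#' the mean single-neuron variance. Perfect synchrony gives \eqn{\rho = 1};
#' asynchronous dynamics give \eqn{\rho \sim N^{-1/2}}.
#'
#' @param v_samples numeric matrix of membrane potentials, time samples in
#'   rows and neurons in columns (>= 2 of each).
#' @return the scalar coherence.
#' @export
coherence_rho <- function(v_samples) {
  v_samples <- as.matrix(v_samples)
  if (nrow(v_samples) < 2 || ncol(v_samples) < 2)
    stop("need at least 2 neurons and 2 time samples")
  vars <- apply(v_samples, 2, var)
  if (all(vars == 0)) stop("degenerate traces")
  sqrt(var(rowMeans(v_samples)) / mean(vars))
}

#' Inter-spike-interval coefficient of variation
#'
#' Per-neuron cv = SD(ISI)/mean(ISI), defined for neurons with at least 3
#' spikes; the population CV is the mean over neurons with a defined cv.
#'
#' @param raster data.frame with columns `t_ms` and `neuron` (as returned in
#'   `$raster` by [simulate_network()]).
#' @param n_neurons number of neurons (defaults to `max(raster$neuron)`).
#' @return list with `cv` (per-neuron, `NA` when undefined) and `CV`
#'   (population mean).
#' @export
isi_cv <- function(raster, n_neurons = NULL) {
  if (is.null(n_neurons))
    n_neurons <- if (nrow(raster) > 0) max(raster$neuron) else 0L
  cv <- rep(NA_real_, n_neurons)
  if (nrow(raster) > 0) {
    spl <- split(raster$t_ms, factor(raster$neuron, levels = seq_len(n_neurons)))
    n <- lengths(spl)
    idx <- which(n >= 3L)
    cv[idx] <- vapply(spl[idx], function(t) {
      isi <- diff(sort(t)); sd(isi) / mean(isi)
    }, numeric(1))
  }
  list(cv = cv, CV = if (any(!is.na(cv))) mean(cv, na.rm = TRUE) else NA_real_)
}

#' Binned population firing-rate trace
#'
#' Spike counts per bin, per population, divided by bin width and population
#' size (Hz per neuron). The integral of the trace times `N * bin` recovers
#' the total spike count exactly.
#'
#' @param raster data.frame with `t_ms`, `neuron`, `pop`.
#' @param bin_ms bin width, ms.
#' @param T_ms trace duration, ms.
#' @param N_e,N_i population sizes.
#' @return data.frame `t_ms` (bin centres), `R_e_Hz`, `R_i_Hz`.
#' @export
population_rate_trace <- function(raster, bin_ms, T_ms, N_e, N_i) {
  stopifnot(bin_ms > 0)
  n_bins <- ceiling(T_ms / bin_ms)
  bin_of <- function(t) pmin(pmax(ceiling(t / bin_ms), 1L), n_bins)
  ce <- ci <- rep(0L, n_bins)
  if (nrow(raster) > 0) {
    e <- raster$pop == "e"
    ce <- tabulate(bin_of(raster$t_ms[e]), nbins = n_bins)
    ci <- tabulate(bin_of(raster$t_ms[!e]), nbins = n_bins)
  }
  data.frame(t_ms = (seq_len(n_bins) - 0.5) * bin_ms,
             R_e_Hz = ce / (bin_ms * N_e) * 1000,
             R_i_Hz = ci / (bin_ms * N_i) * 1000)
}

#' Power spectrum of a mean-field or mean-potential trace
#'
#' Mean-removed segments of the trace are Fourier transformed; the one-sided
#' modulus-squared spectra are averaged over segments and, optionally, over
#' independent realizations supplied as a list. With the defaults (10 ms
#' sampling, 10,000-sample segments) the resolution is \eqn{\Delta\nu = 0.01}
#' Hz. The spectrum is normalised so that its sum equals the variance of the
#' analysed segments (Parseval).
#'
#' @param v_trace numeric vector, or list of numeric vectors (one per
#'   realization).
#' @param sample_interval_ms sampling interval of the trace, ms.
#' @param segment_length samples per segment.
#' @return object of class `qif_spectrum`: data.frame `freq_Hz`, `power`;
#'   attributes `delta_nu_Hz`, `n_avg`.
#' @export
power_spectrum <- function(v_trace, sample_interval_ms = 10,
                           segment_length = 10000) {
  traces <- if (is.list(v_trace)) v_trace else list(v_trace)
  n <- segment_length
  acc <- NULL; n_avg <- 0
  for (tr in traces) {
    if (length(tr) < n) stop("trace shorter than one segment")
    n_seg <- floor(length(tr) / n)
    for (s in seq_len(n_seg)) {
      x <- tr[((s - 1) * n + 1):(s * n)]
      x <- x - mean(x)
      P <- Mod(fft(x))^2 / n^2
      acc <- if (is.null(acc)) P else acc + P
      n_avg <- n_avg + 1
    }
  }
  P <- acc / n_avg
  half <- floor(n / 2)
  one <- P[1:(half + 1)]
  if (n %% 2 == 0) { if (half >= 2) one[2:half] <- 2 * one[2:half] }
  else one[2:(half + 1)] <- 2 * one[2:(half + 1)]
  dt_s <- sample_interval_ms / 1000
  out <- data.frame(freq_Hz = (0:half) / (n * dt_s), power = one)
  attr(out, "delta_nu_Hz") <- 1 / (n * dt_s)
  attr(out, "n_avg") <- n_avg
  class(out) <- c("qif_spectrum", "data.frame")
  out
}

# local maxima of `power` exceeding `prominence` times the running median
# background in a +/- window_Hz neighbourhood (DC bin excluded); an absolute
# floor relative to the strongest peak guards against numerically-zero
# backgrounds in noiseless synthetic signals
spectrum_peaks <- function(spec, prominence = 5, window_Hz = 0.5,
                           floor_rel = 1e-9) {
  f <- spec$freq_Hz; P <- spec$power
  n <- length(P)
  loc <- which(P > c(-Inf, P[-n]) & P >= c(P[-1], -Inf) & f > 0)
  floor_abs <- floor_rel * max(P[loc], 0)
  keep <- vapply(loc, function(i) {
    w <- abs(f - f[i]) <= window_Hz
    bg <- median(P[w])
    P[i] > prominence * bg && P[i] > floor_abs
  }, logical(1))
  loc <- loc[keep]
  data.frame(freq_Hz = f[loc], power = P[loc])[order(-P[loc]), ]
}

#' Fundamental frequencies and locking detection
#'
#' Greedy identification of the two fundamental frequencies of a (quasi-)
#' periodic spectrum: \eqn{\nu_1} is the most powerful peak; \eqn{\nu_2} the
#' most powerful peak that is not an integer multiple of \eqn{\nu_1};
#' remaining peaks are validated as combinations \eqn{|a\nu_1 \pm b\nu_2|}
#' with \eqn{a, b \le 4}. Locking of order p:q (\eqn{p, q \le 6}) is declared
#' when \eqn{\nu_1/\nu_2} matches a ratio of small integers within 1%; the
#' order is reported as `"q:p"` with \eqn{\nu_2 : \nu_1 = q : p} in lowest
#' terms.
#'
#' @param spec a [power_spectrum()] result.
#' @param prominence,window_Hz peak-detection settings (see details).
#' @param tol relative tolerance for harmonic/combination matching.
#' @return list `nu_1`, `nu_2` (Hz; `nu_2 = NA` for a single rhythm),
#'   `locked`, `locking_order`, `peaks`, `validated_fraction`.
#' @export
fundamental_frequencies <- function(spec, prominence = 5, window_Hz = 0.5,
                                    tol = 0.01) {
  pk <- spectrum_peaks(spec, prominence, window_Hz)
  if (nrow(pk) == 0) stop("no oscillation")
  dnu <- attr(spec, "delta_nu_Hz")
  nu1 <- pk$freq_Hz[1]
  is_harmonic <- function(f, base) {
    m <- round(f / base)
    m >= 1 & abs(f - m * base) < pmax(2 * dnu, tol * base)
  }
  rest <- pk$freq_Hz[-1]
  cand <- rest[!is_harmonic(rest, nu1)]
  nu2 <- if (length(cand) > 0) cand[1] else NA_real_
  validated <- NA_real_
  if (!is.na(nu2)) {
    combos <- unique(abs(c(outer(0:4 * nu1, 0:4 * nu2, "+"),
                           outer(0:4 * nu1, 0:4 * nu2, "-"))))
    combos <- combos[combos > 0]
    ok <- vapply(pk$freq_Hz, function(f)
      any(abs(f - combos) < pmax(2 * dnu, tol * f)), logical(1))
    validated <- mean(ok)
  }
  locked <- FALSE; order_str <- NA_character_
  if (!is.na(nu2)) {
    ratio <- nu1 / nu2
    grid <- expand.grid(p = 1:6, q = 1:6)
    err <- abs(ratio - grid$p / grid$q) / ratio
    j <- which.min(err)
    if (err[j] < tol) {
      locked <- TRUE
      g <- gcd_int(grid$p[j], grid$q[j])
      order_str <- sprintf("%d:%d", grid$q[j] / g, grid$p[j] / g)
    }
  }
  list(nu_1 = nu1, nu_2 = nu2, locked = locked, locking_order = order_str,
       peaks = pk, validated_fraction = validated)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Firing-rate distribution and log-normal fit
#'
#' Rates below the silence threshold (0.01 Hz, i.e. less than one spike in
#' 100 s) define the silent fraction; a log-normal distribution is fitted by
#' maximum likelihood to the rates of active neurons only. The arithmetic
#' mean and SD of the fitted distribution are reported alongside the
#' log-scale parameters.
#'
#' @param rates_Hz per-neuron firing rates (including zeros for silent
#'   neurons).
#' @param threshold_Hz silence threshold.
#' @return list `rates_active_Hz`, `silent_fraction`, `mu_log`, `sigma_log`,
#'   `mean_Hz`, `sd_Hz` (the last four `NA` when no active neurons).
#' @export
rate_distribution <- function(rates_Hz, threshold_Hz = 0.01) {
  silent <- rates_Hz < threshold_Hz
  act <- rates_Hz[!silent]
  if (length(act) == 0)
    return(list(rates_active_Hz = numeric(0), silent_fraction = 1,
                mu_log = NA_real_, sigma_log = NA_real_,
                mean_Hz = NA_real_, sd_Hz = NA_real_))
  mu <- mean(log(act))
  sg <- sqrt(mean((log(act) - mu)^2))   # MLE (biased) sigma
  m <- exp(mu + sg^2 / 2)
  list(rates_active_Hz = act, silent_fraction = mean(silent),
       mu_log = mu, sigma_log = sg,
       mean_Hz = m, sd_Hz = m * sqrt(exp(sg^2) - 1))
}

# local maxima of a sampled trace above a midrange height threshold
trace_peaks <- function(x, t, min_height = NULL) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  if (is.null(min_height)) min_height <- min(x) + 0.5 * (max(x) - min(x))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  i <- i[x[i] >= min_height]
  t[i]
}

#' Delay between excitatory and inhibitory activity bursts
#'
#' Detects burst peaks in the two rate traces and returns the circular mean
#' over cycles of (inhibitory peak time - preceding excitatory peak time),
#' mapped into half a period around zero. The estimator is antisymmetric in
#' its arguments for shifted copies of a periodic trace.
#'
#' @param rate_e,rate_i numeric rate traces sampled on the common grid `t_ms`.
#' @param t_ms sample times, ms.
#' @param min_height peak height threshold (default: trace midrange).
#' @return list with `delay_ms`, `sd_ms`, `n_cycles`, `period_ms`.
#' @export
burst_delay <- function(rate_e, rate_i, t_ms, min_height = NULL) {
  pe <- trace_peaks(rate_e, t_ms, min_height)
  pi_ <- trace_peaks(rate_i, t_ms, min_height)
  if (length(pe) < 5 || length(pi_) < 5) stop("not oscillatory")
  delay_between_peaks(pe, pi_)
}
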