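# Sparse E-I QIF network: Lorentzian in-degree sampling, directed wiring,
# Euler integration with delta-pulse coupling, per-neuron diagnostics.

#' Sample Lorentzian-distributed in-degrees
#'
#' Draws integer in-degrees from a Lorentzian (Cauchy) distribution centred at
#' the median `K` with half-width at half-maximum \eqn{\Delta_0 \sqrt{K}} by
#' inverse-CDF sampling, rounds to the nearest integer, and rejection-resamples
#' values outside `[1, N-1]` (rejection, not clipping, to avoid mass at the
#' boundaries). `delta0 = 0` returns all-`K` in-degrees.
#'
#' @param N population size (draws one in-degree per neuron; `N > K`).
#' @param K median in-degree (>= 1).
#' @param delta0 heterogeneity width \eqn{\Delta_0} (>= 0).
#' @param seed RNG seed (optional; sampling is deterministic given the seed).
#' @return integer vector of length `N` with values in `[1, N-1]`.
#' @export
sample_lorentzian_indegrees <- function(N, K, delta0, seed = NULL) {
  stopifnot(N > K, K >= 1, delta0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (delta0 == 0) return(rep.int(as.integer(round(K)), N))
  hwhm <- delta0 * sqrt(K)
  out <- integer(0)
  drawn <- 0
  while (length(out) < N) {
    need <- N - length(out)
    u <- runif(max(need, 100L))
    k <- as.integer(round(K + hwhm * tan(pi * (u - 0.5))))
    drawn <- drawn + length(k)
    k <- k[k >= 1L & k <= N - 1L]
    out <- c(out, k)
    if (drawn > 200L * N && length(out) < 0.01 * drawn)
      stop("distribution inconsistent with population size")
  }
  out[seq_len(N)]
}

# presynaptic set of size k for post neuron j, uniform without replacement;
# within-population blocks exclude self-connections
sample_presyn <- function(k, n_source, self = NA) {
  if (is.na(self)) return(sample.int(n_source, k))
  idx <- sample.int(n_source - 1L, k)
  idx[idx >= self] <- idx[idx >= self] + 1L
  idx
}

#' Build the directed connectivity of the E-I network
#'
#' Within-population in-degrees are Lorentzian draws ([
#' sample_lorentzian_indegrees()]); cross-population in-degrees are exactly
#' `K` for every neuron. Presynaptic partners are drawn uniformly without
#' replacement, excluding self-connections; duplicate edges cannot occur.
#'
#' @param N_e,N_i population sizes.
#' @param K median in-degree (`K < min(N_e, N_i)`).
#' @param delta0_ee,delta0_ii heterogeneity widths of the two
#'   within-population blocks.
#' @param seed RNG seed; the build is reproducible from it.
#' @return object of class `qif_connectivity`: per-block lists `ee, ei, ie,
#'   ii` each with `indeg` (per-postsynaptic in-degrees) and `pre` (list of
#'   presynaptic index vectors, indices local to the source population),
#'   plus `N_e`, `N_i`, `K`, `delta0_ee`, `delta0_ii`, `seed`.
#' @export
build_connectivity <- function(N_e, N_i, K, delta0_ee = 0, delta0_ii = 0,
                               seed = 1L) {
  stopifnot(K >= 1, K < min(N_e, N_i))
  set.seed(seed)
  k_ee <- sample_lorentzian_indegrees(N_e, K, delta0_ee)
  k_ii <- sample_lorentzian_indegrees(N_i, K, delta0_ii)
  Kint <- as.integer(round(K))
  blocks <- list(
    ee = list(indeg = k_ee,
              pre = lapply(seq_len(N_e), function(j) sample_presyn(k_ee[j], N_e, j))),
    ei = list(indeg = rep.int(Kint, N_e),
              pre = lapply(seq_len(N_e), function(j) sample_presyn(Kint, N_i))),
    ie = list(indeg = rep.int(Kint, N_i),
              pre = lapply(seq_len(N_i), function(j) sample_presyn(Kint, N_e))),
    ii = list(indeg = k_ii,
              pre = lapply(seq_len(N_i), function(j) sample_presyn(k_ii[j], N_i, j))))
  structure(c(blocks, list(N_e = N_e, N_i = N_i, K = K,
                           delta0_ee = delta0_ee, delta0_ii = delta0_ii,
                           seed = seed)),
            class = "qif_connectivity")
}

#' @export
print.qif_connectivity <- function(x, ...) {
  cat(sprintf("E-I connectivity: N_e=%d N_i=%d K=%g Delta0=(%g, %g) seed=%s\n",
              x$N_e, x$N_i, x$K, x$delta0_ee, x$delta0_ii, x$seed))
  cat(sprintf("  edges: ee=%d ei=%d ie=%d ii=%d\n",
              sum(x$ee$indeg), sum(x$ei$indeg), sum(x$ie$indeg), sum(x$ii$indeg)))
  invisible(x)
}

# CSR over global indices (1..N_e excitatory, N_e+1..N inhibitory),
# presynaptic neuron -> its postsynaptic targets, 0-based for C++
conn_to_csr <- function(conn) {
  Ne <- conn$N_e; Ni <- conn$N_i; N <- Ne + Ni
  # edge list (pre_global, post_global) over all four blocks
  pre <- c(unlist(conn$ee$pre),
           unlist(conn$ei$pre) + Ne,
           unlist(conn$ie$pre),
           unlist(conn$ii$pre) + Ne)
  post <- c(rep(seq_len(Ne), conn$ee$indeg),
            rep(seq_len(Ne), conn$ei$indeg),
            rep(seq_len(Ni) + Ne, conn$ie$indeg),
            rep(seq_len(Ni) + Ne, conn$ii$indeg))
  ord <- order(pre)
  pre <- pre[ord]; post <- post[ord]
  offsets <- c(0L, cumsum(tabulate(pre, nbins = N)))
  list(offsets = as.integer(offsets), targets = as.integer(post - 1L))
}

#' Simulate the sparse E-I QIF network
#'
#' Euler integration of the membrane potentials
#' \eqn{\tau_m \dot v = v^2 + \sqrt{K} I_0 + \mathrm{pulses}} with
#' instantaneous delta-pulse synapses. A neuron spikes when `v >= v_peak`, is
#' reset to `-v_peak` and held for a refractory interval
#' \eqn{2\tau_m/v_\mathrm{peak}} (the finite-threshold surrogate of the QIF
#' traverse through infinity; held neurons receive no input and are excluded
#' from the reported mean potential). Each presynaptic spike applies a jump of
#' `pulse_factor * g0 / sqrt(K)` (positive for excitatory, negative for
#' inhibitory sources) to all its targets at the next time step. The default
#' `pulse_factor = 1` is the convention consistent with the neural mass drive;
#' `pulse_factor = 2` reproduces the literal pulse amplitude of the network
#' equations.
#'
#' @param conn a [build_connectivity()] object.
#' @param params a [model_params()] object (`K` taken from `conn`).
#' @param dt Euler step, ms (default 1e-3; a warning is raised when
#'   `dt >= tau_m / (10 v_peak)`).
#' @param T simulated time after the transient, ms.
#' @param transient discarded time, ms.
#' @param v_peak spike threshold (reset at `-v_peak`).
#' @param pulse_factor 1 (mean-field-consistent, default) or 2 (literal).
#' @param hold_ms refractory hold, ms; default `2 * tau_m / v_peak` per
#'   population, 0 disables the hold.
#' @param seed seed for the uniform initial potentials in
#'   `[-v_peak/10, v_peak/10]`.
#' @param trace_bin width of the rate/potential trace bins, ms.
#' @param record_v_stride if > 0, per-neuron potentials are sampled every this
#'   many ms and returned as a matrix (time x neuron).
#' @return list of class `qif_simulation`: `raster` (data.frame `t_ms,
#'   neuron, pop`; times relative to the end of the transient), `rates_Hz`
#'   (per neuron), `counts`, `trace` (data.frame `t_ms, R_e_Hz, V_e, R_i_Hz,
#'   V_i`), `v_samples`, and the run settings.
#' @export
simulate_network <- function(conn, params, dt = 1e-3, T = 1000, transient = 0,
                             v_peak = 100, pulse_factor = 1, hold_ms = NULL,
                             seed = 1L, trace_bin = 1, record_v_stride = 0) {
  stopifnot(inherits(conn, "qif_connectivity"))
  validate_params(params)
  stopifnot(dt > 0, v_peak > 0, T > 0, transient >= 0,
            pulse_factor %in% c(1, 2))
  if (dt >= min(params$tau_m_e, params$tau_m_i) / (10 * v_peak))
    warning("dt is large relative to tau_m / (10 v_peak); spike timing may be inaccurate")
  p <- params; p$K <- conn$K
  sK <- sqrt(p$K)
  csr <- conn_to_csr(conn)
  N <- conn$N_e + conn$N_i
  set.seed(seed)
  v0 <- runif(N, -v_peak / 10, v_peak / 10)
  if (is.null(hold_ms)) hold_ms <- 2 * c(p$tau_m_e, p$tau_m_i) / v_peak
  if (length(hold_ms) == 1) hold_ms <- rep(hold_ms, 2)
  out <- cpp_simulate_qif(conn$N_e, conn$N_i, csr$offsets, csr$targets, v0,
                          pulse_factor * p$g0_ee / sK, pulse_factor * p$g0_ie / sK,
                          pulse_factor * p$g0_ei / sK, pulse_factor * p$g0_ii / sK,
                          sK * p$I0_e, sK * p$I0_i, p$tau_m_e, p$tau_m_i,
                          dt, round(transient / dt), round(T / dt),
                          v_peak, hold_ms[1], hold_ms[2],
                          max(1L, round(trace_bin / dt)),
                          if (record_v_stride > 0) round(record_v_stride / dt) else 0L)
  if (isTRUE(out$blown))
    stop(sprintf("non-finite membrane potential at t = %.4g ms", out$t_blowup))
  raster <- data.frame(t_ms = out$spike_t, neuron = out$spike_id + 1L,
                       pop = ifelse(out$spike_id < conn$N_e, "e", "i"))
  tr <- out$trace
  trace <- data.frame(t_ms = tr[, 1], R_e_Hz = tr[, 2] * 1000, V_e = tr[, 3],
                      R_i_Hz = tr[, 4] * 1000, V_i = tr[, 5])
  structure(list(raster = raster, counts = out$counts,
                 rates_Hz = out$counts / T * 1000,
                 trace = trace,
                 v_samples = if (record_v_stride > 0) out$v_samples else NULL,
                 conn = conn, params = p,
                 settings = list(dt = dt, T = T, transient = transient,
                                 v_peak = v_peak, pulse_factor = pulse_factor,
                                 hold_ms = hold_ms, seed = seed,
                                 trace_bin = trace_bin)),
            class = "qif_simulation")
}

#' @export
print.qif_simulation <- function(x, ...) {
  cat(sprintf("QIF network simulation: N_e=%d N_i=%d K=%g, T=%g s (dt=%g ms)\n",
              x$conn$N_e, x$conn$N_i, x$conn$K, x$settings$T / 1000, x$settings$dt))
  e <- seq_len(x$conn$N_e)
  cat(sprintf("  %d spikes; mean rates: R_e=%.3f Hz R_i=%.3f Hz\n",
              nrow(x$raster), mean(x$rates_Hz[e]), mean(x$rates_Hz[-e])))
  invisible(x)
}

#' Per-neuron effective currents, rates, variability and driving class
#'
#' Computes for every neuron its firing rate over the window, the coefficient
#' of variation of its inter-spike intervals (requires >= 3 spikes), its
#' time-averaged effective input current
#' \deqn{\langle i_{eff,j} \rangle = \sqrt{K} I_0 +
#'   \tau_m \sum_{p \in \mathrm{pre}(j)} (\pm\, \mathrm{pulse\ factor}\,
#'   g_0/\sqrt{K})\, r_p,}
#' its total in-degree, and a driving-class tag: `silent` (rate < 0.01 Hz),
#' `mean-driven` (active with supra-threshold mean current,
#' \eqn{\langle i_{eff,j}\rangle > 0}), or `fluctuation-driven` otherwise.
#'
#' @param sim a [simulate_network()] result (or a raster data.frame plus
#'   `conn`, `params`, `window_ms`).
#' @param conn,params,window_ms used when `sim` is a raw raster.
#' @param pulse_factor pulse convention used by the simulation.
#' @param silent_threshold_Hz rate below which a neuron is tagged silent.
#' @return data.frame of class `qif_neuron_stats` with columns `neuron, pop,
#'   rate_Hz, cv, i_eff, k_tot, class`.
#' @export
measure_neuron_effective_currents <- function(sim, conn = NULL, params = NULL,
                                              window_ms = NULL,
                                              pulse_factor = NULL,
                                              silent_threshold_Hz = 0.01) {
  if (inherits(sim, "qif_simulation")) {
    raster <- sim$raster
    conn <- sim$conn
    params <- sim$params
    if (is.null(window_ms)) window_ms <- sim$settings$T
    if (is.null(pulse_factor)) pulse_factor <- sim$settings$pulse_factor
  } else {
    raster <- sim
    if (is.null(conn) || is.null(params) || is.null(window_ms))
      stop("conn, params and window_ms are required with a raw raster")
    if (is.null(pulse_factor)) pulse_factor <- 1
  }
  Ne <- conn$N_e; Ni <- conn$N_i; N <- Ne + Ni
  counts <- tabulate(raster$neuron, nbins = N)
  r <- counts / window_ms                      # 1/ms
  sK <- sqrt(conn$K)
  # synaptic term: tau_pop * pulse_factor/sqrt(K) * (g_exc * sum r_pre_e - g_inh * sum r_pre_i)
  sum_pre <- function(block, src_offset) {
    vapply(block$pre, function(idx) sum(r[idx + src_offset]), numeric(1))
  }
  syn_e <- params$tau_m_e * pulse_factor / sK *
    (params$g0_ee * sum_pre(conn$ee, 0L) - params$g0_ei * sum_pre(conn$ei, Ne))
  syn_i <- params$tau_m_i * pulse_factor / sK *
    (params$g0_ie * sum_pre(conn$ie, 0L) - params$g0_ii * sum_pre(conn$ii, Ne))
  i_eff <- c(sK * params$I0_e + syn_e, sK * params$I0_i + syn_i)
  cv <- rep(NA_real_, N)
  spl <- split(raster$t_ms, factor(raster$neuron, levels = seq_len(N)))
  has3 <- which(counts >= 3L)
  cv[has3] <- vapply(spl[has3], function(t) {
    isi <- diff(sort(t)); sd(isi) / mean(isi)
  }, numeric(1))
  k_tot <- c(conn$ee$indeg + conn$ei$indeg, conn$ii$indeg + conn$ie$indeg)
  rate_Hz <- r * 1000
  cls <- ifelse(rate_Hz < silent_threshold_Hz, "silent",
                ifelse(i_eff > 0, "mean-driven", "fluctuation-driven"))
  out <- data.frame(neuron = seq_len(N),
                    pop = rep(c("e", "i"), c(Ne, Ni)),
                    rate_Hz = rate_Hz, cv = cv, i_eff = i_eff,
                    k_tot = k_tot, class = cls)
  class(out) <- c("qif_neuron_stats", "data.frame")
  out
}
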