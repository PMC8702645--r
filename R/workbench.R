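# Experiment plumbing: YAML configs with schema validation, canonical
# parameter-set fixtures, file I/O, and experiment orchestration.

config_schema <- list(
  model = c("g0_ee", "g0_ei", "g0_ie", "g0_ii", "I0_e", "I0_i", "K",
            "delta0_ee", "delta0_ii", "tau_m_e", "tau_m_i"),
  run = c("dt", "T", "transient", "N_e", "N_i", "v_peak", "pulse_factor",
          "trace_bin", "record_v_stride", "stride"),
  scan = c("control", "values", "from", "to", "n_points", "log"),
  seeds = c("connectivity", "init", "tangent"),
  analysis = c("task"),
  output = c("dir")
)

run_defaults <- list(dt = 0.01, T = 1000, transient = 0, N_e = 10000,
                     N_i = 2500, v_peak = 100, pulse_factor = 1,
                     trace_bin = 1, record_v_stride = 0, stride = 10)

#' Load and validate an experiment configuration
#'
#' Reads a YAML config with blocks `model`, `run`, `scan`, `seeds`,
#' `analysis`, `output`. Unknown blocks or keys are rejected; model values are
#' validated through [model_params()]; run defaults are filled in. Seeds must
#' be explicit — fixtures carry them, and random runs require one.
#'
#' @param path path to a YAML file.
#' @return object of class `qif_config`: `params` ([model_params()]), `run`,
#'   `scan`, `seeds`, `task`, `output`, `source`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(config_schema))
  if (length(unknown) > 0)
    stop(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")))
  for (blk in names(raw)) {
    bad <- setdiff(names(raw[[blk]]), config_schema[[blk]])
    if (length(bad) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", blk, paste(bad, collapse = ", ")))
  }
  params <- do.call(model_params, raw$model %||% list())
  run <- modifyList(run_defaults, raw$run %||% list())
  for (f in c("dt", "T", "v_peak")) {
    if (!is.numeric(run[[f]]) || run[[f]] <= 0)
      stop(sprintf("run key '%s' must be positive", f))
  }
  if (run$transient < 0) stop("run key 'transient' must be non-negative")
  scan <- raw$scan
  if (!is.null(scan)) {
    if (is.null(scan$control)) stop("scan block requires 'control'")
    if (is.null(scan$values)) {
      if (is.null(scan$from) || is.null(scan$to) || is.null(scan$n_points))
        stop("scan block requires 'values' or 'from'/'to'/'n_points'")
      scan$values <- if (isTRUE(scan$log))
        exp(seq(log(scan$from), log(scan$to), length.out = scan$n_points))
      else seq(scan$from, scan$to, length.out = scan$n_points)
    }
    scan$values <- as.numeric(scan$values)
  }
  structure(list(params = params, run = run, scan = scan,
                 seeds = raw$seeds %||% list(),
                 task = raw$analysis$task %||% NULL,
                 output = raw$output %||% list(), source = path),
            class = "qif_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical parameter-set fixtures
#'
#' Named configuration fixtures shipped with the package, one per canonical
#' figure-style parameter set (asynchronous-regime scan over K, the two
#' bifurcation cuts, the PING-delay set, phase-diagram grids, the
#' frequency-locking and scaling sets).
#'
#' @param name fixture name; `fixture_names()` lists them.
#' @return `fixture_config()`: a validated `qif_config`.
#' @export
fixture_config <- function(name) {
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "qifbalance")
  if (path == "") stop(sprintf("unknown fixture '%s'", name))
  load_config(path)
}

#' @rdname fixture_config
#' @export
fixture_names <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "configs", package = "qifbalance"),
                 pattern = "\\.yaml$"))
}

#' Write/read a macroscopic trace as delimited text
#'
#' CSV with header `t_ms, R_e_Hz, V_e, R_i_Hz, V_i`.
#' @param trace a `qif_trace` data.frame.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  write.table(as.data.frame(trace)[, c("t_ms", "R_e_Hz", "V_e", "R_i_Hz", "V_i")],
              path, sep = ",", row.names = FALSE, quote = FALSE)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE)
  class(df) <- c("qif_trace", "data.frame")
  df
}

#' Write/read a spike raster as delimited text
#'
#' Whitespace-delimited columns `t_ms neuron_id pop` with a header row.
#' @param raster raster data.frame (`t_ms`, `neuron`, `pop`).
#' @param path file path.
#' @export
write_raster <- function(raster, path) {
  write.table(raster, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  read.table(path, header = TRUE, colClasses = c("numeric", "integer", "character"))
}

#' Write a connectivity object as an edge list plus JSON header
#'
#' Produces `<prefix>_edges.tsv` (columns `pre_pop pre_id post_pop post_id`,
#' ids local to each population) and `<prefix>_header.json` (sizes, K,
#' heterogeneity widths, seed).
#' @param conn a `qif_connectivity`.
#' @param prefix path prefix for the two files.
#' @export
write_connectivity <- function(conn, prefix) {
  blk <- function(b, pre_pop, post_pop, n_post) {
    data.frame(pre_pop = pre_pop, pre_id = unlist(conn[[b]]$pre),
               post_pop = post_pop, post_id = rep(seq_len(n_post), conn[[b]]$indeg))
  }
  edges <- rbind(blk("ee", "e", "e", conn$N_e), blk("ei", "i", "e", conn$N_e),
                 blk("ie", "e", "i", conn$N_i), blk("ii", "i", "i", conn$N_i))
  write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  hdr <- list(N_e = conn$N_e, N_i = conn$N_i, K = conn$K,
              delta0_ee = conn$delta0_ee, delta0_ii = conn$delta0_ii,
              seed = conn$seed)
  jsonlite::write_json(hdr, paste0(prefix, "_header.json"), auto_unbox = TRUE)
}

result_to_json <- function(x, path) {
  strip <- function(o) {
    if (inherits(o, "qif_params") || inherits(o, "qif_state")) return(unclass(o))
    if (is.list(o)) return(lapply(o, strip))
    if (is.complex(o)) return(list(re = Re(o), im = Im(o)))
    o
  }
  jsonlite::write_json(strip(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
}

#' Run an experiment described by a configuration
#'
#' Dispatches on `analysis.task` — one of `"fixed_point"`, `"eigen"`,
#' `"lyapunov"`, `"hopf"`, `"scan_peaks"`, `"scan_regimes"`, `"network"`,
#' `"ping_delay"` — runs the corresponding computation, writes the results
#' (JSON records, CSV traces, TSV rasters) into the output directory, and
#' writes a manifest (config echo and checksum, package version, seeds, wall
#' time, collected warnings) that allows an exact re-run. A scan with an
#' empty grid is a no-op that still writes a (empty-result) manifest.
#'
#' @param config a `qif_config` from [load_config()] / [fixture_config()].
#' @param out_dir output directory (overrides the config's `output.dir`).
#' @return (invisibly) list of results, also written to disk.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "qif_config"))
  out_dir <- out_dir %||% config$output$dir %||% tempfile("qif_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  p <- config$params; run <- config$run; seeds <- config$seeds
  warn <- character(0)
  results <- withCallingHandlers(
    run_task(config$task %||% "fixed_point", p, run, config$scan, seeds, out_dir),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  cfg_tmp <- tempfile(fileext = ".json")
  result_to_json(unclass(config)[c("params", "run", "scan", "seeds", "task")], cfg_tmp)
  manifest <- list(task = config$task %||% "fixed_point",
                   config = jsonlite::read_json(cfg_tmp),
                   config_md5 = unname(tools::md5sum(cfg_tmp)),
                   package_version = as.character(utils::packageVersion("qifbalance")),
                   seeds = seeds, warnings = warn,
                   wall_time_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

run_task <- function(task, p, run, scan, seeds, out_dir) {
  switch(task,
    fixed_point = {
      fp <- stationary_state(p)
      result_to_json(fp, file.path(out_dir, "fixed_point.json"))
      list(fixed_point = fp)
    },
    eigen = {
      eig <- jacobian_eigenvalues(p)
      result_to_json(eig, file.path(out_dir, "eigen.json"))
      list(eigen = eig)
    },
    lyapunov = {
      ly <- lyapunov_spectrum(p, dt = run$dt, T = run$T,
                              transient = run$transient,
                              seed = seeds$tangent %||% 1L)
      result_to_json(ly[c("lambda", "settings")],
                     file.path(out_dir, "lyapunov.json"))
      list(lyapunov = ly)
    },
    hopf = {
      if (is.null(scan)) stop("hopf task requires a scan block (control + 2-value bracket)")
      h <- find_hopf(p, scan$control, range(scan$values))
      result_to_json(h, file.path(out_dir, "hopf.json"))
      list(hopf = h)
    },
    scan_peaks = {
      if (is.null(scan) || length(scan$values) == 0) return(list())
      pm <- peak_map(p, scan$control, scan$values, dt = run$dt, T = run$T,
                     transient = run$transient)
      result_to_json(pm$summary, file.path(out_dir, "peak_map.json"))
      list(peak_map = pm)
    },
    scan_regimes = {
      if (is.null(scan) || length(scan$values) == 0) return(list())
      labs <- lapply(scan$values, function(v) {
        classify_regime(set_control(p, scan$control, v), dt = run$dt,
                        T = run$T, transient = run$transient,
                        seed = seeds$tangent %||% 1L)
      })
      out <- data.frame(value = scan$values,
                        label = vapply(labs, `[[`, "", "label"),
                        co_class = vapply(labs, `[[`, "", "co_class"))
      result_to_json(out, file.path(out_dir, "regimes.json"))
      list(regimes = out, details = labs)
    },
    network = {
      conn <- build_connectivity(run$N_e, run$N_i, p$K, p$delta0_ee,
                                 p$delta0_ii, seed = seeds$connectivity %||% 1L)
      sim <- simulate_network(conn, p, dt = run$dt, T = run$T,
                              transient = run$transient, v_peak = run$v_peak,
                              pulse_factor = run$pulse_factor,
                              seed = seeds$init %||% 1L,
                              trace_bin = run$trace_bin,
                              record_v_stride = run$record_v_stride)
      write_raster(sim$raster, file.path(out_dir, "raster.tsv"))
      write_trace_csv(sim$trace, file.path(out_dir, "trace.csv"))
      result_to_json(list(mean_rate_e_Hz = mean(sim$rates_Hz[seq_len(run$N_e)]),
                          mean_rate_i_Hz = mean(sim$rates_Hz[-seq_len(run$N_e)]),
                          n_spikes = nrow(sim$raster)),
                     file.path(out_dir, "network_summary.json"))
      list(sim = sim)
    },
    ping_delay = {
      d <- ping_delay_mf(p, dt = run$dt, T = run$T, transient = run$transient)
      result_to_json(d, file.path(out_dir, "ping_delay.json"))
      list(ping_delay = d)
    },
    stop(sprintf("unknown task '%s'", task))
  )
}
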