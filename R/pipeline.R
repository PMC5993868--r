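#' Write a voltage trace as delimited text
#'
#' Tab-separated columns: `time_ms`, `v_mV`, `i_inj_pA`, then one column of
#' current density (uA/cm2) per recorded channel.  Long traces are
#' downsampled by keeping every `every`-th sample (the default turns the
#' 0.025 ms solver grid into a 1 ms file grid).
#'
#' @param trace a `voltage_trace`.
#' @param path output file.
#' @param every keep every `every`-th sample (integer >= 1).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, every = 40L) {
  idx <- seq(1L, length(trace$time), by = max(1L, as.integer(every)))
  d <- data.frame(time_ms = trace$time[idx], v_mV = trace$v[idx],
                  i_inj_pA = trace$i_inj[idx])
  if (!is.null(trace$currents)) {
    cc <- as.data.frame(trace$currents[idx, , drop = FALSE])
    names(cc) <- paste0("i_", names(cc), "_uA_cm2")
    d <- cbind(d, cc)
  }
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a voltage trace written by [write_trace]
#'
#' @param path file path.
#' @return a `voltage_trace` (without epoch annotations).
#' @export
read_trace <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  cur <- NULL
  extra <- grep("^i_.*_uA_cm2$", names(d), value = TRUE)
  if (length(extra)) {
    cur <- as.matrix(d[extra])
    colnames(cur) <- sub("^i_(.*)_uA_cm2$", "\\1", extra)
  }
  structure(list(time = d$time_ms, v = d$v_mV, i_inj = d$i_inj_pA,
                 currents = cur, dt = d$time_ms[2] - d$time_ms[1],
                 rmp = NA_real_, epochs = list()),
            class = "voltage_trace")
}

scenario_catalog <- function(path = system.file("extdata", "scenarios.json",
                                                package = "chipause")) {
  jsonlite::read_json(path)$scenarios
}

# compartment config with a subset of the base config's channels, recalibrated
subset_config <- function(cfg, set, target_rmp = cfg$target_rmp,
                          holding = cfg$holding_current) {
  mc <- model_config(geometry = cfg$geometry, leak_g = cfg$leak_g,
                     leak_e = NULL, channels = cfg$channels[set],
                     target_rmp = target_rmp, holding_current = holding,
                     temperature = cfg$temperature, dt = cfg$dt,
                     record_currents = cfg$record_currents)
  mc$d2_defaults <- cfg$d2_defaults
  mc
}

d2_from_config <- function(cfg, onset_latency = NULL, decay_dur = NULL) {
  d <- cfg$d2_defaults %||% list(peak_pA = -20, onset_latency_ms = 100,
                                 rise_dur_ms = 150, decay_dur_ms = 250,
                                 decay_shape = "linear")
  d2_spec(peak = d$peak_pA,
          onset_latency = onset_latency %||% d$onset_latency_ms,
          rise_dur = d$rise_dur_ms,
          decay_dur = decay_dur %||% d$decay_dur_ms,
          decay_shape = d$decay_shape)
}

set_label <- function(set) {
  if (!length(set)) "leak" else paste(c("leak", unlist(set)), collapse = "_")
}

#' Run a named end-to-end scenario
#'
#' Executes one entry of the scenario catalog (a shipped JSON file mapping
#' labels to parameterized protocol kinds) against the model configuration,
#' computes the scenario's metrics, and optionally writes traces, metrics
#' and a run manifest to `out_dir`.
#'
#' @param name scenario label (see the shipped catalog: `fig4a`, `fig4b`,
#'   `fig4c`, `fig4d`, `fig4e`, `fig4f`, `fig4g`, `fig4h`, `s2a_mimic`,
#'   `discussion_25pA`, `invivo_phase`).
#' @param config a calibrated [model_config], a path to a model JSON file,
#'   or `NULL` for the packaged default.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing.
#' @param seed integer seed for stochastic scenarios.
#' @param catalog path to a scenario catalog JSON, or `NULL` for the
#'   packaged one.
#' @return an object of class `scenario_result`: `scenario`, `params`,
#'   `metrics` (flat named list of numbers), `traces` (named list),
#'   `seed`, `version`, `config_snapshot`.
#' @export
run_scenario <- function(name, config = NULL, out_dir = NULL, seed = 1L,
                         catalog = NULL) {
  cat_path <- catalog %||% system.file("extdata", "scenarios.json",
                                       package = "chipause")
  scen <- scenario_catalog(cat_path)
  if (!name %in% names(scen)) {
    stop("unknown scenario '", name, "'; catalog: ",
         paste(names(scen), collapse = ", "))
  }
  p <- scen[[name]]
  if (is.null(config)) {
    config <- default_model_config()
  } else if (is.character(config)) {
    config <- default_model_config(path = config)
  }
  stopifnot(inherits(config, "model_config"))

  run <- switch(p$kind,
    vclamp_family = scenario_vclamp(config, p),
    trapezoid_channel_compare = scenario_trapezoid_compare(config, p),
    ramp_lag = scenario_ramp_lag(config, p),
    rmp_compare = scenario_rmp_compare(config, p),
    sine_amplitude_series = scenario_sine_series(config, p),
    d2_combination = scenario_d2_combination(config, p),
    d2_timing = scenario_d2_timing(config, p),
    learning_series = scenario_learning(config, p, scen),
    undershoot_mimic = scenario_mimic(config, p),
    small_withdrawal = scenario_small_withdrawal(config, p),
    invivo_phase = scenario_invivo_phase(config, p, seed),
    stop("unimplemented scenario kind: ", p$kind))

  res <- structure(list(
    scenario = name, params = p, metrics = run$metrics,
    traces = run$traces, seed = as.integer(seed),
    version = as.character(utils::packageVersion("chipause")),
    config_snapshot = list(
      leak_g = config$leak_g, leak_e = config$leak_e,
      target_rmp = config$target_rmp,
      holding_pA = config$holding_current, dt = config$dt,
      gbar = lapply(config$channels, `[[`, "gbar"))),
    class = "scenario_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(run$traces)) {
      tr <- run$traces[[nm]]
      if (inherits(tr, "voltage_trace")) {
        write_trace(tr, file.path(out_dir, paste0(name, "_", nm, ".tsv")))
      }
    }
    jsonlite::write_json(run$metrics,
                         file.path(out_dir, paste0(name, "_metrics.json")),
                         auto_unbox = TRUE, digits = NA)
    manifest <- res[c("scenario", "params", "seed", "version",
                      "config_snapshot")]
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

scenario_vclamp <- function(config, p) {
  vc <- simulate_voltage_steps(config, holding = p$holding_mV,
                               step = p$step_mV, n_steps = p$n_steps,
                               step_dur = p$step_dur_ms)
  metrics <- list()
  for (ch in names(vc$currents)) {
    top <- vc$currents[[ch]][, ncol(vc$currents[[ch]])]
    late <- mean(top[vc$time >= 0.9 * max(vc$time)])
    metrics[[paste0(ch, "_peak_uA_cm2")]] <- max(top)
    metrics[[paste0(ch, "_late_over_peak")]] <- late / max(top)
  }
  list(metrics = metrics, traces = list(vclamp = vc))
}

trapezoid_stim <- function(p, dt, scale = 1) {
  trapezoid_current(peak = p$peak_pA * scale, ramp_up = p$ramp_up_ms,
                    plateau = p$plateau_ms, ramp_down = p$ramp_down_ms,
                    dt = dt, pre = p$pre_ms, post = p$post_ms)
}

scenario_trapezoid_compare <- function(config, p) {
  metrics <- list()
  traces <- list()
  for (set in p$channel_sets) {
    set <- unlist(set)
    cfg <- subset_config(config, set)
    stim <- trapezoid_stim(p, cfg$dt)
    tr <- simulate_current_clamp(cfg, stim)
    us <- undershoot(tr)
    lbl <- set_label(set)
    metrics[[paste0("undershoot_", lbl)]] <- us$trough
    metrics[[paste0("overshoot_", lbl)]] <- us$peak
    traces[[lbl]] <- tr
  }
  list(metrics = metrics, traces = traces)
}

scenario_ramp_lag <- function(config, p) {
  stim <- trapezoid_stim(p, config$dt)
  tr <- simulate_current_clamp(config, stim)
  t_inj <- tr$time[which.max(tr$i_inj)]
  t_ikr <- tr$time[which.max(tr$currents[, "IKr"])]
  list(metrics = list(t_peak_inj_ms = t_inj, t_peak_ikr_ms = t_ikr,
                      lag_ms = t_ikr - t_inj),
       traces = list(ramp = tr))
}

scenario_rmp_compare <- function(config, p) {
  stim <- trapezoid_stim(p, config$dt)
  u_of <- function(cfg) undershoot(simulate_current_clamp(cfg, stim))$trough
  u_control <- u_of(config)
  blocked <- apply_pharmacology(config, "zd7288",
                               blocked_rmp = p$blocked_rmp_mV)
  u_blocked <- u_of(blocked)
  restored <- apply_pharmacology(config, "zd7288_restored",
                                 blocked_rmp = p$blocked_rmp_mV)
  u_restored <- u_of(restored)
  list(metrics = list(
    undershoot_control_mV = u_control, undershoot_blocked_mV = u_blocked,
    undershoot_restored_mV = u_restored,
    blocked_frac = u_blocked / u_control,
    restored_frac = u_restored / u_control),
    traces = list())
}

scenario_sine_series <- function(config, p) {
  amps <- unlist(p$amplitudes_pA)
  troughs <- numeric(length(amps))
  lat <- numeric(length(amps))
  traces <- list()
  for (i in seq_along(amps)) {
    stim <- sine_current(amps[i], p$freq_Hz, p$duration_ms, dt = config$dt,
                         pre = p$pre_ms, post = p$post_ms,
                         half = isTRUE(p$half))
    tr <- simulate_current_clamp(config, stim)
    us <- undershoot(tr)
    troughs[i] <- us$trough
    lat[i] <- us$trough_latency
    traces[[paste0("sine_", amps[i], "pA")]] <- tr
  }
  metrics <- list(trough_monotone = as.numeric(all(diff(troughs) > 0)),
                  latency_range_ms = max(lat) - min(lat))
  for (i in seq_along(amps)) {
    metrics[[paste0("trough_", amps[i], "pA_mV")]] <- troughs[i]
    metrics[[paste0("latency_", amps[i], "pA_ms")]] <- lat[i]
  }
  list(metrics = metrics, traces = traces)
}

excit_pulse <- function(p, dt, scale = 1) {
  trapezoid_current(peak = p$excit_peak_pA * scale,
                    ramp_up = p$excit_rise_ms, plateau = p$excit_plateau_ms,
                    ramp_down = p$excit_fall_ms, dt = dt, pre = p$pre_ms,
                    post = p$post_ms)
}

scenario_d2_combination <- function(config, p) {
  dt <- config$dt
  excit <- excit_pulse(p, dt)
  d2 <- d2_current(d2_from_config(config,
                                  onset_latency = p$d2_onset_ms %||% NULL,
                                  decay_dur = p$d2_decay_ms %||% NULL),
                   dt = dt)
  pad <- stimulus_waveform(excit$time, numeric(length(excit$time)))
  mk <- function(parts, shifts, scales) {
    simulate_current_clamp(config, compose_scenario(parts, shifts, scales))
  }
  tr_excit <- mk(list(excit), 0, 1)
  tr_d2 <- mk(list(pad, d2), c(0, p$pre_ms), c(1, p$d2_scale))
  tr_both <- mk(list(excit, d2), c(0, p$pre_ms), c(1, p$d2_scale))
  input <- excit$epochs[["input"]]
  u <- function(tr) undershoot(tr, rmp = config$target_rmp,
                               input_epochs = list(input = input))
  m <- list(
    trough_ikr_mV = u(tr_excit)$trough,
    trough_d2_mV = max(0, config$target_rmp - min(tr_d2$v)),
    trough_combined_mV = u(tr_both)$trough,
    hyper_dur_ikr_ms = hyper_duration_from(tr_excit, input[2]),
    hyper_dur_combined_ms = hyper_duration_from(tr_both, input[2]))
  m$combined_over_ikr <- m$trough_combined_mV / m$trough_ikr_mV
  m$prolong_ms <- m$hyper_dur_combined_ms - m$hyper_dur_ikr_ms
  list(metrics = m,
       traces = list(excit = tr_excit, d2 = tr_d2, combined = tr_both))
}

hyper_duration_from <- function(tr, t_from, margin = 0.5) {
  after <- tr$time > t_from
  sum(tr$v[after] < tr$rmp - margin) * tr$dt
}

d2_timing_traces <- function(config, p, learning_scale = 1) {
  dt <- config$dt
  excit <- excit_pulse(p, dt, scale = learning_scale)
  reb <- trapezoid_current(peak = p$rebound_peak_pA * learning_scale,
                           ramp_up = p$rebound_rise_ms,
                           plateau = p$rebound_plateau_ms,
                           ramp_down = p$rebound_fall_ms, dt = dt)
  d2 <- d2_current(d2_from_config(config,
                                  decay_dur = p$d2_decay_ms %||% NULL),
                   dt = dt)
  list(excit = excit, reb = reb, d2 = d2)
}

scenario_d2_timing <- function(config, p, learning_scale = NULL,
                               d2_scales = NULL) {
  learning_scale <- learning_scale %||% (p$learning_scale %||% 1)
  d2_scales <- d2_scales %||% unlist(p$d2_scales)
  parts <- d2_timing_traces(config, p, learning_scale)
  input <- parts$excit$epochs[["input"]]
  reb_window <- parts$reb$epochs[["input"]] + p$rebound_onset_ms
  metrics <- list()
  traces <- list()
  for (s in d2_scales) {
    wf <- compose_scenario(list(parts$excit, parts$reb, parts$d2),
                           t_shift = c(0, p$rebound_onset_ms, p$d2_onset_ms),
                           scale = c(1, 1, s))
    tr <- simulate_current_clamp(config, wf)
    # trough between input offset and rebound onset
    win <- tr$time > input[2] & tr$time < reb_window[1]
    trough <- max(0, tr$rmp - min(tr$v[win]))
    in_reb <- tr$time >= reb_window[1] & tr$time <= reb_window[2] + 200
    rebound <- max(0, max(tr$v[in_reb]) - tr$rmp)
    lbl <- sprintf("d2_%g", s)
    metrics[[paste0("trough_", lbl, "_mV")]] <- trough
    metrics[[paste0("rebound_", lbl, "_mV")]] <- rebound
    traces[[lbl]] <- tr
  }
  if (all(c(1, 0) %in% d2_scales)) {
    t1 <- metrics[["trough_d2_1_mV"]]
    t0 <- metrics[["trough_d2_0_mV"]]
    metrics$trough_change_frac <- abs(t1 - t0) / t0
    metrics$rebound_reduced <- as.numeric(
      metrics[["rebound_d2_1_mV"]] < metrics[["rebound_d2_0_mV"]])
  }
  list(metrics = metrics, traces = traces)
}

scenario_learning <- function(config, p, scen) {
  base <- scen[[p$base]]
  scales <- unlist(p$learning_scales)
  troughs <- numeric(length(scales))
  for (i in seq_along(scales)) {
    run <- scenario_d2_timing(config, base, learning_scale = scales[i],
                              d2_scales = p$d2_scale)
    troughs[i] <- run$metrics[[sprintf("trough_d2_%g_mV", p$d2_scale)]]
  }
  metrics <- list(trough_monotone = as.numeric(all(diff(troughs) > 0)))
  for (i in seq_along(scales)) {
    metrics[[sprintf("trough_scale_%g_mV", scales[i])]] <- troughs[i]
  }
  list(metrics = metrics, traces = list())
}

scenario_mimic <- function(config, p) {
  wf <- negative_undershoot_mimic(p$r_in_MOhm, p$v_target_mV, dt = config$dt)
  grid <- seq(0, p$pre_ms + max(wf$time) + p$post_ms, by = config$dt)
  pad <- stimulus_waveform(grid, numeric(length(grid)))
  full <- compose_scenario(list(pad, wf), t_shift = c(0, p$pre_ms))
  tr <- simulate_current_clamp(config, full)
  list(metrics = list(
    amplitude_pA = min(wf$current),
    hyperpolarization_mV = max(0, config$target_rmp - min(tr$v))),
    traces = list(mimic = tr))
}

scenario_small_withdrawal <- function(config, p) {
  stim <- trapezoid_stim(p, config$dt)
  tr <- simulate_current_clamp(config, stim)
  list(metrics = list(undershoot_mV = undershoot(tr)$trough),
       traces = list(withdrawal = tr))
}

scenario_invivo_phase <- function(config, p, seed) {
  spec <- recording_spec(seed = seed)
  rec <- generate_recording(spec)
  win <- c(0, spec$duration * 1000)
  h_chi <- rate_histogram(rec$chi_trains, bin = p$bin_ms, align = 0,
                          window = win)
  h_spn <- rate_histogram(rec$spn_trains, bin = p$bin_ms, align = 0,
                          window = win)
  lag <- phase_lag(h_chi, h_spn, ref_freq = spec$slow_freq)
  list(metrics = list(lag_deg = lag, true_lag_deg = spec$spn_lag,
                      n_sweeps = spec$n_sweeps),
       traces = list())
}

#' Collate scenario results against acceptance thresholds
#'
#' @param results list of `scenario_result` objects (or a single one).
#' @param thresholds path to a thresholds JSON file; `NULL` for the packaged
#'   defaults.  Each entry gives `scenario`, `metric`, `cmp` (one of `ge`,
#'   `le`, `gt`, `lt`, `eq`, `abs_err_le`), `value`, and optionally
#'   `target` (for `abs_err_le`) and `tol` (for `eq`).
#' @return a data frame with one row per threshold found in the results:
#'   scenario, metric, value, cmp, bound, pass.
#' @export
report <- function(results, thresholds = NULL) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (!length(results)) stop("need at least one scenario result")
  if (!all(vapply(results, function(r) length(r$metrics) > 0, TRUE))) {
    stop("scenario result with empty metrics")
  }
  th_path <- thresholds %||% system.file("extdata",
                                         "acceptance_thresholds.json",
                                         package = "chipause")
  th <- jsonlite::read_json(th_path)$thresholds
  by_name <- stats::setNames(results,
                             vapply(results, `[[`, "", "scenario"))
  rows <- list()
  for (t in th) {
    r <- by_name[[t$scenario]]
    if (is.null(r)) next
    val <- r$metrics[[t$metric]]
    if (is.null(val)) next
    pass <- switch(t$cmp,
      ge = val >= t$value, le = val <= t$value,
      gt = val > t$value, lt = val < t$value,
      eq = abs(val - t$value) <= (t$tol %||% 1e-9),
      abs_err_le = abs(val - t$target) <= t$value,
      stop("unknown cmp: ", t$cmp))
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = t$scenario, metric = t$metric, value = val,
      cmp = t$cmp, bound = t$value, pass = pass)
  }
  do.call(rbind, rows)
}
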