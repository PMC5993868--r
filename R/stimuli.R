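#' Stimulus waveform container
#'
#' A uniformly sampled injected-current time series (pA at the soma,
#' depolarizing positive), with named epoch annotations (ms).
#'
#' @param time time grid (ms), uniform.
#' @param current current per sample (pA), finite.
#' @param epochs named list of times or `c(start, end)` windows (ms).
#' @return an object of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(time, current, epochs = list()) {
  stopifnot(length(time) == length(current), length(time) >= 2L)
  if (any(!is.finite(current))) stop("stimulus current must be finite")
  dts <- diff(time)
  if (max(abs(dts - dts[1])) > 1e-9) stop("time grid must be uniform")
  structure(list(time = time, current = current, dt = dts[1],
                 epochs = epochs),
            class = "stimulus_waveform")
}

# zero-padded time base: delay of `pre` ms, body, tail of `post` ms
wf_grid <- function(duration, dt, pre = 0, post = 0) {
  seq(0, pre + duration + post, by = dt)
}

#' Sine-wave current injection
#'
#' Depolarizing-first full sine cycles of the given amplitude riding on an
#' optional offset, zero outside the stimulation window (protocol amplitudes
#' in the ex-vivo experiments were 25, 50, 75 and 100 pA over 500 ms).
#'
#' @param amplitude sine amplitude (pA), >= 0.
#' @param freq frequency (Hz).
#' @param duration stimulation duration (ms), > 0.
#' @param offset constant offset added during the stimulation window (pA).
#' @param dt sample interval (ms).
#' @param pre,post zero-current padding before/after the window (ms).
#' @param half if `TRUE`, a single depolarizing lobe spanning `duration`
#'   (`A sin(pi t / duration)`, `freq` ignored): the input ends as
#'   depolarization recedes, which is the variant that isolates the
#'   K+-current-driven after-hyperpolarization from the input-driven dip a
#'   full cycle's negative lobe would impose.
#' @return a [stimulus_waveform] with epochs `input` = c(start, end).
#' @export
sine_current <- function(amplitude, freq, duration, offset = 0, dt = 0.025,
                         pre = 0, post = 0, half = FALSE) {
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("`amplitude` must be >= 0")
  time <- wf_grid(duration, dt, pre, post)
  cur <- numeric(length(time))
  on <- time >= pre & time <= pre + duration
  cur[on] <- offset + if (half) {
    amplitude * sin(pi * (time[on] - pre) / duration)
  } else {
    amplitude * sin(2 * pi * freq * (time[on] - pre) / 1000)
  }
  stimulus_waveform(time, cur,
                    epochs = list(input = c(pre, pre + duration)))
}

#' Trapezoid current injection
#'
#' Linear ramp up, plateau, linear ramp down (the ex-vivo protocol used 4 s
#' phases).  `sign = -1` gives the mirrored hyperpolarizing input.
#'
#' @param peak plateau current magnitude (pA), >= 0.
#' @param ramp_up,plateau,ramp_down phase durations (ms), >= 0, not all zero.
#' @param sign +1 depolarizing (default) or -1 hyperpolarizing.
#' @param dt sample interval (ms).
#' @param pre,post zero-current padding (ms).
#' @return a [stimulus_waveform] with epochs `ramp_up`, `plateau`,
#'   `ramp_down` and `input`.
#' @export
trapezoid_current <- function(peak, ramp_up = 4000, plateau = 4000,
                              ramp_down = 4000, sign = 1, dt = 0.025,
                              pre = 0, post = 0) {
  durs <- c(ramp_up, plateau, ramp_down)
  if (any(!is.finite(durs)) || any(durs < 0)) stop("durations must be >= 0")
  if (sum(durs) == 0) stop("at least one phase must have positive duration")
  stopifnot(sign %in% c(-1, 1), peak >= 0)
  t0 <- pre
  t1 <- t0 + ramp_up
  t2 <- t1 + plateau
  t3 <- t2 + ramp_down
  time <- wf_grid(sum(durs), dt, pre, post)
  cur <- numeric(length(time))
  if (ramp_up > 0) {
    i <- time >= t0 & time < t1
    cur[i] <- peak * (time[i] - t0) / ramp_up
  }
  i <- time >= t1 & time <= t2
  cur[i] <- peak
  if (ramp_down > 0) {
    i <- time > t2 & time <= t3
    cur[i] <- peak * (t3 - time[i]) / ramp_down
  }
  stimulus_waveform(time, sign * cur,
                    epochs = list(ramp_up = c(t0, t1), plateau = c(t1, t2),
                                  ramp_down = c(t2, t3), input = c(t0, t3)))
}

#' Dopamine D2-receptor current specification
#'
#' The evoked D2 current is hyperpolarizing with a delayed onset; its rise is
#' modeled as a quarter sine (matching the rise of phasic dopamine-neuron
#' activity) and its decay as a linear (or exponential) return to zero.
#'
#' @param peak peak current (pA); hyperpolarizing by convention, so <= 0.
#' @param onset_latency delay from waveform start to current onset (ms), >= 0.
#' @param rise_dur quarter-sine rise duration (ms), > 0.
#' @param decay_dur decay duration (ms), > 0.
#' @param total_dur total waveform duration (ms); defaults to
#'   onset + rise + decay.
#' @param decay_shape `"linear"` (default) or `"exp"` (time constant
#'   decay_dur / 3).
#' @return an object of class `d2_spec`.
#' @export
d2_spec <- function(peak = -20, onset_latency = 100, rise_dur = 150,
                    decay_dur = 250, total_dur = NULL,
                    decay_shape = c("linear", "exp")) {
  decay_shape <- match.arg(decay_shape)
  if (peak > 0) stop("`peak` must be <= 0 (hyperpolarizing convention)")
  if (onset_latency < 0) stop("`onset_latency` must be >= 0")
  if (rise_dur <= 0 || decay_dur <= 0) stop("durations must be > 0")
  total_dur <- total_dur %||% (onset_latency + rise_dur + decay_dur)
  structure(list(peak = peak, onset_latency = onset_latency,
                 rise_dur = rise_dur, decay_dur = decay_dur,
                 total_dur = total_dur, decay_shape = decay_shape),
            class = "d2_spec")
}

#' D2-receptor current waveform
#'
#' @param spec a [d2_spec].
#' @param dt sample interval (ms).
#' @return a [stimulus_waveform] with epochs `d2_onset`, `d2_peak`.
#' @export
d2_current <- function(spec, dt = 0.025) {
  stopifnot(inherits(spec, "d2_spec"))
  time <- seq(0, spec$total_dur, by = dt)
  cur <- numeric(length(time))
  t_on <- spec$onset_latency
  t_pk <- t_on + spec$rise_dur
  rise <- time >= t_on & time <= t_pk
  cur[rise] <- spec$peak * sin(pi / 2 * (time[rise] - t_on) / spec$rise_dur)
  dec <- time > t_pk & time <= t_pk + spec$decay_dur
  if (spec$decay_shape == "linear") {
    cur[dec] <- spec$peak * (1 - (time[dec] - t_pk) / spec$decay_dur)
  } else {
    cur[dec] <- spec$peak * exp(-(time[dec] - t_pk) / (spec$decay_dur / 3))
  }
  stimulus_waveform(time, cur,
                    epochs = list(d2_onset = t_on, d2_peak = t_pk))
}

#' Compose a stimulus scenario from shifted, scaled parts
#'
#' Pointwise sum of waveforms after shifting each by `t_shift` ms and
#' scaling by `scale`.  All parts must share the same `dt`.  Scaling the
#' excitatory part implements learning-related potentiation; scaling the D2
#' part implements partial dopamine signaling.
#'
#' @param parts list of [stimulus_waveform] objects.
#' @param t_shift numeric vector of shifts (ms), recycled.
#' @param scale numeric vector of multiplicative scales, recycled.
#' @return a [stimulus_waveform] spanning all shifted parts; epochs are
#'   merged with part-index prefixes (`p1.input`, ...), shifted accordingly.
#' @export
compose_scenario <- function(parts, t_shift = 0, scale = 1) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  lapply(parts, function(p) stopifnot(inherits(p, "stimulus_waveform")))
  dts <- vapply(parts, `[[`, 0, "dt")
  if (max(abs(dts - dts[1])) > 1e-12) stop("all parts must share the same dt")
  dt <- dts[1]
  t_shift <- rep_len(t_shift, length(parts))
  scale <- rep_len(scale, length(parts))
  t_end <- max(vapply(seq_along(parts), function(i) {
    max(parts[[i]]$time) + t_shift[i]
  }, 0))
  time <- seq(0, t_end, by = dt)
  cur <- numeric(length(time))
  epochs <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    idx <- round((p$time + t_shift[i]) / dt) + 1L
    keep <- idx >= 1L & idx <= length(time)
    cur[idx[keep]] <- cur[idx[keep]] + scale[i] * p$current[keep]
    if (length(p$epochs)) {
      shifted <- lapply(p$epochs, function(e) e + t_shift[i])
      names(shifted) <- paste0("p", i, ".", names(p$epochs))
      epochs <- c(epochs, shifted)
    }
  }
  stimulus_waveform(time, cur, epochs = epochs)
}

#' Negative current mimicking the I_Kr-driven undershoot
#'
#' Builds the hyperpolarizing current whose amplitude follows Ohm's law from
#' the cell's input resistance and the target hyperpolarization:
#' amplitude (pA) = -v_target (mV) / r_in (MOhm) * 1000.  With the typical
#' ChI input resistance of 200 MOhm and a 2.72 mV I_Kr hyperpolarization the
#' amplitude is -13.6 pA.  The shape is a canonical undershoot template: a
#' quarter-sine descent to the trough followed by an exponential recovery.
#'
#' @param r_in input resistance (MOhm), > 0.
#' @param v_target hyperpolarization amplitude to mimic (mV, positive).
#' @param fall_dur descent duration to the trough (ms).
#' @param recovery_tau exponential recovery time constant (ms).
#' @param total_dur waveform duration (ms).
#' @param dt sample interval (ms).
#' @return a [stimulus_waveform] with epoch `trough`; attribute-free, the
#'   peak (most negative) value equals the Ohm's-law amplitude.
#' @export
negative_undershoot_mimic <- function(r_in, v_target, fall_dur = 150,
                                      recovery_tau = 150, total_dur = 800,
                                      dt = 0.025) {
  if (!is.finite(r_in) || r_in <= 0) stop("`r_in` must be > 0 (MOhm)")
  amplitude <- -(v_target / r_in) * 1000  # mV / MOhm = nA -> pA
  time <- seq(0, total_dur, by = dt)
  cur <- numeric(length(time))
  fall <- time <= fall_dur
  cur[fall] <- amplitude * sin(pi / 2 * time[fall] / fall_dur)
  rec <- time > fall_dur
  cur[rec] <- amplitude * exp(-(time[rec] - fall_dur) / recovery_tau)
  stimulus_waveform(time, cur, epochs = list(trough = fall_dur))
}

#' Resample a waveform onto a new uniform grid
#'
#' Linear interpolation; resampling to a finer grid that contains the
#' original sample times (and back) preserves the original values exactly.
#'
#' @param wf a [stimulus_waveform].
#' @param dt new sample interval (ms).
#' @return a [stimulus_waveform] on the new grid.
#' @export
resample_waveform <- function(wf, dt) {
  stopifnot(inherits(wf, "stimulus_waveform"), dt > 0)
  time <- seq(min(wf$time), max(wf$time), by = dt)
  cur <- stats::approx(wf$time, wf$current, xout = time, rule = 2)$y
  stimulus_waveform(time, cur, epochs = wf$epochs)
}

#' Read/write waveforms as two-column delimited text
#'
#' Columns: `time_ms`, `current_pA` (tab-separated, with header).
#'
#' @param wf a [stimulus_waveform].
#' @param path file path.
#' @return `write_waveform` returns `path` invisibly; `read_waveform`
#'   returns a [stimulus_waveform] (epoch annotations are not persisted).
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "stimulus_waveform"))
  utils::write.table(
    data.frame(time_ms = wf$time, current_pA = wf$current),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stimulus_waveform(d$time_ms, d$current_pA)
}
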