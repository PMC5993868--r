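#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings; crossings closer than the refractory window to
#' the previous accepted spike are merged into it.
#'
#' @param trace a `voltage_trace` (from [simulate_current_clamp]) or any list
#'   with uniform `time` (ms) and `v` (mV).
#' @param threshold detection threshold (mV).
#' @param refractory merge window (ms).
#' @return an object of class `spike_train`: sorted spike times (ms) plus
#'   optional metadata.
#' @export
detect_spikes <- function(trace, threshold = 0, refractory = 2) {
  v <- trace$v
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- trace$time[up]
  if (length(times) > 1L) {
    keep <- logical(length(times))
    keep[1] <- TRUE
    last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last > refractory) {
        keep[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[keep]
  }
  spike_train(times)
}

#' Spike train container
#'
#' @param times strictly increasing spike times (ms).
#' @param sweep sweep identifier.
#' @param waveform_dur mean extracellular waveform duration (ms), optional.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times, sweep = 1L, waveform_dur = NA_real_) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing")
  }
  structure(list(times = times, sweep = sweep, waveform_dur = waveform_dur),
            class = "spike_train")
}

as_spike_times <- function(x) {
  if (inherits(x, "spike_train")) x$times else as.numeric(x)
}

#' Peri-event firing-rate histogram
#'
#' Spike counts per aligned bin divided by (number of sweeps x bin width).
#' The baseline is the mean rate over the configured pre-event window.
#'
#' @param trains list of spike trains (`spike_train` objects or bare numeric
#'   vectors of times in ms).
#' @param bin bin width (ms), > 0; the pause/rebound analysis convention is
#'   20 ms.
#' @param align alignment event time (ms); bin edges are placed relative to
#'   it (time 0 in the histogram is the event).
#' @param window histogram extent relative to the event, `c(from, to)` ms.
#' @param baseline_window window (relative to the event) whose mean rate
#'   defines the baseline; default all bins ending at or before -100 ms.
#' @return an object of class `rate_histogram`: `edges`, `centers` (ms,
#'   relative to the event), `rate` (Hz), `n_sweeps`, `baseline` (Hz),
#'   `bin` (ms).
#' @export
rate_histogram <- function(trains, bin = 20, align = 0,
                           window = c(-1000, 2000),
                           baseline_window = c(-Inf, -100)) {
  if (!is.finite(bin) || bin <= 0) stop("`bin` must be > 0 ms")
  if (!length(trains)) stop("need at least one spike train")
  if (inherits(trains, "spike_train") || is.numeric(trains)) {
    trains <- list(trains)
  }
  edges <- seq(window[1], window[2], by = bin)
  if (length(edges) < 2L) stop("window shorter than one bin")
  n_sweeps <- length(trains)
  counts <- numeric(length(edges) - 1L)
  for (tr in trains) {
    t_rel <- as_spike_times(tr) - align
    t_rel <- t_rel[t_rel >= edges[1] & t_rel < edges[length(edges)]]
    if (length(t_rel)) {
      idx <- findInterval(t_rel, edges, rightmost.closed = FALSE)
      tab <- tabulate(idx, nbins = length(counts))
      counts <- counts + tab
    }
  }
  rate <- counts / (n_sweeps * bin / 1000)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  in_base <- edges[-1] <= baseline_window[2] & edges[-length(edges)] >=
    baseline_window[1]
  baseline <- if (any(in_base)) mean(rate[in_base]) else NA_real_
  structure(list(edges = edges, centers = centers, rate = rate,
                 n_sweeps = n_sweeps, baseline = baseline,
                 baseline_window = baseline_window, bin = bin),
            class = "rate_histogram")
}

# centered three-bin moving average with shrinking windows at the edges
moving_avg3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - 1L):min(n, i + 1L)])
  }, 0)
}

#' Pause and rebound quantification from a rate histogram
#'
#' The histogram is normalized to its baseline (100%); a centered moving
#' average over three bins is computed; the pause amplitude is the minimum
#' and the rebound amplitude the maximum of that moving average (in % of
#' baseline).  Onset and end times are the nearest moving-average crossings
#' of the 100% level bracketing each extremum, reported at bin resolution
#' (left edge of the first crossing bin); they are `NA` (flagged) when the
#' moving average never crosses back.
#'
#' @param hist a [rate_histogram] with a positive baseline.
#' @param search_window restrict the extremum search to bins whose centers
#'   fall in this window (ms relative to the event); default from the event
#'   onward.
#' @return an object of class `pause_rebound_stats` with fields
#'   `pause_amplitude`, `rebound_amplitude` (% of baseline),
#'   `pause_onset`, `pause_end`, `pause_duration`, `rebound_onset`,
#'   `rebound_end`, `rebound_duration` (ms), and `normalized` (the
#'   moving-average profile).
#' @export
pause_rebound <- function(hist, search_window = c(0, Inf)) {
  stopifnot(inherits(hist, "rate_histogram"))
  if (!is.finite(hist$baseline) || hist$baseline <= 0) {
    stop("histogram baseline must be > 0")
  }
  norm <- 100 * hist$rate / hist$baseline
  ma <- moving_avg3(norm)
  in_win <- hist$centers >= search_window[1] & hist$centers <= search_window[2]
  if (!any(in_win)) stop("empty search window")
  cand <- which(in_win)
  i_min <- cand[which.min(ma[cand])]
  i_max <- cand[which.max(ma[cand])]

  # Boundaries of the sub-(or supra-)baseline run containing the extremum.
  # A centered 3-bin moving average drags each boundary of a step-like
  # change one bin outward, so the reported crossing is pulled back one bin
  # toward the extremum (never past it); ties (MA exactly 100) terminate
  # the run, i.e. break toward the extremum.
  run_bounds <- function(i_ext, below) {
    cmp <- if (below) function(x) x < 100 else function(x) x > 100
    if (!cmp(ma[i_ext])) {
      return(c(NA_real_, NA_real_))
    }
    lo <- i_ext
    while (lo > 1L && cmp(ma[lo - 1L])) lo <- lo - 1L
    hi <- i_ext
    while (hi < length(ma) && cmp(ma[hi + 1L])) hi <- hi + 1L
    onset <- if (lo == 1L) NA_real_ else hist$edges[min(lo + 1L, i_ext)]
    end <- if (hi == length(ma)) NA_real_ else hist$edges[max(hi, i_ext + 1L)]
    c(onset, end)
  }
  pb <- run_bounds(i_min, below = TRUE)
  rb <- run_bounds(i_max, below = FALSE)
  structure(list(
    pause_amplitude = ma[i_min], rebound_amplitude = ma[i_max],
    pause_onset = pb[1], pause_end = pb[2],
    pause_duration = pb[2] - pb[1],
    rebound_onset = rb[1], rebound_end = rb[2],
    rebound_duration = rb[2] - rb[1],
    normalized = ma, centers = hist$centers, bin = hist$bin),
    class = "pause_rebound_stats")
}

#' Membrane-potential undershoot and overshoot statistics
#'
#' Measures, on a spike-free (TTX-like) trace, the trough depth below the
#' resting potential after the input is withdrawn, the peak height above
#' rest during the input, their ratio, and the trough latency from the input
#' offset.
#'
#' @param trace a `voltage_trace`.
#' @param rmp resting membrane potential reference (mV); defaults to the
#'   trace's recorded `rmp`.
#' @param input_epochs epoch annotations carrying an `input = c(start, end)`
#'   window (ms); defaults to the trace's own epochs.  An epoch named
#'   `input` is required.
#' @return an object of class `undershoot_stats`: `trough` (mV >= 0 below
#'   rest), `peak` (mV >= 0 above rest), `ratio` (trough/peak, 0 when peak
#'   is 0), `trough_latency` (ms from input offset), `trough_time` (ms).
#' @export
undershoot <- function(trace, rmp = trace$rmp, input_epochs = trace$epochs) {
  input <- input_epochs[["input"]]
  if (is.null(input)) {
    nm <- grep("\\binput$", names(input_epochs), value = TRUE)
    if (length(nm)) input <- input_epochs[[nm[1]]]
  }
  if (is.null(input) || length(input) != 2L) {
    stop("`input_epochs` must contain an `input = c(start, end)` annotation")
  }
  during <- trace$time >= input[1] & trace$time <= input[2]
  after <- trace$time > input[2]
  if (!any(after)) stop("trace ends at input offset; nothing to measure")
  v_after <- trace$v[after]
  t_after <- trace$time[after]
  i_tr <- which.min(v_after)
  trough <- max(0, rmp - v_after[i_tr])
  peak <- if (any(during)) max(0, max(trace$v[during]) - rmp) else 0
  ratio <- if (peak > 0) trough / peak else 0
  structure(list(trough = trough, peak = peak, ratio = ratio,
                 trough_latency = t_after[i_tr] - input[2],
                 trough_time = t_after[i_tr]),
            class = "undershoot_stats")
}

#' Phase lag between two rate profiles at a reference frequency
#'
#' Fits the first harmonic of each profile at `ref_freq` by projection onto
#' cosine/sine at the bin centers and returns the phase difference
#' phase(b) - phase(a), wrapped to (-180, 180] degrees.  A positive value
#' means `b` lags `a` (is delayed).
#'
#' @param rate_a,rate_b [rate_histogram] objects with identical binning, or
#'   lists with `centers` (ms) and `rate`.
#' @param ref_freq reference (slow-oscillation) frequency, Hz, > 0.
#' @return phase lag in degrees.
#' @export
phase_lag <- function(rate_a, rate_b, ref_freq) {
  if (!is.finite(ref_freq) || ref_freq <= 0) stop("`ref_freq` must be > 0 Hz")
  if (length(rate_a$centers) != length(rate_b$centers) ||
      max(abs(rate_a$centers - rate_b$centers)) > 1e-9) {
    stop("profiles must share the same binning")
  }
  phase_of <- function(h) {
    w <- 2 * pi * ref_freq * h$centers / 1000
    r <- h$rate - mean(h$rate)
    a <- sum(r * cos(w))
    b <- sum(r * sin(w))
    if (sqrt(a^2 + b^2) < 1e-12 * max(1, max(abs(r)))) {
      stop("profile has no power at the reference frequency")
    }
    atan2(b, a)
  }
  d <- (phase_of(rate_b) - phase_of(rate_a)) * 180 / pi
  d <- d %% 360
  if (d > 180) d <- d - 360
  d
}

#' Classify a striatal unit from extracellular criteria
#'
#' Rules: broad waveforms (total spike duration > 1.1 ms) firing tonically
#' (rate within `tonic_range`) with minimum ISI > 20 ms are putative ChIs;
#' broad waveforms with rate < 1 Hz are SPNs; short waveforms are FSIs;
#' tonic units with minimum ISI < 10 ms are LTS interneurons; anything else
#' is unclassified.
#'
#' @param rate mean firing rate (Hz).
#' @param waveform_dur total spike duration of the average waveform (ms).
#' @param min_isi minimum inter-spike interval (ms).
#' @param tonic_range tonic-firing range (Hz), default 3-10.
#' @return one of `"pChI"`, `"SPN"`, `"FSI"`, `"LTS"`, `"unclassified"`.
#' @export
classify_unit <- function(rate, waveform_dur, min_isi,
                          tonic_range = c(3, 10)) {
  stopifnot(is.finite(rate), is.finite(waveform_dur), is.finite(min_isi))
  if (waveform_dur <= 1.1) return("FSI")
  tonic <- rate >= tonic_range[1] & rate <= tonic_range[2]
  if (rate < 1) return("SPN")
  if (tonic && min_isi > 20) return("pChI")
  if (tonic && min_isi < 10) return("LTS")
  "unclassified"
}

#' Squared correlation between firing rate and membrane potential
#'
#' Bins both signals into `n_bins` equal bins over their overlapping time
#' support and returns the squared Pearson correlation between the binned
#' mean membrane potential and the binned rate.
#'
#' @param rate a [rate_histogram] (its centers are interpreted on the same
#'   clock as the trace).
#' @param v a `voltage_trace`.
#' @param n_bins number of correlation bins (default 100).
#' @return squared Pearson correlation (r^2).
#' @export
rate_voltage_correlation <- function(rate, v, n_bins = 100) {
  t0 <- max(min(rate$centers), min(v$time))
  t1 <- min(max(rate$centers), max(v$time))
  if (t1 <= t0) stop("no overlapping time support")
  edges <- seq(t0, t1, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  r_i <- stats::approx(rate$centers, rate$rate, xout = mid, rule = 2)$y
  vb <- findInterval(v$time, edges, rightmost.closed = TRUE)
  ok <- vb >= 1L & vb <= n_bins
  v_i <- vapply(seq_len(n_bins), function(b) mean(v$v[ok & vb == b]), 0)
  if (stats::sd(r_i) == 0 || stats::sd(v_i) == 0) {
    stop("constant input; correlation undefined")
  }
  stats::cor(r_i, v_i)^2
}

#' Read/write spike trains as delimited text
#'
#' Two tab-separated columns: `sweep_id`, `spike_time_ms`.
#'
#' @param trains list of `spike_train` objects or numeric vectors.
#' @param path file path.
#' @return `write_spike_trains` returns `path` invisibly;
#'   `read_spike_trains` returns a list of [spike_train] objects.
#' @export
write_spike_trains <- function(trains, path) {
  rows <- do.call(rbind, lapply(seq_along(trains), function(i) {
    tt <- as_spike_times(trains[[i]])
    if (!length(tt)) return(NULL)
    data.frame(sweep_id = i, spike_time_ms = tt)
  }))
  if (is.null(rows)) rows <- data.frame(sweep_id = integer(),
                                        spike_time_ms = numeric())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  lapply(split(d$spike_time_ms, d$sweep_id), function(tt) {
    spike_train(sort(tt))
  })
}

#' @importFrom stats sd
NULL
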