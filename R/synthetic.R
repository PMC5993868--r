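#' Specification of a synthetic in-vivo-like recording
#'
#' Describes the slow-wave inverted-LFP (iLFP) oscillation and the
#' phase-coupled firing of putative ChIs and SPNs that the generator
#' emulates: tonic ChI firing (3-10 Hz) whose rate tracks the *derivative*
#' of the iLFP (peaking on the ascending phase, dipping on the receding
#' phase), and slower SPN firing lagging the ChI profile by a fixed phase of
#' the slow cycle.
#'
#' @param slow_freq slow-oscillation frequency (Hz).
#' @param lfp_amplitude iLFP oscillation amplitude (a.u.).
#' @param noise_sd additive Gaussian noise SD on the iLFP (a.u.).
#' @param n_sweeps number of sweeps to generate.
#' @param chi_baseline ChI baseline rate (Hz), in the tonic 3-10 Hz range.
#' @param chi_mod_depth modulation depth in \[0, 1\]; 1 gives rate
#'   excursions of +/-100% of baseline.
#' @param spn_baseline SPN baseline rate (Hz).
#' @param spn_lag SPN phase lag behind the ChI profile (degrees of the slow
#'   cycle).
#' @param refractory absolute refractory period enforced on sampled trains
#'   (ms); 20 ms reproduces the ChI minimum-ISI criterion by construction.
#' @param seed integer RNG seed; fixing it makes every generated object
#'   reproducible bit-for-bit.
#' @param duration sweep duration (s); should hold an integer number of slow
#'   cycles so circular phase shifts are exact.
#' @param dt profile sample interval (ms).
#' @return an object of class `recording_spec`.
#' @export
recording_spec <- function(slow_freq = 1, lfp_amplitude = 1, noise_sd = 0.1,
                           n_sweeps = 100, chi_baseline = 6,
                           chi_mod_depth = 0.8, spn_baseline = 2,
                           spn_lag = 60, refractory = 20, seed = 42,
                           duration = 16, dt = 1) {
  stopifnot(slow_freq > 0, chi_baseline >= 0, spn_baseline >= 0,
            chi_mod_depth >= 0, chi_mod_depth <= 1, n_sweeps >= 1,
            refractory >= 0, duration > 0, dt > 0)
  structure(list(slow_freq = slow_freq, lfp_amplitude = lfp_amplitude,
                 noise_sd = noise_sd, n_sweeps = n_sweeps,
                 chi_baseline = chi_baseline, chi_mod_depth = chi_mod_depth,
                 spn_baseline = spn_baseline, spn_lag = spn_lag,
                 refractory = refractory, seed = as.integer(seed),
                 duration = duration, dt = dt),
            class = "recording_spec")
}

#' Generate an inverted-LFP-like slow oscillation
#'
#' A sinusoid at the slow frequency plus seeded Gaussian noise; the iLFP is
#' the proxy of net excitatory input to the striatum.
#'
#' @param spec a [recording_spec].
#' @return list with `time` (ms) and `value` (a.u.), deterministic per seed.
#' @export
generate_ilfp <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  # endpoint excluded: the grid holds exactly duration/dt samples, so the
  # circular smoothing and phase shifts downstream see a periodic signal
  time <- seq(0, spec$duration * 1000 - spec$dt, by = spec$dt)
  clean <- spec$lfp_amplitude * sin(2 * pi * spec$slow_freq * time / 1000)
  noise <- if (spec$noise_sd > 0) {
    with_seed(spec$seed, rnorm(length(time), sd = spec$noise_sd))
  } else {
    0
  }
  list(time = time, value = clean + noise)
}

# running-mean smoother with a centered window of w samples (w odd)
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  as.numeric(stats::filter(x, k, sides = 2, circular = TRUE))
}

# normalized derivative of the (smoothed) iLFP, max |.| = 1
ilfp_derivative <- function(ilfp, smooth_ms = 201, dt = NULL) {
  dt <- dt %||% (ilfp$time[2] - ilfp$time[1])
  w <- max(1L, 2L * floor(smooth_ms / dt / 2) + 1L)
  s <- running_mean(ilfp$value, w)
  n <- length(s)
  d <- (s[c(2:n, 1)] - s[c(n, 1:(n - 1))]) / (2 * dt)  # circular central diff
  m <- max(abs(d))
  if (m == 0) d else d / m
}

#' Ground-truth ChI rate profile from an iLFP trace
#'
#' Differentiator-like response: rate = baseline * (1 + mod_depth *
#' normalized d(iLFP)/dt), floored at zero.  For a pure sinusoidal iLFP the
#' rate maximum therefore leads the iLFP maximum by 90 degrees of the slow
#' cycle (ascending phase) and the minimum falls on the receding phase while
#' the iLFP still exceeds its mean.
#'
#' @param ilfp output of [generate_ilfp] (uniform grid).
#' @param spec a [recording_spec].
#' @param smooth_ms running-mean smoothing applied before differentiation
#'   (ms); tames noise amplification.
#' @return an object of class `rate_profile`: `time` (ms), `rate` (Hz),
#'   `baseline`, `modulation` (the normalized derivative), `spec`.
#' @export
chi_rate_profile <- function(ilfp, spec, smooth_ms = 201) {
  stopifnot(inherits(spec, "recording_spec"))
  mod <- ilfp_derivative(ilfp, smooth_ms)
  rate <- pmax(0, spec$chi_baseline * (1 + spec$chi_mod_depth * mod))
  structure(list(time = ilfp$time, rate = rate,
                 baseline = spec$chi_baseline, modulation = mod,
                 lag_deg = 0, spec = spec),
            class = "rate_profile")
}

#' Ground-truth SPN rate profile
#'
#' The SPN profile uses the same normalized modulation as the ChI profile
#' but phase-delayed by `spec$spn_lag` degrees of the slow cycle (circular
#' shift; exact when the sweep holds an integer number of cycles), scaled to
#' the SPN baseline.
#'
#' @inheritParams chi_rate_profile
#' @return a `rate_profile` with `lag_deg = spec$spn_lag`.
#' @export
spn_rate_profile <- function(ilfp, spec, smooth_ms = 201) {
  stopifnot(inherits(spec, "recording_spec"))
  mod <- ilfp_derivative(ilfp, smooth_ms)
  dt <- ilfp$time[2] - ilfp$time[1]
  shift <- round(spec$spn_lag / 360 / spec$slow_freq * 1000 / dt)
  n <- length(mod)
  shift <- ((shift %% n) + n) %% n
  if (shift > 0) mod <- c(mod[(n - shift + 1):n], mod[1:(n - shift)])
  rate <- pmax(0, spec$spn_baseline * (1 + spec$chi_mod_depth * mod))
  structure(list(time = ilfp$time, rate = rate,
                 baseline = spec$spn_baseline, modulation = mod,
                 lag_deg = spec$spn_lag, spec = spec),
            class = "rate_profile")
}

#' Sample spike trains from a rate profile
#'
#' Inhomogeneous Poisson sampling by thinning (homogeneous candidates at the
#' profile maximum, accepted with probability rate(t)/max rate), followed by
#' sequential enforcement of the absolute refractory period.  Seeded through
#' `spec$seed` (offset by `seed_offset`), so repeated calls with the same
#' spec reproduce bit-for-bit.
#'
#' @param profile a `rate_profile` (rate >= 0).
#' @param spec a [recording_spec]; supplies `n_sweeps`, `refractory`, `seed`.
#' @param seed_offset added to `spec$seed` to decorrelate different units
#'   generated from the same spec.
#' @return list of `spike_train` objects (times in ms), one per sweep.
#' @export
sample_spikes <- function(profile, spec, seed_offset = 0) {
  stopifnot(inherits(spec, "recording_spec"))
  rmax <- max(profile$rate)
  t_end <- max(profile$time)
  with_seed(spec$seed + seed_offset, {
    lapply(seq_len(spec$n_sweeps), function(s) {
      if (rmax <= 0) return(spike_train(numeric(0), sweep = s))
      n_cand <- rpois(1, rmax * t_end / 1000)
      cand <- sort(runif(n_cand, 0, t_end))
      r_at <- stats::approx(profile$time, profile$rate, xout = cand,
                            rule = 2)$y
      keep <- runif(n_cand) < r_at / rmax
      tt <- cand[keep]
      if (length(tt) > 1L && spec$refractory > 0) {
        ok <- logical(length(tt))
        ok[1] <- TRUE
        last <- tt[1]
        for (i in 2:length(tt)) {
          if (tt[i] - last > spec$refractory) {
            ok[i] <- TRUE
            last <- tt[i]
          }
        }
        tt <- tt[ok]
      }
      spike_train(tt, sweep = s)
    })
  })
}

#' Bin a ground-truth rate profile into a rate histogram
#'
#' Averages a continuous rate profile within peri-event bins, producing the
#' same container [rate_histogram] yields for spike trains.  This is the
#' noiseless closed-loop path: feeding a generator profile straight to the
#' estimator isolates estimator error (binning, smoothing, crossing rules)
#' from spike-sampling noise.
#'
#' @param profile a `rate_profile`.
#' @param bin bin width (ms).
#' @param align alignment event time (ms) on the profile clock.
#' @param window histogram extent relative to the event (ms).
#' @param baseline_window window defining the baseline rate (ms, relative).
#' @return a [rate_histogram].
#' @export
bin_profile <- function(profile, bin = 20, align = 0,
                        window = c(-1000, 2000),
                        baseline_window = c(-Inf, -100)) {
  edges <- seq(window[1], window[2], by = bin)
  t_rel <- profile$time - align
  idx <- findInterval(t_rel, edges, rightmost.closed = FALSE)
  ok <- idx >= 1L & idx <= length(edges) - 1L
  rate <- vapply(seq_len(length(edges) - 1L), function(b) {
    mean(profile$rate[ok & idx == b])
  }, 0)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  in_base <- edges[-1] <= baseline_window[2] &
    edges[-length(edges)] >= baseline_window[1]
  baseline <- if (any(in_base)) mean(rate[in_base]) else NA_real_
  structure(list(edges = edges, centers = centers, rate = rate,
                 n_sweeps = NA_integer_, baseline = baseline,
                 baseline_window = baseline_window, bin = bin),
            class = "rate_histogram")
}

#' Rate profile with an inserted pause (and optional rebound)
#'
#' Fixture generator for closed-loop validation of [pause_rebound]: a flat
#' baseline profile with a rectangular dip of known depth and duration,
#' optionally followed by a rectangular rebound bump.
#'
#' @param depth_pct pause depth as a percentage of baseline removed inside
#'   the pause (100 silences the unit; 40 drops the rate to 60% of
#'   baseline).
#' @param duration_ms pause duration (ms).
#' @param rebound_pct rebound level in % of baseline (> 100 adds a bump of
#'   the same duration right after the pause; 100 = no rebound).
#' @param spec a [recording_spec] (baseline, duration, dt, seed).
#' @param pause_onset_ms pause onset time (ms).
#' @return list with `profile` (a `rate_profile`) and `truth` (named list:
#'   `depth_pct`, `level_pct`, `duration_ms`, `onset_ms`, `end_ms`,
#'   `rebound_pct`).
#' @export
pause_scenario <- function(depth_pct, duration_ms, rebound_pct = 100, spec,
                           pause_onset_ms = 1000) {
  stopifnot(depth_pct >= 0, depth_pct <= 100, duration_ms > 0)
  time <- seq(0, spec$duration * 1000 - spec$dt, by = spec$dt)
  rate <- rep(spec$chi_baseline, length(time))
  p0 <- pause_onset_ms
  p1 <- pause_onset_ms + duration_ms
  rate[time >= p0 & time < p1] <- spec$chi_baseline * (100 - depth_pct) / 100
  if (rebound_pct > 100) {
    r1 <- p1 + duration_ms
    rate[time >= p1 & time < r1] <- spec$chi_baseline * rebound_pct / 100
  }
  profile <- structure(list(time = time, rate = rate,
                            baseline = spec$chi_baseline,
                            modulation = rate / spec$chi_baseline - 1,
                            lag_deg = 0, spec = spec),
                       class = "rate_profile")
  list(profile = profile,
       truth = list(depth_pct = depth_pct, level_pct = 100 - depth_pct,
                    duration_ms = duration_ms, onset_ms = p0, end_ms = p1,
                    rebound_pct = rebound_pct))
}

#' Generate a full synthetic recording
#'
#' Bundles the iLFP trace, ChI and SPN ground-truth rate profiles, and
#' sampled spike trains with class labels; all randomness flows from
#' `spec$seed`.
#'
#' @param spec a [recording_spec].
#' @return an object of class `synthetic_recording`: `ilfp`, `chi_profile`,
#'   `spn_profile`, `chi_trains`, `spn_trains`, `labels`, `spec`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "recording_spec"))
  ilfp <- generate_ilfp(spec)
  chi <- chi_rate_profile(ilfp, spec)
  spn <- spn_rate_profile(ilfp, spec)
  structure(list(
    ilfp = ilfp, chi_profile = chi, spn_profile = spn,
    chi_trains = sample_spikes(chi, spec, seed_offset = 1),
    spn_trains = sample_spikes(spn, spec, seed_offset = 2),
    labels = c(chi = "pChI", spn = "SPN"), spec = spec),
    class = "synthetic_recording")
}
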