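#' Gate parameter set for one Hodgkin-Huxley-style gating variable
#'
#' Describes a first-order gate with a Boltzmann steady state
#' \eqn{x_\infty(V) = 1/(1+\exp(-(V-V_{1/2})/k))} and either a constant time
#' constant or a bell-shaped (Gaussian-in-voltage) voltage-dependent one.
#'
#' @param v_half half-activation voltage (mV).
#' @param slope Boltzmann slope factor k (mV, signed; positive gives an
#'   activation-like gate that opens with depolarization, negative an
#'   inactivation-like gate).
#' @param tau either a single positive number (constant time constant, ms) or
#'   a named list/vector with elements `tau_min`, `tau_max`, `v_peak`,
#'   `width` describing a Gaussian bell
#'   \eqn{\tau(V) = \tau_{min} + (\tau_{max}-\tau_{min})
#'   \exp(-((V-V_{peak})/w)^2)}; all times in ms.
#' @param power positive integer exponent applied to the gate in the
#'   conductance product.
#' @return an object of class `gate_params`.
#' @export
gate_params <- function(v_half, slope, tau, power = 1L) {
  stopifnot(is.numeric(v_half), length(v_half) == 1L, is.finite(v_half))
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
      slope == 0) {
    stop("`slope` must be a single non-zero finite number (mV)")
  }
  if (!(is.numeric(power) && length(power) == 1L && power >= 1 &&
        power == round(power))) {
    stop("`power` must be a positive integer")
  }
  if (is.numeric(tau) && length(tau) == 1L) {
    if (!is.finite(tau) || tau <= 0) stop("constant `tau` must be > 0 ms")
    tau_spec <- list(type = "constant", tau = as.numeric(tau))
  } else if ((is.list(tau) || is.numeric(tau)) &&
             all(c("tau_min", "tau_max", "v_peak", "width") %in% names(tau))) {
    tau <- lapply(as.list(tau)[c("tau_min", "tau_max", "v_peak", "width")],
                  as.numeric)
    if (tau$tau_min <= 0 || tau$tau_max <= 0) {
      stop("bell `tau_min` and `tau_max` must be > 0 ms")
    }
    if (tau$width <= 0) stop("bell `width` must be > 0 mV")
    tau_spec <- c(list(type = "bell"), tau)
  } else {
    stop("`tau` must be a positive scalar or a list with ",
         "tau_min, tau_max, v_peak, width")
  }
  structure(list(v_half = as.numeric(v_half), slope = as.numeric(slope),
                 tau_spec = tau_spec, power = as.integer(power)),
            class = "gate_params")
}

#' Ionic-channel description
#'
#' @param name channel label (e.g. `"IKr"`, `"IA"`).
#' @param gbar maximal conductance density (mS/cm2), >= 0.
#' @param e_rev reversal potential (mV).
#' @param activation a [gate_params] object.
#' @param inactivation a [gate_params] object, or `NULL` for a
#'   non-inactivating channel.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, gbar, e_rev, activation, inactivation = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(gbar) || length(gbar) != 1L || !is.finite(gbar) || gbar < 0) {
    stop("`gbar` must be a single finite number >= 0 (mS/cm2)")
  }
  stopifnot(is.numeric(e_rev), length(e_rev) == 1L, is.finite(e_rev))
  if (!inherits(activation, "gate_params")) {
    stop("`activation` must be a gate_params object")
  }
  if (!is.null(inactivation) && !inherits(inactivation, "gate_params")) {
    stop("`inactivation` must be a gate_params object or NULL")
  }
  structure(list(name = name, gbar = as.numeric(gbar),
                 e_rev = as.numeric(e_rev), activation = activation,
                 inactivation = inactivation),
            class = "channel_spec")
}

#' Boltzmann steady-state gate value
#'
#' @param v membrane potential (mV); vectorized.
#' @param p a [gate_params] object.
#' @return steady-state open fraction(s) in (0, 1).
#' @export
steady_state <- function(v, p) {
  stopifnot(inherits(p, "gate_params"))
  if (!is.numeric(v) || any(!is.finite(v))) stop("`v` must be finite (mV)")
  1 / (1 + exp(-(v - p$v_half) / p$slope))
}

#' Gate time constant at a given voltage
#'
#' Returns the constant value for constant-tau gates, or the Gaussian bell
#' value for voltage-dependent ones (peaking at `v_peak`, approaching
#' `tau_min` far from it).
#'
#' @inheritParams steady_state
#' @return time constant(s), ms (> 0).
#' @export
time_constant <- function(v, p) {
  stopifnot(inherits(p, "gate_params"))
  if (!is.numeric(v) || any(!is.finite(v))) stop("`v` must be finite (mV)")
  ts <- p$tau_spec
  if (ts$type == "constant") {
    rep(ts$tau, length(v))
  } else {
    z <- (v - ts$v_peak) / ts$width
    ts$tau_min + (ts$tau_max - ts$tau_min) * exp(-z^2)
  }
}

#' First-order gate relaxation rate
#'
#' dx/dt = (x_inf(V) - x) / tau(V); zero exactly at the steady state.
#'
#' @inheritParams steady_state
#' @param x current gate value(s) in \[0, 1\].
#' @return rate(s) in 1/ms.
#' @export
gate_derivative <- function(v, x, p) {
  stopifnot(inherits(p, "gate_params"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("gate value `x` must lie in [0, 1]")
  }
  (steady_state(v, p) - x) / time_constant(v, p)
}

#' Membrane current density carried by one channel
#'
#' \eqn{I = \bar g \, m^{p_m} \, h^{p_h} \, (V - E_{rev})} in uA/cm2
#' (gbar in mS/cm2 times mV gives uA/cm2).  Outward current is positive.
#'
#' @param v membrane potential (mV).
#' @param gates named list with element `m` (activation gate value) and,
#'   for inactivating channels, `h`.
#' @param spec a [channel_spec] object.
#' @return current density (uA/cm2); vectorized over `v` if gates are scalar.
#' @export
current_density <- function(v, gates, spec) {
  stopifnot(inherits(spec, "channel_spec"))
  if (is.null(gates$m)) stop("missing activation gate `m` for ", spec$name)
  has_h <- !is.null(spec$inactivation)
  if (has_h && is.null(gates$h)) {
    stop("channel ", spec$name, " requires an inactivation gate `h`")
  }
  if (!has_h && !is.null(gates$h)) {
    stop("channel ", spec$name, " is non-inactivating; no `h` gate expected")
  }
  g <- spec$gbar * gates$m^spec$activation$power
  if (has_h) g <- g * gates$h^spec$inactivation$power
  g * (v - spec$e_rev)
}

# steady-state current density of one channel at voltage v (uA/cm2)
steady_current_density <- function(v, spec) {
  gates <- list(m = steady_state(v, spec$activation))
  if (!is.null(spec$inactivation)) {
    gates$h <- steady_state(v, spec$inactivation)
  }
  current_density(v, gates, spec)
}

# ---- configuration file I/O ------------------------------------------------

gate_from_config <- function(g) {
  tau <- if (!is.null(g$tau_ms)) {
    g$tau_ms
  } else {
    list(tau_min = g$tau$tau_min_ms, tau_max = g$tau$tau_max_ms,
         v_peak = g$tau$v_peak_mV, width = g$tau$width_mV)
  }
  gate_params(v_half = g$v_half_mV, slope = g$slope_mV, tau = tau,
              power = g$power %||% 1L)
}

channel_from_config <- function(ch) {
  inact <- if (!is.null(ch$inactivation)) gate_from_config(ch$inactivation)
  channel_spec(name = ch$name, gbar = ch$gbar_mS_cm2, e_rev = ch$e_rev_mV,
               activation = gate_from_config(ch$activation),
               inactivation = inact)
}

#' Read channel definitions from a JSON configuration file
#'
#' @param path path to a JSON file whose `channels` array holds objects with
#'   keys `name`, `gbar_mS_cm2`, `e_rev_mV`, `activation`, `inactivation`
#'   (the latter `null` for non-inactivating channels); gates use keys
#'   `v_half_mV`, `slope_mV`, `power` and either `tau_ms` or a `tau` object
#'   with `tau_min_ms`, `tau_max_ms`, `v_peak_mV`, `width_mV`.
#' @return named list of [channel_spec] objects.
#' @export
read_channel_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  chans <- lapply(cfg$channels, channel_from_config)
  stats::setNames(chans, vapply(chans, `[[`, "", "name"))
}

# flatten channel specs into the parameter matrix consumed by the C++ stepper
channel_matrix <- function(channels) {
  pack_gate <- function(p) {
    ts <- p$tau_spec
    if (ts$type == "constant") c(p$power, p$v_half, p$slope, 0, ts$tau, 0, 0, 1)
    else c(p$power, p$v_half, p$slope, 1, ts$tau_min, ts$tau_max, ts$v_peak,
           ts$width)
  }
  rows <- lapply(channels, function(ch) {
    a <- pack_gate(ch$activation)
    if (is.null(ch$inactivation)) {
      i <- c(0, 1, 0, 1, 0, 1, 0, 0, 1)
    } else {
      i <- c(1, pack_gate(ch$inactivation))
    }
    c(ch$gbar, ch$e_rev, a, i)
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(0, nrow = 0, ncol = 19)
  m
}
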