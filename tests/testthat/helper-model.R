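# shared fixtures built in code

# reference first-order gate integrator (exponential Euler in plain R),
# independent of the C++ stepper
relax_gate <- function(p, v, x0, t_end, dt = 0.025) {
  n <- floor(t_end / dt)
  x <- x0
  for (i in seq_len(n)) {
    xi <- steady_state(v, p)
    x <- xi + (x - xi) * exp(-dt / time_constant(v, p))
  }
  x
}

# default model with a chosen channel subset, memoized across tests
model_cache <- new.env(parent = emptyenv())
cached_config <- function(channels = c("IA", "IKr"), target_rmp = -40) {
  key <- paste(c(channels, target_rmp), collapse = "|")
  if (is.null(model_cache[[key]])) {
    model_cache[[key]] <- default_model_config(target_rmp = target_rmp,
                                               channels = channels)
  }
  model_cache[[key]]
}

# simple synthetic voltage trace on a uniform grid
make_trace <- function(time, v, rmp = -40, epochs = list()) {
  structure(list(time = time, v = v, i_inj = numeric(length(time)),
                 currents = NULL, dt = time[2] - time[1], rmp = rmp,
                 epochs = epochs),
            class = "voltage_trace")
}
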