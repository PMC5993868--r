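test_that("membrane_area is the cylinder lateral surface in cm2", {
  g <- cell_geometry(diameter = 15, length = 40, cm = 1)
  expect_equal(membrane_area(g), 1.884956e-5, tolerance = 1e-9 / 1.9e-5)
  g2 <- cell_geometry(diameter = 30, length = 40)
  expect_equal(membrane_area(g2), 2 * membrane_area(g))
  expect_error(cell_geometry(diameter = 0), "> 0")
})

test_that("resting potential calibration hits the target", {
  leak_only <- model_config(channels = list(), target_rmp = -40)
  expect_equal(leak_only$leak_e, -40)          # no other currents
  full <- cached_config()
  expect_lt(abs(resting_potential(full) - (-40)), 0.1)
  hyp <- cached_config(target_rmp = -76)
  expect_lt(abs(resting_potential(hyp) - (-76)), 0.1)
})

test_that("calibration errors when no leak reversal in [-120, 0] works", {
  big_kr <- channel_spec("IKr", 10, -85, gate_params(-45, 8, tau = 300))
  expect_error(model_config(channels = list(big_kr), target_rmp = -40),
               "\\[-120, 0\\]")
})

test_that("zero-input trace stays at the calibrated RMP", {
  cfg <- cached_config()
  grid <- seq(0, 10000, by = cfg$dt)
  stim <- stimulus_waveform(grid, numeric(length(grid)))
  tr <- simulate_current_clamp(cfg, stim)
  expect_lt(max(abs(tr$v - (-40))), 0.5)
  expect_lt(abs(tr$v[length(tr$v)] - (-40)), 0.1)
})

test_that("leak-only step response matches the RC closed form within 1%", {
  cfg <- model_config(channels = list(), target_rmp = -40)
  area <- membrane_area(cfg$geometry)
  r_in <- 1 / (cfg$leak_g * 1e-3 * area)            # Ohm
  tau <- cfg$geometry$cm / cfg$leak_g               # ms
  i_pA <- 20
  stim <- trapezoid_current(i_pA, ramp_up = 0, plateau = 1000, ramp_down = 0,
                            dt = cfg$dt, post = 500)
  tr <- simulate_current_clamp(cfg, stim)
  dv_inf <- i_pA * 1e-12 * r_in * 1e3               # mV
  during <- tr$time > 0 & tr$time <= 1000
  expected <- -40 + dv_inf * (1 - exp(-tr$time[during] / tau))
  expect_lt(max(abs(tr$v[during] - expected)) / dv_inf, 0.01)
})

test_that("passivity: with all conductances but leak at zero, V relaxes monotonically to leak_e", {
  cfg <- model_config(channels = list(), leak_e = -55, target_rmp = -40)
  grid <- seq(0, 200, by = cfg$dt)
  tr <- simulate_current_clamp(cfg, stimulus_waveform(grid,
                                                      numeric(length(grid))))
  expect_true(all(diff(tr$v) <= 1e-12))
  expect_lt(abs(tr$v[length(tr$v)] - (-55)), 0.01)
})

test_that("full model trapezoid shows overshoot, sag and undershoot", {
  cfg <- cached_config()
  stim <- trapezoid_current(100, 4000, 4000, 4000, dt = cfg$dt, pre = 500,
                            post = 3000)
  tr <- simulate_current_clamp(cfg, stim)
  plateau <- tr$epochs$plateau
  v_plateau_end <- tr$v[max(which(tr$time <= plateau[2]))]
  expect_gt(max(tr$v), v_plateau_end + 0.1)   # overshoot then sag
  expect_lt(min(tr$v[tr$time > tr$epochs$input[2]]), -41)  # undershoot
})

test_that("hyperpolarizing trapezoid mirrors into undershoot-then-overshoot", {
  cfg <- cached_config()
  stim <- trapezoid_current(100, 4000, 4000, 4000, sign = -1, dt = cfg$dt,
                            pre = 500, post = 3000)
  tr <- simulate_current_clamp(cfg, stim)
  during <- tr$time >= tr$epochs$input[1] & tr$time <= tr$epochs$input[2]
  after <- tr$time > tr$epochs$input[2]
  expect_lt(min(tr$v[during]), -45)            # input-driven hyperpolarization
  expect_gt(max(tr$v[after]), -40 + 0.2)       # rebound overshoot above RMP
})

test_that("non-finite stimulus and solver divergence raise errors", {
  cfg <- cached_config()
  grid <- seq(0, 10, by = cfg$dt)
  bad <- stimulus_waveform(grid, numeric(length(grid)))
  bad$current[5] <- NA_real_
  expect_error(simulate_current_clamp(cfg, bad), "finite")
  huge <- stimulus_waveform(grid, rep(1e9, length(grid)))
  expect_error(simulate_current_clamp(cfg, huge), "diverged")
})

test_that("voltage-clamp steps match the analytic steady state", {
  cfg <- cached_config()
  vc <- simulate_voltage_steps(cfg, holding = -100, step = 20, n_steps = 8,
                               step_dur = 3000)
  expect_true(all(diff(vc$levels) > 0))
  for (nm in names(vc$currents)) {
    ch <- cfg$channels[[nm]]
    final <- vc$currents[[nm]][nrow(vc$currents[[nm]]), ]
    gates <- list(m = steady_state(vc$levels, ch$activation))
    if (!is.null(ch$inactivation)) {
      gates$h <- steady_state(vc$levels, ch$inactivation)
    }
    analytic <- ch$gbar * gates$m *
      (if (is.null(gates$h)) 1 else gates$h) * (vc$levels - ch$e_rev)
    big <- abs(analytic) > 1e-3
    expect_lt(max(abs(final[big] - analytic[big]) / abs(analytic[big])),
              0.005)
  }
  # a step landing exactly on the reversal potential passes zero current
  vc2 <- simulate_voltage_steps(cfg, holding = -100, step = 15, n_steps = 1,
                                step_dur = 500)
  expect_true(all(abs(vc2$currents$IKr) < 1e-12))
})

test_that("IKr voltage-clamp family is non-inactivating, IA inactivates", {
  cfg <- cached_config()
  vc <- simulate_voltage_steps(cfg, holding = -100, step = 20, n_steps = 8,
                               step_dur = 500)
  top_kr <- vc$currents$IKr[, 8]
  expect_equal(max(top_kr), top_kr[length(top_kr)], tolerance = 1e-6)
  expect_true(all(diff(top_kr) >= -1e-12))     # monotone approach, no decay
  top_a <- vc$currents$IA[, 8]
  expect_lt(top_a[length(top_a)], 0.05 * max(top_a))  # transient
})

test_that("apply_pharmacology builds the documented scenario configs", {
  cfg <- cached_config()
  expect_identical(apply_pharmacology(cfg, "control"), cfg)
  expect_error(apply_pharmacology(cfg, "tetrodotoxin"), "valid")

  xe <- apply_pharmacology(cfg, "xe991_or_tea")
  expect_equal(xe$channels$IKr$gbar, 0)
  expect_equal(cfg$channels$IKr$gbar, 0.5)     # original untouched
  expect_lt(abs(resting_potential(xe) - (-40)), 0.1)

  fa <- apply_pharmacology(cfg, "four_ap")
  expect_equal(fa$channels$IA$gbar, 0)

  zd <- apply_pharmacology(cfg, "zd7288")
  expect_lt(abs(resting_potential(zd) - (-76)), 0.1)

  zr <- apply_pharmacology(cfg, "zd7288_restored")
  expect_gt(zr$holding_current, 0)             # depolarizing bias current
  expect_lt(abs(resting_potential(zr) - (-40)), 0.1)
})

test_that("dt halving changes the trapezoid trace by < 0.1 mV", {
  cfg <- cached_config()
  cfg2 <- model_config(channels = cfg$channels, target_rmp = -40,
                       dt = cfg$dt / 2)
  stim <- trapezoid_current(100, 2000, 1000, 2000, dt = cfg$dt, pre = 200,
                            post = 1500)
  t1 <- simulate_current_clamp(cfg, stim)
  t2 <- simulate_current_clamp(cfg2, stim)
  expect_lt(max(abs(t1$v - t2$v[seq(1, length(t2$v), by = 2)])), 0.1)
})
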