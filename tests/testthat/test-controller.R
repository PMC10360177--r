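# PG/PS controller: clock quantization, Gaussian basis, adaptive updates,
# sigh insertion, channel mapping and charge accounting.

test_that("pattern-generator clock quantizes the period and wraps phase", {
  ck <- pg_clock(1.5, 0.040)
  expect_identical(ck$n_steps, 37L)          # 1.5 s rounds down to 1.48 s
  expect_equal(ck$cycle_period, 1.48)
  expect_equal(pg_phase(ck), 0)
  expect_identical(ck$cycle_index, 0L)

  for (i in 1:37) ck <- pg_step(ck)
  expect_identical(ck$cycle_index, 1L)
  expect_equal(pg_phase(ck), 0)
  for (i in 1:37) ck <- pg_step(ck)
  expect_identical(ck$cycle_index, 2L)

  # phase increases monotonically within a cycle
  ck2 <- pg_clock(1.52, 0.040)
  expect_identical(ck2$n_steps, 38L)
  ph <- numeric(38)
  for (i in 1:38) {
    ph[i] <- pg_phase(ck2)
    ck2 <- pg_step(ck2)
  }
  expect_true(all(diff(ph) > 0))
  expect_true(all(ph >= 0 & ph < 1))
})

test_that("Gaussian basis peaks at its center, wraps circularly, and tiles", {
  ps <- ps_state()
  phi <- ps_basis(ps$basis_centers[3], ps$basis_centers, ps$basis_width)
  expect_equal(phi[3], 1.0)
  expect_true(all(phi > 0 & phi <= 1))

  # circular wrap: phase just below 1 is close to phase 0 for center 0
  a <- ps_basis(0.0, 0, 1 / 25)
  b <- ps_basis(0.9999, 0, 1 / 25)
  expect_equal(a, b, tolerance = 1e-3)

  # tiling: uniform weights give an output flat in phase to within 1%
  grid <- seq(0, 1 - 1e-9, length.out = 500)
  out <- vapply(grid, function(p)
    sum(0.3 * ps_basis(p, ps$basis_centers, ps$basis_width)), numeric(1))
  expect_lt((max(out) - min(out)) / mean(out), 0.01)
})

test_that("pattern-shaper output is the clipped weighted sum and is buffered", {
  ps <- ps_state()
  expect_equal(ps_output(ps, 0.3)$u, 0)      # all weights zero

  set.seed(42)
  w <- runif(25, 0, 0.2)
  ps <- ps_state(weights = w)
  for (p in c(0.05, 0.37, 0.81)) {
    direct <- sum(w * ps_basis(p, ps$basis_centers, ps$basis_width))
    expect_equal(ps_output(ps, p)$u, min(max(direct, 0), 1))
  }

  # clipping at 1 when the raw sum exceeds it
  ps_big <- ps_state(weights = rep(1, 25))
  expect_equal(ps_big$weights[3] * 25 > 1, TRUE)
  expect_equal(ps_output(ps_big, 0.5)$u, 1)

  # outputs accumulate in the cycle buffer and commit to stored_outputs
  r <- ps_output(ps, 0.1)
  r <- ps_output(r$state, 0.2)
  st <- ps_cycle_commit(r$state)
  expect_length(st$stored_outputs, 2L)
  expect_length(st$current_outputs, 0L)
})

test_that("delta-rule update is local, nonnegative, and frozen when disabled", {
  ps <- ps_state(weights = rep(0.1, 25), tau_d = 0.080, cycle_period = 1.48)
  expect_identical(ps_update(ps, 0, 0.4)$weights, ps$weights)

  up <- ps_update(ps, 0.5, 0.4)
  dw <- up$weights - ps$weights
  expect_true(all(dw >= 0))
  # the largest increase is at the center nearest the delay-shifted phase
  shifted <- (0.4 - ps$delay_frac) %% 1
  expect_identical(which.max(dw),
                   which.min(abs(ps$basis_centers - shifted)))

  # nonnegativity clipping for large negative errors
  down <- ps_update(ps, -50, 0.4)
  expect_true(all(down$weights >= 0))

  ps$learning_enabled <- FALSE
  expect_identical(ps_update(ps, 1, 0.4)$weights, ps$weights)
})

test_that("on a static linear plant the shaper converges and error shrinks", {
  # independent fixed-point oracle: V = g * u, no dynamics, no noise
  g <- 1.5
  n_steps <- 37L
  phase <- (seq_len(n_steps) - 1) / n_steps
  desired <- sin(pi * phase)
  window <- inspiratory_window(desired)
  ps <- ps_state(eta = 0.02, tau_d = 0, cycle_period = 1.48)
  irmse <- numeric(300)
  final_err <- NULL
  for (cyc in 1:300) {
    errs <- numeric(0)
    for (k in seq_len(n_steps)) {
      if (!window[k]) next
      r <- ps_output(ps, phase[k])
      ps <- r$state
      e <- (desired[k] - g * r$u) / max(desired)
      errs <- c(errs, e)
      ps <- ps_update(ps, e, phase[k])
    }
    ps <- ps_cycle_commit(ps)
    irmse[cyc] <- 100 * sqrt(mean(errs^2))
    final_err <- errs
  }
  expect_lt(max(abs(final_err)), 0.05)
  expect_lt(irmse[300], 10)
  expect_true(all(diff(irmse[50:300]) <= 1e-6))
})

test_that("sigh insertion doubles stored outputs and pauses learning", {
  sched <- sigh_schedule(30L)
  ps <- ps_state()
  ps$stored_outputs <- c(0.2, 0.4, 0.3)

  s30 <- apply_sigh(sched, ps, 30L)
  expect_true(s30$is_sigh)
  expect_true(s30$learning_pause)
  expect_identical(s30$pre_clip, c(0.4, 0.8, 0.6))

  s29 <- apply_sigh(sched, ps, 29L)
  expect_false(s29$is_sigh)
  expect_false(s29$learning_pause)
  expect_null(s29$pre_clip)

  s31 <- apply_sigh(sched, ps, 31L)
  expect_false(s31$is_sigh)
  expect_true(s31$learning_pause)
  s32 <- apply_sigh(sched, ps, 32L)
  expect_false(s32$learning_pause)

  ps$stored_outputs <- numeric(0)
  expect_error(apply_sigh(sched, ps, 30L), "empty")
  expect_error(sigh_schedule(1L))
})

test_that("channel map spans twitch threshold to max and saturates", {
  dia <- stim_channel("dia", twitch_mA = 1.5, max_mA = 3.0)
  eic <- stim_channel("eic", twitch_mA = 1.0, max_mA = 2.0)
  chans <- list(dia, eic)

  expect_identical(unname(channel_map(0, chans)), c(0, 0))
  expect_identical(unname(channel_map(0.04, chans)), c(0, 0))  # below u_on
  expect_equal(unname(channel_map(1, chans)), c(3.0, 2.0))
  expect_equal(unname(channel_map(2, chans)), c(3.0, 2.0))     # sigh doubling clips
  mid <- channel_map(0.5, chans)
  expect_equal(unname(mid), c(1.5 + 0.5 * 1.5, 1.0 + 0.5 * 1.0))

  # amplitude bounds hold for arbitrary nonnegative outputs
  set.seed(7)
  for (u in runif(200, 0, 3)) {
    a <- channel_map(u, chans)
    expect_true(all(a >= 0 & a <= c(3.0, 2.0)))
    if (u < 0.05) expect_true(all(a == 0))
  }

  expect_error(stim_channel("dia", 1.5, max_mA = 5),
               "\\[1.5, 2\\]")
  expect_silent(stim_channel("dia", 1.5, max_mA = 5, allow_override = TRUE))
})

test_that("pulse-train charge follows the width x amplitude x rate formula", {
  ch <- stim_channel("dia", twitch_mA = 1.5, pulse_us = 80, pulse_hz = 75)
  expect_equal(encode_charge(2, ch, 1), 0.012)   # 2 mA leading-phase train
  expect_identical(encode_charge(0, ch, 1), 0)

  # per-cycle additivity: 37 steps of 40 ms equal one shot of 1.48 s
  amp <- 2.37
  per_step <- sum(rep(encode_charge(amp, ch, 0.040), 37))
  one_shot <- encode_charge(amp, ch, 1.48)
  expect_lt(abs(per_step - one_shot) / one_shot, 1e-12)

  # doubling the amplitude doubles the charge
  expect_equal(encode_charge(2 * amp, ch, 0.7), 2 * encode_charge(amp, ch, 0.7))
})
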