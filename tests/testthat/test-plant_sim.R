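# Synthetic respiratory plant: recruitment, fatigue dynamics, lung mechanics,
# intrinsic oscillator with the inflation reflex, sensing, and the closed-loop
# trial contract.

test_that("recruitment is zero below threshold and linear up to saturation", {
  m <- muscle_plant(1.5, 3.0)
  expect_identical(recruit(1.5 - 1e-9, m), 0)
  expect_identical(recruit(0, m), 0)
  expect_equal(recruit(3.0, m), 1)
  expect_equal(recruit(3.5, m), 1)
  expect_equal(recruit((1.5 + 3.0) / 2, m), 0.5)
  expect_error(muscle_plant(1.5, sat_mA = 1.5), "exceed")
})

test_that("fatigue relaxes to the closed-form equilibrium and is monotone in charge", {
  m0 <- muscle_plant(1.5, k_f = 0.07, rho = 0.0017)

  # no stimulation, no fatigue
  m <- m0
  for (i in 1:100) m <- fatigue_step(m, 0, 0.01)
  expect_identical(m$F, 0)

  # pure recovery decays exponentially at rate rho
  m <- m0; m$F <- 0.5
  t_tot <- 200
  for (i in seq_len(t_tot / 0.01)) m <- fatigue_step(m, 0, 0.01)
  expect_equal(m$F, 0.5 * exp(-m0$rho * t_tot), tolerance = 1e-3)

  # constant charge rate: equilibrium k_f q / (k_f q + rho) within 1%
  q <- 0.01
  eq <- m0$k_f * q / (m0$k_f * q + m0$rho)
  tau <- 1 / (m0$k_f * q + m0$rho)
  m <- m0
  for (i in seq_len(round(5 * tau / 0.05))) m <- fatigue_step(m, q, 0.05)
  expect_equal(m$F, eq, tolerance = 0.01)

  # monotonicity: larger charge rate dominates at every time point
  m1 <- m0; m2 <- m0
  for (i in 1:2000) {
    m1 <- fatigue_step(m1, 0.005, 0.05)
    m2 <- fatigue_step(m2, 0.012, 0.05)
    expect_true(m1$F <= m2$F)
  }
})

test_that("lung volume decays passively and reaches synergistic steady states", {
  lg0 <- lung_model()

  # passive expiration: exponential decay at tau_lung
  lg <- lg0; lg$V <- 1
  for (i in 1:150) lg <- lung_step(lg, 0, 0, 0, 0.001)
  expect_equal(lg$V, exp(-0.15 / lg0$tau_lung), tolerance = 5e-3)

  run_to_ss <- function(a_dia, a_eic) {
    lg <- lg0
    for (i in 1:2000) lg <- lung_step(lg, a_dia, a_eic, 0, 0.001)
    lg$V
  }
  v_dia <- run_to_ss(1, 0)
  v_eic <- run_to_ss(0, 1)
  v_both <- run_to_ss(1, 1)
  expect_equal(v_dia, lg0$g_dia, tolerance = 1e-3)
  expect_equal(v_eic, lg0$g_eic, tolerance = 1e-3)
  expect_equal(v_both, lg0$g_dia + lg0$g_eic + lg0$g_syn, tolerance = 1e-3)
  # synergy: combined exceeds the sum of singles by exactly g_syn
  expect_equal(v_both - (v_dia + v_eic), lg0$g_syn, tolerance = 1e-2)
})

test_that("Euler integration converges under step-size refinement", {
  sim_trace <- function(dt) {
    p <- resp_plant()
    p$cpg$enabled <- FALSE
    p$cpg$D0 <- 1.2
    n <- round(1.5 / dt)
    v <- numeric(n)
    for (i in seq_len(n)) {
      out <- plant_advance(p, 0.4, 0.3, 0.005, 0.004, n_sub = 1L, dt = dt)
      p <- out$plant
      v[i] <- p$lung$V
    }
    v
  }
  v1 <- sim_trace(0.001)
  v2 <- sim_trace(0.0005)
  # compare at common time points (every 1 ms)
  expect_lt(max(abs(v2[seq(2, length(v2), by = 2)] - v1)) / max(v1), 0.005)
})

test_that("intrinsic oscillator free-runs at T0 and is silenced by V_HB = Inf", {
  cpg <- intrinsic_cpg(T0 = 1.5, D0 = 1.2)
  onsets <- c()
  t <- 0
  for (i in 1:6000) {
    st <- cpg_step(cpg, 0, 0.001)   # V always 0: no reflex action
    cpg <- st$cpg
    t <- t + 0.001
    if (st$onset) onsets <- c(onsets, t)
    expect_false(st$reset)
  }
  expect_equal(diff(onsets), rep(1.5, length(onsets) - 1), tolerance = 1e-2)

  cpg2 <- intrinsic_cpg(V_HB = Inf)
  resets <- 0
  for (i in 1:3000) {
    st <- cpg_step(cpg2, 100, 0.001)  # huge volume, disabled reflex
    cpg2 <- st$cpg
    resets <- resets + st$reset
  }
  expect_identical(resets, 0)
})

test_that("inflation reflex terminates inspiration and defers onsets", {
  cpg <- intrinsic_cpg(V_HB = 1.1, V_release = 0.33)
  cpg$theta <- 0.25
  st <- cpg_step(cpg, 1.2, 0.001)     # inflated during inspiration: reset
  expect_true(st$reset)
  expect_equal(st$cpg$theta, 0.5)

  cpg$theta <- 1 - 1e-4
  st <- cpg_step(cpg, 0.5, 0.001)     # above release level: onset deferred
  expect_false(st$onset)
  expect_lt(st$cpg$theta, 1)
  st2 <- cpg_step(st$cpg, 0.1, 0.001) # deflated: onset fires
  expect_true(st2$onset)
})

test_that("sensor is exact without noise and reproducible with a seed", {
  sn <- sensor_model(noise_sd = 0)
  expect_identical(measure(sn, 1.3, 0.2), 1.1)

  sn <- sensor_model(noise_sd = 0.02)
  set.seed(11); a <- replicate(50, measure(sn, 1, 0))
  set.seed(11); b <- replicate(50, measure(sn, 1, 0))
  expect_identical(a, b)

  set.seed(12)
  x <- replicate(1e4, measure(sn, 1, 0))
  expect_equal(sd(x), 0.02, tolerance = 0.05)
})

test_that("compiled plant integrator matches the R reference composition", {
  set.seed(99)
  p_cpp <- resp_plant()
  p_cpp$cpg$D0 <- 1.2
  p_r <- p_cpp
  for (i in 1:60) {
    a_d <- runif(1); a_e <- runif(1)
    q_d <- runif(1, 0, 0.02); q_e <- runif(1, 0, 0.02)
    out_cpp <- plant_advance(p_cpp, a_d, a_e, q_d, q_e, 40L, 0.001,
                             use_compiled = TRUE)
    out_r <- plant_advance(p_r, a_d, a_e, q_d, q_e, 40L, 0.001,
                           use_compiled = FALSE)
    p_cpp <- out_cpp$plant
    p_r <- out_r$plant
    expect_equal(pack_plant_state(p_cpp), pack_plant_state(p_r),
                 tolerance = 1e-12)
    expect_identical(out_cpp$onset_sub, out_r$onset_sub)
    expect_identical(out_cpp$n_resets, out_r$n_resets)
    expect_equal(out_cpp$v_max, out_r$v_max, tolerance = 1e-12)
  }
})

test_that("with all inputs zero the plant relaxes to rest", {
  p <- resp_plant()
  p$cpg$enabled <- FALSE
  p$cpg$D0 <- 0
  p$lung$V <- 1.4
  p$dia$F <- 0.4
  p$eic$F <- 0.3
  out <- plant_advance(p, 0, 0, 0, 0, n_sub = 4000L, dt = 0.001)
  expect_lt(out$plant$lung$V, 1e-6)
  expect_lt(out$plant$dia$F, 0.4)   # recovering
  # recovery time constant is 1/rho ~ 10 min; integrate one hour
  out <- plant_advance(out$plant, 0, 0, 0, 0, 3600000L, 0.001)
  expect_lt(out$plant$dia$F, 1e-3)
  expect_lt(out$plant$eic$F, 1e-3)
})

test_that("spontaneous trials reproduce the calibrated baseline tidal volume", {
  tr <- cached_trial("spontaneous", cycles = 20L, seed = 5L)
  expect_equal(tr$meta$baseline_tidal_ml, 1.0, tolerance = 0.02)
  # unstimulated: no charge, no commanded current anywhere
  expect_true(all(tr$steps$i_dia_mA == 0))
  expect_true(all(tr$steps$i_eic_mA == 0))
  expect_true(all(tr$cycles$charge_dia == 0))
})

test_that("trials are bit-identical under the same config and seed", {
  a <- cached_trial("spontaneous", cycles = 20L, seed = 5L)
  b <- simulate_trial(mode = "spontaneous", pacing_cycles = 20L, seed = 5L)
  expect_identical(a$steps, b$steps)
  expect_identical(a$cycles, b$cycles)
  expect_identical(a$weights, b$weights)
  # a different seed produces different sensor noise
  c2 <- simulate_trial(mode = "spontaneous", pacing_cycles = 20L, seed = 6L)
  expect_false(identical(a$steps$v_meas, c2$steps$v_meas))
})

test_that("the desired tidal volume is exactly 120% of the measured baseline", {
  tr <- cached_trial("combined", cycles = 60L, seed = 1L)
  expect_identical(tr$meta$desired_tidal_ml, 1.2 * tr$meta$baseline_tidal_ml)
  # the sampled trajectory peaks at the grid point nearest the true peak
  expect_lte(max(tr$meta$desired), tr$meta$desired_tidal_ml)
  expect_gt(max(tr$meta$desired), 0.995 * tr$meta$desired_tidal_ml)
  expect_identical(tr$meta$n_steps_per_cycle,
                   as.integer(round(tr$meta$cycle_period_s / 0.040)))
})

test_that("breath detection recovers onsets, tidal volumes and the period", {
  # synthetic trace: 8 breaths of period 1.5 s at 25 Hz, one sigh-like breath
  dt <- 0.04
  t <- seq(0, 12 - dt, by = dt)
  amp <- rep(1, 8); amp[5] <- 1.7   # sigh-like
  v <- numeric(length(t))
  for (j in 0:7) {
    sel <- t >= j * 1.5 & t < j * 1.5 + 0.75
    v[sel] <- amp[j + 1] * sin(pi * (t[sel] - j * 1.5) / 0.75)
  }
  br <- detect_breaths(v, dt)
  expect_equal(br$period_s, 1.5, tolerance = 0.05)
  expect_equal(length(br$tidal_ml), length(br$onsets) - 1L)
  keep <- respacer:::filter_sigh_like(br$tidal_ml)
  expect_equal(sum(!keep), 1L)      # the sigh-like cycle is excluded
  expect_equal(mean(br$tidal_ml[keep]), 1, tolerance = 0.05)
})
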