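# Closed-loop trial simulation: baseline breathing, desired-pattern
# derivation, and the adaptive pacing loop coupling the PG/PS controller to
# the synthetic plant.

#' Detect breath onsets in a volume trace
#'
#' Hysteresis onset detector: a breath onset is recorded when the volume
#' crosses above `hi_frac` of the trace maximum after having dipped below
#' `lo_frac` of it.  Tidal volume per cycle is the maximum between
#' consecutive onsets.
#'
#' @param v Measured volume trace, ml.
#' @param dt Sample interval, seconds.
#' @param hi_frac,lo_frac Hysteresis thresholds as fractions of the trace
#'   maximum.
#' @return A list with `onsets` (sample indices), `onset_times` (s),
#'   `tidal_ml` (one per complete cycle) and `period_s` (median
#'   onset-to-onset interval).
#' @export
detect_breaths <- function(v, dt, hi_frac = 0.5, lo_frac = 0.2) {
  stopifnot(length(v) > 2, dt > 0)
  amp <- max(v)
  if (amp <= 0) stop("volume trace has no positive excursion")
  hi <- hi_frac * amp
  lo <- lo_frac * amp
  onsets <- integer(0)
  armed <- v[1] <= lo
  for (i in seq_along(v)) {
    if (armed && v[i] >= hi) {
      onsets <- c(onsets, i)
      armed <- FALSE
    } else if (!armed && v[i] <= lo) {
      armed <- TRUE
    }
  }
  if (length(onsets) < 2)
    return(list(onsets = onsets, onset_times = (onsets - 1) * dt,
                tidal_ml = numeric(0), period_s = NA_real_))
  tidal <- vapply(seq_len(length(onsets) - 1L), function(j)
    max(v[onsets[j]:(onsets[j + 1L] - 1L)]), numeric(1))
  list(onsets = onsets, onset_times = (onsets - 1) * dt, tidal_ml = tidal,
       period_s = median(diff(onsets)) * dt)
}

# exclude sigh-like cycles: tidal volume > 1.5x the running median
filter_sigh_like <- function(tidal) {
  keep <- logical(length(tidal))
  for (i in seq_along(tidal)) {
    keep[i] <- tidal[i] <= 1.5 * median(tidal[1:i])
  }
  keep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Desired breath-volume shape over one cycle
#'
#' An asymmetric half-sine of unit peak: rising over the inspiratory fraction
#' of the cycle and falling over the remainder.  The default inspiratory
#' fraction (0.75) mirrors the morphology of an entrained breath in the
#' synthetic plant - inspiration slightly longer than half the cycle,
#' terminated by the inflation reflex just before the peak, with passive
#' expiration after it.
#'
#' @param phase Cycle phase values in `[0, 1)`.
#' @param insp_fraction Fraction of the cycle occupied by the rise
#'   (default 0.75).
#' @return Shape values in `[0, 1]`, peak 1 at `phase = insp_fraction`.
#' @export
desired_shape <- function(phase, insp_fraction = 0.75) {
  stopifnot(insp_fraction > 0, insp_fraction < 1)
  g <- ifelse(phase < insp_fraction,
              phase / (2 * insp_fraction),
              0.5 + (phase - insp_fraction) / (2 * (1 - insp_fraction)))
  sin(pi * g)
}

# wrap a phase difference into (-0.5, 0.5]
wrap_phase <- function(x) {
  y <- (x + 0.5) %% 1 - 0.5
  ifelse(y == -0.5, 0.5, y)
}

build_plant <- function(config) {
  ctl <- config$controller
  pl <- config$plant
  resp_plant(
    lung = lung_model(pl$tau_lung_s, pl$g_dia_ml, pl$g_eic_ml, pl$g_syn_ml),
    dia = muscle_plant(ctl$channels$dia$twitch_mA,
                       pl$sat_factor * ctl$channels$dia$twitch_mA,
                       k_f = pl$dia$k_f_per_mC, rho = pl$dia$rho_per_s),
    eic = muscle_plant(ctl$channels$eic$twitch_mA,
                       pl$sat_factor * ctl$channels$eic$twitch_mA,
                       k_f = pl$eic$k_f_per_mC, rho = pl$eic$rho_per_s),
    cpg = intrinsic_cpg(T0 = pl$T0_s, D0 = 1,
                        V_HB = pl$hb_threshold_factor * pl$baseline_tidal_ml,
                        V_release = (pl$hb_release_factor %||% 0.3) *
                          pl$hb_threshold_factor * pl$baseline_tidal_ml)
  )
}

# Calibrate the oscillator drive amplitude so the free-running (unstimulated,
# reflex-free) tidal volume equals the target.  V is linear in D0, so one
# corrective iteration is exact; a second guards against the transient.
calibrate_cpg_drive <- function(plant, target_tidal, dt = 0.001) {
  plant$cpg$enabled <- FALSE
  for (iter in 1:2) {
    p <- plant
    p$lung$V <- 0
    p$cpg$theta <- 0
    n_cycle <- round(p$cpg$T0 / dt)
    v_max <- 0
    for (cyc in 1:6) {
      out <- plant_advance(p, 0, 0, 0, 0, n_sub = n_cycle, dt = dt)
      p <- out$plant
      if (cyc >= 5) v_max <- max(v_max, out$v_max)
    }
    plant$cpg$D0 <- plant$cpg$D0 * target_tidal / v_max
  }
  plant$cpg$enabled <- TRUE
  plant
}

#' Simulate one closed-loop pacing trial
#'
#' Runs the full trial protocol against the synthetic plant: (1) a baseline
#' phase of spontaneous breathing from which the breath period and tidal
#' volume are derived (cycles with tidal volume above 1.5x the running
#' median, i.e. sigh-like breaths, are excluded from the averages);
#' (2) derivation of the desired pattern - a half-sine at the baseline period
#' with peak equal to 120% of the baseline tidal volume (`target_factor`);
#' (3) the adaptive closed-loop pacing phase, in which the single pattern
#' shaper drives both stimulation channels (the intercostal channel is forced
#' to zero in `dia_only` mode; both are off in `spontaneous` mode) and, when
#' `sigh = TRUE`, every 30th cycle replays the previous cycle's stored
#' outputs at twice the magnitude with learning paused for that cycle and the
#' next.
#'
#' All stochastic draws derive from `seed` in a fixed order, so the returned
#' record is bit-identical across reruns with the same configuration and
#' seed; the caller's random stream is left untouched.
#'
#' @param config Configuration list (see [default_config()]).
#' @param mode `"combined"`, `"dia_only"` or `"spontaneous"`.
#' @param sigh Enable the periodic sigh scheduler.
#' @param pacing_cycles Number of paced cycles; default
#'   `floor(protocol$pacing_s / cycle_period)`.
#' @param seed Integer seed for the trial.
#' @return An object of class `trial_record`: `steps` (per-control-step data
#'   frame), `cycles` (per-cycle summaries), `weights` (pattern-shaper weight
#'   snapshots at each cycle start, one row per cycle plus the final state)
#'   and `meta`.
#' @export
simulate_trial <- function(config = default_config(),
                           mode = c("combined", "dia_only", "spontaneous"),
                           sigh = FALSE, pacing_cycles = NULL, seed = 1L) {
  mode <- match.arg(mode)
  validate_config(config)
  with_local_seed(seed, simulate_trial_impl(config, mode, sigh,
                                            pacing_cycles, seed))
}

simulate_trial_impl <- function(config, mode, sigh, pacing_cycles, seed) {
  ctl <- config$controller
  pl <- config$plant
  control_dt <- ctl$control_dt_ms / 1000
  dt_p <- pl$plant_dt_ms / 1000
  n_sub <- as.integer(round(control_dt / dt_p))
  noise_sd <- config$sensor$noise_sd_ml

  plant <- build_plant(config)
  plant <- calibrate_cpg_drive(plant, pl$baseline_tidal_ml, dt_p)
  pars <- pack_plant_pars(plant)
  st <- pack_plant_state(plant)

  ## ---- baseline phase -----------------------------------------------------
  n_base <- as.integer(round(config$protocol$baseline_s / control_dt))
  base_noise <- rnorm(n_base, 0, noise_sd)
  v_base <- numeric(n_base)
  for (i in seq_len(n_base)) {
    out <- plant_advance_cpp(st, pars, 0, 0, 0, 0, n_sub, dt_p)
    st <- out[1:4]
    v_base[i] <- st[1] + base_noise[i]
  }
  br <- detect_breaths(v_base, control_dt)
  if (length(br$tidal_ml) < 5)
    stop("baseline contains fewer than 5 breath cycles")
  keep <- filter_sigh_like(br$tidal_ml)
  baseline_tidal <- mean(br$tidal_ml[keep])
  baseline_period <- br$period_s

  ## ---- desired pattern ----------------------------------------------------
  n_steps <- quantize_steps(baseline_period, control_dt)
  period_q <- n_steps * control_dt
  desired_tidal <- ctl$target_factor * baseline_tidal
  phase_grid <- (seq_len(n_steps) - 1) / n_steps
  desired <- desired_tidal *
    desired_shape(phase_grid, ctl$insp_fraction %||% 0.75)
  gate <- inspiratory_window(desired)
  max_desired <- max(desired)

  n_cycles <- if (is.null(pacing_cycles))
    as.integer(floor(config$protocol$pacing_s / period_q))
  else as.integer(pacing_cycles)
  stopifnot(n_cycles >= 1L)

  ## ---- align pacing onset to the next intrinsic inspiration ---------------
  max_align <- as.integer(ceiling(2 * pl$T0_s / control_dt))
  n_align <- 0L
  for (i in seq_len(max_align)) {
    out <- plant_advance_cpp(st, pars, 0, 0, 0, 0, n_sub, dt_p)
    st <- out[1:4]
    n_align <- n_align + 1L
    if (out[5] > 0) break
  }

  ## ---- controller setup ---------------------------------------------------
  ps <- ps_state(n_basis = ctl$n_basis, eta = ctl$eta,
                 tau_d = ctl$tau_d_ms / 1000,
                 cycle_period = period_q, control_dt = control_dt)
  w <- ps$weights
  centers <- ps$basis_centers
  width <- ps$basis_width
  Phi <- t(vapply(phase_grid, ps_basis, numeric(ctl$n_basis),
                  centers = centers, width = width))
  Phi_d <- t(vapply((phase_grid - ps$delay_frac) %% 1, ps_basis,
                    numeric(ctl$n_basis), centers = centers, width = width))
  schedule <- sigh_schedule(ctl$sigh_interval)
  ch_dia <- stim_channel("dia", ctl$channels$dia$twitch_mA,
                         ctl$channels$dia$max_mA,
                         ctl$channels$dia$pulse_us, ctl$channels$dia$pulse_hz,
                         u_on = ctl$u_on)
  ch_eic <- stim_channel("eic", ctl$channels$eic$twitch_mA,
                         ctl$channels$eic$max_mA,
                         ctl$channels$eic$pulse_us, ctl$channels$eic$pulse_hz,
                         u_on = ctl$u_on)
  tw_d <- ch_dia$twitch_mA; mx_d <- ch_dia$max_mA
  tw_e <- ch_eic$twitch_mA; mx_e <- ch_eic$max_mA
  qfac_d <- ch_dia$pulse_us * 1e-6 * ch_dia$pulse_hz   # mC/s per mA
  qfac_e <- ch_eic$pulse_us * 1e-6 * ch_eic$pulse_hz
  sat_d <- plant$dia$sat_mA; sat_e <- plant$eic$sat_mA
  u_on <- ctl$u_on
  eta <- ps$eta
  stim_dia <- mode %in% c("combined", "dia_only")
  stim_eic <- mode == "combined"

  ## ---- pacing loop --------------------------------------------------------
  n_total <- n_cycles * n_steps
  noise <- rnorm(n_total, 0, noise_sd)
  t0 <- (n_base + n_align) * control_dt
  col <- function() numeric(n_total)
  S <- list(time_s = col(), cycle = integer(n_total), phase = col(),
            v_desired = col(), v_true = col(), v_meas = col(),
            u_live = col(), u_preclip = col(),
            i_dia_mA = col(), i_eic_mA = col(),
            q_dia_mC = col(), q_eic_mC = col(),
            f_dia = col(), f_eic = col(),
            sigh_flag = logical(n_total), learning_flag = logical(n_total))
  C <- list(cycle = integer(n_cycles), t_start_s = numeric(n_cycles),
            irmse_pct = numeric(n_cycles),
            charge_dia = numeric(n_cycles), charge_eic = numeric(n_cycles),
            tidal_ml = numeric(n_cycles), is_sigh = logical(n_cycles),
            learning_paused = logical(n_cycles),
            onset_phase_error = numeric(n_cycles),
            hb_resets = integer(n_cycles))
  W <- matrix(0, n_cycles + 1L, ctl$n_basis)

  prev_u <- numeric(n_steps)
  cur_u <- numeric(n_steps)
  n_gate <- sum(gate)
  learning <- mode != "spontaneous"
  # sensor baseline: end-expiratory level (minimum true volume) of the
  # previous cycle, captured at each cycle start
  prev_vmin <- st[1]

  for (cyc in seq_len(n_cycles)) {
    c0 <- cyc - 1L                     # 0-based cycle index
    is_sigh_c <- sigh && is_sigh_cycle(schedule, c0)
    paused <- sigh && (is_sigh_c || is_sigh_cycle(schedule, c0 - 1L))
    W[cyc, ] <- w
    base <- prev_vmin
    cycle_t0 <- t0 + (cyc - 1L) * n_steps * control_dt
    err2 <- 0
    qd_sum <- 0; qe_sum <- 0
    vmax <- -Inf
    vmin_true <- st[1]
    onset_err <- NA_real_
    resets <- 0L

    for (k in seq_len(n_steps)) {
      u_live <- sum(w * Phi[k, ])
      u_live <- if (u_live > 1) 1 else if (u_live < 0) 0 else u_live
      cur_u[k] <- u_live
      pre <- if (is_sigh_c) 2 * prev_u[k] else u_live
      ue <- if (gate[k]) pre else 0

      A_d <- if (stim_dia && ue >= u_on)
        tw_d + min(ue, 1) * (mx_d - tw_d) else 0
      A_e <- if (stim_eic && ue >= u_on)
        tw_e + min(ue, 1) * (mx_e - tw_e) else 0
      a_d <- if (A_d > tw_d) min(1, (A_d - tw_d) / (sat_d - tw_d)) else 0
      a_e <- if (A_e > tw_e) min(1, (A_e - tw_e) / (sat_e - tw_e)) else 0
      q_d_rate <- A_d * qfac_d
      q_e_rate <- A_e * qfac_e

      out <- plant_advance_cpp(st, pars, a_d, a_e, q_d_rate, q_e_rate,
                               n_sub, dt_p)
      st <- out[1:4]
      idx <- (cyc - 1L) * n_steps + k
      v_true <- st[1]
      v_meas <- v_true - base + noise[idx]
      if (out[5] > 0) {
        onset_t <- cycle_t0 + (k - 1L) * control_dt + out[5] * dt_p
        onset_err <- wrap_phase((onset_t - cycle_t0) / period_q)
      }
      resets <- resets + as.integer(out[6])

      S$time_s[idx] <- cycle_t0 + (k - 1L) * control_dt
      S$cycle[idx] <- c0
      S$phase[idx] <- phase_grid[k]
      S$v_desired[idx] <- desired[k]
      S$v_true[idx] <- v_true
      S$v_meas[idx] <- v_meas
      S$u_live[idx] <- u_live
      S$u_preclip[idx] <- pre
      S$i_dia_mA[idx] <- A_d
      S$i_eic_mA[idx] <- A_e
      S$q_dia_mC[idx] <- q_d_rate * control_dt
      S$q_eic_mC[idx] <- q_e_rate * control_dt
      S$f_dia[idx] <- st[2]
      S$f_eic[idx] <- st[3]
      S$sigh_flag[idx] <- is_sigh_c
      S$learning_flag[idx] <- learning && !paused

      if (gate[k]) {
        err <- desired[k] - v_meas
        err2 <- err2 + err * err
        if (learning && !paused) {
          w <- w + eta * (err / desired_tidal) * Phi_d[k, ]
          w[w < 0] <- 0
        }
      }
      qd_sum <- qd_sum + q_d_rate * control_dt
      qe_sum <- qe_sum + q_e_rate * control_dt
      if (v_meas > vmax) vmax <- v_meas
      if (v_true < vmin_true) vmin_true <- v_true
    }
    prev_vmin <- vmin_true

    prev_u_tmp <- prev_u
    prev_u <- cur_u
    cur_u <- prev_u_tmp   # reuse buffer

    C$cycle[cyc] <- c0
    C$t_start_s[cyc] <- cycle_t0
    C$irmse_pct[cyc] <- 100 * sqrt(err2 / n_gate) / max_desired
    C$charge_dia[cyc] <- qd_sum
    C$charge_eic[cyc] <- qe_sum
    C$tidal_ml[cyc] <- vmax
    C$is_sigh[cyc] <- is_sigh_c
    C$learning_paused[cyc] <- paused
    C$onset_phase_error[cyc] <- onset_err
    C$hb_resets[cyc] <- resets
  }
  W[n_cycles + 1L, ] <- w

  meta <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("respacer")),
    mode = mode,
    sigh = sigh,
    seed = as.integer(seed),
    control_dt_s = control_dt,
    plant_dt_s = dt_p,
    n_baseline_steps = n_base,
    n_baseline_cycles = length(br$tidal_ml),
    baseline_tidal_ml = baseline_tidal,
    baseline_period_s = baseline_period,
    cycle_period_s = period_q,
    n_steps_per_cycle = n_steps,
    n_cycles = n_cycles,
    desired_tidal_ml = desired_tidal,
    target_factor = ctl$target_factor,
    calibrated_D0 = plant$cpg$D0,
    v_hb_ml = plant$cpg$V_HB,
    desired = desired,
    gate = gate,
    config_fingerprint = config_fingerprint(config),
    config = unclass(config)
  )
  structure(list(steps = as.data.frame(S), cycles = as.data.frame(C),
                 weights = W, meta = meta),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Pacing trial record: mode %s%s, seed %d\n", m$mode,
              if (isTRUE(m$sigh)) " (sighs on)" else "", m$seed))
  cat(sprintf("  baseline: tidal %.3f ml, period %.3f s (%d cycles)\n",
              m$baseline_tidal_ml, m$baseline_period_s, m$n_baseline_cycles))
  cat(sprintf("  pacing: %d cycles x %d steps @ %.0f ms, desired tidal %.3f ml\n",
              m$n_cycles, m$n_steps_per_cycle, 1000 * m$control_dt_s,
              m$desired_tidal_ml))
  cat(sprintf("  final iRMSE %.2f%%, mean dia charge %.4g mC/cycle\n",
              x$cycles$irmse_pct[m$n_cycles], mean(x$cycles$charge_dia)))
  invisible(x)
}
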