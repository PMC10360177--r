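# Synthetic respiratory plant: recruitment curves, charge-driven fatigue,
# first-order lung mechanics with diaphragm-intercostal synergy, an intrinsic
# breathing oscillator with Hering-Breuer volume-triggered phase reset, and
# noisy breath-volume sensing.

#' Muscle plant
#'
#' One stimulated muscle: piecewise-linear amplitude recruitment between the
#' twitch threshold and a saturation current, a volume-equivalent drive gain,
#' and a charge-driven fatigue state `F` in `[0, 1]` with first-order
#' recovery.  Effective activation is the commanded recruitment scaled by
#' `(1 - F)`.
#'
#' @param twitch_mA Twitch threshold current, mA (> 0).
#' @param sat_mA Saturation current, mA (default twice the threshold).
#' @param k_f Fatigue gain, 1/mC.
#' @param rho Recovery rate, 1/s.
#' @param F Initial fatigue state in `[0, 1]`.
#' @return An object of class `muscle_plant`.  The muscle's volume-equivalent
#'   drive gain lives in the [lung_model()] (`g_dia`, `g_eic`).
#' @export
muscle_plant <- function(twitch_mA, sat_mA = 2 * twitch_mA,
                         k_f = 0.07, rho = 0.0017, F = 0) {
  stopifnot(twitch_mA > 0, k_f >= 0, rho >= 0, F >= 0, F <= 1)
  if (sat_mA <= twitch_mA)
    stop("saturation current must exceed the twitch threshold")
  structure(list(twitch_mA = twitch_mA, sat_mA = sat_mA,
                 k_f = k_f, rho = rho, F = F),
            class = "muscle_plant")
}

#' Amplitude recruitment curve
#'
#' Zero below the twitch threshold, then linear up to full recruitment at the
#' saturation current.
#'
#' @param amplitude_mA Stimulation amplitude(s), mA (>= 0).
#' @param muscle A [muscle_plant()].
#' @return Activation(s) in `[0, 1]` (not yet scaled by fatigue).
#' @export
recruit <- function(amplitude_mA, muscle) {
  stopifnot(all(amplitude_mA >= 0))
  a <- (amplitude_mA - muscle$twitch_mA) / (muscle$sat_mA - muscle$twitch_mA)
  pmin(pmax(a, 0), 1)
}

#' One Euler step of the charge-driven fatigue state
#'
#' `F <- F + dt * (k_f * charge_rate * (1 - F) - rho * F)`, clipped to
#' `[0, 1]`.  Under a constant charge rate `q` the state approaches the
#' equilibrium `k_f q / (k_f q + rho)` with time constant `1/(k_f q + rho)`.
#'
#' @param muscle A [muscle_plant()].
#' @param charge_rate Delivered charge rate, mC/s (>= 0).
#' @param dt Step size, seconds (> 0).
#' @return The `muscle_plant` with updated `F`.
#' @export
fatigue_step <- function(muscle, charge_rate, dt) {
  stopifnot(charge_rate >= 0, dt > 0)
  F <- muscle$F + dt * (muscle$k_f * charge_rate * (1 - muscle$F) -
                          muscle$rho * muscle$F)
  muscle$F <- min(max(F, 0), 1)
  muscle
}

#' Lung model
#'
#' First-order lung volume dynamics above the end-expiratory level with a
#' synergy term: the combined drive of diaphragm plus external intercostal
#' activation exceeds the sum of the individual drives by
#' `g_syn * a_dia * a_eic` (rib-cage stabilization by the intercostals).
#'
#' @param tau_lung Volume time constant, seconds (default 0.15).
#' @param g_dia Diaphragm drive gain, ml (default 2.0).
#' @param g_eic External intercostal drive gain, ml (default 0.55).
#' @param g_syn Synergy gain, ml (default 0.75).
#' @param V Initial volume above end-expiratory level, ml.
#' @return An object of class `lung_model`.
#' @export
lung_model <- function(tau_lung = 0.15, g_dia = 2.0, g_eic = 0.55,
                       g_syn = 0.75, V = 0) {
  stopifnot(tau_lung > 0, g_dia >= 0, g_eic >= 0, g_syn >= 0, V >= 0)
  structure(list(tau_lung = tau_lung, g_dia = g_dia, g_eic = g_eic,
                 g_syn = g_syn, V = V),
            class = "lung_model")
}

#' One Euler step of the lung volume
#'
#' Total drive `P = intrinsic_drive + g_dia a_dia + g_eic a_eic +
#' g_syn a_dia a_eic` (the intrinsic drive arrives already scaled by the
#' oscillator's drive amplitude); then `V <- V + dt (P - V)/tau_lung`.  With
#' zero drive the volume decays passively to 0.
#'
#' @param lung A [lung_model()].
#' @param a_dia_eff,a_eic_eff Effective (fatigue-scaled) activations in
#'   `[0, 1]`.
#' @param intrinsic_drive Intrinsic oscillator drive, ml (already `D0`-scaled;
#'   see [cpg_step()]).
#' @param dt Step size, seconds.
#' @return The `lung_model` with updated `V`.
#' @export
lung_step <- function(lung, a_dia_eff, a_eic_eff, intrinsic_drive, dt) {
  stopifnot(a_dia_eff >= 0, a_dia_eff <= 1, a_eic_eff >= 0, a_eic_eff <= 1,
            dt > 0)
  P <- intrinsic_drive + lung$g_dia * a_dia_eff + lung$g_eic * a_eic_eff +
    lung$g_syn * a_dia_eff * a_eic_eff
  V <- lung$V + dt * (P - lung$V) / lung$tau_lung
  lung$V <- max(V, 0)
  lung
}

#' Intrinsic breathing oscillator
#'
#' A phase oscillator at the intrinsic period `T0` producing a half-sine
#' inspiratory drive over the first half of its phase and zero during the
#' expiratory half.  The Hering-Breuer inflation reflex acts on it in both
#' directions: when the lung volume reaches `V_HB` during intrinsic
#' inspiration the phase jumps to the start of the expiratory half
#' (inspiratory termination by pulmonary stretch receptors), and a new
#' inspiration cannot start until the lung has deflated below `V_release`
#' (expiratory prolongation, with hysteresis).  This is the mechanism through
#' which paced large breaths entrain, and sighs reset, the intrinsic rhythm.
#'
#' @param T0 Intrinsic period, seconds (default 1.5).
#' @param D0 Drive amplitude, ml (calibrated in [simulate_trial()] so the
#'   free-running tidal volume matches the configured baseline).
#' @param theta Initial phase in `[0, 1)`.
#' @param V_HB Hering-Breuer volume threshold, ml; `Inf` disables the reflex.
#' @param V_release Deflation level below which a pending inspiratory onset
#'   is released, ml (default 0.3 of `V_HB`).
#' @param enabled Logical; `FALSE` also disables the reflex.
#' @return An object of class `intrinsic_cpg`.
#' @export
intrinsic_cpg <- function(T0 = 1.5, D0 = 1, theta = 0, V_HB = 1.1,
                          V_release = 0.3 * V_HB, enabled = TRUE) {
  stopifnot(T0 > 0, D0 >= 0, theta >= 0, theta < 1, V_HB > 0,
            V_release > 0, V_release <= V_HB)
  structure(list(T0 = T0, D0 = D0, theta = theta, V_HB = V_HB,
                 V_release = V_release, enabled = isTRUE(enabled)),
            class = "intrinsic_cpg")
}

#' One Euler step of the intrinsic oscillator
#'
#' Returns the intrinsic drive at the current phase (`D0 sin(2 pi theta)` for
#' `theta < 0.5`, else 0), then advances the phase by `dt/T0`, wraps it at 1
#' (a new intrinsic inspiration), and applies the Hering-Breuer reset against
#' the supplied volume.
#'
#' @param cpg An [intrinsic_cpg()].
#' @param V Current lung volume, ml.
#' @param dt Step size, seconds.
#' @return A list with `cpg` (advanced), `drive` (drive at the pre-advance
#'   phase, ml), `onset` (logical: the phase wrapped into a new inspiration)
#'   and `reset` (logical: a Hering-Breuer reset fired).
#' @export
cpg_step <- function(cpg, V, dt) {
  stopifnot(dt > 0)
  hb <- cpg$enabled && is.finite(cpg$V_HB)
  drive <- if (cpg$theta < 0.5) cpg$D0 * sin(2 * pi * cpg$theta) else 0
  theta <- cpg$theta + dt / cpg$T0
  onset <- FALSE
  if (theta >= 1) {
    if (hb && V >= cpg$V_release) {
      theta <- 1 - 1e-9              # onset inhibited until the lung deflates
    } else {
      theta <- theta - 1
      onset <- TRUE
    }
  }
  reset <- FALSE
  if (hb && V >= cpg$V_HB && theta < 0.5) {
    theta <- 0.5
    reset <- TRUE
  }
  cpg$theta <- theta
  list(cpg = cpg, drive = drive, onset = onset, reset = reset)
}

#' Breath-volume sensor
#'
#' Integrated-pneumotachometer volume sensing: the measured volume is the true
#' volume minus a baseline re-zeroed at each breath-cycle start, plus Gaussian
#' noise.  The hardware integrator's time constant is carried as metadata (the
#' plant's volume state is taken as the already-integrated flow signal).
#'
#' @param noise_sd Noise standard deviation, ml (default 0.02).
#' @param integrator_tau Integrator time constant, seconds (default 0.2;
#'   metadata).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(noise_sd = 0.02, integrator_tau = 0.2) {
  stopifnot(noise_sd >= 0, integrator_tau > 0)
  structure(list(noise_sd = noise_sd, integrator_tau = integrator_tau),
            class = "sensor_model")
}

#' Measure the breath volume
#'
#' `V_measured = (V_true - baseline) + N(0, noise_sd)`.  Draws from the
#' current R random stream; seed it (or the trial seed) for reproducibility.
#'
#' @param sensor A [sensor_model()].
#' @param V_true True lung volume, ml.
#' @param baseline Baseline captured at the current cycle start, ml.
#' @return Measured volume, ml.
#' @export
measure <- function(sensor, V_true, baseline = 0) {
  (V_true - baseline) + rnorm(length(V_true), 0, sensor$noise_sd)
}

#' Assemble a full respiratory plant
#'
#' @param lung A [lung_model()].
#' @param dia,eic [muscle_plant()] objects for the diaphragm and external
#'   intercostal channels.
#' @param cpg An [intrinsic_cpg()].
#' @return An object of class `resp_plant`.
#' @export
resp_plant <- function(lung = lung_model(),
                       dia = muscle_plant(1.5),
                       eic = muscle_plant(1.0),
                       cpg = intrinsic_cpg()) {
  structure(list(lung = lung, dia = dia, eic = eic, cpg = cpg),
            class = "resp_plant")
}

pack_plant_state <- function(plant) {
  c(plant$lung$V, plant$dia$F, plant$eic$F, plant$cpg$theta)
}

pack_plant_pars <- function(plant) {
  c(plant$lung$tau_lung, plant$lung$g_dia, plant$lung$g_eic, plant$lung$g_syn,
    plant$cpg$D0, plant$cpg$T0,
    if (is.finite(plant$cpg$V_HB)) plant$cpg$V_HB else .Machine$double.xmax,
    plant$cpg$V_release,
    plant$dia$k_f, plant$dia$rho, plant$eic$k_f, plant$eic$rho,
    as.numeric(plant$cpg$enabled && is.finite(plant$cpg$V_HB)))
}

#' Advance the plant over one control interval
#'
#' Integrates the plant by `n_sub` explicit-Euler substeps of `dt` seconds
#' (default: 40 x 1 ms per 40 ms control step) with the stimulation command
#' held constant.  The compiled path and the pure-R composition of
#' [cpg_step()], [lung_step()] and [fatigue_step()] are interchangeable; the
#' R path exists as the reference the compiled code is tested against.
#'
#' @param plant A [resp_plant()].
#' @param a_dia,a_eic Commanded recruitment activations in `[0, 1]` (from
#'   [recruit()]; fatigue scaling is applied inside).
#' @param q_dia_rate,q_eic_rate Charge rates, mC/s.
#' @param n_sub Number of substeps.
#' @param dt Substep size, seconds.
#' @param use_compiled Use the compiled integrator (default) or the R
#'   reference composition.
#' @return A list with the advanced `plant`, `onset_sub` (1-based substep of
#'   an intrinsic inspiratory onset, 0 if none), `n_resets` (Hering-Breuer
#'   resets during the interval) and `v_max` (maximum volume reached).
#' @export
plant_advance <- function(plant, a_dia, a_eic, q_dia_rate, q_eic_rate,
                          n_sub = 40L, dt = 0.001, use_compiled = TRUE) {
  stopifnot(inherits(plant, "resp_plant"), n_sub >= 1L, dt > 0,
            a_dia >= 0, a_dia <= 1, a_eic >= 0, a_eic <= 1)
  if (use_compiled) {
    out <- plant_advance_cpp(pack_plant_state(plant), pack_plant_pars(plant),
                             a_dia, a_eic, q_dia_rate, q_eic_rate,
                             as.integer(n_sub), dt)
    plant$lung$V <- out[1]
    plant$dia$F <- out[2]
    plant$eic$F <- out[3]
    plant$cpg$theta <- out[4]
    return(list(plant = plant, onset_sub = as.integer(out[5]),
                n_resets = as.integer(out[6]), v_max = out[7]))
  }
  onset_sub <- 0L
  n_resets <- 0L
  v_max <- plant$lung$V
  for (i in seq_len(n_sub)) {
    ad <- a_dia * (1 - plant$dia$F)
    ae <- a_eic * (1 - plant$eic$F)
    st <- cpg_step(plant$cpg, plant$lung$V, dt)
    plant$cpg <- st$cpg
    if (st$onset) onset_sub <- i
    if (st$reset) n_resets <- n_resets + 1L
    plant$lung <- lung_step(plant$lung, ad, ae, st$drive, dt)
    v_max <- max(v_max, plant$lung$V)
    plant$dia <- fatigue_step(plant$dia, q_dia_rate, dt)
    plant$eic <- fatigue_step(plant$eic, q_eic_rate, dt)
  }
  list(plant = plant, onset_sub = onset_sub, n_resets = n_resets,
       v_max = v_max)
}
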