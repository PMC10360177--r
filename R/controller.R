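# PG/PS controller: fixed-period cycle clock, adaptive pattern shaper,
# per-channel amplitude mapping, biphasic pulse-train charge accounting and
# the periodic sigh scheduler.

#' Pattern-generator cycle clock
#'
#' The pattern generator (PG) is a fixed-frequency oscillator that sets breath
#' timing: it divides a fixed cycle period into control steps of `control_dt`
#' seconds (25 Hz by default) and exposes the within-cycle phase.  The period
#' is quantized to an integer number of control steps (ties round down), so a
#' nominal 1.5 s period at 40 ms steps runs as 37 steps = 1.48 s.
#'
#' @param cycle_period Nominal breath period, seconds.
#' @param control_dt Control interval, seconds (default 0.040, i.e. 25 Hz).
#' @return An object of class `pg_clock` with fields `cycle_period` (the
#'   quantized period), `nominal_period`, `control_dt`, `n_steps`,
#'   `step_index`, `cycle_index` and `step_in_cycle`.
#' @seealso [pg_step()], [pg_phase()]
#' @export
#' @examples
#' ck <- pg_clock(1.5)
#' ck$n_steps        # 37
#' ck$cycle_period   # 1.48
pg_clock <- function(cycle_period, control_dt = 0.040) {
  stopifnot(is.numeric(cycle_period), length(cycle_period) == 1L,
            cycle_period > 0, is.numeric(control_dt), control_dt > 0)
  n_steps <- quantize_steps(cycle_period, control_dt)
  if (n_steps < 2L)
    stop("cycle_period must span at least 2 control steps")
  structure(list(
    cycle_period = n_steps * control_dt,
    nominal_period = cycle_period,
    control_dt = control_dt,
    n_steps = n_steps,
    step_index = 0L,
    cycle_index = 0L,
    step_in_cycle = 0L
  ), class = "pg_clock")
}

# round period/dt to the nearest integer, ties toward zero (half-down)
quantize_steps <- function(period, dt) {
  as.integer(ceiling(period / dt - 0.5))
}

#' Advance the pattern-generator clock by one control step
#'
#' Increments the global step index and the step-within-cycle; at a cycle
#' boundary the cycle index increments and the phase wraps to 0.
#'
#' @param clock A [pg_clock()] object.
#' @return The advanced `pg_clock`.
#' @export
pg_step <- function(clock) {
  stopifnot(inherits(clock, "pg_clock"))
  clock$step_index <- clock$step_index + 1L
  clock$step_in_cycle <- clock$step_in_cycle + 1L
  if (clock$step_in_cycle >= clock$n_steps) {
    clock$step_in_cycle <- 0L
    clock$cycle_index <- clock$cycle_index + 1L
  }
  clock
}

#' Within-cycle phase of the pattern-generator clock
#'
#' @param clock A [pg_clock()] object.
#' @return Phase as a fraction of the cycle in `[0, 1)`.
#' @export
pg_phase <- function(clock) {
  clock$step_in_cycle / clock$n_steps
}

#' Pattern-shaper state
#'
#' The pattern shaper (PS) is a single-layer adaptive network mapping cycle
#' phase to a normalized stimulation amplitude `u` in `[0, 1]`.  It uses
#' `n_basis` Gaussian basis neurons uniformly tiling cycle phase (circular
#' distance), nonnegative weights, and a delta-rule update driven by the
#' instantaneous normalized volume error, applied at a phase shifted back by
#' `tau_d` seconds to compensate actuation plus sensing lag.
#'
#' @param n_basis Number of Gaussian basis neurons (default 25).
#' @param eta Learning rate per control step (default 0.02, dimensionless).
#' @param basis_width Gaussian width in phase units (default `1/n_basis`).
#' @param tau_d Delay compensation, seconds (default 0.080 = 2 control steps).
#' @param cycle_period Breath period, seconds (quantized as in [pg_clock()]).
#' @param control_dt Control interval, seconds.
#' @param weights Optional initial nonnegative weight vector.
#' @return An object of class `ps_state`.
#' @seealso [ps_basis()], [ps_output()], [ps_update()], [ps_cycle_commit()]
#' @export
ps_state <- function(n_basis = 25L, eta = 0.02, basis_width = 1 / n_basis,
                     tau_d = 0.080, cycle_period = 1.5, control_dt = 0.040,
                     weights = rep(0, n_basis)) {
  stopifnot(n_basis >= 2L, eta > 0, basis_width > 0, tau_d >= 0,
            length(weights) == n_basis, all(weights >= 0))
  n_steps <- quantize_steps(cycle_period, control_dt)
  structure(list(
    weights = as.numeric(weights),
    basis_centers = (seq_len(n_basis) - 1) / n_basis,
    basis_width = basis_width,
    eta = eta,
    tau_d = tau_d,
    delay_frac = tau_d / (n_steps * control_dt),
    n_steps = n_steps,
    current_outputs = numeric(0),
    stored_outputs = numeric(0),
    learning_enabled = TRUE
  ), class = "ps_state")
}

#' Gaussian basis activations on circular phase distance
#'
#' Each basis neuron peaks at 1 at its center; activation decays with the
#' circular (wrap-around) phase distance.  With centers uniformly spaced and
#' width equal to the spacing, the basis tiles the cycle: a uniform weight
#' vector yields an output constant in phase to well within 1%.
#'
#' @param phase Cycle phase; wrapped into `[0, 1)`.
#' @param centers Basis center phases in `[0, 1)`.
#' @param width Gaussian width in phase units.
#' @return Numeric vector of activations in `(0, 1]`, one per center.
#' @export
ps_basis <- function(phase, centers, width) {
  stopifnot(length(phase) == 1L, is.finite(phase), width > 0)
  phase <- phase %% 1
  d <- abs(phase - centers)
  d <- pmin(d, 1 - d)
  exp(-(d * d) / (2 * width * width))
}

#' Pattern-shaper output at a given phase
#'
#' Computes the normalized output `u = clip(sum_i w_i phi_i(phase), 0, 1)` and
#' appends it to the buffer of outputs for the current cycle (used by the sigh
#' scheduler, which replays the previous cycle at twice the magnitude).
#'
#' @param state A [ps_state()] object.
#' @param phase Cycle phase in `[0, 1)`.
#' @return A list with elements `u` (the clipped output) and `state` (with
#'   `current_outputs` extended).
#' @export
ps_output <- function(state, phase) {
  stopifnot(inherits(state, "ps_state"))
  u <- sum(state$weights * ps_basis(phase, state$basis_centers, state$basis_width))
  u <- min(max(u, 0), 1)
  state$current_outputs <- c(state$current_outputs, u)
  list(u = u, state = state)
}

#' Commit the current cycle's outputs to the stored buffer
#'
#' At each cycle boundary the outputs of the just-completed cycle become the
#' `stored_outputs` replayed (doubled) on a sigh cycle.
#'
#' @param state A [ps_state()] object.
#' @return The updated `ps_state` with `stored_outputs` set and
#'   `current_outputs` cleared.
#' @export
ps_cycle_commit <- function(state) {
  stopifnot(inherits(state, "ps_state"))
  state$stored_outputs <- state$current_outputs
  state$current_outputs <- numeric(0)
  state
}

#' Delta-rule weight update of the pattern shaper
#'
#' Applies `w_i <- max(0, w_i + eta * error * phi_i(phase - tau_d/T))`, i.e.
#' the instantaneous normalized volume error credited to the basis neurons
#' active `tau_d` seconds earlier.  A no-op while learning is disabled
#' (e.g. around a sigh).
#'
#' @param state A [ps_state()] object.
#' @param error Normalized instantaneous volume error,
#'   `(V_desired - V_measured) / V_desired_peak`.
#' @param phase Cycle phase in `[0, 1)` at which the error was observed.
#' @return The updated `ps_state`.
#' @export
ps_update <- function(state, error, phase) {
  stopifnot(inherits(state, "ps_state"), is.finite(error))
  if (!state$learning_enabled) return(state)
  phi <- ps_basis((phase - state$delay_frac) %% 1,
                  state$basis_centers, state$basis_width)
  state$weights <- pmax(0, state$weights + state$eta * error * phi)
  state
}

#' Stimulation channel description
#'
#' One muscle's stimulation properties: twitch threshold, maximum amplitude
#' (1.5-2x the twitch threshold unless explicitly overridden), and the
#' biphasic pulse-train parameters (cathodic-first, per-phase width 80 us at
#' 75 Hz by default).  Outputs below the activation floor `u_on` are
#' suppressed entirely.
#'
#' @param name Channel name, `"dia"` or `"eic"`.
#' @param twitch_mA Twitch threshold current, mA (> 0).
#' @param max_mA Maximum amplitude, mA; default twice the twitch threshold.
#' @param pulse_us Pulse width per phase, microseconds (default 80).
#' @param pulse_hz Pulse frequency, Hz (default 75).
#' @param u_on Normalized activation floor below which no pulses are sent
#'   (default 0.05).
#' @param allow_override Allow `max_mA` outside `[1.5, 2] * twitch_mA`.
#' @return An object of class `stim_channel`.
#' @export
stim_channel <- function(name = c("dia", "eic"), twitch_mA,
                         max_mA = 2 * twitch_mA, pulse_us = 80,
                         pulse_hz = 75, u_on = 0.05,
                         allow_override = FALSE) {
  name <- match.arg(name)
  stopifnot(twitch_mA > 0, pulse_us > 0, pulse_hz > 0, u_on >= 0)
  if (!allow_override &&
      (max_mA < 1.5 * twitch_mA - 1e-12 || max_mA > 2 * twitch_mA + 1e-12))
    stop("max_mA must lie within [1.5, 2] x twitch_mA (use allow_override)")
  structure(list(name = name, twitch_mA = twitch_mA, max_mA = max_mA,
                 pulse_us = pulse_us, pulse_hz = pulse_hz, u_on = u_on),
            class = "stim_channel")
}

#' Sigh schedule
#'
#' Periodic augmented breaths: every `sigh_interval` cycles the previous
#' cycle's stored PS outputs are replayed at twice their magnitude, and
#' adaptive learning is paused for the sigh cycle and the following cycle.
#'
#' @param sigh_interval Cycles between sighs (default 30, must be >= 2).
#' @param amplification Replay gain on sigh cycles (fixed at 2).
#' @param pause_span Cycles over which learning is paused starting at the sigh
#'   cycle (fixed at 2: the sigh cycle and the one after).
#' @return An object of class `sigh_schedule`.
#' @export
sigh_schedule <- function(sigh_interval = 30L, amplification = 2,
                          pause_span = 2L) {
  stopifnot(sigh_interval >= 2, amplification == 2, pause_span == 2L)
  structure(list(sigh_interval = as.integer(sigh_interval),
                 amplification = amplification,
                 pause_span = as.integer(pause_span)),
            class = "sigh_schedule")
}

#' Is a given cycle a sigh cycle?
#'
#' Sigh cycles are the positive multiples of the sigh interval (0-based cycle
#' indexing: cycles 30, 60, ... for the default interval).
#'
#' @param schedule A [sigh_schedule()].
#' @param cycle_index 0-based cycle index.
#' @return Logical.
#' @export
is_sigh_cycle <- function(schedule, cycle_index) {
  cycle_index > 0L & cycle_index %% schedule$sigh_interval == 0L
}

#' Sigh insertion for one cycle
#'
#' On a sigh cycle, returns the pre-clip output trajectory for the whole
#' cycle: exactly twice the stored PS outputs of the previous cycle, with
#' learning paused; learning also stays paused on the cycle following a sigh.
#'
#' @param schedule A [sigh_schedule()].
#' @param state A [ps_state()] whose `stored_outputs` hold the previous
#'   completed cycle.
#' @param cycle_index 0-based cycle index (>= 1).
#' @return A list with `is_sigh`, `learning_pause` and `pre_clip` (the doubled
#'   stored outputs on a sigh cycle, otherwise `NULL`, meaning "use the live
#'   PS output").
#' @export
apply_sigh <- function(schedule, state, cycle_index) {
  stopifnot(inherits(schedule, "sigh_schedule"), inherits(state, "ps_state"))
  if (cycle_index < 1L)
    stop("cycle_index must be >= 1 (the first cycle has no stored outputs)")
  sigh <- is_sigh_cycle(schedule, cycle_index)
  pause <- sigh || is_sigh_cycle(schedule, cycle_index - 1L)
  pre_clip <- NULL
  if (sigh) {
    if (length(state$stored_outputs) == 0L)
      stop("stored_outputs is empty: cannot insert a sigh")
    pre_clip <- schedule$amplification * state$stored_outputs
  }
  list(is_sigh = sigh, learning_pause = pause, pre_clip = pre_clip)
}

#' Map the normalized controller output to per-channel current amplitudes
#'
#' Per channel, the affine map from the activation floor to the channel's
#' limits: amplitude 0 below `u_on`, otherwise
#' `twitch_mA + min(u, 1) * (max_mA - twitch_mA)`.  Amplitudes therefore never
#' exceed `max_mA`, even for the doubled pre-clip output of a sigh cycle.
#'
#' @param u Normalized (pre-clip) controller output, >= 0.
#' @param channels A list of [stim_channel()] objects.
#' @return Named numeric vector of amplitudes in mA, one per channel.
#' @export
channel_map <- function(u, channels) {
  stopifnot(is.numeric(u), length(u) == 1L, u >= 0)
  amps <- vapply(channels, function(ch) {
    if (u < ch$u_on) 0
    else ch$twitch_mA + min(u, 1) * (ch$max_mA - ch$twitch_mA)
  }, numeric(1))
  names(amps) <- vapply(channels, `[[`, character(1), "name")
  amps
}

#' Charge delivered by a biphasic pulse train over an interval
#'
#' Leading (cathodic) phase charge of the train: amplitude x per-phase pulse
#' width x pulse frequency x interval.  Biphasic pulses are charge-balanced,
#' so only the leading phase is counted; summed over a cycle this is the
#' "charge per cycle" performance measure.
#'
#' @param amplitude_mA Current amplitude, mA (>= 0).
#' @param channel A [stim_channel()] (supplies pulse width and frequency).
#' @param dt Interval over which pulses are delivered, seconds (> 0).
#' @return Charge in mC (mA x s).
#' @export
#' @examples
#' ch <- stim_channel("dia", twitch_mA = 1.5)
#' encode_charge(2, ch, 1)   # 2 mA * 80e-6 s * 75 Hz * 1 s = 0.012 mC
encode_charge <- function(amplitude_mA, channel, dt) {
  stopifnot(all(amplitude_mA >= 0), dt > 0)
  amplitude_mA * channel$pulse_us * 1e-6 * channel$pulse_hz * dt
}
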