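# Run configuration: defaults, validation, YAML round-trip.

#' Default run configuration
#'
#' Nested list describing plant, controller, sensor and protocol parameters.
#' All values are plain numbers/strings so the configuration round-trips
#' through YAML unchanged.  See the `adaptive-pacing` vignette for the
#' rationale behind each default.
#'
#' @return A list of class `respacer_config` with blocks `plant`,
#'   `controller`, `sensor`, `protocol`, plus `seed` and `format_version`.
#' @export
default_config <- function() {
  structure(list(
    format_version = 1L,
    seed = 1L,
    protocol = list(
      baseline_s = 60,
      pacing_s = 600,
      modes = c("dia_only", "combined"),
      sigh = c(FALSE, TRUE)
    ),
    controller = list(
      n_basis = 25L,
      eta = 0.02,
      tau_d_ms = 80,
      control_dt_ms = 40,
      u_on = 0.05,
      sigh_interval = 30L,
      target_factor = 1.2,
      insp_fraction = 0.75,
      channels = list(
        dia = list(twitch_mA = 1.5, max_mA = 3.0, pulse_us = 80, pulse_hz = 75),
        eic = list(twitch_mA = 1.0, max_mA = 2.0, pulse_us = 80, pulse_hz = 75)
      )
    ),
    plant = list(
      tau_lung_s = 0.15,
      g_dia_ml = 2.0,
      g_eic_ml = 0.55,
      g_syn_ml = 0.75,
      T0_s = 1.5,
      baseline_tidal_ml = 1.0,
      hb_threshold_factor = 1.1,
      hb_release_factor = 0.3,
      plant_dt_ms = 1,
      sat_factor = 2.0,
      dia = list(k_f_per_mC = 0.07, rho_per_s = 0.0017),
      eic = list(k_f_per_mC = 0.07, rho_per_s = 0.0017)
    ),
    sensor = list(
      noise_sd_ml = 0.02,
      integrator_tau_s = 0.2
    )
  ), class = "respacer_config")
}

config_error <- function(msg) {
  stop(structure(class = c("respacer_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Validate a run configuration
#'
#' Checks the presence of every block and the protocol/channel invariants
#' (positive durations, baseline of at least 60 s, pacing duration within
#' 5-15 min, per-channel amplitude limits within 1.5-2x the twitch
#' threshold, plant step dividing the control step).  Signals a condition of
#' class `respacer_config_error` on failure.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  need <- c("protocol", "controller", "plant", "sensor", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    config_error(paste0("missing config block(s): ", paste(miss, collapse = ", ")))
  p <- config$protocol
  if (!is.numeric(p$baseline_s) || p$baseline_s < 60)
    config_error("protocol$baseline_s must be >= 60 seconds")
  if (!is.numeric(p$pacing_s) || p$pacing_s < 300 || p$pacing_s > 900)
    config_error("protocol$pacing_s must lie in [300, 900] seconds")
  if (!all(p$modes %in% c("dia_only", "combined", "spontaneous")))
    config_error("protocol$modes must be dia_only/combined/spontaneous")
  ctl <- config$controller
  if (ctl$control_dt_ms <= 0 || ctl$eta <= 0 || ctl$n_basis < 2)
    config_error("controller block: control_dt_ms, eta must be positive; n_basis >= 2")
  if (ctl$sigh_interval < 2)
    config_error("controller$sigh_interval must be >= 2")
  for (chn in c("dia", "eic")) {
    ch <- ctl$channels[[chn]]
    if (is.null(ch))
      config_error(paste0("missing controller channel block: ", chn))
    if (ch$twitch_mA <= 0 || ch$pulse_us <= 0 || ch$pulse_hz <= 0)
      config_error(paste0(chn, ": twitch_mA, pulse_us, pulse_hz must be positive"))
    if (ch$max_mA < 1.5 * ch$twitch_mA - 1e-9 ||
        ch$max_mA > 2 * ch$twitch_mA + 1e-9)
      config_error(paste0(chn, ": max_mA must be within [1.5, 2] x twitch_mA"))
  }
  pl <- config$plant
  if (pl$tau_lung_s <= 0 || pl$T0_s <= 0 || pl$baseline_tidal_ml <= 0)
    config_error("plant block: tau_lung_s, T0_s, baseline_tidal_ml must be positive")
  if (pl$plant_dt_ms <= 0 ||
      abs(ctl$control_dt_ms / pl$plant_dt_ms -
            round(ctl$control_dt_ms / pl$plant_dt_ms)) > 1e-9)
    config_error("plant_dt_ms must divide control_dt_ms")
  if (config$sensor$noise_sd_ml < 0)
    config_error("sensor$noise_sd_ml must be >= 0")
  invisible(config)
}

#' Read / write a run configuration (YAML)
#'
#' @param path File path.
#' @return `read_config` returns the validated config; `write_config` returns
#'   the path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "respacer_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# cheap text fingerprint of a config (no cryptographic hash dependency)
config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967291)
}

#' Apply inter-subject parameter jitter to a configuration
#'
#' Simulated "animals": plant drive gains, baseline tidal volume and the
#' per-channel twitch thresholds are scaled by independent uniform factors in
#' `1 +/- jitter`; channel amplitude limits follow the thresholds so the
#' 1.5-2x invariant is preserved.  Draws are taken from the supplied seed
#' without disturbing the caller's random stream.
#'
#' @param config A configuration list.
#' @param seed Integer seed for the jitter draws.
#' @param jitter Relative half-width (default 0.10).
#' @return The jittered config.
#' @export
jitter_config <- function(config, seed, jitter = 0.10) {
  validate_config(config)
  f <- with_local_seed(seed, runif(6, 1 - jitter, 1 + jitter))
  pl <- config$plant
  pl$g_dia_ml <- pl$g_dia_ml * f[1]
  pl$g_eic_ml <- pl$g_eic_ml * f[2]
  pl$g_syn_ml <- pl$g_syn_ml * f[3]
  pl$baseline_tidal_ml <- pl$baseline_tidal_ml * f[4]
  config$plant <- pl
  for (i in seq_along(c("dia", "eic"))) {
    chn <- c("dia", "eic")[i]
    ch <- config$controller$channels[[chn]]
    ratio <- ch$max_mA / ch$twitch_mA
    ch$twitch_mA <- ch$twitch_mA * f[4 + i]
    ch$max_mA <- ch$twitch_mA * ratio
    config$controller$channels[[chn]] <- ch
  }
  config
}

# run expr with a temporary RNG seed, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a bounded child seed from a base seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 104729) %% 2147483587)
}
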