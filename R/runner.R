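# Trial orchestration and file I/O: the in-silico experimental sequence
# (baseline -> desired pattern -> one trial per stimulation mode), simulated
# cohorts with inter-subject jitter, and CSV/JSON trial records.

STEP_COLUMNS <- c("time_s", "cycle", "phase", "v_desired", "v_true", "v_meas",
                  "u_live", "u_preclip", "i_dia_mA", "i_eic_mA",
                  "q_dia_mC", "q_eic_mC", "f_dia", "f_eic",
                  "sigh_flag", "learning_flag")
CYCLE_COLUMNS <- c("cycle", "t_start_s", "irmse_pct", "charge_dia",
                   "charge_eic", "tidal_ml", "is_sigh", "learning_paused",
                   "onset_phase_error", "hb_resets")

#' Run the full in-silico experimental sequence
#'
#' One simulated subject: for every requested stimulation mode and sigh
#' setting, runs a complete [simulate_trial()] (each trial re-runs its own
#' baseline; fatigue resets between trials, standing in for the rest period
#' between recordings) in an order shuffled by the seed, then computes the
#' metrics report for each trial.  Aborts if no trial achieves entrainment.
#'
#' @param config Configuration list; `protocol$modes` and `protocol$sigh`
#'   define the trial grid.
#' @param outdir Optional output directory; when given, per-trial CSV/JSON
#'   records, metric reports and the effective configuration are written.
#' @param seed Base seed (default `config$seed`); per-trial seeds derive
#'   from it.
#' @param pacing_cycles Optional per-trial cycle count override.
#' @return A list of class `respacer_experiment` with `trials` (named
#'   `trial_record`s), `metrics`, `order` and `seed`.
#' @export
run_experiment <- function(config = default_config(), outdir = NULL,
                           seed = config$seed, pacing_cycles = NULL) {
  validate_config(config)
  grid <- expand.grid(mode = config$protocol$modes,
                      sigh = config$protocol$sigh,
                      stringsAsFactors = FALSE)
  labels <- paste0(grid$mode, ifelse(grid$sigh, "_sigh", ""))
  order <- with_local_seed(derive_seed(seed, 999L), sample(nrow(grid)))
  trials <- vector("list", nrow(grid))
  names(trials) <- labels
  for (j in seq_along(order)) {
    i <- order[j]
    trials[[i]] <- simulate_trial(config, mode = grid$mode[i],
                                  sigh = grid$sigh[i],
                                  pacing_cycles = pacing_cycles,
                                  seed = derive_seed(seed, i))
  }
  metrics <- lapply(trials, trial_metrics)
  if (all(vapply(metrics, function(m) is.na(m$entrainment_onset), logical(1))))
    stop("entrainment was not achieved in any mode: check plant calibration ",
         "and channel limits")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(outdir, "config.yaml"))
    for (lab in labels) {
      write_trial(trials[[lab]], file.path(outdir, lab))
      write_metrics(metrics[[lab]], file.path(outdir, paste0(lab, "_metrics.json")))
    }
  }
  structure(list(trials = trials, metrics = metrics, order = labels[order],
                 seed = seed),
            class = "respacer_experiment")
}

#' Simulate a cohort of subjects and compare stimulation modes
#'
#' For each simulated subject (plant gains, baseline tidal volume and twitch
#' thresholds jittered by +/-10%), runs matched diaphragm-only and combined
#' trials from the same trial seed, computes the diaphragm fatigue index for
#' each (initial window at entrainment onset, final window 400 cycles later,
#' clamped to the series end for late entrainers), and tests whether the
#' combined-mode fatigue index and the post-entrainment diaphragm charge are
#' lower, with the exact one-sided Wilcoxon signed-rank test.
#'
#' @param config Configuration list.
#' @param n_subjects Number of simulated subjects (default 6).
#' @param pacing_cycles Cycles per trial (default 550).
#' @param seed Base seed.
#' @return A list of class `respacer_cohort` with `table` (one row per
#'   subject), `p_fi` and `p_charge`.
#' @export
run_cohort <- function(config = default_config(), n_subjects = 6L,
                       pacing_cycles = 550L, seed = config$seed) {
  validate_config(config)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    scfg <- jitter_config(config, derive_seed(seed, 100L + i))
    tseed <- derive_seed(seed, i)
    tr_d <- simulate_trial(scfg, mode = "dia_only", sigh = FALSE,
                           pacing_cycles = pacing_cycles, seed = tseed)
    tr_c <- simulate_trial(scfg, mode = "combined", sigh = FALSE,
                           pacing_cycles = pacing_cycles, seed = tseed)
    m_d <- trial_metrics(tr_d)
    m_c <- trial_metrics(tr_c)
    fi_d <- if (!is.null(m_d$fatigue_index_dia)) m_d$fatigue_index_dia$FI else NA_real_
    fi_c <- if (!is.null(m_c$fatigue_index_dia)) m_c$fatigue_index_dia$FI else NA_real_
    chg <- function(m, tr) {
      if (is.na(m$entrainment_onset)) return(NA_real_)
      idx <- m$entrainment_onset:nrow(tr$cycles)
      mean(tr$cycles$charge_dia[idx])
    }
    rows[[i]] <- data.frame(
      subject = i,
      entrain_dia = m_d$entrainment_onset, entrain_comb = m_c$entrainment_onset,
      fi_dia = fi_d, fi_comb = fi_c,
      fi_ratio = fi_c / fi_d,
      charge_dia = chg(m_d, tr_d), charge_comb = chg(m_c, tr_c))
  }
  tab <- do.call(rbind, rows)
  ok <- stats::complete.cases(tab[, c("fi_dia", "fi_comb")])
  p_fi <- if (sum(ok) >= 4)
    wilcoxon_signed_rank_one_sided(tab$fi_comb[ok], tab$fi_dia[ok], "less")
  else NULL
  okc <- stats::complete.cases(tab[, c("charge_dia", "charge_comb")])
  p_charge <- if (sum(okc) >= 4)
    wilcoxon_signed_rank_one_sided(tab$charge_comb[okc], tab$charge_dia[okc],
                                   "less")
  else NULL
  structure(list(table = tab, p_fi = p_fi, p_charge = p_charge, seed = seed,
                 pacing_cycles = pacing_cycles),
            class = "respacer_cohort")
}

#' @export
print.respacer_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects, %d cycles per trial (seed %d)\n",
              nrow(x$table), x$pacing_cycles, x$seed))
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$p_fi))
    cat(sprintf("FI combined < FI dia-only: exact one-sided Wilcoxon p = %.4g\n",
                x$p_fi$p_value))
  if (!is.null(x$p_charge))
    cat(sprintf("dia charge combined < dia-only: exact one-sided Wilcoxon p = %.4g\n",
                x$p_charge$p_value))
  invisible(x)
}

#' Write / read a trial record
#'
#' A record is stored as plain-text artifacts under a path prefix:
#' `<prefix>_steps.csv`, `<prefix>_cycles.csv`, `<prefix>_weights.csv` and
#' `<prefix>_meta.json`.  Numeric values are stored to 9 significant digits,
#' so `read_trial(write_trial(x))` reproduces `x` to that precision.
#' Reading validates the schema: a missing column is an error naming the
#' column; unknown extra columns are accepted with a warning.
#'
#' @param record A `trial_record`.
#' @param prefix Path prefix (directories are created as needed).
#' @return `write_trial` returns the prefix invisibly; `read_trial` returns
#'   the reconstructed `trial_record`.
#' @export
write_trial <- function(record, prefix) {
  stopifnot(inherits(record, "trial_record"))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  sig <- function(df) {
    df[] <- lapply(df, function(col) if (is.double(col)) signif(col, 9) else col)
    df
  }
  write.csv(sig(record$steps), paste0(prefix, "_steps.csv"), row.names = FALSE)
  write.csv(sig(record$cycles), paste0(prefix, "_cycles.csv"), row.names = FALSE)
  w <- as.data.frame(signif(record$weights, 9))
  names(w) <- paste0("w", seq_len(ncol(w)))
  write.csv(w, paste0(prefix, "_weights.csv"), row.names = FALSE)
  jsonlite::write_json(record$meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

check_schema <- function(df, expected, what) {
  miss <- setdiff(expected, names(df))
  if (length(miss))
    stop("missing column(s) in ", what, ": ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), expected)
  if (length(extra))
    warning("ignoring extra column(s) in ", what, ": ",
            paste(extra, collapse = ", "))
  df[expected]
}

#' @rdname write_trial
#' @export
read_trial <- function(prefix) {
  paths <- paste0(prefix, c("_steps.csv", "_cycles.csv", "_weights.csv",
                            "_meta.json"))
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files))
    stop("trial record file(s) not found: ",
         paste(missing_files, collapse = ", "))
  steps <- check_schema(read.csv(paths[1]), STEP_COLUMNS, paths[1])
  cycles <- check_schema(read.csv(paths[2]), CYCLE_COLUMNS, paths[2])
  weights <- as.matrix(read.csv(paths[3]))
  dimnames(weights) <- NULL
  meta <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  structure(list(steps = steps, cycles = cycles, weights = weights,
                 meta = meta),
            class = "trial_record")
}

#' Write a metrics report as JSON
#'
#' @param metrics A `trial_metrics` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
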