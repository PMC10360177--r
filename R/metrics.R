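# Performance measures: inspiratory RMSE, fatigue index, entrainment and
# adaptation detection, sigh tidal volume factor, synchrony events, and the
# exact one-sided Wilcoxon signed-rank test.

#' Inspiratory window of a desired volume trajectory
#'
#' Samples where the desired volume is rising or within 10% of its peak.
#' Pacing assists inspiration only (expiration is passive), so tracking error
#' and learning are restricted to this window.
#'
#' @param desired Desired volume trace over one cycle.
#' @return Logical vector marking the inspiratory samples.
#' @export
inspiratory_window <- function(desired) {
  stopifnot(length(desired) >= 2)
  rising <- c(diff(desired) > 0, FALSE)
  rising | desired >= 0.9 * max(desired)
}

#' Percent inspiratory root-mean-squared error of one cycle
#'
#' `100 * sqrt(mean((Vd - Vm)^2))` over the inspiratory-window samples,
#' normalized by the peak of the desired trajectory above its minimum (for
#' baseline-zeroed volume traces the minimum is 0, so this is the desired
#' peak).  Invariant to adding the same constant to both traces and to
#' scaling both traces by a positive constant.
#'
#' @param desired,measured Aligned volume traces of equal length.
#' @param window Logical/integer index of the inspiratory samples; default
#'   [inspiratory_window()] of `desired`.
#' @return iRMSE in percent.
#' @export
irmse_cycle <- function(desired, measured, window = inspiratory_window(desired)) {
  stopifnot(length(desired) == length(measured))
  peak <- max(desired) - min(desired)
  if (peak <= 0) stop("desired trajectory peak must be positive")
  d <- (desired - measured)[window]
  if (length(d) == 0) stop("empty inspiratory window")
  100 * sqrt(mean(d^2)) / peak
}

#' Fatigue index from a per-cycle charge series
#'
#' `FI = (Q_final - Q_initial) / Q_initial`, where `Q_initial` and `Q_final`
#' are the mean charges over two disjoint windows of `window` cycles (50 by
#' default) roughly 400 cycles apart.  By default the initial window starts
#' at the first entrained cycle and the final window 400 cycles later; both
#' are overridable.  A positive index means more charge was needed late in
#' the trial (fatigue); a negative index means less.
#'
#' @param charge_per_cycle Numeric series of per-cycle charge (mC).
#' @param initial_start 1-based start of the initial window.
#' @param final_start 1-based start of the final window (default
#'   `initial_start + 400`).
#' @param window Window length in cycles (default 50).
#' @return A list of class `fatigue_index` with `FI`, `Q_initial`, `Q_final`
#'   and the two window ranges.
#' @export
fatigue_index <- function(charge_per_cycle, initial_start = 1L,
                          final_start = initial_start + 400L, window = 50L) {
  n <- length(charge_per_cycle)
  stopifnot(initial_start >= 1, window >= 1)
  if (final_start < initial_start + window)
    stop("fatigue-index windows must be disjoint")
  if (n < final_start + window - 1L)
    stop("charge series too short: need at least ", final_start + window - 1L,
         " cycles for the requested windows")
  iw <- initial_start:(initial_start + window - 1L)
  fw <- final_start:(final_start + window - 1L)
  Qi <- mean(charge_per_cycle[iw])
  Qf <- mean(charge_per_cycle[fw])
  if (Qi <= 0) stop("initial-window mean charge must be positive")
  structure(list(FI = (Qf - Qi) / Qi, Q_initial = Qi, Q_final = Qf,
                 initial_window = range(iw), final_window = range(fw)),
            class = "fatigue_index")
}

run_onset <- function(x, threshold, run_length, inclusive) {
  ok <- if (inclusive) x <= threshold else x < threshold
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values & r$lengths >= run_length)[1]
  if (is.na(i)) NA_integer_ else starts[i]
}

#' First entrained cycle of an iRMSE series
#'
#' Entrainment is declared at the first cycle beginning a run of at least
#' `run_length` consecutive cycles with iRMSE strictly below `threshold_pct`
#' (default: below 20% for 20 breaths).  Returns the 1-based cycle position,
#' or `NA` if the series never entrains.
#'
#' @param irmse_pct Per-cycle iRMSE series (percent); `NA`s count as
#'   non-entrained cycles.
#' @param threshold_pct Threshold in percent (default 20).
#' @param run_length Required consecutive cycles (default 20).
#' @return Integer cycle position or `NA`.
#' @export
entrainment_onset <- function(irmse_pct, threshold_pct = 20, run_length = 20L) {
  stopifnot(length(irmse_pct) >= 1)
  run_onset(irmse_pct, threshold_pct, run_length, inclusive = FALSE)
}

#' First adapted cycle of an iRMSE series
#'
#' The controller counts as adapted at the first cycle beginning a run of at
#' least `run_length` cycles with iRMSE at or below `threshold_pct`
#' (default: 10% or less for 20 cycles).
#'
#' @inheritParams entrainment_onset
#' @param threshold_pct Threshold in percent (default 10, inclusive).
#' @return Integer cycle position or `NA`.
#' @export
adaptation_detect <- function(irmse_pct, threshold_pct = 10, run_length = 20L) {
  stopifnot(length(irmse_pct) >= 1)
  run_onset(irmse_pct, threshold_pct, run_length, inclusive = TRUE)
}

#' Lowest iRMSE level sustained over a run of cycles
#'
#' The smallest level `L` such that some run of `run_length` consecutive
#' cycles stays at or below `L`; i.e. the minimum over all windows of the
#' window maximum.  `adaptation_detect(x, sustained_irmse_level(x, k), k)`
#' always succeeds.
#'
#' @param irmse_pct Per-cycle iRMSE series (percent).
#' @param run_length Window length in cycles (default 20).
#' @return The sustained level, percent.
#' @export
sustained_irmse_level <- function(irmse_pct, run_length = 20L) {
  n <- length(irmse_pct)
  stopifnot(n >= run_length)
  wmax <- vapply(seq_len(n - run_length + 1L), function(i)
    max(irmse_pct[i:(i + run_length - 1L)]), numeric(1))
  min(wmax)
}

#' Sigh tidal volume factor
#'
#' Measured sigh tidal volume normalized by the targeted (desired, non-sigh)
#' tidal volume of the trial.
#'
#' @param sigh_tidal Measured sigh tidal volume(s), ml.
#' @param desired_tidal Targeted tidal volume, ml (> 0).
#' @return Dimensionless factor(s).
#' @export
sigh_volume_factor <- function(sigh_tidal, desired_tidal) {
  if (any(desired_tidal <= 0)) stop("desired tidal volume must be positive")
  sigh_tidal / desired_tidal
}

#' Synchrony loss and reset around each sigh
#'
#' A loss of synchrony before a sigh is declared when at least `n_before`
#' consecutive pre-sigh cycles have the measured breath initiation out of
#' phase with the desired initiation (|onset phase error| > `phase_tol`); a
#' reset is declared when the error returns within tolerance within
#' `n_after` post-sigh cycles.  `NA` onset errors (no intrinsic onset
#' observed in a cycle) count as out of phase.
#'
#' @param onset_phase_error Per-cycle onset phase error in cycle fractions
#'   (wrapped to `(-0.5, 0.5]`).
#' @param sigh_cycles 1-based positions of the sigh cycles in the series.
#' @param phase_tol Phase tolerance in cycle fractions (default 0.25).
#' @param n_before,n_after Cycle counts for the loss/reset rules (default 3).
#' @return A data frame with one row per sigh: `sigh_cycle`, `loss_before`,
#'   `reset_after`.
#' @export
synchrony_events <- function(onset_phase_error, sigh_cycles, phase_tol = 0.25,
                             n_before = 3L, n_after = 3L) {
  n <- length(onset_phase_error)
  if (length(sigh_cycles) == 0L)
    return(data.frame(sigh_cycle = integer(0), loss_before = logical(0),
                      reset_after = logical(0)))
  res <- lapply(sigh_cycles, function(s) {
    out_of_phase <- abs(onset_phase_error) > phase_tol
    out_of_phase[is.na(out_of_phase)] <- TRUE
    loss <- if (s > n_before)
      all(out_of_phase[(s - n_before):(s - 1L)]) else FALSE
    reset <- if (s < n)
      any(!out_of_phase[seq(s + 1L, min(s + n_after, n))]) else FALSE
    data.frame(sigh_cycle = s, loss_before = loss, reset_after = reset)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Exact one-sided Wilcoxon signed-rank test
#'
#' Paired one-sided test for small samples: zero differences are dropped,
#' absolute differences are ranked with average ranks on ties, and the exact
#' p-value is the null probability that the positive-rank sum reaches or
#' exceeds the observed one, taken over all `2^n` equiprobable sign
#' assignments (computed by the equivalent generating-polynomial recursion).
#' The direction must be stated explicitly: `"greater"` tests whether `a`
#' exceeds `b`, `"less"` the reverse.
#'
#' @param a,b Paired numeric vectors.
#' @param alternative `"greater"` or `"less"` (no default; the hypotheses are
#'   directional).
#' @return A list of class `wsr_test` with `p_value`, `statistic` (the
#'   positive-rank sum in the tested direction), `n` (non-zero pairs) and
#'   `alternative`.
#' @export
#' @examples
#' # six strictly positive differences: p = 1/64
#' wilcoxon_signed_rank_one_sided(2:7, 1:6, "greater")$p_value
wilcoxon_signed_rank_one_sided <- function(a, b,
                                           alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 1)
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    stop("all paired differences are zero")
  if (alternative == "less") d <- -d
  n <- length(d)
  if (n > 25)
    stop("exact enumeration supported for at most 25 non-zero pairs")
  r <- rank(abs(d))
  W2 <- as.integer(round(2 * sum(r[d > 0])))
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  # distribution of the doubled positive-rank sum over all sign assignments
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2) {
    g <- f / 2
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
      f[1L:(total + 1L - ri)] / 2
    f <- g
  }
  p <- sum(f[(W2 + 1L):(total + 1L)])
  structure(list(p_value = p, statistic = W2 / 2, n = n,
                 alternative = alternative),
            class = "wsr_test")
}

#' Metrics report for a simulated trial
#'
#' Recomputes the full performance-measure suite from a [simulate_trial()]
#' record: the per-cycle iRMSE trace (from the per-step tables, so stored
#' records can be re-analyzed), entrainment and adaptation onsets, the
#' diaphragm and intercostal fatigue indices (initial window at entrainment
#' onset, final window 400 cycles later, clamped to the series end when the
#' trial is short), sigh tidal volume factors, and synchrony events around
#' each sigh.
#'
#' @param record A `trial_record` from [simulate_trial()].
#' @param fi_gap Cycles between the fatigue-index windows (default 400).
#' @param fi_window Fatigue-index window length (default 50).
#' @return A list of class `trial_metrics`.
#' @export
trial_metrics <- function(record, fi_gap = 400L, fi_window = 50L) {
  stopifnot(inherits(record, "trial_record"))
  cyc <- record$cycles
  irmse <- cyc$irmse_pct
  ent <- entrainment_onset(irmse)
  adp <- adaptation_detect(irmse)
  n <- nrow(cyc)
  fi <- list(dia = NULL, eic = NULL)
  fi_note <- NA_character_
  if (!is.na(ent)) {
    fs <- min(ent + fi_gap, n - fi_window + 1L)
    if (fs >= ent + fi_window && all(cyc$charge_dia[ent:(ent + fi_window - 1L)] > 0)) {
      fi$dia <- fatigue_index(cyc$charge_dia, ent, fs, fi_window)
      if (any(cyc$charge_eic > 0))
        fi$eic <- fatigue_index(cyc$charge_eic, ent, fs, fi_window)
      if (fs < ent + fi_gap)
        fi_note <- sprintf("final window clamped: gap %d cycles", fs - ent)
    }
  }
  sighs <- which(cyc$is_sigh)
  sf <- if (length(sighs))
    sigh_volume_factor(cyc$tidal_ml[sighs], record$meta$desired_tidal_ml)
  else numeric(0)
  sync <- if (length(sighs))
    synchrony_events(cyc$onset_phase_error, sighs) else NULL
  structure(list(
    mode = record$meta$mode,
    sigh_enabled = record$meta$sigh,
    n_cycles = n,
    irmse_pct = irmse,
    mean_irmse_pct = mean(irmse),
    sustained_irmse_pct = if (n >= 20) sustained_irmse_level(irmse) else NA_real_,
    entrainment_onset = ent,
    adaptation_onset = adp,
    mean_charge_dia_mC = mean(cyc$charge_dia),
    mean_charge_eic_mC = mean(cyc$charge_eic),
    fatigue_index_dia = fi$dia,
    fatigue_index_eic = fi$eic,
    fi_note = fi_note,
    sigh_cycles = sighs,
    sigh_volume_factors = sf,
    synchrony = sync
  ), class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat("Trial metrics (", x$mode,
      if (isTRUE(x$sigh_enabled)) " + sighs" else "", ")\n", sep = "")
  cat(sprintf("  cycles: %d  mean iRMSE: %.2f%%  sustained iRMSE: %s%%\n",
              x$n_cycles, x$mean_irmse_pct,
              formatC(x$sustained_irmse_pct, digits = 3)))
  cat(sprintf("  entrainment onset: %s  adaptation onset: %s\n",
              format(x$entrainment_onset), format(x$adaptation_onset)))
  if (!is.null(x$fatigue_index_dia))
    cat(sprintf("  diaphragm fatigue index: %.3f\n", x$fatigue_index_dia$FI))
  if (length(x$sigh_volume_factors))
    cat(sprintf("  sighs: %d  mean volume factor: %.2f\n",
                length(x$sigh_cycles), mean(x$sigh_volume_factors)))
  invisible(x)
}

#' @export
print.fatigue_index <- function(x, ...) {
  cat(sprintf("Fatigue index: %.4f (Q_initial %.4g -> Q_final %.4g mC; windows %d-%d, %d-%d)\n",
              x$FI, x$Q_initial, x$Q_final,
              x$initial_window[1], x$initial_window[2],
              x$final_window[1], x$final_window[2]))
  invisible(x)
}

#' @export
print.wsr_test <- function(x, ...) {
  cat(sprintf("Exact one-sided Wilcoxon signed-rank: W = %.1f, n = %d, p = %.6g (%s)\n",
              x$statistic, x$n, x$p_value, x$alternative))
  invisible(x)
}
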