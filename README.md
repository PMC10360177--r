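# respacer

Adaptive closed-loop respiratory pacing, in silico.

Respiratory pacing by functional electrical stimulation is an alternative to
mechanical ventilation when neural control of breathing is compromised, but
fixed open-loop stimulation fatigues the diaphragm and cannot provide the
periodic sighs (augmented breaths) that keep alveoli open. `respacer`
implements and exercises a closed-loop answer to both problems: a
pattern-generator/pattern-shaper (PG/PS) controller in which a fixed
oscillator (PG) sets the breath period and a single-layer adaptive network
(PS) learns, breath by breath, the stimulation-amplitude profile that makes
the measured breath volume track a desired pattern — driving *two* muscle
channels (diaphragm and external intercostal) through independent
twitch-threshold-derived amplitude limits, and inserting a sigh every 30
cycles by replaying the previous cycle's output at twice the magnitude with
learning paused.

The PS maps cycle phase $p$ to a normalized output
$u(p)=\mathrm{clip}(\sum_i w_i \varphi_i(p),0,1)$ over 25 Gaussian basis
neurons and adapts by a delta rule on the instantaneous normalized volume
error, $w_i \leftarrow \max(0,\, w_i + \eta\, e\, \varphi_i(p - \tau_d/T))$.
Stimulation is a cathodic-first biphasic train (80 µs/phase, 75 Hz),
amplitude-modulated at 25 Hz; charge per cycle sums amplitude × pulse width
over the delivered train (leading phase).

Because everything runs against a built-in synthetic plant — piecewise-linear
recruitment, charge-driven muscle fatigue $\dot F = k_f q (1-F) - \rho F$,
first-order lung mechanics with a diaphragm–intercostal synergy term, an
intrinsic breathing oscillator entrained through the Hering–Breuer inflation
reflex, and noisy breath-by-breath volume sensing — the controller's claimed
behaviors are reproducible and testable end to end: adaptation to a 120%
-of-baseline target, reduced diaphragm fatigue under combined stimulation,
sigh elicitation, and synchrony resetting. The package also ships the full
performance-metric suite (percent inspiratory RMSE, charge per cycle, fatigue
index, entrainment/adaptation detection, sigh tidal volume factor, synchrony
events, exact one-sided Wilcoxon signed-rank test) and a strength-duration
toolkit (Weiss-model fitting of rheobase and chronaxie).

Intended users: neural-engineering and control researchers prototyping
closed-loop FES strategies, and anyone needing a reproducible testbed for
breath-tracking controllers and their metrics.

## Worked example

```r
library(respacer)

tr <- simulate_trial(mode = "combined", sigh = TRUE,
                     pacing_cycles = 120, seed = 1)
tr
#> Pacing trial record: mode combined (sighs on), seed 1
#>   baseline: tidal 1.011 ml, period 1.480 s (39 cycles)
#>   pacing: 120 cycles x 37 steps @ 40 ms, desired tidal 1.213 ml
#>   final iRMSE 4.53%, mean dia charge 0.01113 mC/cycle

trial_metrics(tr)
#> Trial metrics (combined + sighs)
#>   cycles: 120  mean iRMSE: 9.11%  sustained iRMSE:    5%
#>   entrainment onset: 4  adaptation onset: 32
#>   diaphragm fatigue index: 0.129
#>   sighs: 3  mean volume factor: 2.35
```

Reading this: the trial first recorded 60 s of spontaneous breathing (tidal
volume 1.011 ml at a 1.48 s period), set the desired pattern to 120% of that
baseline (1.213 ml), then ran 120 paced cycles. The intrinsic rhythm
entrained to the pacing clock by cycle 4 (iRMSE < 20% for ≥ 20 cycles) and
the controller "adapted" by cycle 32 (iRMSE ≤ 10% sustained); the best
20-cycle sustained error level was 5%. Sighs fired at cycles 30, 60 and 90
with tidal volumes ~2.35× the desired non-sigh tidal volume. The positive
fatigue index (0.129) says the controller had to deliver ~13% more diaphragm
charge per cycle late in the trial to hold the target — stimulation-induced
fatigue being compensated automatically.

The paired mode comparison across simulated subjects:

```r
run_cohort(n_subjects = 6, pacing_cycles = 550, seed = 1)
#> ... fi_dia 0.179-0.320, fi_comb 0.090-0.176, all ratios < 1
#> FI combined < FI dia-only: exact one-sided Wilcoxon p = 0.01562
#> dia charge combined < dia-only: exact one-sided Wilcoxon p = 0.01562
```

Strength-duration fitting:

```r
sim <- simulate_sd_measurement(0.8, 60, noise_sd = 0.02, seed = 3)
fit_sd(sim$pulse_widths, sim$thresholds)
#> Strength-duration fit (14 pulse widths, 10-500 us)
#>   rheobase:  0.7884 mA (asymptote), 0.8788 mA (at 500 us)
#>   chronaxie: 61.62 us (model), 50.12 us (2x rheobase-500 crossing)
#>   RMS residual: 0.0323 mA
```

A command-line wrapper is installed at `inst/scripts/respacer`
(subcommands `simulate`, `metrics`, `sdcurve`, `report`).

See `vignettes/adaptive-pacing.Rmd` for the full model description, the
calibration rationale behind every default, and the limitations of the
synthetic plant.

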