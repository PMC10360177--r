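---
title: "Adaptive closed-loop respiratory pacing in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive closed-loop respiratory pacing in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

respacer is an in-silico testbed for adaptive closed-loop respiratory pacing:
a pattern-generator/pattern-shaper (PG/PS) controller modulates the current
amplitude of two intramuscular stimulation channels — diaphragm (*dia*) and
external intercostal (*eic*) — to make a noisy measured breath-volume signal
track a desired breath-volume pattern, breath by breath, against a synthetic
respiratory plant that emulates a spontaneously breathing anesthetized rat.
This vignette documents the models, every tunable that matters, the numerical
choices, and what the synthetic plant can and cannot say about real animals.

## The controller

**Pattern generator (PG).** A fixed-frequency oscillator sets the breath
timing. The cycle period is derived from the measured baseline breathing
period and quantized to an integer number of 40 ms control steps (25 Hz, the
sampling rate of the control loop); ties in the quantization round down, so a
nominal 1.5 s period runs as 37 steps = 1.48 s. All controller state is
indexed by the within-cycle phase $p \in [0,1)$.

**Pattern shaper (PS).** A single-layer adaptive network maps phase to a
normalized stimulation output $u \in [0,1]$:

$$u(p) = \mathrm{clip}\Big(\sum_{i=1}^{N} w_i\,\varphi_i(p),\ 0,\ 1\Big),
\qquad
\varphi_i(p) = \exp\!\big(-d(p, c_i)^2 / 2\sigma^2\big),$$

with $N = 25$ Gaussian basis neurons at centers $c_i$ uniformly tiling the
cycle, width $\sigma = 1/N$ phase units ($d$ is circular distance). With
width equal to the spacing, a uniform weight vector produces an output flat
in phase to well under 1%, so the basis can represent smooth amplitude
profiles without ripple. Weights adapt by a delta rule driven by the
instantaneous normalized volume error
$e_k = (V_\mathrm{des}(p_k) - V_\mathrm{meas,k}) / V_\mathrm{des}^{peak}$:

$$w_i \leftarrow \max\!\big(0,\ w_i + \eta\, e_k\,
\varphi_i(p_k - \tau_d / T)\big),$$

applied only at steps inside the stimulation window (below). The learning
rate $\eta = 0.02$ per step gives a closed-loop adaptation time constant of
roughly 20–30 cycles at the default plant gain; on a static linear plant the
tracking error falls below 5% of the peak well within 300 cycles (tested).
The delay compensation $\tau_d = 80$ ms (two control steps) credits the
error to the basis neurons that were active when the responsible stimulation
was emitted, partially compensating the lung time constant; it
under-compensates the 150 ms lung lag deliberately — the residual
misattribution is smaller than the basis correlation length, so it blurs
rather than destabilizes adaptation.

**Channel mapping.** A single PS drives both muscles. Per channel, the
normalized output is mapped affinely onto the usable current range:
amplitude $= I_{tw} + \min(u, 1)\,(I_{max} - I_{tw})$ for $u \ge u_{on}$
(the activation floor, 0.05), zero otherwise. $I_{max}$ is constrained to
1.5–2× the twitch threshold at construction (defaults: dia 1.5 → 3.0 mA,
eic 1.0 → 2.0 mA, i.e. the 2–4 mA regime of intramuscular rodent
electrodes), so commanded amplitudes can never exceed the per-channel limit,
even for the doubled output of a sigh cycle.

**Pulse encoding and charge.** Stimulation is a cathodic-first biphasic
train, 80 µs per phase at 75 Hz, amplitude-modulated by the controller.
Charge bookkeeping counts the leading (cathodic) phase only — biphasic
pulses are charge-balanced, so the leading phase is the unambiguous
dose-like quantity: over an interval $\Delta t$,
$Q = I \cdot 80\,\mathrm{\mu s} \cdot 75\,\mathrm{Hz} \cdot \Delta t$
(mC for $I$ in mA). Per-cycle charge is the sum of per-step charges and
equals the closed form at constant amplitude to $10^{-12}$ relative
(tested).

**Stimulation window.** Pacing assists inspiration only; expiration is
passive. Stimulation and learning are restricted to steps where the desired
volume is rising or within 10% of its peak. The same window defines the
"inspiratory" samples of the iRMSE metric, so the controller is evaluated
exactly where it can act.

**Sigh scheduler.** Every 30th cycle the controller replays the stored PS
outputs of the previous cycle at exactly twice their magnitude (before
channel mapping, so per-channel saturation still applies), and adaptive
learning is paused for the sigh cycle and the one after, preventing the
deliberately outsized breath from being "learned away". Weight snapshots at
cycle starts are recorded in the trial record, so the freeze is verifiable
bit for bit.

## The synthetic plant

The plant is intentionally minimal — the simplest mechanistic model in which
the phenomena of interest (adaptation, charge-dependent fatigue,
muscle synergy, entrainment, sigh resetting) are all present and testable.

**Recruitment.** Activation is piecewise linear in amplitude: zero below the
twitch threshold, full at the saturation current (2× threshold by default).

**Fatigue.** Each muscle carries a fatigue state $F \in [0,1]$ driven by the
delivered charge rate $q$ (mC/s):

$$\dot F = k_f\, q\, (1 - F) - \rho F,$$

and the effective activation is scaled by $(1-F)$. Under constant charge
rate, $F \to k_f q/(k_f q + \rho)$ with time constant $1/(k_f q + \rho)$
(verified against the closed form to 1%). The defaults $k_f = 0.07$ /mC and
$\rho = 0.0017$ /s are calibrated, not physiological claims: they put the
fatigue time constant at roughly 7–9 minutes for typical pacing charge
rates, so that over a 550-cycle (~13.5 min) diaphragm-only trial the
diaphragm fatigue index lands in the 0.1–0.3 range while remaining below
amplitude saturation — the regime in which the fatigue-index comparison
between modes is meaningful. (Stronger fatigue silently *suppresses* the
measured index, because the compensating amplitude pins at $I_{max}$ and
charge can no longer rise.)

**Lung.** First-order volume dynamics above the end-expiratory level:

$$\tau_{lung}\,\dot V = P - V, \qquad
P = D_0\, d(\theta) + g_{dia}\, a_{dia} + g_{eic}\, a_{eic}
  + g_{syn}\, a_{dia} a_{eic},$$

with $\tau_{lung} = 0.15$ s. The bilinear synergy term realizes the
observation that combined diaphragm + intercostal activation yields more
volume than the sum of the parts (rib-cage stabilization): at full
co-activation the steady-state volume exceeds the sum of the single-muscle
steady states by exactly $g_{syn}$ (tested). Defaults $g_{dia} = 2.0$,
$g_{eic} = 0.55$, $g_{syn} = 0.75$ ml. The diaphragm gain is sized so that
after the inflation reflex has cut the intrinsic drive (which always happens
*below* the desired peak — see next paragraph), the diaphragm alone can
still push the lung to 120% of baseline with moderate headroom; fatigue then
erodes that headroom toward saturation over a long trial. A materially
smaller $g_{dia}$ makes the 120% target structurally unattainable in
diaphragm-only mode; a much larger one removes the near-saturation behavior
that the fatigue comparison depends on.

**Intrinsic oscillator and the inflation reflex.** Spontaneous breathing is
a phase oscillator at $T_0 = 1.5$ s producing a half-sine inspiratory drive
over the first half of its phase, with amplitude $D_0$ calibrated at trial
start (exactly, since $V$ is linear in $D_0$) so the free-running tidal
volume equals the configured baseline (1.0 ml). The Hering–Breuer inflation
reflex couples the oscillator to lung volume in both directions, with
hysteresis:

* *inspiratory termination*: if $V \ge V_{HB}$ (1.1× baseline tidal) during
  intrinsic inspiration, the phase jumps to the start of the expiratory
  half;
* *expiratory prolongation*: a pending inspiratory onset is inhibited until
  the lung has deflated below $V_{release}$ (0.3 × $V_{HB}$).

Termination alone is not a workable entrainment mechanism in this plant: it
has a strongly attracting anti-phase orbit in which the intrinsic onset
fires while the lung is still inflated, is instantly reset, and the rhythm
decouples from pacing (the tracking error then oscillates between ~20% and
~50% indefinitely). The onset-inhibition half of the reflex — which is part
of the physiological inflation reflex — removes that orbit: an intrinsic
breath can only begin after genuine deflation, and the phase then locks with
the intrinsic onset near the pacing-cycle start. Because the desired volume
(120% of baseline) exceeds $V_{HB}$ while the baseline breath (100%) does
not reliably, entrainment is robust at the 120% target, marginal at 100%,
and absent with stimulation off (the oscillator free-runs at $T_0$) — all
three regimes are tested.

**Sensor.** Measured volume is the true volume minus a baseline re-zeroed at
each cycle start, plus Gaussian noise (sd 0.02 ml, i.e. ~2% of baseline
tidal). The baseline value is the *end-expiratory level* — the minimum true
volume of the preceding cycle — mirroring breath-by-breath re-zeroing of an
integrated pneumotachometer signal. Re-zeroing against the instantaneous
cycle-start volume instead creates a feedback artifact: any intrinsic
head-start volume is subtracted from the measurement, the controller chases
the offset, and the loop can hold the lung inflated permanently. The
hardware integrator time constant (0.2 s) is carried as metadata; the
plant's volume state already represents the integrated flow signal.

## The trial protocol

Each trial is self-contained: 60 s of spontaneous breathing; breath
detection on the noisy measured volume (hysteresis onset detector); baseline
tidal volume and period averaged over detected cycles, excluding sigh-like
cycles whose tidal volume exceeds 1.5× the running median; then the desired
pattern is set to **120% of the baseline tidal volume** (exact to float
precision, by construction) as an asymmetric half-sine at the baseline
period, and the closed loop runs for the requested number of cycles with the
PS weights starting at zero. Pacing begins at the next intrinsic inspiratory
onset. In `dia_only` mode the intercostal amplitude is forced to zero; in
`spontaneous` mode both channels are off.

**Desired-pattern shape.** The desired trajectory rises as a half-sine over
the first 75% of the cycle and falls as a half-sine over the remainder
(`desired_shape()`, `insp_fraction = 0.75`). The late peak reflects the
morphology of an *entrained* breath in this plant: the reflex terminates the
intrinsic drive just below the peak, the stimulated muscles top up the last
~0.1 ml, and expiration is passive. The inspiratory fraction matters for
closed-loop geometry, not just cosmetics: the reflex fixes the interval from
inspiratory termination to the next intrinsic onset at half the intrinsic
period, so the phase at which the desired pattern crosses $V_{HB}$
determines where the intrinsic onset lands relative to the cycle start. With
a symmetric (mid-cycle-peak) pattern the lock point leaves an intrinsic
volume head start that the controller cannot cancel (outputs are
nonnegative), leaving an irreducible ~11–16% iRMSE floor; at
`insp_fraction = 0.75` the lock places the intrinsic onset essentially at
the cycle start and the floor drops to ~4–5%. The value was chosen by a
coarse scan of this geometry during plant calibration and then frozen.

**Simulated subjects.** `run_cohort()` emulates inter-animal variability by
scaling plant drive gains, baseline tidal volume, and per-channel twitch
thresholds by independent uniform ±10% factors (amplitude limits follow the
thresholds, preserving the 1.5–2× invariant). Each subject's diaphragm-only
and combined trials share one seed, making the comparison paired; fatigue
resets between trials, standing in for the rest period between recordings.

## Performance measures

* **%iRMSE** per cycle: RMS of (desired − measured) over the inspiratory
  window, normalized by the desired pattern's peak-to-minimum range (the
  peak, for baseline-zeroed traces) — 0–100% scale.
* **Entrainment onset**: first cycle starting ≥20 consecutive cycles with
  iRMSE < 20%. **Adaptation**: same rule at ≤ 10%. Both are verified
  against a brute-force window scan on 1000 random series.
* **Charge per cycle** per channel, as above.
* **Fatigue index**: $(\bar Q_{final} - \bar Q_{initial}) / \bar
  Q_{initial}$ over two 50-cycle windows, the initial one at entrainment
  onset and the final one 400 cycles later (clamped to the series end for
  late entrainers; the realized gap is recorded). Positive = more charge
  needed late in the trial.
* **Sigh tidal volume factor**: measured sigh tidal volume / desired tidal
  volume.
* **Synchrony events**: per sigh, a loss of synchrony is ≥3 consecutive
  pre-sigh cycles with the intrinsic onset out of phase by more than 0.25
  cycle (a default tolerance, configurable; cycles with no observed onset
  count as out of phase), and a reset is the error returning within
  tolerance within 3 post-sigh cycles.
* **Exact one-sided Wilcoxon signed-rank test** for the paired mode
  comparisons: zero differences dropped, average ranks on ties, exact null
  distribution over all $2^n$ sign assignments (computed by the equivalent
  generating-polynomial recursion; verified against explicit enumeration for
  $n \le 10$ and against the reference implementation in the tie-free case).
  The direction of the alternative must be supplied explicitly, because the
  scientific hypotheses here are directional.

## Strength-duration toolkit

Twitch-threshold measurements over the descending pulse-width ladder
500→100 µs (steps of 100) and 90→10 µs (steps of 10) are simulated from the
Weiss hyperbolic law $I(pw) = I_{rh}(1 + t_{ch}/pw)$ with multiplicative
noise; parameter priors span rheobase 0.35–1.3 mA and chronaxie 35–100 µs,
the plausible range for intramuscular rodent electrodes. Fitting exploits
that the Weiss model is linear on the charge scale ($I \cdot pw$ vs $pw$),
so ordinary least squares returns the rheobase (slope) and chronaxie
(intercept/slope) robustly. Two conventions are reported side by side: the
asymptotic rheobase from the fit, and the operational one (threshold at
500 µs) with the chronaxie read off where the fitted curve crosses twice
that value. The conventions differ systematically —
$t_{ch}^{interp} = t_{ch} / (1 + 2 t_{ch}/500)$, about 24% low at
$t_{ch} = 80$ µs — which is why both are reported.

## Numerical choices

* Plant integration: explicit Euler at 1 ms (40 substeps per control step,
  stimulation zero-order-held), in compiled code; a pure-R composition of
  the exported single-step operations is kept as the reference and the two
  paths agree to $10^{-12}$ (tested), with a step-halving refinement test
  bounding the discretization error below 0.5% per cycle.
* Period quantization: nearest integer number of 40 ms steps, ties down.
* Randomness: one seed per trial; every stochastic draw (baseline sensor
  noise, then pacing sensor noise) flows from it in a fixed order, so a
  trial record is bit-identical across reruns; helper seeds for subjects and
  trials are derived arithmetically and stay below $2^{31}$. Seeded
  utilities save and restore the caller's random stream.
* Degenerate inputs are rejected loudly: fewer than 5 baseline breaths,
  non-positive desired peak, empty inspiratory window, all-zero Wilcoxon
  differences, flat strength-duration data, fatigue-index series shorter
  than the requested windows.

## Problem sizes

Default analyses use 500-cycle single trials (~12 s of compute) and
6-subject × 2-mode × 550-cycle cohorts (~6 s total); these sizes are large
enough that entrainment, adaptation and the fatigue-index windows (50 cycles,
400 apart) are all well inside the series.

## What the synthetic plant does and does not show

The plant reproduces the *qualitative* phenomena: adaptation of the measured
pattern to the 120% target; faster, lower-charge attainment under combined
stimulation; positive diaphragm fatigue indices that are uniformly smaller
under combined stimulation; sighs at twice the stored output that reset the
intrinsic rhythm via the inflation reflex. It does not model compliance/
resistance partitioning, gas exchange or CO₂ chemoreception, anesthesia
depth, electrode drift, or inter-animal physiology beyond ±10% parameter
jitter. Quantities that depend on real rat physiology — cycles-to-entrainment
counts, animal p-values, per-animal sigh statistics — are not claimed, and
passing tests here demonstrate correctness of the algorithms and internal
consistency of the simulator, not animal-level prediction.
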