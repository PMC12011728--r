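---
title: "Simulating and analyzing motor-imagery neurofeedback EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing motor-imagery neurofeedback EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Motor imagery (MI) — the mental rehearsal of a movement — suppresses the
sensorimotor mu (8–12 Hz) and beta (13–30 Hz) rhythms over the hemisphere
contralateral to the imagined hand. This event-related desynchronization
(ERD) is the control signal of most EEG neurofeedback (NF) and
brain–computer-interface paradigms: band power during the task is expressed
relative to a pre-task reference,

$$\mathrm{ERD}(t) = \frac{A(t) - R}{R}\cdot 100\,\%,$$

where $A(t)$ is the power timecourse averaged across trials **first** and
$R$ is the mean of $A$ over the reference interval (−6 to −4 s before MI
onset). Negative values are desynchronization. `erdnf` implements a complete
MI-NF analysis chain of this kind — simulation, preprocessing, Common
Spatial Patterns (CSP), cross-validated linear classifiers with border
calibration, ERD quantification, and the group statistics — so that every
stage can be exercised and validated without access to raw recordings.

## Study conditions emulated by the generator

The synthetic paradigm follows a fixed session grammar: a *block* is three
runs of 40 trials (20 left / 20 right hand, pseudorandomized with at most 3
same-hand repeats); the first run (`T`) is plain MI and trains the feedback
parameters, the next two (`NF1`, `NF2`) are NF runs; three blocks make a
dataset. A trial is 5 s baseline + 3 s cue + 5 s MI + a uniform 0–4 s
inter-trial interval. Acquisition is 64 channels at 500 Hz.

`sim_config()` holds every generator knob. The forward model has four
rhythm sources (left/right hemisphere × mu/beta) with Gaussian spatial
topographies over the sensorimotor clusters of a generic equidistant
layout, on top of spatially mixed $1/f$ background noise scaled to a
~10 µV channel SD. During each MI interval the contralateral source
amplitude is scaled by $\sqrt{1-d}$ — band power drops by exactly the
configured depth $d$ — and the ipsilateral source by `ipsi_ratio * d`
(default 0.5). Transitions ramp linearly over 0.25 s to avoid spectral
edge artifacts. `snr` is the amplitude ratio of a rhythm to the in-band
background at the topography's peak sensor.

Defaults chosen once, where the emulated study is silent: depths 0.3 in
both bands (matching the −25…−30 % block means the paradigm produces),
`snr = 3` as a realistic sensorimotor signal-to-background ratio,
$1/f$ exponent 1, and a +0.15 depth gain during NF runs reproducing the
robust NF-versus-training enhancement (paired $d > 0.9$). The two
experiment groups are identical by default (the studied manipulation had
a null result); `group_depth_effect` adds a group difference for power
studies.

What the generator deliberately does **not** emulate: realistic volume
conduction from anatomical head models, non-stationary rhythm dynamics,
eye/heart physiology beyond threshold-exercising blink transients, and
electrode drift. Passing tests therefore demonstrate correctness of the
analysis chain under controlled ground truth, not robustness to every
property of real EEG.

```{r}
library(erdnf)
cfg <- sim_config(n_channels = 16, n_trials_per_run = 20,
                  erd_depth_mu = 0.3, erd_depth_beta = 0.3,
                  snr = 10, seed = 1)
rec <- simulate_recording(cfg, run_events(generate_schedule(cfg), "T", 1))
```

## Preprocessing

The offline path mirrors the emulated pipeline: zero-phase FIR filtering
(high-pass 8 Hz order 826, low-pass 30 Hz order 220, Hamming window;
forward–backward with 3 × order odd-reflection padding), epoching from −7
to 9 s around MI onset (closed-open intervals; 8000 samples at 500 Hz),
baseline correction over −6 to −4 s, bad-channel detection (overall SD
outside mean ± 2 SD across channels), inverse-distance interpolation of
bad channels from up to 6 neighbors, and common-average referencing. The
online path uses a causal 4th-order Butterworth 8–30 Hz band-pass. The
printed description of that filter carries a "0.5 dB passband ripple";
a Butterworth design is maximally flat, so the ripple figure is stored as
provenance only.

Trial rejection offers the two threshold rules of the protocol: an
amplitude criterion (±100 µV on band-passed EEG; the emulated study
rejected "epochs containing artifacts" without stating a threshold, so the
value is exposed in `qc_config()`) and the EMG movement rule — a trial is
flagged when a 250-sample centered moving SD exceeds 2.5 × the trial's
overall SD. The reference SD is computed per trial and channel; whether the
original computed it per trial or per recording is not documented, and the
choice is isolated inside `artifact_mask()`.

## CSP and the neurofeedback quantities

CSP solves $C_L w = \lambda (C_L + C_R) w$ on the pooled-run class
covariances (per-trial trace-normalized, averaged, shrunk by
$\gamma = 0.05$ toward the scaled identity). Eigenvalues lie in (0, 1);
the right-class filter sits at the high extreme, the left-class filter at
the low extreme (its output variance is smallest on left-hand trials,
i.e. it tracks the contralateral, suppressed source). Manual
"neurophysiologically plausible" screening is automated: the default
`"scored"` mode re-ranks the three most extreme filters per side by
sensorimotor-cluster weight × spatial smoothness of the pattern (both
deterministic), which suppresses the occasional noise-latched extreme
filter; `"eigenvalue"` mode simply takes the extremes and is used by
tests that pin down the extreme-eigenvalue semantics. Applying a hand's own filter
to its own trials yields contralateral activity; swapping filters yields
ipsilateral activity.

Features are log band powers of 1-s bins sliding with 0.9375 s overlap.
The nominal hop of 0.0625 s is 31.25 samples at 500 Hz; bins are placed at
`round(k * 31.25)`, i.e. alternating 31/32-sample hops, making the average
overlap exact. Three linear discriminants (pooled covariance, optional
shrinkage) drive the feedback ball: `LR` (right- vs left-hand MI,
horizontal), `BaseL` and `BaseR` (MI vs baseline, vertical). All three see
the same 2-D feature vector (both CSP channels). Cross-validation is
7-fold, stratified by class and *grouped by trial* so overlapping bins of
one trial never straddle a fold split. The *border* of each classifier is
the 75th percentile (linear interpolation) of its held-out target-class
scores; the ball position is the score divided by the border, clipped to
[−1, 1]. Parameters fit on run `T` calibrate `NF1`, and `NF1` fits
calibrate `NF2`; the pipeline manifest records every train→score pair so
the no-leakage chain is auditable.

```{r}
pf <- preset_filters()
ep <- epoch_data(fir_filter(fir_filter(rec, pf$hp8), pf$lp30))
ep <- baseline_correct(ep)
mod <- csp(ep)
contra <- apply_csp(ep, mod, "contra")
tc <- average_contralateral(
  compute_erd(subset_trials(contra, contra$hand == "left")),
  compute_erd(subset_trials(contra, contra$hand == "right")))
plot(tc)
```

## ERD summaries and statistics

`compute_erd()` squares the projected signal, averages across trials,
smooths with a 0.25-s moving average (a free choice; the source protocol
does not mention smoothing) and normalizes to the reference interval.
Scalar block summaries average the timecourse over the MI window — 0.5 to
4.5 s by default, matching the feature window; `c(0, 5)` selects the full
MI interval, since the original wording ("within the MI interval") leaves
this open. The NF measure pools the trials of both NF runs before
normalizing (trial-count-weighted pooling of power, *then* relative
change); pooling order matters and is asserted by a test on
heteroscedastic data. Baseline power is the mean square over −6 to −4 s of
the CSP-projected signal, in µV² up to the (arbitrary but within-dataset
consistent) CSP scaling.

The statistics module reproduces the study's battery: one-sided paired t
(training vs NF ERD) with $d = t/\sqrt{n}$ and a noncentral-t CI for $d$;
pooled-variance independent t between groups with $d$ from the pooled SD
and the CI of the mean difference; Holm correction in two variants —
the standard step-down (default) and a "raw-multiplier" variant
($p_i \times (m - \mathrm{rank}_i + 1)$, no monotonicity pass) that
reproduces published non-monotone adjusted values; a mixed
repeated-measures ANOVA (blocks within, group between) via the classical
SS decomposition with $\eta^2 = SS_{\rm term}/SS_{\rm total}$ (total
including between-subject variance; partial $\eta^2$ optional), Mauchly's
test, and Greenhouse–Geisser corrected p whenever the factor has more than
two levels; Shapiro–Wilk and mean-centered Levene checks attached to the
group comparisons.

## Numerical choices and degenerate inputs

FFT work (noise synthesis, FIR convolution) is padded to 2-3-5-composite
lengths; FIR application matches direct convolution to ~1e-13. Covariance
shrinkage (0.05) guards CSP and LDA against singular estimates; a pooled
covariance still singular after shrinkage is an error, as are: odd trial
counts, cutoffs at or above Nyquist, baseline intervals outside the epoch,
more than 25 % bad channels, zero reference power, zero-variance paired
differences, k-fold requests exceeding a class's trial count, and
unbalanced ANOVA tables (no imputation). All-zero feature bins are floored
at a configurable epsilon before the log, with a warning. Ties in the
border quantile follow R's type-7 convention.

## Validation scale

The correctness claims are validated on reduced problem sizes chosen to
keep the checks at ordinary desk runtimes: property simulations use 10–16
channels and 8–20 trials per run; classifier-accuracy and depth-recovery
checks use the study's 40-trial runs where the claim depends on trial
count; the full 64-channel, 34-subject scale is exercised through the
generator's contracts rather than end-to-end. Depth recovery regresses the
estimated MI-window ERD on $-100 d$ over $d \in \{0.1, 0.2, 0.3, 0.4\}$
across 20 replicates; within a replicate the four depths share one seed
(a paired design — the run-level realization noise cancels out of the
slope). Slope and intercept are reported by `scripts/acceptance.R`.

## Known limitations

Independent component analysis (and trained component classifiers) and
wavelet EMG denoising are intentionally absent; rejection is threshold
based. The BrainVision reader supports the multiplexed binary layouts the
writer emits (IEEE float32 and int16 at 0.1 µV resolution). Holm's
raw-multiplier variant exists only to mirror published values and is not
recommended for new analyses — it can be non-monotone, which the function
reports. The noncentral-t CI for paired $d$ and the mean-difference CI for
independent tests follow the conventions of the emulated report, which
differ between its two tables.
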