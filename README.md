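# erdnf

Motor-imagery (MI) neurofeedback (NF) training uses the event-related
desynchronization (ERD) of the sensorimotor mu (8–12 Hz) and beta
(13–30 Hz) rhythms — the power decrease over the hemisphere contralateral
to an imagined hand movement — as its control signal. `erdnf` is an R
package for researchers in EEG neurofeedback and brain–computer
interfacing who want a fully testable re-implementation of a classic
MI-NF analysis chain, from raw continuous EEG to the group statistics,
together with a synthetic-EEG generator that provides ground truth for
every stage.

The chain: FIR/Butterworth band filtering → epoching around MI onset →
channel QC, interpolation, common-average reference and threshold-based
trial rejection → Common Spatial Patterns, fit from the generalized
eigenproblem

```
C_L w = λ (C_L + C_R) w,        λ ∈ (0, 1),
```

applied under the contralateral convention (each hand's filter to its own
trials) → log band-power features in 1-s bins (0.9375 s overlap) → three
cross-validated linear discriminants (LR, BaseL, BaseR) with upper-quartile
border calibration driving a feedback ball in [−1, 1]² → ERD
quantification

```
ERD(t) = (A(t) − R) / R · 100 %,   R = mean power over −6…−4 s,
```

→ paired and pooled independent t-tests with Cohen's *d*, Bonferroni–Holm
correction, and a mixed repeated-measures ANOVA with Mauchly's test and
Greenhouse–Geisser correction.

## Worked example

Simulate one 40-trial training run with a 0.3 ERD depth in both bands,
run the offline path, and quantify contralateral ERD:

```r
library(erdnf)
cfg <- sim_config(n_channels = 16, n_trials_per_run = 40,
                  erd_depth_mu = 0.3, erd_depth_beta = 0.3,
                  snr = 10, seed = 1)
rec <- simulate_recording(cfg, run_events(generate_schedule(cfg), "T", 1))
pf  <- preset_filters()
ep  <- baseline_correct(epoch_data(fir_filter(fir_filter(rec, pf$hp8),
                                              pf$lp30)))
mod <- csp(ep)
contra <- apply_csp(ep, mod, "contra")
tc <- average_contralateral(
  compute_erd(subset_trials(contra, contra$hand == "left")),
  compute_erd(subset_trials(contra, contra$hand == "right")))
print(mod); print(tc)
#> CSP model: 16 filters on 16 channels
#>   eigenvalue range: 0.453 .. 0.547
#>   selected: right = filter 1 (lambda 0.547), left = filter 16 (lambda 0.453)
#> ERD timecourse (contra, 40 trials): -7.0 to 9.0 s
#>   mean ERD over 0.5-4.5 s: -28.5%
```

The recovered −28.5 % tracks the injected 30 % contralateral power
decrease (residual background power and finite trial counts account for
the gap). The statistics module also works directly from published
summary statistics:

```r
sapply(c(5.185, 4.041, 3.932), d_from_t_paired, n = 17)
#> [1] 1.258 0.980 0.954            # paired Cohen's d per block (3 dp)
independent_ttest(mean1 = -25.289, sd1 = 14.490, n1 = 17,
                  mean2 = -29.285, sd2 = 9.589,  n2 = 17)
#> Independent t-test: t(32) = 0.948, p = 0.3501, d = 0.325
#>   95% CI for d: (-0.354, 1.000); for the difference: (-4.588, 12.580)
holm_adjust(c(0.350, 0.295, 0.822), "standard")
#> [1] 0.885 0.885 0.885
```

`run_full_pipeline(pipeline_config(...))` chains everything for a
two-group synthetic experiment — per block it calibrates NF1 from run T
and NF2 from NF1 (the manifest records every train→score pair), computes
block-level CSP over the pooled runs, and emits block summaries plus the
paired, group-comparison and ANOVA tables; `export_tables()` writes them
as CSV.

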