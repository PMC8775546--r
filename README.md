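# kinentropy

Approximate-entropy analysis of joint-angle kinematics, built for studies of
movement regularity in Parkinson's disease (PD) and older adults (OA) —
for example wearable-IMU recordings of hip and knee angles captured at
100 Hz during community dance classes. The package asks a simple question
of such recordings: **is movement on one side of the body more regular
(less complex) than on the other?** Under the loss-of-complexity
hypothesis, reduced physiological variability accompanies disease
progression, so the more-affected side of a person with PD is expected to
show *lower* entropy than the less-affected side.

## The statistic

Approximate entropy (ApEn) measures the regularity of a time series
u(1), …, u(N). With embedding dimension m, delay τ and tolerance r, form
the delayed embedding vectors

    x_d(i) = ( u(i), u(i+τ), …, u(i+(d−1)τ) ),   i = 1, …, M_d,   M_d = N − (d−1)τ

and for each i the fraction of vectors within Chebyshev distance r
(self-match included):

    C_i^d(r) = #{ j : max_k |x_d(i)_k − x_d(j)_k| ≤ r } / M_d
    Φ^d(r)   = (1/M_d) Σ_i ln C_i^d(r)

    ApEn(m, r, τ) = Φ^m(r) − Φ^{m+1}(r)  ≥ 0.

ApEn is near 0 for repetitive, predictable signals and grows with
irregularity; with r tied to the series SD it is invariant to affine
rescaling of the signal. Defaults are the field conventions m = 2 and
r = 0.2 × SD.

The delay τ is chosen from the autocorrelation function (ACF): the
smallest lag at which the ACF is closest to zero, operationalised as the
first lag k with |acf(k)| < 0.1. At 100 Hz sampling this typically selects
delays far above the textbook 1–5 samples.

On top of the per-series statistic, the cohort pipeline aggregates ApEn by
participant, limb side and dance type, and runs the full left-vs-right
statistical battery: Shapiro–Wilk normality per side, Brown–Forsythe
Levene variance check, Tukey-fence outlier flagging (outliers are
reported, never removed), then a two-sided unpaired Welch t-test — or the
Mann–Whitney test when normality fails — plus between-group Welch
comparisons (recording length, τ, ACF at τ) and across-dance one-way
ANOVAs. A synthetic cohort generator (quasi-periodic harmonics + AR(1)
noise + optional per-cycle phase jitter, with a side-asymmetry knob)
makes every stage testable without any participant data.

## Worked example

Simulate a small PD-like cohort whose left side is markedly more regular
(noise SD scaled by γ = 0.25) and analyse it:

```r
library(kinentropy)

spec <- cohort_spec(n_pd = 3, n_oa = 0, dances = "tango",
                    recordings_per_dance = 2,
                    duration_range_min = c(0.5, 0.5),
                    channels = "knee_flexion",
                    asymmetry_gamma = 0.25, seed = 5)
sim <- simulate_cohort(spec)
report <- run_pipeline(sim$cohort, pipeline_config())
report
#> <analysis_report> 12 series analysed (0 failed QC), 6 aggregates
#>   PD knee_flexion ApEn left vs right            t =  -11.627  p = 0.0062 *
#>   PD knee_flexion mean angle left vs right      W =    6.000  p = 0.7000
#>   (9 contrast(s) skipped)
```

The entropy contrast detects the built-in asymmetry (t = −11.6: the left
side's mean ApEn is far below the right's), while the mean-angle contrast
is null — the generator perturbs regularity, not posture. Per-participant
values live in `report$aggregates`:

```r
head(report$aggregates, 2)
#>   participant_id group dance joint measure  side mean_apen mean_angle n_recordings
#> 1           pd01    PD tango  knee flexion  left 0.3367394   29.98923            2
#> 2           pd01    PD tango  knee flexion right 0.5500881   29.94420            2
```

A single series can be analysed directly:

```r
s <- simulate_joint_series(signal_params(), duration_s = 30, seed = 7)
res <- analyze_series(s)
res$tau
#> <tau_estimate> tau = 25 samples, acf(tau) = 0.0704 (threshold 0.1)
res$apen
#> <apen_result> ApEn = 0.699567  (m = 2, r = 2.977, tau = 25, n = 3000)
```

A thin command-line wrapper ships in `inst/cli/kinentropy` with
`analyze`, `simulate`, `apen` and `fixtures` subcommands.

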