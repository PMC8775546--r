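---
title: "Movement entropy of joint-angle kinematics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement entropy of joint-angle kinematics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinentropy)
```

## The question and the model

People with Parkinson's disease commonly present motor symptoms more
strongly on one side of the body. Under the loss-of-complexity hypothesis,
physiological variability declines with age and disease, so the
more-affected side should produce *more regular* (less complex) movement.
This package quantifies that with approximate entropy (ApEn) of joint-angle
time series — hip flexion/abduction/rotation and knee flexion recorded by
body-worn inertial sensors at 100 Hz — and tests left-vs-right entropy
differences across a cohort.

ApEn compares pattern-match frequencies at embedding dimensions $m$ and
$m+1$. With delay $\tau$, vectors
$x_d(i) = (u(i), u(i+\tau), \dots, u(i+(d-1)\tau))$, $M_d = N-(d-1)\tau$,
match fraction
$C_i^d = M_d^{-1}\,\#\{j : \max_k |x_d(i)_k - x_d(j)_k| \le r\}$
(Chebyshev distance, non-strict tolerance, self-match $j=i$ included), and
$\Phi^d = M_d^{-1}\sum_i \ln C_i^d$,

$$\mathrm{ApEn}(m, r, \tau) = \Phi^m - \Phi^{m+1}.$$

We use the classic formulation — self-matches in, $\le r$ — because it
guarantees $\mathrm{ApEn} \ge 0$ and $\mathrm{ApEn} = 0$ exactly for a
constant series, and it is what "ApEn" means in the physiological
time-series literature. The compiled kernel counts matches for both
dimensions in one pass over vector pairs; an independent plain-R
transcription of the definition (`apen_reference()`) is kept in the package
and the test suite verifies the two agree to $10^{-10}$ on random series.

## Parameters

* **`m = 2`** (pattern length). The field convention for physiological
  series; $m+1$-dimensional conditioning needs $N - m\tau \ge 10$ vectors,
  below which the package refuses with an "insufficient embedding" error
  rather than returning a log of a near-empty frequency.
* **`r_factor = 0.2`** (tolerance = 0.2 × sample SD, $n-1$ denominator).
  Scaling $r$ with the series makes ApEn exactly invariant under affine
  maps of the signal, so units (degrees) never matter. `r = 0` is allowed —
  matches degenerate to exact equality — but flagged with a warning on
  non-constant data.
* **`acf_threshold = 0.1`** (delay selection). $\tau$ is the smallest lag
  whose autocorrelation is closest to zero in the operational sense
  $|\hat\rho(k)| < 0.1$. The absolute value is the default reading of
  "closest to 0" (a strongly negative ACF is far from zero); a signed mode
  (`tau_mode = "signed"`) is available. At 100 Hz this routinely selects
  $\tau$ in the tens-to-hundreds of samples — far above the textbook 1–5 —
  because high-rate samples are strongly correlated.
* **`max_shift_fraction = 1`**. The ACF is computed over all shifts up to
  $N-1$ by default; it can be restricted for speed.

The ACF estimator is the demeaned, shared-denominator form
$\hat\rho(k) = \sum_{t\le n-k}(x_t-\bar x)(x_{t+k}-\bar x) / \sum_t (x_t-\bar x)^2$,
which guarantees $|\hat\rho| \le 1$ and $\hat\rho(0)=1$. A consequence worth
stating: because the numerator has $n-k$ terms against a fixed
denominator, $\hat\rho(k)$ decays towards zero as $k \to n$ for *any*
series, so a delay search over the full shift range always terminates. A
genuinely unfindable delay can only occur under a restricted search
window; the `tau_not_found` fixture therefore pairs a slow-trend series
with `max_shift_fraction = 0.05` to exercise that failure path.

## Numerical behaviour of ApEn worth knowing

* **Nonnegativity** holds by construction with self-matches included, and
  is property-tested on 1000 random inputs.
* **Monotonicity in r** holds in the match-rich regime (here verified over
  a grid of $r \in [0.5, 2.5]\,\mathrm{SD}$), but *not* globally: as
  $r \to 0$ the self-match floor $C_i^d \to 1/M_d$ dominates both
  dimensions and ApEn collapses towards 0, so the curve rises from 0 to a
  peak (around $r \approx 0.3$–$0.5$ SD at a few hundred samples) before
  its familiar decrease. Tests of the decreasing property are therefore
  anchored at $r \ge 0.5$ SD.
* **A deterministic quasi-sinusoid is not at zero entropy** when embedded
  at the ACF-selected delay with a coarse tolerance: at the generator's
  defaults (30 s, $\tau = 25$, $r = 0.2$ SD) the noiseless signal scores
  ApEn ≈ 0.27. What matters for the analysis — and what the tests pin
  down — is the *ordering*: the near-periodic signal scores far below iid
  noise of equal SD in every seeded replicate.

## The cohort pipeline

Per recording and channel the pipeline runs ACF → delay → tolerance →
ApEn, also recording the raw-series mean ("mean movement"). Failures
(constant channel, delay not found, series too short) are tagged per
recording in the QC table and excluded from aggregation — never silently
dropped, never fatal to the run.

Results are averaged within participant × dance × channel × side
(`aggregate_results()`); that participant-by-dance mean is the analysis
unit for the side contrasts (configurable to pool dances per participant).
For each group and channel, left vs right is tested for mean ApEn and for
mean angle:

* **Assumption checks first**: Shapiro–Wilk per side; Levene's test in its
  Brown–Forsythe (median-centred) form; Tukey fences with type-7
  (linear-interpolation) quantiles, flagging outliers at 1.5 IQR and
  extremes at 3 IQR. Flagged values are *kept* — small cohorts cannot
  afford discarding — and the tests verify that flagging never alters any
  downstream statistic.
* **Test choice**: the parametric path is the two-sided unpaired Welch
  t-test with Welch–Satterthwaite fractional df (the behaviour of a
  default two-sample `t.test`); if either side fails Shapiro–Wilk at 0.05
  the contrast switches to the two-sided Mann–Whitney test (exact for
  small tie-free samples, tie- and continuity-corrected normal
  approximation otherwise). Effects are reported as mean(right) −
  mean(left).
* **No multiplicity adjustment by default**, mirroring common practice of
  reporting unadjusted per-contrast p-values in small exploratory cohorts;
  a Holm-adjusted column can be switched on (`holm = TRUE`).
* Between-group (PD vs OA) Welch comparisons are run for recording length,
  $\tau$ and ACF-at-$\tau$; across-dance one-way fixed-effects ANOVAs
  (df $(k-1, N-k)$) for recording length and $\tau$. Contrasts with fewer
  than three matched units per side are reported as skipped with a reason.

All statistical machinery is delegated to the standard implementations
(`t.test`, `wilcox.test`, `shapiro.test`, `oneway.test`,
`car::leveneTest`); the test suite cross-checks every one against
independent closed-form or enumeration oracles to $10^{-10}$, including
the two-group identity $F = t^2$ for the pooled ANOVA.

## The synthetic cohort generator

Real recordings of this kind are not redistributable, so validation runs
on simulated cohorts with the statistical structure the analysis assumes:

$$\theta(t) = \mu + \sum_h A_h \sin(2\pi h f t + \phi_h + J(t)) + \varepsilon(t)$$

with fundamental $f = 0.9$ Hz (an unhurried step rate), a second harmonic,
channel-typical means and amplitudes (e.g. knee flexion: 30° ± ~25°),
AR(1) noise $\varepsilon$ with coefficient 0.3 and stationary SD
`noise_sd` (default 2°, the irregularity knob), and a per-cycle cumulative
phase jitter $J$ (default SD 0.05 rad per cycle at the cohort level —
slight step-timing drift, so recordings are quasi- rather than strictly
periodic). Cohorts default to 7 PD-like and 5 OA-like participants, four
dance types, 1–4 min recordings at 100 Hz — the shape of a small
community-dance study. PD-like participants have the *left*-side noise SD
multiplied by `asymmetry_gamma` (default 0.25) on every channel: reduced
stochastic irregularity models reduced movement complexity on the
more-affected side, which is the direction of interest, while amplitude
and mean are kept side-equal so mean-angle contrasts are null by
construction. γ is chosen to give a clearly detectable effect for
validation and power analysis; no quantitative effect size is available to
calibrate it against a real cohort, so it should be read as a test
condition, not a clinical estimate.

Everything is deterministic under the master seed (durations from the
master stream; per-channel sub-seeds derived arithmetically), and the
generator's output passes the package's own I/O validation.

What the generator does *not* emulate: biomechanical coupling between
joints, partner-interaction dynamics, nonstationarity within a recording
(fatigue, tempo changes), sensor drift and soft-tissue artefact, and any
dance-type-specific movement signature (dance labels only partition
recordings). Passing tests on simulated cohorts therefore demonstrate that
the pipeline recovers regularity asymmetries of the assumed form — not
that real dance recordings satisfy those assumptions.

## Validation problem sizes

The test suite and `scripts/acceptance.R` use deliberately compact
designs: kernel-vs-reference equivalence on series up to $n = 500$;
regularity ordering on 30 s signals; false-positive calibration on 200
symmetric cohorts (5 participants, two 30 s tango recordings each, knee
flexion); power on 100 asymmetric cohorts (γ = 0.25, 7 participants,
likewise); and a 12-participant demonstration cohort with 1–2 min
recordings for the headline pipeline run. These sizes give stable
Monte-Carlo estimates (binomial SE ≈ 1.5–4 percentage points) while
keeping a full validation run in minutes on one core.

## Known limitations

* ApEn is biased at short $N$ and sensitive to the $(m, r, \tau)$ choice;
  cross-study comparisons require identical parameters.
* The ACF-based delay makes $\tau$ recording-specific; two recordings of
  the same participant can be embedded at very different delays, which is
  deliberate (it tracks each recording's own correlation structure) but
  means ApEn values are not delay-matched across recordings.
* The side contrasts treat participant-by-dance means as independent
  units; repeated-measures structure (several dances from one participant)
  is not modelled. A mixed-effects extension is out of scope here.
* With both sides generated from identical parameters, the left and right
  series of one simulated recording are independent; real bilateral
  kinematics are mechanically coupled, which the type-I calibration does
  not capture.
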