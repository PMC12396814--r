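---
title: "Dopamine ramps and environmental timescales: models, pipeline, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dopamine ramps and environmental timescales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopramp)
```

## The scientific problem

Mesolimbic dopamine sometimes rises steadily across a trial as reward
approaches — a "ramp" — and sometimes does not, and the conditions that
decide between the two have been contested. `dopramp` packages the two
computational halves of one resolution of that question: (i) a simulator
for a retrospective causal-learning model (ANCCR: Adjusted Net
Contingency for Causal Relations) in which the *inter-trial interval*
(ITI) controls the memory timescale and therefore whether ramps appear,
and (ii) the trial-level fiber-photometry analysis pipeline needed to
measure ramps in head-fixed cue–reward experiments — isosbestic
correction, per-trial ramp-slope regression in time (Pavlovian) or in
virtual distance (VR navigation), and the statistics relating each
trial's slope to its preceding ITI. A synthetic-data generator with
known ground truth makes every stage testable end-to-end without animal
data.

## The model

The model learns by looking *backwards* in time from meaningful events
(e.g. reward) for potential causes. Its memory of event type $i$ is the
eligibility trace

$$E_{i}(t) = \sum_{t_k \le t} e^{-(t - t_k)/T},$$

a sum of exponentials over past occurrences with time constant $T$.
Pairwise memories are running averages of eligibility sampled at events:
at each occurrence of event $j$,
$M_{i \leftarrow j} \mathrel{+}= \alpha\,(E_i - M_{i \leftarrow j})$,
while a baseline memory $\bar M_i$ updates every $dt$ seconds with rate
$\alpha_0$ and so tracks the long-run time average of $E_i$. The
*predecessor representation contingency*
$\mathrm{PRC}_{i \to j} = M_{i \leftarrow j} - \bar M_i$ measures how
much more eligible $i$ is at occurrences of $j$ than on average — the
retrospective association strength.

Two quantities adapt to the environment's timescale, set by the
inter-reward interval (IRI):

* $T = k \cdot \mathrm{IRI}$ with $k = 0.2$: when rewards are frequent,
  memory is short. For the simulated short condition
  ($\mathrm{IRI} = 17$ s) this gives $T = 3.4$ s; for the long condition
  ($\mathrm{IRI} = 64$ s), $T = 12.8$ s.
* $\alpha = 1 - (1 - \alpha_0)^{\mathrm{IRI}/dt}$: the per-event
  learning rate compounds the baseline rate over one IRI of baseline
  samples ($\approx 0.347$ at $\mathrm{IRI} = 17$ s,
  $\alpha_0 = 5\times10^{-3}$, $dt = 0.2$ s).

Both are fixed per condition from the condition's mean IRI; an
`online_iri` flag enables a running-mean update instead, off by default
because trial-by-trial time-constant changes are deliberately not part
of the modelled conditions.

### The dopamine composition layer

The published simulation parameter set this simulator targets
($w = 0.5$, $b_{\text{cues}} = 0$, $b_{\text{reward}} = 0.5$,
threshold $0.2$, $\alpha_R = 1$) does not by itself pin down the
equations that convert contingencies into a dopamine response; those
are defined across the ANCCR literature rather than in any single
parameter table. The package therefore reconstructs that layer from the
parameters' roles, and treats it as correct insofar as it reproduces
the model family's qualitative signatures (the contract tests in
`test-anccr-simulation.R`). The reconstruction:

1. **Prospective conversion.** The retrospective PRC is converted to a
   prospective contingency by a Bayes base-rate correction,
   $\mathrm{SRC}_{i \to j} = \mathrm{PRC}_{i \to j}\,\bar M_j / \bar M_i$,
   and the two are mixed:
   $\mathrm{NC}_{i \to j} = w\,\mathrm{SRC} + (1 - w)\,\mathrm{PRC}$.
2. **Value scaling.** The raw credit of predecessor $i$ toward target
   $j$ is $\mathrm{NC}_{i \to j} \cdot R_j$, where $R_j$ is the target's
   estimated value, seeded by its innate value $b_j$ and updated with
   rate $\alpha_R$ at each occurrence
   ($R_j \leftarrow R_j + \alpha_R(b_j + \text{acquired credit} - R_j)$).
   Only events whose value exceeds the threshold are *meaningful* and
   act as credit targets; reward starts meaningful because
   $b_{\text{reward}} = 0.5 > 0.2$.
3. **Predecessor competition.** Credits are assigned at each meaningful
   event, over its predecessors in order of occurrence: an event's
   credit is reduced by the credit already assigned to events that
   predict *its own* occurrence, weighted by their positive net
   contingency on it. The target's own (self) credit is what its
   predecessors since its previous occurrence leave unexplained.

The competition step is the design decision that required real choice.
An alternative reading — discounting each cue by the credit of events
*interposed* between it and the reward — was implemented first and
rejected: it produces late-cue dominance in the long-ITI condition as
well, contradicting the model family's serial-conditioning behaviour in
which, with a long memory constant, the *earliest* reliable predictor
absorbs the credit. Under predecessor competition both regimes fall out
of the same rule:

* **Short ITI ($T$ small relative to the trial).** Early cues are barely
  eligible at reward, so their net contingency is at or below baseline;
  cues close to reward hold most of the credit. The within-trial
  response profile rises monotonically across the cue sequence — a ramp —
  and the cue-onset response is slightly negative (a known divergence of
  the model from experiment at onset, which this package intentionally
  does not correct).
* **Long ITI ($T$ large).** All cues are eligible at reward, and the
  competition concentrates credit on the first cue, each later cue being
  largely explained by its predecessors: a large onset response and a
  flat profile. One caveat is documented and tested as such: events
  immediately adjacent to reward (the last sub-cue and the cue offset)
  retain somewhat elevated credit, so "first cue largest" holds against
  the early/mid cue sequence rather than against every event in the
  trial.

The dopamine response at an event is the sum of its stored credits
toward all meaningful targets, plus the innate value at output for
reward only (configurable via `add_innate_to_reward`; innate values of
cues only seed $R$).

### Simulation structure and numerics

Trials mimic the dynamic-tone condition as 8 distinct sub-cues at 1 s
spacing (a 400 Hz/s frequency change being the assumed discriminable
step), the offset of the last cue as a ninth event, and reward 1 s
later. The reward-to-next-cue gap is drawn from the experimental ITI
distribution (mean 8 s short, 55 s long); its first 6 s are the fixed
consummatory period, so the simulation ITI proper averages 2 s and 49 s
and the IRI averages $9 + 6 + 2 = 17$ s and $9 + 6 + 49 = 64$ s.
Simulations run 1000 trials per condition, 20 independent iterations,
with the last 100 trials analysed.

The engine is event-driven. Eligibility decays lazily between events
(the recursion is property-tested against the brute-force sum to
1e-10). Baseline updates nominally occur on a global $dt$ grid; across
an inter-event gap of $n$ grid samples the EWMA has the closed form
$\bar M' = (1-\alpha_0)^n \bar M + \alpha_0 E_1
\frac{(1-\alpha_0)^n - \rho^n}{(1-\alpha_0) - \rho}$
with $\rho = e^{-dt/T}$, which the engine uses and which is tested
against stepping the grid sample-by-sample. One master seed spawns
per-iteration stream seeds, recorded in the result's attributes.

## The photometry pipeline

The pipeline follows the standard two-channel recipe: a least-squares
fit scales the dopamine-insensitive 405 nm channel to the 470 nm
channel, and $\mathrm{dF/F} = (470 - \widehat{405}) / \widehat{405}
\times 100$. The fit is affine (slope and intercept) by default because
an intercept guards against offset differences between detection paths;
`intercept = FALSE` gives the pure scaling reading. Per trial, the
pipeline reports:

* **onset peak**: max dF/F within 1 s after onset minus the mean over
  the 1 s before;
* **ramp slope**: OLS slope of dF/F against time over the ramp window
  3–8 s after cue onset (excluding onset and offset transients),
  in %dF/F per s, always on the *unsmoothed* trace — Gaussian smoothing
  (`smooth_gaussian`, default $\sigma$ = 2 samples) exists only for
  visualisation;
* **pre-cue slope** over a 2 s window before onset (window length is a
  package default; it is not pinned by the task description), used to
  check ramps are not post-reward recovery;
* **previous ITI** (reward to next cue onset) and **previous IRI**,
  undefined on a session's first trial.

All windows are half-open $[a, b)$ on sample timestamps, so a sample at
exactly the right edge is excluded; this makes binning unambiguous.
Trials whose windows extend beyond the recording are dropped with a
warning rather than raising errors.

For VR sessions, virtual distance (30 ms samples) and dF/F (10 ms
samples) are synced by assigning the mean of every three dF/F values to
the corresponding distance sample; distance samples equal to their
predecessor are dropped together with their dF/F (stationarity guard),
and the ramp slope is fit over 20–57 cm of the 67 cm hallway
(%dF/F per cm). Per-centimetre binned means (`bin_by_cm`) serve
visualisation. Velocity is the first difference of 50 ms distance
samples; onset velocity change and pre-reward velocity use the 1–2 s
post-onset and 1 s pre-reward windows respectively.

One numerical caveat is worth stating precisely: when the synthetic
generator injects a known multiplicative dF/F signal and the session is
noise-free, recovery through the full pipeline is limited by the
isosbestic fit itself — the injected signal is not exactly orthogonal
to the span of the 405 channel and a constant, so the affine fit leaks
a small fraction of it into the baseline. Under the default bleaching
constants this leakage perturbs recovered ramp slopes by well under 1%
of their true value (asserted in the tests); recovery from the injected
signal itself, bypassing the fit, is exact. On real data the same
mechanism exists and is equally negligible.

## Trial-level statistics

`previous_iti_beta` regresses per-trial ramp slope on the preceding ITI
within an animal; `pooled_zscore_beta` z-scores slopes within animal
(mean 0, SD 1 — removing between-animal mean differences) before
pooling; slopes alone are z-scored, not the ITIs. `delta_iti_analysis`
works on consecutive-trial pairs,
$\Delta\mathrm{ITI}_i = \mathrm{ITI}_{i-1 \to i} -
\mathrm{ITI}_{i-2 \to i-1}$ against
$\Delta\text{slope}_i$, with category means for clear decreases
($< -1$ s) and increases ($> +1$ s). `average_prev_iti_beta` replaces
the single preceding ITI with the mean of the `k_back` preceding ones;
note that under independent ITIs this *dilutes the evidence* (the
regressor's variance shrinks with $k$, inflating the standard error)
while leaving the coefficient unbiased — which is how a single-lag
dependency loses significance under broader averaging, and what the
tests assert.
`filter_iri_outliers` removes values more than 3 SDs from the mean with
both statistics computed once on the original distribution (population
SD, single pass — hence idempotent). Condition contrasts default to
two-sided paired t-tests on per-animal means with $\alpha = 0.05$; the
exact test behind each published comparison is not recoverable from the
text, so the choice is configurable.

First trials (no preceding ITI) are excluded from all ITI-history
analyses. The $\Delta$ITI pairing uses the ITIs *preceding* each trial
of the pair, the quantity hypothesised to drive each trial's ramp.

## The synthetic-data generator

`ground_truth()` fixes every generating parameter; the presets encode
the study conditions: short-ITI sessions of 100 trials (ITIs from the
calibrated truncated exponential on 6–12 s with mean 8 s), long-ITI
Pavlovian sessions capped at 40 trials (6–186 s, mean 55 s), VR
sessions of 50 trials. The short-dynamic preset injects a positive
within-cue ramp whose per-trial slope is
$0.6 - 0.045 \cdot \mathrm{ITI}_{\text{prev}}$ plus Gaussian
trial-to-trial scatter (SD 0.15 %dF/F/s, chosen to match the visible
per-trial slope spread in this kind of recording); long and fixed-tone
presets inject no ramp; long presets use a large onset transient
(4 %dF/F) and short presets a small one (1.5 %dF/F). Amplitude and
timescale choices not printed anywhere (reward transient 3 %dF/F,
post-reward dip −1.5 %dF/F recovering with $\tau = 3$ s, bleach
double-exponentials of minutes-scale $\tau$) are order-of-magnitude
values typical of dLight photometry, recorded in the manifest, and used
only for robustness — never as acceptance quantities.

The raw channels are composed as: 405 = bleaching baseline + noise;
470 = affine function of the clean 405 baseline, multiplied by
$(1 + \mathrm{dF/F}/100)$, plus a small 470-specific drift that the
isosbestic cannot capture, plus noise. Licking is an inhomogeneous
Poisson train (baseline 2 Hz ramping to 6 Hz at the trace period). VR
trials integrate an exponential-rise velocity profile to a 20 cm/s
plateau until the 67 cm hallway ends.

What the generator deliberately does **not** emulate — so passing tests
must not be over-read: sensor binding/unbinding kinetics (kernels are
piecewise linear/exponential, not convolved with indicator dynamics),
hemodynamic or motion artifacts beyond a shared multiplicative term,
session-level nonstationarities such as satiety, and any coupling
between licking and the dopamine signal. Recovery results demonstrate
the pipeline's correctness on data satisfying its assumptions, not the
biological fidelity of those assumptions.

Two statistical subtleties the tests respect:

* The **onset peak** is a max-statistic, so under per-sample noise its
  estimate is biased upward by extreme-value selection; exact recovery
  is therefore asserted only on noise-free sessions.
* For the **null calibration** of the ITI regression (false-positive
  rate at nominal 5%), the null world must actually satisfy the null:
  the post-reward dip is disabled there, because its recovery tail
  inside the ramp window makes the slope genuinely, if weakly, depend
  on the previous ITI — precisely the confound the fixed-tone control
  condition and the pre-cue-slope check exist to address (the generator
  reproduces that confound, and a dedicated test shows the dip alone
  yields a positive pre-cue slope at short ITIs).

## Problem sizes and determinism

The test suite runs the simulator contracts at 400 trials × 2 iterations
and the full published configuration (20 × 1000, last 100 analysed) in
the acceptance tests; sampler calibrations are verified with $10^5$–$10^6$
draws against the closed-form truncated-exponential mean
(root-finding by bisection via `uniroot` to 1e-6 s); parameter-recovery
coverage uses 200 seeded replicates of 300-trial sessions and the null
calibration 200 replicates of 150-trial sessions. Every stochastic step
takes an explicit seed, and generators re-derive their streams from the
seed recorded in the ground-truth manifest, which round-trips through a
checksummed JSON file.

## Known limitations

* The dopamine composition layer is a reconstruction constrained by
  printed parameters and qualitative behaviour, not a line-by-line port
  of the companion model; quantitative response magnitudes should not be
  compared against other implementations.
* Event-memory learning uses a fixed per-condition $\alpha$ (or the
  optional running-mean IRI); neither reproduces acquisition-phase
  dynamics in environments whose event rates drift quickly.
* The pipeline assumes a session-wide isosbestic relationship; sessions
  with segment-wise gain changes would need piecewise fitting, which is
  not implemented.
* `distance_align` assumes the 3:1 dF/F-to-distance sample-rate ratio of
  the VR recordings (10 ms vs 30 ms); other ratios must be resampled
  upstream.
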