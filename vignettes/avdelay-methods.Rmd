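---
title: "Audiovisual delay tuning and connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiovisual delay tuning and connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avdelay)
```

`avdelay` analyses sorted extracellular spike trains recorded while visual
and auditory stimuli are presented alone, together, or together at a range
of onset asynchronies (AV delays; positive values mean the visual stimulus
leads).  The package covers the full chain from raw spike/event tables to
population-level conclusions: responsiveness and neuron taxonomy, spatial
receptive fields, AV delay tuning and multisensory interaction indices,
population decoding of AV delay, cross-correlogram connectivity, and a
hierarchical bootstrap for nested data.  Every stage can be exercised
against a seeded synthetic spike-train generator with known ground truth,
which is itself part of the package's tested surface.

All times are milliseconds on the session clock; all histograms use
left-closed, right-open bins; every stochastic routine takes an explicit
seed and is reproducible bit for bit.

## The synthetic session generator

Spike trains are drawn from an inhomogeneous Bernoulli process at 1 ms
resolution.  For neuron $i$ and bin $t$ the spiking probability is

$$ p_i(t) = \tfrac{1}{1000}\Big[\, b_i \, e(t) + V_i(t) + A_i(t - d)
   + g_i \, w(d - d^*_i)\, B_i(t - d) \,\Big]^+ $$

with $b_i$ a lognormal baseline rate (median 5 spikes/s), $V_i$ and $A_i$
Gaussian evoked kernels, $e(t)$ an optional shared slow rate envelope, and
the last term a multisensory interaction component present only on AV
trials of bimodal and gated neurons: a Gaussian bump locked to the onset of
the completing (auditory) stimulus at a neuron-specific interaction latency,
with amplitude tuned to the AV delay $d$ through a Gaussian
$w(\cdot)$ of width $\sigma_d$ (default 15 ms) centred on the neuron's
preferred delay $d^*_i$.  After the independent per-bin draws, each planted
connection copies presynaptic spikes into the postsynaptic train at an
integer lag of 1--5 ms with probability equal to its efficacy, so
spike-transmission probabilities are exact at the correlogram's 1 ms
resolution.

Choices worth spelling out:

* **Protocols.** The visual-leading delay protocol presents 100 ms stimuli
  at AV delays 0--100 ms in 10 ms steps plus unisensory visual, unisensory
  auditory and blank conditions, 50 repetitions each, in randomised blocks.
  The receptive-field protocol presents 5 elevations (−36° to 36°) by 7
  azimuths at 18° steps, 25 repetitions per modality.  (A 7-point azimuth
  grid at 18° steps spans 108°, so the grid runs −162° to −54°; the
  contralateral hemifield is negative.)  The auditory-leading protocol uses
  negative delays at 25 ms steps.  The inter-onset interval defaults to
  3 s and is configurable, but must stay at 2 s or more so the 1--2 s
  post-onset correlogram window never overlaps the next trial.
* **Class mix.** The default population is 16% visual, 14% auditory,
  10% bimodal, 16% gated and 44% non-responsive, matching the reported
  taxonomy.  Gated neurons have no unisensory kernels; their multisensory
  kernel amplitude is drawn from the same lognormal distribution as the
  other evoked amplitudes.
* **Latencies.** Onset latencies are drawn lognormally around medians of
  69 ms (visual) and 21 ms (auditory) and clipped to the onset windows.
  The full latency distributions are not specified by the protocol, so the
  lognormal is a modelling choice, not a claim.  On top of the per-neuron
  latency, every trial jitters each pathway's latency by a rounded Gaussian
  (SD 5 ms): single trials of real evoked responses do not repeat at fixed
  latency, and several estimator choices below exist precisely because of
  this.
* **Interaction family.** Only the phenomenon is constrained by data
  (supralinearity peaked at the preferred delay), not a mechanism.  Any
  family monotone in a gain parameter that can reproduce a target
  interaction index works; ours uses an auditory-locked bump because a
  multisensory response tracks the completing stimulus, and because the
  family is invertible: `generate_session()` solves the gain $g_i$ by root
  finding so that the *expected, measurable* MII at $d^*_i$ (computed on
  the jitter-convolved noiseless rates with the same peak-window rules as
  the estimator) equals the configured target.  The default target, 0.33,
  is the reported median MII at the preferred delay.  A literal product of
  the V and A kernels was rejected: it vanishes whenever $d^*$ is far from
  the kernel-alignment delay, making most target indices unreachable.
* **Slow envelope.** For correlogram work the generator can impose a
  common multiplicative rate envelope: an AR(1) process on a 10 ms grid
  with a configurable correlation time (at least 50 ms), piecewise constant
  within blocks.  This provides exactly the slow co-modulation that jitter
  correction is meant to remove.

What the generator does *not* emulate: burstiness and refractoriness,
uninstructed body movements, electrode drift, cross-neuron noise
correlations beyond the optional shared envelope, and any dependence of
kernels on stimulus intensity.  Passing parameter-recovery tests on this
model therefore shows the estimators are correct and calibrated under
realistic rates, trial counts and latency jitter — not that they are robust
to every pathology of real recordings.

## Peak firing rate: one statistic everywhere

The single response summary used throughout is the mean firing rate over a
20 ms window.  On a smooth profile this equals "the mean rate in a 20 ms
window centred on the response maximum".  On a sparse 1 ms histogram the
raw argmax is dominated by single-bin coincidences (with 50 trials of a
5 Hz baseline, one bin with three coincident spikes reads 60 Hz), so
`peak_firing_rate()` centres the window on the maximum of the *windowed*
profile, i.e. reports the largest 20 ms centred-window mean, with windows
clipped at the profile edges and ties broken toward the earliest centre.

The permutation tests refine this one step further.  A two-group statistic
built from two separately maximised windows inherits an extreme-value noise
floor (the windowed maximum of a 4 Hz baseline over 250 candidate centres
is about 10 Hz at 50 repetitions), which destroys power exactly where it
matters.  `test_responsiveness()` and `delay_significance_test()` therefore
locate the 20 ms window *once* on the pooled (merged-group) mean profile
and compare group mean rates within that fixed window.  Because the window
is a symmetric function of the merged data, the merge-and-resplit null
remains an exact permutation null; the acceptance suite verifies the 5%
type-I rate on 500 null neurons.

## Responsiveness and taxonomy

Responsiveness per condition is a two-sided permutation test of the
peak-window rate against interspersed blank trials (10,000-fold label
shuffling recommended; the examples use fewer).  This replaces an external
published responsiveness test with a construction that reuses the package's
own peak statistic; `classify_neuron()` accepts externally computed
p-values unchanged if a different test is preferred.  P-values are
Benjamini--Hochberg corrected across the family of conditions tested for
that neuron (V, A, and each AV delay), and the taxonomy is: visual (only V
significant), auditory (only A), bimodal (V and A), gated (only
multisensory conditions), else non-responsive.  For gating, the summary
p-value over AV conditions is the minimum BH-adjusted p over the 11
delays — the family choice is not dictated by the protocol and is exposed.

Unisensory latency is the left edge of the argmax bin of the 1 ms PSTH
over [0, 250) ms; response phase is assigned by fixed windows (visual
onset 0--128 ms, offset 129--250 ms; auditory onset 0--76 ms, offset
77--250 ms).  The windows are constants rather than re-derived per dataset
by density estimation; they can be overridden.

## Delay tuning

For each neuron the preferred unisensory condition is whichever of V or A
has the larger peak rate.  Each AV delay is tested against it by merging
the two trial sets and re-splitting at random into groups of the observed
sizes, 10,000 times; the delay is significant if the observed difference
falls outside the null's 2.5th--97.5th percentiles.  The test is two-sided
as specified even though "exceeds unisensory" is one-sided; delays that are
significant but *below* the unisensory peak are flagged and excluded from
the preferred-delay argmax (ties break toward the smaller delay).

The indices are: specificity $SI = 1 - \mathrm{sig}/N$ over the 11 delays;
firing-rate modulation $(AV_{max} - AV_{min})/(AV_{max} + AV_{min})$ with
$AV_{max}$ the preferred delay's peak; reliability, the mean pairwise
Pearson correlation across repetition response vectors (10 ms bins over
[0, 250) ms by default — the binning is not specified by the protocol and
is configurable).  Pairs containing a zero-variance repetition contribute
$r = 0$ rather than being dropped, keeping the index defined for sparse
responders; the count of such pairs is attached.  Chance reliability
resamples windows of identical geometry at uniform session times avoiding
stimulus-evoked periods.

The multisensory interaction index is
$\mathrm{MII} = (AV - (A+V))/(A+V)$ on peak rates, where the $A+V$ peak is
taken on the shifted-sum profile: the auditory PSTH shifted by the delay
and added to the visual PSTH after subtracting the auditory baseline (mean
rate in [−200, 0) ms), undefined shifted bins taking the baseline.  MII
above 0.5 is supralinear, below −0.5 sublinear, strict inequalities.
Gated neurons are excluded by the $A+V > 0$ precondition (their unisensory
profiles are baseline-only, and subtracting the baseline leaves nothing to
sum).  At strong planted gains the estimated MII is biased a little toward
zero — both measured peaks carry a small positive sampling inflation that
cancels in the numerator but not in the denominator — which is a property
of the estimator at 50 trials, shared by any reimplementation of it.

The linear-sum predicted preferred delay scans the tested delays and
returns the one whose shifted-sum profile has the largest peak.

## Receptive fields

An axis-aligned 2D Gaussian with offset is least-squares fitted
(box-constrained quasi-Newton) to the peak rates on the 5 × 7 grid,
initialised at the rate-weighted centroid with 18° widths; centres are
constrained to the grid extended by one step.  A rotation term is omitted
on a 35-point grid.  Alignment between modalities is the Pearson
correlation of converged fit centres, per axis, at neuron and session
level; session-level 90% confidence ellipses use the chi-squared quantile
with 2 degrees of freedom (the elliptical rather than per-axis reading of
a 90% region).  Pairwise multisensory signal correlation is the Pearson
correlation of two neurons' 35-point AV response maps.

## Connectivity

Correlograms are computed on 1 ms binary bin trains from the 1--2 s
post-onset window of every trial (spontaneous activity; the trial filter
is configurable), concatenated across repetitions:

$$ CCG(\tau) = \frac{\frac{1}{M}\sum_i \sum_t x_1^i(t)\, x_2^i(t+\tau)}
   {\theta(\tau)\sqrt{\lambda_1 \lambda_2}}, \qquad
   \theta(\tau) = N - |\tau| $$

with $M$ trials, $N$ bins per trial and $\lambda$ the in-window mean
rates.  The corrected correlogram subtracts the expectation under spike
relocation within fixed, non-overlapping 10 ms windows
($CCG_{corrected} = CCG - CCG_{jittered}$).  The relocation expectation
has a closed form — a spike pair's offset distribution is the convolution
of two discrete uniforms, a triangle across the window offset — used by
default; Monte-Carlo resampling (`jitter = "resample"`) is retained and
equivalence-tested.  Support is ±25 ms so the 10--15 ms noise band (12
lags, both tails pooled) fits with margin.

A pair is a putative connection when the corrected peak within ±5 ms
exceeds five noise-band standard deviations and sits at a lag of 1--5 ms;
the earlier-firing neuron is presynaptic, and the peak height is the
interaction strength.  Significant peaks at exactly 0 ms are recorded
separately as shared-input pairs.  Neurons enter the analysis if
responsive to any stimulus, or non-responsive with baseline at least
10 spikes/s.  The false-positive rate is estimated by assembling, for each
session, a surrogate population of neurons drawn from *other* sessions
matched on the dorso-ventral depth histogram (13 × 150 µm bins), aligning
trials by index, and re-running detection.  The trend of connection
probability with receptive-field similarity uses equal-count correlation
bins, a Cochran--Armitage statistic with the per-bin mean correlations as
scores (bin centres vs indices is not specified; scores are exposed), and
a within-session permutation null with the add-one p-value
$(k+1)/(n+1)$.

## Population decoding

Features are per-neuron spike counts in 10 ms bins over [0, 250) ms
(window configurable; the span is not specified by the protocol) on single
trials.  Class sets combine the 11 AV delays, V, A, blank, and ten
shifted-auditory controls built by translating unisensory auditory trials
to the auditory onset time of each delay (delay 0 would duplicate A and is
not generated).  Linear-sum synthetic AV trials add a visual trial to a
time-shifted auditory trial under a seeded random bijection, minus the
neuron's expected baseline counts so the baseline is not counted twice.
Within one session, rows are true simultaneous trials; across sessions,
pseudo-trials permute repetition indices per neuron within class — the
field-standard construction, isolated in one operation so it can be
replaced.

The linear classifier is a one-vs-rest maximum-margin machine with a
precomputed linear Gram matrix (C = 1, raw counts; both exposed since
neither is specified), the nonlinear alternative a random forest.
Training uses a stratified 80/20 split with optional 5-fold
cross-validation inside the training portion; the headline accuracy is the
percentage of correctly classified AV-delay trials in the held-out 20%.
`nonlinearity_benefit()` runs the observed-versus-linear-sum comparison
with both decoders scored on the same five disjoint held-out folds of the
observed trials (the linear-sum decoder never sees observed trials, so it
is fitted once on the full synthetic set).  On delay-selective synthetic
populations with strongly supralinear planted gain (target MII 1.5, and
the 35/65 bimodal/gated composition implied by the reported taxonomy and
delay-modulated fractions), the observed-trained decoder beats the
linear-sum decoder by about 30--40 percentage points, because most of the
pool's delay information lives in the gated neurons' multisensory
responses, which the linear-sum construction cannot contain.  With the
gain switched off the gap collapses, though not exactly to zero: summing
two recorded trials doubles the trial noise and reuses each auditory trial
across classes, which costs the linear-sum decoder a few points even when
the data are perfectly linear.  The same residual is intrinsic to the
construction on real data.

## Hierarchical bootstrap

For statistics pooled over nested recordings, resampling draws animals
with replacement, then sessions within each drawn animal, then units
within each drawn session, with resample sizes equal to the observed
counts at each level (the standard convention; sizes are not specified).
The two-sided p-value is $P = 2\min(q, 1-q)$, floored at $2/(n_{boot}+1)$,
where $q$ is the mid-rank quantile of the null value (default 0) within
the bootstrap distribution of the statistic.  Taken literally, "quantile
of the observed statistic within the bootstrap distribution" would always
be about 0.5, since the distribution is centred on the observed value; the
percentile-test reading used here is the standard construction that the
worked examples ($q = 0.975 \Rightarrow P = 0.05$) imply.  The statistic
is caller-supplied (mean, median, a correlation, ...) because different
analyses summarise differently.  With one animal and one session the
procedure reduces to a flat bootstrap over units, and under an
exchangeable null the rejection rate at the 5% level stays at or below 7%
(it is in fact conservative with two animals).

## Problem sizes used by the tests

The test-suite and the acceptance script exercise the pipeline at the
protocol's repetition counts (50 trials per condition, 25 for the RF
grid) with populations of 40--500 neurons, 2,000-fold resampling for the
delay tests and 1,000-fold for the bootstrap calibration, and two
replicate populations per decoding contrast — sizes chosen so each
property is measured with useful precision while a full run stays
comfortably on a laptop.

## Known limitations

* The permutation responsiveness test is less sensitive than dedicated
  responsiveness statistics for sustained, low-amplitude responses.
* Inhibitory (negative-peak) correlogram features are not detected.
* The linear mixed-effects analyses relating indices to anatomy are out of
  scope; the per-neuron tables exported by the pipeline are their input.
* The generator's Bernoulli bins cap instantaneous rates at 1000 Hz and
  collapse duplicate spikes within a bin, so planted transmission
  probabilities are approached slightly from below at high rates.
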