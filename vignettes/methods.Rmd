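---
title: "Simulating and analysing somatosensory temporal discrimination EEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing somatosensory temporal discrimination EEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdtsim)
```

## The scientific problem

When two brief electrical pulses are delivered to the median nerve in
rapid succession, they are felt as a single pulse at short
interstimulus intervals (ISIs) and as two pulses at long ones. The ISI
at which "felt as two" reaches 50% is the somatosensory temporal
discrimination threshold (STDT). Because the physical stimulus can be
held constant at the threshold while the percept varies
trial-by-trial, this paradigm isolates the neural correlates of a
perceptual *content* (one versus two) from stimulus confounds. The
package simulates every stage of such a study — psychophysical
calibration, a report-dissociating matching task, evoked-potential
generation — and implements the analysis chain up to cluster-level
family-wise-error (FWE) corrected spatiotemporal inference, so the
whole pipeline can be validated against ground truth that real data
never provide.

## Observer model

An observer is a two-parameter logistic psychometric function

$$p(\text{two} \mid \mathrm{ISI}) \;=\; \frac{\lambda}{2} + (1-\lambda)\,
\frac{1}{1 + e^{-(\mathrm{ISI} - T_{50})/s}},$$

with threshold $T_{50}$ (ms), scale $s$ (ms; the slope at threshold is
$(1-\lambda)/4s$ per ms) and a lapse probability $\lambda$ that
defaults to 0, reproducing the plain two-parameter model. The lapse
term exists only so that imperfect low/high-ISI behaviour — the
pathology that drives the fitted 1% threshold $T_{01}$ negative in
some participants — can be generated on demand; it is a modelling
stand-in, not a claim about mechanism. The derived thresholds obey
$T_{01} = T_{50} - s\ln 99$ and $T_{99} = T_{50} + s\ln 99$, hence
$T_{99} = 2T_{50} - T_{01}$ identically.

Cohorts draw $T_{50}$ log-normally. A log-normal is the natural choice
for a positive, right-skewed threshold distribution, and its shape
parameter is pinned by the published population median (30.38 ms) and
mean (45.19 ms) through $\sigma = \sqrt{2\ln(\text{mean}/\text{median})}
\approx 0.89$; the population SD is then implied rather than enforced
separately (it comes out close to, but not exactly at, the printed
value — a documented approximation). The scale parameter is log-normal
around 8.28 ms, the value implied by the population $T_{01}$/$T_{99}$
span, and detection thresholds are normal with mean 2.425 mA — half
the reported doubled stimulation intensity.

## Calibration chain

*Detection staircase.* Ascending from 1 mA in 0.1 mA steps until the
pulse is felt, then halving the step at every reversal, for three
ascending and three descending progressions. The threshold read-out is
not uniquely determined by that description; we use the mean of the six
reversal values, standard psychophysics practice that is exactly
testable: for a deterministic observer the whole trace is a hand
computable sequence, and the estimate lands within 0.05 mA of any
threshold in the 1.2–5 mA range. Responses at exactly threshold count
as "felt" (inclusive boundary, with a 1e-9 mA tolerance absorbing
floating-point step accumulation). Stimulation intensity is twice the
estimate.

*Initial STDT staircase.* Three ascending series (from 2 ms, +5 ms
steps, stopping at the first "two") interleaved with three descending
series (from 120 ms, −5 ms, stopping at the first "one"); the
estimate is the mean of the six stopping ISIs. Series starting points
and step size are not uniquely specified by the protocol wording;
these defaults are fixed in configuration. When an observer's
threshold exceeds the descending start (so the descending series
terminate immediately), the pipeline doubles the descending start and
repeats — emulating what an experimenter adjusting the procedure would
do. The estimate is floored at 3 ms before building the calibration
grid, which needs a centre above 2 ms.

*Psychometric session and fit.* Fifteen ISIs, linearly spaced with the
initial estimate as the 8th value and 2 ms as the lowest (20
repetitions each, 300 trials). The logistic is fitted by binomial
maximum likelihood (box-bounded quasi-Newton on $(T_{50}, \log s)$,
with $s \in [0.5, 1000]$ ms). The bounds matter only in degenerate
sessions: perfectly separated responses drive the unbounded MLE of
$s$ to 0, and flat responses drive it to infinity with catastrophic
cancellation downstream; the bounds pin such fits at usable values
without affecting regular ones. The reported mean squared error
between observed and fitted per-ISI proportions is a post-fit
diagnostic, not the fitting criterion — the protocol wording does not
say which was minimised, and likelihood is the defensible choice for
binomial counts.

*Main-experiment design.* Ten equally spaced ISI levels spanning
$[T_{01}, T_{99}]$. If $T_{01} < 1$ ms, the minimum is set to 1 ms,
the maximum reduced by the same amount $\Delta = 1 - T_{01}$, and the
levels shifted symmetrically toward the STDT: in both branches the
level midpoint equals $T_{50}$ exactly (the shifted upper edge is
computed as $2T_{50} - 1$, the numerically stable form of
$T_{99} - \Delta$). Per run, 200 trials are allocated over the levels
as 8, 13, 20, 27, 32, 32, 27, 20, 13, 8: the outer (8) and central
(32) counts are fixed anchors, and the interior counts follow a
normal density centred between levels 5 and 6 whose width is pinned by
the anchor ratio, with largest-remainder rounding. No simple rounding
of a normalised discretised normal reaches both anchors, so the
anchors are treated as constraints — the allocation is reproduced
exactly, and the derivation documents the "normal distribution of
trial numbers" reading.

## Matching task

Each trial couples the tactile double pulse with a visual cue that
announces "two" (white disk) or "one" (dark disk), drawn 50/50
independently of the ISI. The participant reports whether the percept
*matches* the cue. Because the cue is independent of the stimulus,
the overt match/mismatch report carries no information about the
percept: $P(\text{match}) = \tfrac12$ at every ISI, and percept and
report are statistically independent by construction. The default
reporter is error-free (participants passed a high-accuracy screen); a
symmetric report-error rate is available for robustness studies.
Reaction times are log-normal with identical parameters for both
percepts (the study found no evidence of a difference), and 2.1% of
trials are missed and excluded from all analyses. Near-threshold
("STDT") trials are selected per run as the single ISI level closest
to that run's fitted threshold, ties going to the lower level.

## Behavioural statistics

Reaction-time differences use the JZS Bayes factor: a Cauchy prior
(scale $\sqrt2/2$, the conventional default — the underlying test is
cited without its prior scale) on the standardised effect, evaluated
by numerical integration over the variance-scaling parameter. The
percept-report association uses the Gunel–Dickey joint-multinomial
Bayes factor with unit Dirichlet concentration: independence and
saturated marginal likelihoods are closed-form Dirichlet normaliser
ratios. Both choices are parameterised, since the exact prior
conventions of the original analyses are not recoverable. Tests
cross-check the JZS integral against an independent quadrature over
the effect-size prior using the non-central t density, and the
contingency BF against a Monte-Carlo Dirichlet marginal-likelihood
estimate. Evidence labels follow the conventional bins: BF in
$[1,3)$ negligible, $[3,20)$ positive, $[20,150)$ strong, $\ge 150$
very strong.

## Synthetic EEG

Sixty-four scalp channels (idealised extended 10–20 geometry,
azimuthally projected into the unit disk) plus vertical and horizontal
EOG. Evoked components are separable Gaussians in space (around a peak
electrode) and time (around a peak latency): P50 (50 ms, CP4), an
early N140 (120 ms, C6, negative), P170 (170 ms, FC2) and P300
(300 ms, CPz). Only the P170 is percept-dependent: its "felt as two"
amplitude exceeds "felt as one" by $\delta$, so the injected
condition difference is a single fronto-central component whose
maximum falls inside the 129–178 ms window of interest. Component
widths are not reported quantities; the defaults (temporal
$\sigma$ 10–60 ms, spatial $\sigma \approx 0.25$ of the head radius)
are tuning choices and flagged as such.

Noise is spatially mixed $1/f$ (exponent 1) with a 10 Hz alpha bump,
8 µV per channel per trial. The default $\delta = 2$ µV together with
90 near-threshold trials per condition per subject and a
between-subject amplitude scaling SD of 0.2 was fixed by an a-priori
power analysis: the per-subject contrast SNR at the peak voxel is then
$d \approx 1.6$, which gives a 12-subject one-tailed cluster test
power above 0.8. The study this emulates did not report its effect
amplitude in µV, so the choice is the generator's own, made once.

Blinks are stereotyped 300 ms bumps added to the vEOG (200 µV) and,
scaled by a frontally weighted topography, to the scalp. Continuous
2048 Hz generation exists to exercise the full preprocessing chain;
epoched 512 Hz generation is the fast default.

What the generator does *not* emulate: non-Gaussian artifact
distributions, non-stationary drift, volume-conduction physics (no
dipoles or head model — source analysis is out of scope), latency
jitter differences between conditions (available but off by default),
and any dependence of reaction time or miss rate on the percept.
Passing tests therefore demonstrate correctness of the *pipeline*
under a known generative model, not robustness to everything real
recordings contain.

## Preprocessing

The chain runs high-pass (0.01 Hz) → notch (48–52 Hz) → downsample to
512 Hz → common-average reference → blink removal → epoching
(−100…600 ms; at 512 Hz exactly 359 samples, indices −51…307) →
artifact rejection with bad-channel interpolation → 40 Hz low-pass →
baseline correction (−100…0 ms). All filters are zero-phase
Butterworth (forward–backward): first-order high-pass, order-2
band-stop, order-4 low-pass — effective orders double after the two
passes; exact orders are pinned in configuration because the original
report does not state them. The 0.01 Hz high-pass is deliberately
first-order in transfer-function form: its normalised corner
($\sim 10^{-5}$) makes higher-order designs numerically fragile.

Visual artifact inspection is replaced by a deterministic
peak-to-peak criterion (150 µV default) — automation requires it.
Channels bad on more than 20% of trials (per run when run labels are
present) are interpolated by inverse-distance weighting over up to six
nearest scalp neighbours, a documented approximation to
spherical-spline interpolation. Blink removal detects vEOG threshold
crossings (80 µV, 0.5 s refractory period), averages the scalp
pattern at the peaks into a template topography, and projects that
rank-1 spatial component out of the scalp data.

Channel data are linearly interpolated per time sample onto a 32 × 32
grid covering the unit-disk bounding box — barycentric interpolation
on a Delaunay triangulation, which reproduces electrode values exactly
and is exact for affine fields. Cells outside the electrode convex
hull are masked (the mask is identical for every subject sharing a
layout). The per-trial result is a 32 × 32 × 359 scalp-space volume;
the exact scalp-projection convention of the original analysis
software is not recoverable, so the grid geometry is pinned by
configuration.

## Group inference

First level: per-voxel regression of per-trial volumes on the two
percept indicators. For that dummy design the least-squares solution
*is* the pair of condition means, so the contrast equals the ERP
difference at machine precision — an identity the tests assert.
Second level: per voxel, $y = \beta_0 + \beta_1(\mathrm{STDT} -
\overline{\mathrm{STDT}}) + \varepsilon$ across subjects, with the
one-tailed t statistic for $\beta_0 > 0$ on $n-2$ degrees of freedom.
One-tailed is the directional reading of the positive-going
fronto-central effect; a two-tailed mode exists.

Cluster inference replaces the original random-field-theory FWE
correction with sign-flip permutation — implementable exactly,
assumption-light, and testable by simulation — while keeping the
cluster-defining threshold $\alpha = 0.001$ (one-tailed). Clusters are
face-connected components (6-connectivity over grid x, grid y and
time; the original connectivity convention is not stated).
Covariates are handled Freedman–Lane style: subject contrasts are
residualised against the centred covariate(s), the residuals are
randomly sign-flipped, and the full-model t-map is recomputed; the
null distributions of the maximum cluster extent and maximum peak t
give corrected p-values with the permutation floor
$1/(n_\text{perm}+1)$. Control variants mirror the original
analyses: a run-drift covariate (per-subject mean selected ISI level)
added to the model, and a median-split of the cohort at 30 ms analysed
per subgroup.

## Numerical and scale choices

Simulation sizes are chosen so the full validation suite runs on a
single CPU: the default pipeline profile uses 12 subjects and 2 runs
(per-run structure intact at 200 trials over 10 levels), group
simulations for FWE calibration use 200 experiments of 12 subjects
with 200 permutations each, and power checks use 50 simulations.
Group-level simulations draw each subject's contrast directly as
delta-field + averaged-noise difference, which is distributionally
identical to averaging the corresponding number of Gaussian-noise
epochs (averaging is linear) and keeps those loops tractable; the
trial-level route exists and is verified to agree in the noiseless
limit and in variance. Seeds are hierarchical (master → subject →
stage), so any subject is independently re-simulable and every run is
bit-reproducible.

Known limitations: FWE calibration is asserted at the simulation
scale above (Monte-Carlo error ~1.5 percentage points at 200
experiments); the permutation scheme's covariate handling is the
standard approximation, not an exact test; the EDF writer quantises to
16 bits over a 1%-widened per-channel range; and the log-normal
cohort reproduces the published central tendency but not every moment
of the empirical threshold distribution.
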