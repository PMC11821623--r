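---
title: "Models and methods behind prlerp"
author: "prlerp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prlerp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(prlerp)
```

`prlerp` simulates a two-alternative probabilistic reward-learning task
with EEG, and analyses it: behavioural strategies, a cleaning pipeline
from raw epochs to per-condition ERP measures, and the group statistical
battery. This vignette explains the generative models, the analysis
conventions, the tunable parameters with their defaults and rationale,
and the design decisions taken where several choices were defensible.

## The task model

A session runs `nBlocks = 20` blocks of `trialsPerBlock = 18` trials
(practice mode: 2 blocks). Within a block, one of the two stimulus
categories (face, house) is the *set winner*, drawn uniformly per block;
winner placement (left/right of fixation) is re-randomised every trial.
Choosing the set winner yields gain feedback with probability
`pRewardWinner = 0.77`; choosing the other category yields gain with
`pRewardNonwinner = 0.23`.

Two points in this design were genuinely open and are configurable:

* **The non-winner contingency.** A fully deterministic loss for
  non-winner choices would make half the choice space non-probabilistic,
  so the default is the symmetric complement `1 - 0.77`; any value in
  [0, 1] can be set when the complementary-vs-deterministic intent
  matters for a study.
* **Block-boundary transitions.** The set winner changes at the block
  boundary and the block break is explicit, so strategy transitions do
  not cross blocks: the final trial of each block carries
  `strategy_next = "none"` and the first trial of each block has no
  incoming transition label.

### Agents

* `wsls` — repeats a rewarded choice with `pStayAfterWin` and abandons an
  unrewarded one with `pShiftAfterLoss`. With both set to 1 and the
  complementary contingency, the choice process is a two-state Markov
  chain whose stationary set-winner rate equals `pRewardWinner` — the
  closed-form oracle used in the tests.
* `rescorla_wagner` — delta-rule values
  `q[c] <- q[c] + alpha (r - q[c])` with softmax choice
  `P(c) ∝ exp(beta q[c])`. Values reset at block boundaries (the winner
  changes and the break is explicit). The learner-group defaults,
  good = (α 0.25, β 3) and poor = (α 0.06, β 1.8), were fixed once by a
  coarse grid so the groups land near 73% and 56% overall set-winner
  choices — the accuracy regime the task is designed to produce in good
  and poor preadolescent learners — and give cleanly separable
  behavioural learning rates.
* `random` — side-biased coin flip (`sideBias`, default 0.5), the
  chance-level reference.
* `oracle` — always chooses the set winner; a diagnostic agent that
  exposes the feedback contingency directly.

Reaction times are a descriptive log-normal column (median ≈ 670 ms);
no generative RT model is claimed.

## The synthetic EEG model

### Montage

True geodesic sensor coordinates are proprietary, and no analysis here
depends on exact geometry beyond laterality, neighbourhood structure, a
designated outer ring and the mastoid pair. `hydrocelMontage()` therefore
builds a deterministic unit-sphere layout for E1..E128 plus the vertex
E129 that preserves: the named ROI channels (frontal E10/E11/E16;
centro-parietal pairs E37/E87, E31/E80, E53/E86, E60/E85, E67/E77,
E61/E78, E54/E79 with midline E129/E55/E62/E71; occipital pairs E50/E101
and E58/E96), a left/right homologue pairing covering every lateralized
channel, a 24-channel outer ring at the lowest elevation, and the
mastoids E57/E100. The vertex E129 is synthesized as an ordinary
signal-carrying channel; in a recording referenced online to the vertex
it would be flat until re-referencing, so its inclusion in the midline
P300 ROI is kept configurable by subsetting the montage.

### Components

Each injected component is a raised-cosine bump confined to its
measurement window and normalised so that its mean over the in-window
samples (closed-open window on the sample grid) is exactly the requested
amplitude. This makes noise-free recovery exact by construction, which
the tests exploit: measurement error then comes only from noise,
filtering and resampling, never from the injection itself.

* RewP: on the frontal ROI, window 275–375 ms post-feedback; the gain
  bin carries the bump and the loss bin none, so the gain-minus-loss
  difference equals `rewpDiffByGroup[group]`. Defaults: poor +2 µV,
  good −1 µV — poor learners show the larger (and good learners an
  inverted) reward positivity.
* P300: on the centro-parietal ROI, 400–600 ms, amplitude
  `p300ByCell[(feedback, next-trial strategy)]`. Defaults 4/5/5/6 µV:
  two 1 µV main effects (loss > gain, switch > stay), zero interaction.
  Block-final trials (no next trial) receive no P300 bump and are
  excluded from strategy bins.
* N2pc: on the occipital channels contralateral to the chosen side,
  175–225 ms post-cue, default −1.5 µV; and `n2pcWinner` contralateral
  to the set-winner side, default 0 (no winner-driven shift).

A mechanical consequence worth stating explicitly: because choices
correlate with the set winner in a learning agent, a chosen-side
injection *leaks* into the winner-referenced contra-ipsi measure in
proportion to `2 P(choose winner) − 1` (about −0.4 µV at 64% accuracy
with the defaults). The winner-referenced null therefore only holds
exactly under unbiased choice, and the recovery harness evaluates that
null on an unbiased-choice probe cohort, where the chosen-side component
cancels by symmetry. This is a property of any generator that ties
attention to the upcoming choice, not an implementation artifact.

### Background activity

The noise model is `pinkSd` (default 12 µV) of 1/f activity with
exponent `pinkSlope = 1`, of which a fraction `spatialShared = 0.8` of
the variance is a single epoch-wide field common to all channels, plus
`noiseSd = 8` µV white sensor noise, line noise (`lineAmp = 1` µV at
60 Hz with per-channel amplitude scatter and per-epoch phase), blink
transients (rate 0.05/epoch, 120 µV, anterior-weighted), and optional
faulty channels (flat or high-noise, drawn outside ROIs and mastoids).
Totals of ~14 µV per sample give single-trial excursions of ±40–60 µV
after band-limiting, a realistic regime for paediatric EEG.

Two deliberate simplifications:

* The 1/f component is band-limited to `pinkMaxHz = 45`; above that the
  background is white. The analysis band ends at 30 Hz, so the
  measurement pipeline cannot distinguish the two, and the band-limited
  model lets the generator synthesize the coloured part through a small
  Fourier basis (one BLAS multiply per epoch batch) rather than
  per-channel FFTs.
* The strong spatial coherence (80% shared variance) is what real EEG
  background looks like at these scales and is load-bearing in two
  places: it is what mastoid re-referencing removes (the shared field is
  common to the mastoids), and what the low-correlation bad-channel
  criterion presumes when comparing a channel against its neighbours.

What the generator does **not** emulate: volume conduction from dipolar
sources (no forward model — component topographies are indicator maps on
ROI channels), subject-level amplitude variability (every subject in a
group carries the group amplitude; between-subject variance in measures
arises only through noise and trial counts), ocular artifacts with
realistic propagation (blinks are anterior-weighted bumps), and
continuous recordings (epochs are generated directly; epoch extraction
is exercised on small synthetic continuous records in the tests).
Passing recovery tests therefore demonstrates that the *pipeline*
measures what was injected at realistic noise — not that the generator
spans real-data variability.

## The cleaning pipeline

Stage order in `runAnalyze()`: outer-ring removal (24 channels) →
optional bad-channel detection and whole-record spherical-spline
interpolation → resampling to 250 Hz → 0.1–30 Hz band-pass → optional
60 Hz notch → mastoid re-referencing → −200..0 ms baseline →
trial-by-trial rejection → binning and measurement.

Numerical choices, each of which was verified by a dedicated test:

* **Resampling** is FFT-domain spectrum truncation: exact for
  band-limited content, duration-preserving, no pass-band ripple (a
  10 Hz tone survives 1000→250 Hz within 0.1%).
* **Filtering** is an order-4 Butterworth high-pass at 0.1 Hz and an
  order-4 low-pass at 30 Hz, each applied forward and backward
  (zero-phase, so component latencies are not shifted; the magnitude
  order effectively doubles). Epoch-wise zero-phase filtering needs care
  at the edges: the implementation uses mirror padding plus steady-state
  initial conditions anchored at the epoch mean, so a constant maps to
  zero through the high-pass to machine precision and a 60 Hz tone is
  attenuated by ~60 dB in the epoch interior. The high-pass runs first
  because its ~10 s time constant would otherwise smear the low-pass's
  edge transients across a 1.2 s epoch.
* **Bad channels**: flat for > 5 s (on the concatenated-epoch view),
  line-noise power ratio > 4 robust SDs above the montage median
  (median/MAD, so a single contaminated channel cannot mask itself),
  or correlation < 0.8 with the mean of its 8 nearest neighbours.
* **Trial-by-trial rejection**: a channel is flagged within an epoch by
  peak-to-peak > 100 µV in 200 ms windows sliding by 20 ms (computed on
  20 ms chunk extrema), |V| > 150 µV, or epoch log-variance more than
  3 SDs above the channel's own distribution (local) or the all-channel
  distribution (global). At least 10 flagged channels rejects the epoch;
  1–9 are spherical-spline interpolated for that epoch only. The
  threshold is "at least 10" where two readings were possible;
  rejection ⇔ flagged count ≥ 10 is asserted as an invariant.
* **Spherical splines** (stiffness m = 4, 20-term Legendre series, small
  ridge) reproduce spatially constant fields exactly — the standard
  correctness check for the constant-plus-kernel formulation — and
  low-order fields to < 0.01 µV on this montage.
* **Windows** are closed-open `[t0, t1)` on the sample grid everywhere
  (baseline, ROI means, N2pc), so adjacent windows never share samples.
* The N2pc measurement window defaults to 175–225 ms; the wider 175–275
  ms variant used for some group contrasts is selectable
  (`pipeline$n2pcWindow`), in which case the injected 175–225 ms bump is
  diluted by exactly the in-window sample ratio.

## Behavioural analysis

Strategy labels partition all within-block transitions into win-stay /
win-shift / lose-stay / lose-shift. Two denominator conventions exist
for WS/LS proportions: *conditional* (WS over previous-gain transitions,
LS over previous-loss transitions) and *n_minus_1* (both over the total
transition count). The conditional form is the default — it is the
standard WSLS usage and what "proportion given a previously rewarded
trial" means — while the N−1 form is retained behind
`mode = "n_minus_1"` for literal comparability with reports that divide
by the total. Zero-denominator cells are `NA`, never 0.

The behavioural learning rate is the per-subject slope of a pooled
logistic regression of the set-winner indicator on the within-block
trial position (log-odds per trial). A cohort-level mixed model would
estimate the same quantity with partial pooling; the per-subject slope
was chosen because it is simple, monotone in learning ability, and
directly recoverable in simulation. Separated fits fall back to a
ridge-penalised likelihood (penalty 1e-3 on the slope) and are flagged.
The good/poor split is the cohort median on this rate: subjects are
ordered by rate (descending) with ties broken by stable input order, the
top half (ceiling for odd cohorts) is `good`, split sizes never differ
by more than one, and a tie at the boundary warns.

## Statistics

`tTestD` wraps the pooled-variance t-test with the effect-size
conventions stated explicitly since several coexist: pooled-SD Cohen's d
for independent contrasts, difference-SD d for paired and one-sample
contrasts. Zero-variance input yields `NA` with a `degenerate` flag.

`mixedAnova` fits the classical univariate mixed-design 2 × 2 × group
ANOVA through `aov` error strata (`Error(subject/(A*B))`), reports each
effect's F, the degrees of freedom implied by the data, and partial eta
squared against the effect's own stratum error. With two-level within
factors sphericity holds trivially and no correction is applied. The
implementation is validated against a per-effect contrast oracle (each
within effect is a one-sample test on a subject-level contrast) and the
classical identity that the between-group F equals the squared
independent t on subject means. No multiple-testing correction is
applied by default, matching common reporting for planned ERP contrasts;
`holmAdjust` is available.

## Monte-Carlo harnesses and problem sizes

`runRecover` repeats the full chain — simulate a 15 + 15 cohort of good
and poor agents, synthesize epochs, measure every subject, median-split
on the fitted learning rates, run the battery — under counter-based
seed substreams (`subSeed`), so every repetition and stage is
independently reproducible. Inside the repetition loop the problem sizes
are the package's own choices, stated here once:

* synthesis directly at the 250 Hz analysis rate over −200..800 ms
  (every measurement window plus baseline), skipping the resampling and
  filtering stages — the loop injects no artifacts and its noise is
  already band-limited, so those stages would be near-identities;
* feedback epochs on the frontal ROI + the midline centro-parietal
  subset (E129/E55/E62/E71) + mastoids, cue epochs on the occipital
  pairs + mastoids. The lateral centro-parietal pairs only average down
  the channel-private noise that the ROI mean has already suppressed
  (the shared field dominates and is removed by re-referencing), so the
  midline subset carries the same injected amplitude at nearly identical
  measurement noise;
* the winner-referenced N2pc null check runs on a 30-subject
  unbiased-choice probe cohort (6 blocks — a null rejection rate does
  not depend on the trial count) for the symmetry reason given above.

The full-fidelity path (full montage, all stages) remains what
`runAnalyze` does and is exercised by the noise-free fidelity tests and
the pipeline unit tests. `type1Calibration` runs the battery over
all-null cohorts (zero amplitudes, unbiased agents, 10 per nominal
group, 6 blocks, single-channel ROIs) and checks every rejection rate
against a 99.8% binomial acceptance region around the nominal level —
test sizes do not affect a test's level, only its power, which is not at
issue under the null.

## Known limitations

* No forward model: topographies are ROI-indicator maps, so
  scalp-distribution questions (e.g. source localisation, topographic
  dissociations) are out of scope.
* Group effect amplitudes are fixed within group; recovery studies
  quantify pipeline noise, not population heterogeneity.
* The joint-probability criterion with many channels and strongly shared
  noise flags a channel or two in a sizeable fraction of epochs;
  this is conservative (those channels are interpolated, not lost) but
  makes the full trial-by-trial stage the slowest pipeline step.
* EEGLAB `.set` / FIF import-export is not provided; epochs persist as
  RDS plus CSV sidecars through `runSimulate`.
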