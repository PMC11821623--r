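# prlerp

Simulation and ERP analysis of a child-friendly probabilistic
reward-learning task.

## The problem

In a two-alternative probabilistic reward-learning paradigm, a child sees
a face and a house on each trial, picks one, and receives gain or loss
feedback; within each block one category (the *set winner*) is rewarded
with probability 0.77 and the other with 0.23. Three EEG signatures index
the subprocesses of learning:

* **RewP** (reward positivity) — the frontal gain-minus-loss difference,
  measured 275–375 ms after feedback over a fronto-central ROI
  (E10/E11/E16);
* **P300** — the centro-parietal response 400–600 ms after feedback,
  contrasted by feedback (gain/loss) and the strategy taken on the *next*
  trial (stay/switch), and analysed with a 2 × 2 × learner-group
  mixed-design repeated-measures ANOVA with partial eta squared
  (η²ₚ = SS_effect / (SS_effect + SS_error));
* **N2pc** — the lateralized occipital negativity 175–225 ms after the
  choice-cue pair, computed as contralateral minus ipsilateral over
  left/right homologue ROI pairs (E50/E101, E58/E96), referenced either
  to the to-be-chosen side or to the set-winner side.

Behaviour is summarised by Win-Stay/Lose-Shift (WSLS) proportions — WS =
P(stay | previous gain), LS = P(shift | previous loss) — a per-subject
behavioural learning rate (the logistic slope of set-winner choice on
within-block trial position), and a good/poor learner median split on
that rate.

Because participant-level recordings for such paradigms are rarely
deposited, `prlerp` makes the whole analysis chain testable end to end by
*simulating* it: agents (WSLS, Rescorla–Wagner, unbiased, oracle) play
the task, and multichannel epoched EEG is synthesized on a 129-channel
geodesic-style montage with the three components injected at known
amplitudes on top of realistic background activity (spatially shared 1/f
noise, white sensor noise, line noise, blinks, faulty channels). The
cleaning pipeline mirrors a standard paediatric ERP path: outer-ring
removal, downsampling to 250 Hz, 0.1–30 Hz Butterworth band-pass
(zero-phase), bad-channel detection, mastoid re-referencing, −400..800 ms
epochs with −200..0 ms baseline, trial-by-trial rejection
(peak-to-peak > 100 µV in sliding 200 ms windows, |V| > 150 µV,
log-variance improbability > 3 SD; ≥ 10 flagged channels rejects the
epoch, fewer are spherical-spline interpolated), condition binning, and
ROI window means.

## Worked example

```r
library(prlerp)

cfg <- runConfig(seed = 1)     # 15 good + 15 poor Rescorla-Wagner agents
res <- runAnalyze(cfg)         # full pipeline incl. filtering and TBT

head(res$learningCurve$p_winner, 3)   # 0.487 0.538 0.545
tail(res$learningCurve$p_winner, 1)   # 0.737
res$stats$rewpGroupT
#> independent t(28) = 2.053, p = 0.0495, Cohen's d = 0.750
res$stats$p300Anova
#>                     effect df1 df2     SS       F        p   pes
#>                   strategy   1  28 33.335 209.683 1.57e-14 0.882
#>                    learner   1  28  0.097   0.414 5.25e-01 0.015
#>                   feedback   1  28 21.931 137.670 2.53e-12 0.831
#>          feedback:strategy   1  28  0.030   0.165 6.87e-01 0.006
#>           strategy:learner   1  28  0.057   0.358 5.54e-01 0.013
#>           feedback:learner   1  28  0.100   0.628 4.35e-01 0.022
#>  feedback:strategy:learner   1  28  0.139   0.757 3.92e-01 0.026
res$stats$n2pcChosenT
#> one_sample t(29) = -29.431, p = 3.764e-23, Cohen's d = -5.373
```

The learning curve starts in the chance band (~0.49 on block-initial
trials) and climbs to ~0.74 by trial 18. With the default effect
specification (RewP gain-minus-loss of +2 µV for poor learners and
−1 µV for good learners; P300 cells 4/5/5/6 µV giving 1 µV loss > gain
and switch > stay main effects with no interaction; −1.5 µV chosen-side
N2pc and no set-winner N2pc), the group t-test recovers the larger RewP
in poor learners, the ANOVA recovers exactly the two injected main
effects with null interactions, and the one-sample t recovers the
chosen-side N2pc. In a learning cohort the winner-referenced N2pc
inherits part of the chosen-side component (choices correlate with the
set winner), so the winner-side null is assessed on an unbiased-choice
cohort — see the methods vignette.

Monte-Carlo harnesses quantify this over repetitions:
`runRecover(runConfig(seed = 1), nReps = 100)` reports rejection rates
(power / type-I error) and estimate means per effect, and
`type1Calibration(nReps = 500)` checks every test in the battery against
its nominal level on all-null cohorts.

## Package tour

| area | entry points |
|---|---|
| task & agents | `taskConfig`, `agentSpec`, `simulateSession`, `simulateCohort`, `wslsChoice`, `rwUpdate` |
| EEG synthesis | `effectSpec`, `synthesizeEpochs`, `injectArtifacts`, `hydrocelMontage`, `pinkNoiseMatrix` |
| behaviour | `labelTransitions`, `strategyProportions`, `learningCurve`, `fitLearningRate`, `medianSplit`, `halvesContrast` |
| ERP pipeline | `removeOuterRing`, `resampleEpochs`, `bandpassEpochs`, `detectBadChannels`, `rereferenceMastoids`, `extractEpochs`, `baselineCorrect`, `rejectEpochsTBT`, `interpolateSpherical` |
| measurement | `binAverage`, `differenceWave`, `roiWindowMean`, `contraIpsi`, `subjectErpMeasures` |
| statistics | `tTestD`, `mixedAnova`, `cohortStats`, `type1Calibration` |
| workflow | `runConfig`, `runSimulate`, `runAnalyze`, `runRecover`, `writeRunConfig` |

The methods vignette (`vignettes/prlerp-methods.Rmd`) documents the
generative model, the pipeline's numerical choices and the design
decisions in detail.
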