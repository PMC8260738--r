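---
title: "Decoding reward-biased reactivation in sleep fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reward-biased reactivation in sleep fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the synthetic-data generator, the
numerical choices, and the open design decisions behind `sleepreplay`. It
is the package's own account of its science; every empirical statement
here is computed by the test suite or by `scripts/acceptance.R`, nothing
is quoted from elsewhere.

## The experimental structure being modeled

Subjects play two games during one fMRI session — a face-search game and a
maze-navigation game — in a pseudo-random block design: 8 blocks of 60 s
per game, each preceded by a 3-s cue announcing the game and followed by
90 s of rest, with no more than two immediate repetitions of the same game
and the session rigged so that its final block belongs to the game the
subject wins. At TR = 2.1 s over two runs this yields ~1164 scans. The
subject then sleeps in the scanner (~50-160 min) while EEG-fMRI is
recorded; the EEG is staged into 20-s epochs (W/N1/N2/N3), and a delayed
memory test follows two days later.

The analysis asks whether the multivariate BOLD pattern of the *rewarded*
game reappears during sleep — specifically in N3, where slow oscillations
dominate — more than the pattern of the unrewarded game.

## Classifier

We use a linear-chain conditional random field over five states (Face,
Maze, Rest, PreFace, PreMaze). The potentials combine transition weights
$\lambda_{ij}$ with per-state state-feature functions. CRF notation often
writes a scalar weight $\mu_s$ per state function, but scalar weights
cannot classify 58-dimensional ROI vectors; the state term is therefore
realized as a weight vector plus bias per state,
$\mu_s \in \mathbb{R}^{N+1}$ — the standard realization of state feature
functions for continuous observations, and the only one consistent with a
parameter set $\theta = [\lambda_{1,1}, \ldots, \lambda_{S,S}, \mu_1,
\ldots, \mu_S]$ that is supposed to separate the states.

Training maximizes the conditional log-likelihood with a small ridge
penalty, by L-BFGS with analytic gradients (empirical minus expected
feature counts; expected counts by forward-backward). Design choices:

* **Uniform transitions for sleep.** The temporal order of task blocks is
  meaningless in sleep, so transition feature functions are held constant,
  encoded as $\lambda \equiv 0$ (any constant is equivalent after
  normalization). The chain then factorizes and the per-volume posterior
  equals a softmax of state scores. Free-transition training and inference
  are fully implemented and tested (against brute-force enumeration) but
  are not the default.
* **Per-volume "likelihood".** The continuous 0-1 value reported per scan
  is the posterior marginal $p(y_t = s \mid x)$ from forward-backward. A
  Viterbi path alone would be 0/1; both outputs are exposed, Viterbi being
  what cross-validation scores.
* **Ridge `l2 = 1e-3`** keeps the optimum finite on separable training
  data; `l2 = 0` is supported. Convergence: L-BFGS-B with gradient
  projection tolerance `1e-5`, at most 500 iterations by default;
  non-convergence is an error carrying the last iterate.
* **Feature standardization.** Decoding studies rarely report their
  scaling; we z-score with training-set statistics and apply those same
  statistics to held-out and sleep data (a `standardize` switch disables
  it). Zero-variance ROIs are zeroed with a warning.
* **Ties** in Viterbi are broken toward the lower state index, making
  decoding deterministic.
* **Cross-validation** holds out whole subjects, one per fold (a
  one-run-per-fold variant would be a trivial variation but gives the
  classifier a same-subject advantage). Win-block scans and their
  trailing rest are excluded from training, and chains are split around
  exclusions so no transition spans a gap.

## Label conventions

Scans are assigned the state of the block containing their onset, on
half-open intervals `[onset, onset + duration)`; a scan starting exactly
at a boundary belongs to the later block — an unambiguous,
boundary-stable convention. No hemodynamic label shift is applied by
default: the classifier is trained on block timing, exactly as a
block-design GLM models it; an integer scan shift is available for
sensitivity analyses. Exact scan-count balance between
the two games is impossible at TR = 2.1 s against 153-s block units (each
60-s block contributes 28 or 29 scans depending on phase), so the design
is balanced only to within one scan per block; tests assert
near-equality.

## Synthetic-data generator

The generator is first-class, tested code; its defaults *are* the
conditions every analysis and test run under, chosen once:

* **BOLD**: state boxcars convolved with a canonical double-gamma HRF
  (peak 6 s, undershoot 16 s, ratio 6, sampled at TR and normalized to
  unit sum so a sustained block has plateau 1) mixed through per-state ROI
  patterns, plus stationary AR(1) Gaussian noise. Defaults: 58 ROIs, game
  pattern amplitude 1.0, pre-cue amplitude 0.2, noise sd 1.0, AR(1) 0.3 —
  a signal-to-noise regime in which leave-one-subject-out accuracy for
  Face/Maze/Rest sits near 0.9, comfortably above the 0.76 floor the
  acceptance checks use as their validation criterion. Pre-cue patterns
  are weak and brief by design: a
  3-s instruction screen barely moves the hemodynamics, which is what
  makes the pre states collapse into Rest in cross-validation (as they
  should).
* **Hypnograms**: a 20-s-epoch Markov chain over W/N1/N2/N3 descending
  from wake into sustained N3, resampled (bounded retries) until at least
  10 min of N3 and all four stages occur — mirroring a cohort restricted
  to subjects who reached sustained N3. Default session length 100 min,
  in the middle of the 1-2.5 h such scanner sleep sessions achieve.
* **Reactivation**: Poisson events on N3 scans (3 per N3 minute) inject
  the won game's pattern, HRF-convolved, at amplitude `react_amp`. No
  empirical effect size for replay amplitude is available; the default
  `react_amp = 2` (impulse peak ~1 noise-sd per ROI after HRF attenuation,
  ~8 sd along the 58-ROI pattern discriminant) is a calibration choice,
  flagged in the configuration. Per-subject amplitudes vary lognormally
  (sd 0.4 in log units) — the between-subject variance that memory
  correlations feed on.
* **EEG band power** is generated directly in log10 space on the 2-s
  Welch grid with stage-dependent levels (low delta rising into N3, sigma
  peaking in N2, alpha/beta in wake) plus AR noise; low delta is
  additionally elevated around reactivation events (HRF-smoothed kernel,
  gain `delta_coupling = 0.5` log10 units). A raw-EEG path
  (`simulate_band_eeg`) exists for exercising the spectral code.
* **Hippocampus/VTA** seed channels receive the event regressor at gain 2
  plus unit AR(1) noise.
* **Memory**: the latent number of exactly-placed faces and the latent
  maze distance move linearly with `coupling x strength` (strength =
  events per N3 minute x amplitude, typically ~6) before rounding and
  clamping; Gaussian noise sd 2. The no-coupling baseline for the maze
  sits at 80% of the maze's maximum distance — chance-level searchers end
  up well inside the maze, not pinned at the farthest node, and this keeps
  the null non-degenerate.

What the generator does *not* emulate: physiological noise and motion,
spatially structured noise correlations, raw EEG with spindles or
K-complexes, arousals, REM, and drift in the patterns between wake and
sleep. Passing tests therefore demonstrate that the pipeline recovers the
phenomenon *under its own statistical assumptions*; they do not establish
robustness to artifacts that real EEG-fMRI preprocessing must remove.

## Spectral analysis

Band power uses 4-s epochs advancing by 2 s, one Hamming-windowed modified
periodogram per epoch (the epoch time course of a Welch analysis), and is
**band-integrated**: the sum of in-band density bins times the bin width,
lower edge inclusive, upper exclusive, reported as log10. Integration
(rather than mean density) makes a flat spectrum yield power proportional
to bandwidth and total power satisfy Parseval, both of which the tests
assert. Log base 10 is the package's convention. Artifact handling is an
optional boolean epoch mask, not a detector.
Resampling to scan times is linear interpolation with constant
extrapolation at the edges.

## Statistics

Repeated-measures ANOVA is computed through `stats::aov` with subject
error strata; degrees of freedom are uncorrected by default, with a
Greenhouse-Geisser option for single-within-factor designs. Planned
comparisons are paired contrasts, `F(1, n-1) = t^2`, two-sided, as are
all tests. Spearman
correlations use midranks; p-values are exact by enumeration for n <= 7
and t-approximate above (full enumeration at n = 10 costs 3.6M
permutations for no practical gain at the cohort sizes involved). Fisher z
is `atanh` with |rho| clamped below 1. The voxelwise regression and
random-field-corrected conjunction that a voxelwise workflow would use
are replaced by ROI-level OLS plus set intersection — the same
mathematical object at this package's spatial resolution. Likelihood
regressors enter unconvolved by default, with a convolution switch, and
pre-cue states are excluded from the design due to their negligible
occurrence in sleep.

## Problem sizes used by the test suite

The acceptance-style tests run, on one CPU: an 18-subject
leave-one-subject-out validation (~1 min); 100 random small chains against
brute-force enumeration; 50 simulated 13-subject cohorts through the full
pipeline for the directional-recovery checks (~5 min); and 500 null
runs each for the planned-contrast and memory-correlation type-I checks,
the former against a single fixed classifier with fresh 20-min null sleep
sessions per run (the type-I behavior under study concerns the sleep data
and the test, not classifier refitting). These counts were chosen to keep
the suite a few minutes long while leaving the pass criteria statistically
comfortable.

## Known limitations

* The per-volume likelihood with uniform transitions is a softmax
  regression posterior; the chain machinery only adds information when
  transitions are informative, which the sleep analysis deliberately
  forgoes.
* ROI-level conjunction is coarser than voxelwise small-volume-corrected
  conjunction; network membership is top-k by group t rather than
  threshold-by-p.
* The generator's reactivation events are scan-aligned and share one
  amplitude per subject; real replay is likely burstier and graded.
* Real-data ingestion (BIDS/DICOM) is out of scope; the package consumes
  plain CSV/JSON/text tables, and the documented directory layout of
  `write_cohort()` defines the expected formats.
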