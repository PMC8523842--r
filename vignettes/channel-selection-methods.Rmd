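---
title: "Methods: two-stage multitasking channel selection for hybrid BCIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage multitasking channel selection for hybrid BCIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emmoa)
```

## The optimization model

A solution is a binary mask `x` over the `K = 15` electrode montage
(`default_montage()`): eleven motor/central electrodes followed by four
parieto-occipital ones. Three objectives are maximized jointly:

* **MAR**, the motor-imagery accuracy of the selected channels: epochs are
  band-passed 5–30 Hz (zero phase), CSP spatial filters are fitted on
  training folds, trials are summarized by normalized log-variance features,
  and an RBF-SVM is scored on held-out folds;
* **SAR**, the SSVEP accuracy: each trial is assigned to the stimulus whose
  sine/cosine reference set (fundamental plus harmonics) attains the largest
  canonical correlation with the multichannel signal;
* **NC = K − C**, with `C` the selected-channel count, so that sparser masks
  score higher.

Accuracies conflict with parsimony, so the result is a Pareto set under
strict dominance: `a` dominates `b` when it is at least as good in every
objective and strictly better in at least one. The prose definition of
Pareto optimality leaves "better in all objectives" ambiguous for ties;
strict dominance is the standard reading and the one implemented, so
objective-space duplicates are mutually non-dominated and all retained —
distinct channel subsets with equal scores are distinct answers to the
user's question.

## Stage 1: evolutionary multitasking

One population of `N` individuals, each carrying a task label (1 = MI,
2 = SSVEP) inherited from its parents, optimizes both tasks at once. An
individual is evaluated only on its own task's 2-objective view
`(accuracy, NC)`; the two tasks are never compared on raw objective values.
Per generation:

1. **Tournament selection.** Binary tournaments with replacement. The
   comparison criterion is not fixed by the usual description of the
   operator for this setting; we use the NSGA-II convention — non-domination
   rank within the individual's own task group, then crowding distance, then
   a coin flip — which is consistent with how the archives are truncated.
2. **Variation.** Consecutive parent pairs recombine by two-point
   segment exchange (what positional partial-mapped crossover reduces to on
   binary strings, where no permutation semantics exist). Same-label pairs
   always recombine. Mixed-label pairs recombine with probability
   `pc`; otherwise both parents are flip-bit mutated (per-bit rate `1/K`)
   with probability `pm`; otherwise they are copied unchanged — the only
   side-effect-free completion of the branch, which the pseudocode leaves
   open. Offspring inherit their positional parent's label, so the label
   multiset is conserved.
3. **Environmental selection.** Parents and offspring are pooled,
   partitioned by label, and each label group is reduced by NSGA-II-style
   rank-then-crowding selection to a quota proportional to the group's share
   of the pool (rounded, totalling exactly `N`). "Select the fittest" is
   undefined across tasks; the proportional per-label rule keeps both tasks
   represented without cross-task objective comparison. If one label dies
   out entirely the other fills the population, with a warning, and the
   search degenerates gracefully to single-task NSGA-II — forcing all labels
   to one task is in fact used as a reduction test in the suite.
4. **Archive update.** Label-1 survivors update `PS_MI` (view `(MAR, NC)`),
   label-2 survivors update `PS_SSVEP` (view `(SAR, NC)`). Each archive
   keeps the non-dominated subset of old members and candidates, truncated
   to a 100-member cap by *iterated* lowest-crowding removal with
   recomputation after each removal (the NSGA-II-style reading of "members
   with larger crowding distance remain"); among equal-crowding members the
   earliest-inserted survives, for determinism. Per-objective extremes have
   infinite distance and are never truncated, which yields the elitism
   property checked in the tests: the best archived value of each single
   objective never degrades.

**Termination.** The only stopping rule stated for the method is the global
evaluation budget (10000 distinct objective computations per run). Because
same-label pairs always recombine, a converged population eventually
produces only cached masks and would never exhaust the budget, so
`ea_config()` adds a `max_generations` guard (default 100). Budget
accounting: cache hits are free, the cache key includes the task, and the
empty mask scores 0 on either accuracy without consuming budget (the
all-zero chromosome is otherwise undefined — no channels, no classifier).

## Stage 2: decision-variable analysis and guided local search

The per-channel vote: for channel `j` and archive member `x`, toggle bit
`j` and re-score the member's task accuracy. Turning a channel **on** and
improving accuracy, or turning it **off** and hurting accuracy, is evidence
the channel helps (+1); the mirror outcomes are evidence it hurts (−1);
unchanged accuracy contributes nothing. Channels with positive, negative,
and zero tallies form `add_group`, `delete_group`, and `invalid_group`.

Two readings of the surrounding description conflict: the procedure's
pseudocode scores the first eleven channels with MAR over `PS_MI` (and its
published example output labels them "for MI task"), while one prose
sentence pairs them with `PS_SSVEP`. The pseudocode-and-example reading is
implemented: motor/central channels are judged by the MI task, occipital
channels by the SSVEP task. Likewise the pseudocode indexes the groups by a
loop variable that can only sensibly be the channel index, and the local
search below tests the drawn channel index — both are implemented that way,
the only reading under which the groups contain channel indices.

Local search gives each `PS_MI` member one uniformly drawn channel from the
*occipital* block — set if drawn from `add_group` and off, cleared if from
`delete_group` and on, else left alone — and symmetrically each `PS_SSVEP`
member one channel from the motor/central block. One toggle per member per
pass (`stage2_passes`, default 1; whether the analysis/search cycle repeats
is left open by the method's description, and a single pass is the
conservative default). Finally MAR, SAR, and NC are evaluated for every
archive member and candidate — this is where each solution is first scored
on *both* tasks — and the non-dominated set under 3-objective maximization,
capped at the archive cap, is the algorithm's output. Toggle evaluations
and final-assembly evaluations draw on the same ledger and count against
the same budget as any other evaluation.

## Objective backends: numerical choices

* **CSP.** Per-trial covariances are trace-normalized and averaged per
  class; the composite is whitened and the whitened class-1 covariance
  eigendecomposed. Filters are the eigenvectors of the `m` largest and `m`
  smallest eigenvalues with `m = min(2, floor(C/2))` (the filter count is
  not specified by the method; 2 pairs is the common default for small
  montages). A rank-deficient composite is regularized by `εI`,
  `ε = 1e−8 · trace/dim`, with a warning. With a single selected channel
  CSP is skipped and the trial's log-variance is the feature, keeping MAR
  defined on every non-empty mask.
* **Cross-validation.** Stratified 5-fold with a fold assignment fixed once
  per backend from the run seed (so every mask sees the same folds; CSP and
  the SVM are fit on training folds only, avoiding leakage). The fold count
  drops with a warning when a class has fewer trials. Accuracy is the pooled
  fraction of correctly classified held-out trials. The train/test protocol
  behind the method's published accuracies is not described; this CV scheme
  is the package's own stand-in and is flagged as such.
* **SVM.** `cost = 1`, RBF kernel width by the median heuristic
  (`gamma = 1 / median squared pairwise training distance`), features not
  re-scaled (they are already normalized log-variances). Fixed for
  reproducibility; no hyperparameter search.
* **CCA.** The largest canonical correlation is computed from orthonormal
  bases (QR of the centered trial and reference matrices, largest singular
  value of `Qx'Qy`), clamped to `[0, 1]`; rank-deficient inputs use the
  rank-revealing QR basis. References use `n_harmonics = 2` (a harmonic
  count is not stated; two is the common choice for canonical-correlation
  SSVEP detection). Classification is argmax over frequencies with ties
  within `1e−12` broken toward the lowest index.
* **Filtering.** 4th-order Butterworth, forward-backward for zero phase, so
  no class-dependent phase distortion enters the covariances.

## The synthetic generator

`synth_config()` defines the study conditions the package is tested under:
256 Hz sampling, the 15-electrode montage, 2 s trials, 1/f background noise
(spectral shaping of white noise, exponent 1 — so the 5–30 Hz band-pass has
a realistic effect, unlike white noise), 20 MI trials per class and 12 SSVEP
trials per stimulus.

* **MI**: a 10 Hz mu oscillation (amplitude 2 relative to unit-variance
  noise, random phase per trial) on C3 and C4, attenuated by `erd_depth`
  (default 0.8) on the hemisphere contralateral to the imagined hand —
  amplitude attenuation rather than additive activation, matching the
  desynchronization physiology the CSP pipeline assumes.
* **SSVEP**: stimuli {10, 12, 15} Hz with 2 harmonics (the study's stimulus
  frequencies are not stated; these are a free choice in the standard SSVEP
  range) planted on POz/O1/Oz/O2 at amplitude SNR 1.5 relative to the noise
  standard deviation, harmonic `h` scaled by `0.5^(h−1)`, random phase per
  trial and harmonic.

Trial counts and durations are chosen for test speed — the original
experiments' counts are not reported — and the defaults are deliberately
easy: planted channels reach near-ceiling accuracy, so recovery tests probe
the search machinery, not classifier robustness. What the generator does
**not** emulate: volume conduction and realistic cross-channel mixing (each
channel's noise is independent), ocular/muscular artifacts, non-stationary
rhythms, inter-subject variability. Passing tests therefore demonstrate
correctness of the optimization and decoding pipeline on well-posed signals,
not expected accuracy on real recordings.

## Degenerate inputs and edge rules

Empty candidate sets, empty archives (all channels voted invalid, with a
warning), fronts of size ≤ 2 (all crowding distances infinite), zero-range
objectives (contribute 0 to crowding), odd parent counts (last parent copied
through), mid-generation budget exhaustion (the generation completes on
cached values only, unevaluable offspring are dropped, then the stage
stops), and budget exhaustion during stage 2 (the final set is assembled
from the solutions that could be scored, with a warning) are all defined
behaviors with tests.

## Problem sizes

The test suite and the acceptance script run the full pipeline at the
default synthetic scene (40 MI + 36 SSVEP trials, 2 s at 256 Hz); unit and
property tests use a reduced scene (1 s trials, 20 MI + 18 SSVEP trials) and
compact EA settings (populations of 10–30, budgets of 150–1500) chosen so
the whole suite completes in a few minutes on one core. The recovery test
runs ten independent seeds at the default scene with population 30 and a
1500-evaluation budget.

## Known limitations

* The MAR objective's CV protocol and SVM hyperparameters are package
  choices; absolute MAR values are not comparable to accuracies obtained
  under other protocols.
* The two-block structure (motor vs occipital) is hard-wired into stage 2's
  task pairing; montages without that structure would need their own block
  definition (`mi_block` / `ssvep_block` in `ea_config()`).
* The published example group partitions from the original recordings
  cannot be reproduced here — they depend on data that is not deposited;
  the analysis operator is instead validated against exhaustive toggle
  enumeration on mock accuracy tables and recovery of planted channels.
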