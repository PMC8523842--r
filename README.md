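# emmoa

Channel selection for hybrid brain-computer interfaces by two-stage
evolutionary multitasking multiobjective optimization.

## The problem

Hybrid BCIs decode two EEG modalities at once: **motor imagery** (MI),
whose imagined left/right hand movements produce lateralized mu/beta
band-power attenuation (ERD) over motor cortex, and **SSVEP**, the occipital
oscillation at a flickering stimulus's frequency and harmonics. Dense
montages are uncomfortable and slow to set up, but dropping channels
carelessly costs accuracy — and the channels that matter differ between the
two tasks. Channel selection is therefore a multiobjective problem: over
binary decision vectors `x = [x1, …, xK], xi ∈ {0,1}` (here `K = 15`
electrodes: FC3, FC4, C5, C3, C1, Cz, C2, C4, C6, CP3, CP4, POz, O1, Oz,
O2), simultaneously maximize

* **MAR** — MI classification accuracy (5–30 Hz band-pass, CSP spatial
  filtering, normalized log-variance features, RBF-SVM, stratified
  cross-validation),
* **SAR** — SSVEP classification accuracy (argmax of the canonical
  correlation between the trial and sine/cosine references at each stimulus
  frequency and its harmonics),
* **NC = K − C** — channel parsimony, with `C` the number of selected
  channels.

No single mask maximizes all three, so the output is a Pareto set of
non-dominated trade-offs.

## The algorithm

**Stage 1 — evolutionary multitasking.** One population of `N = 100` masks;
each individual carries a task label (1 = MI, 2 = SSVEP) and is evaluated
only on its own task's `(accuracy, NC)` pair. Binary tournaments
(non-domination rank, then crowding distance), two-point segment-exchange
crossover (same-label pairs always recombine; mixed-label pairs recombine
with probability `pc = 0.8`, else flip-bit mutate with probability
`pm = 0.2`), label inheritance, and label-proportional NSGA-II-style
environmental selection. Two capped archives, `PS_MI` and `PS_SSVEP`
(≤ 100 members each, truncated by crowding distance), collect the per-task
fronts. The shared population lets channel subsets that serve one task seed
the other.

**Stage 2 — decision-variable analysis and local search.** Every channel in
the motor/central block (1–11) is voted on by toggling its bit in every
`PS_MI` member and re-scoring MAR; the occipital block (12–15) is voted on
over `PS_SSVEP` with SAR. The vote signs partition channels into
`add_group` / `delete_group` / `invalid_group`. Each archive member then
receives one guided toggle drawn from the *other* task's block, and the
union of archive members and candidates is reduced to the final
three-objective `(MAR, SAR, NC)` Pareto set. The whole run is limited to
10000 distinct objective evaluations (cached re-evaluations are free).

A synthetic hybrid-EEG generator (256 Hz, 1/f background noise, ERD-planted
mu rhythm on C3/C4, stimulus harmonics planted on the occipital electrodes)
makes every stage testable without recordings.

## Worked example

```r
library(emmoa)
scfg <- synth_config()                      # 15-channel synthetic scene
mi   <- generate_mi_epochs(scfg, seed = 1)  # 40 MI trials, 2 s each
ss   <- generate_ssvep_epochs(scfg, seed = 2)
cfg  <- ea_config(pop_size = 30, budget = 1500, max_generations = 10,
                  archive_cap = 50)
res  <- run_emmoa(mi, ss$epochs, ss$stim, cfg, seed = 1)
print(res)
```

```
Two-stage multitasking channel selection
  evaluations used: 205 / 1500
  stage-1 generations: 10
  |PS_MI| = 31, |PS_SSVEP| = 50, |final PS| = 5
  final Pareto set (MAR, SAR, channels):
 MAR       SAR n_channels channels
 0.0 0.0000000          0
 1.0 0.3611111          1       C3
 1.0 0.3611111          1       C4
 0.6 1.0000000          1       Oz
 1.0 1.0000000          2    C4;O1
```

Each row is one non-dominated trade-off: `C3` alone decodes the planted
motor imagery perfectly but leaves SSVEP at chance (0.36 ≈ 1/3 stimuli);
`Oz` alone decodes SSVEP but not MI; `C4;O1` reaches both planted effects
with two channels — the generator placed the MI signal on C3/C4 and the
SSVEP response on the occipital electrodes, and the search recovered them.
The empty mask survives because `NC = 15` is unbeatable on the parsimony
axis. `res$groups` shows the add/delete/invalid channel partition that
steered the stage-2 search, and `write_emmoa_run(res, "run_dir")` writes the
archives, summary table, and a re-launchable manifest.

A shell interface wrapping the same functions lives at `inst/cli/emmoa`
(`emmoa run --synthetic --seed 7 --out run_dir`, `emmoa synth`,
`emmoa summarize run_dir`).

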