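# dfncpm — brain-state sequences and dichotomic pattern mining for dynamic functional connectivity

Resting-state fMRI shows that the coupling between large-scale brain
networks is not static: over a scan, whole-brain connectivity moves
through a small number of recurring configurations ("brain states"),
and *how* a person's brain sequences through those states carries
clinical information — for example, cognitively impaired cohorts dwell
longer in sparsely connected states. `dfncpm` implements the full
analysis chain that turns network component time courses into
group-discriminative state-transition patterns:

1. **Windowed functional connectivity** (`estimate_windowed_fc`) — a
   Gaussian-tapered sliding window (default 26 TR, σ = 3 TR, advanced
   1 TR; a 196-volume scan yields 170 windows) with either tapered
   Pearson correlation or an L1-regularized inverse covariance
   (graphical lasso, reported as partial correlations
   ρᵢⱼ = −Θᵢⱼ/√(ΘᵢᵢΘⱼⱼ), with λ chosen per subject by repeated 80/20
   window subsampling).
2. **Brain states** (`fit_states`, `select_k_elbow`, `assign_states`) —
   city-block k-medians over the pooled windows of all subjects
   (k = 3, 5 seeded replicates), k checked by the elbow criterion of a
   cluster validity index; each window is assigned its nearest
   centroid, giving a dominant-state sequence per subject.
3. **Dwell statistics** (`dwell_statistics`, `dwell_group_comparison`)
   — per-state fraction of windows and mean contiguous dwell, with
   pooled two-sample t-tests between groups (also evaluable from
   summary statistics: `ttest_from_summary(mean_a, sd_a, n_a, ...)`).
4. **Dichotomic pattern mining** (`mine_patterns`,
   `dichotomic_split`) — frequent sequential patterns (ordered state
   tuples, gaps allowed, run-length-compressed sequences, minimum
   support 0.05 per group) mined by prefix projection and partitioned
   into unique-to-A / unique-to-B / shared sets.
5. **Classification** (`one_hot_encode`, `evaluate_classifiers`,
   `rank_feature_importance`) — subjects encoded by pattern
   containment; random forest and LDA tuned on a stratified 80/20
   split and evaluated by 100 iterations of stratified 10-fold
   cross-validation, with the top-10 most discriminative patterns per
   model.

A synthetic-cohort generator (`synthetic_config`, `simulate_cohort`)
produces 11-component time courses (196 volumes, TR 2 s) whose
covariance switches among hypo-connected, hyper-connected and
anticorrelated-block states under group-specific Markov chains, so
every stage can be validated against known ground truth. See the
methods vignette (`vignettes/dfnc-state-patterns.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(configuration in `analysis/config.yaml`, outputs under `results/`):

```sh
Rscript analysis/01_simulate.R   # synthetic two-group cohort + ground truth
Rscript analysis/02_dfnc.R       # windowed FC per subject
Rscript analysis/03_states.R     # states, sequences, dwell stats, t-tests
Rscript analysis/04_mine.R       # sequential patterns + dichotomic split
Rscript analysis/05_classify.R   # RF/LDA over pattern and dwell features
```

With the default configuration (seed 1) this prints, along the way:

```
simulated 30 subjects (HC=15, PD=15)
hidden occupancy of hypo-connected state 1: HC 0.35, PD 0.80
windowed FC for 30 subjects: 170 windows x 55 pairs each (pearson estimator)
elbow criterion: k* = 3
state 1 (largest occupancy) fraction: HC 0.415 vs PD 0.832, t = -5.40, p = 0.0000
mined 363 (HC) and 187 (PD) patterns at support 0.05
dichotomic partition: 268 unique to HC, 92 unique to PD, 95 shared (455 total)
```

and `05_classify.R` finishes with:

```
HC_unique_patterns / RF: accuracy 0.633 +- 0.024, AUC 0.706
HC_unique_patterns / LDA: accuracy 0.732 +- 0.007, AUC 0.665
PD_unique_patterns / RF: accuracy 0.500 +- 0.000, AUC 0.500
PD_unique_patterns / LDA: accuracy 0.500 +- 0.000, AUC 0.500
percent_dwell_times / RF: accuracy 0.767 +- 0.037, AUC 0.871
percent_dwell_times / LDA: accuracy 0.785 +- 0.028, AUC 0.878
```

Reading: the generator biases the impaired-like group toward the
hypo-connected state (hidden occupancy 0.80 vs 0.35); the recovered
state sequences reproduce that bias (fraction 0.832 vs 0.415, pooled
t = −5.40), the elbow criterion recovers the true k = 3, and mining
partitions the 455 distinct patterns into group-unique and shared
sets whose counts sum exactly to the union. In this cohort the group
difference is carried by dwell occupancy, and the classifiers say so:
percent dwell times and the HC-unique patterns (spread across many HC
subjects) discriminate above chance, while the PD-unique patterns sit
at chance — under gaps-allowed matching the strongly state-1-biased
PD sequences are so stereotyped that every pattern unique to the
group comes from a single atypical subject, and cross-validation
rightly refuses to generalize from it. Group-unique *transition
motifs*, when they exist, are what this feature family detects — the
test suite demonstrates the planted-motif case. Full metric tables
and the ten most discriminative patterns per model are written to
`results/classification_report.json` and
`results/classification_summary.md`.

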