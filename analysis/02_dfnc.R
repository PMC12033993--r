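#!/usr/bin/env Rscript
# Estimate windowed functional connectivity for every subject in the
# cohort manifest: Gaussian-tapered 26-TR sliding window advanced 1 TR
# (170 windows from 196 volumes), Fisher z-transformed connectivity
# vectors over the 55 component pairs. Writes one CSV + JSON sidecar per
# subject under results/fc/.

suppressPackageStartupMessages(library(dfncpm))

cfg <- read_pipeline_config("analysis/config.yaml")
cohort <- read_cohort("results/cohort/manifest.csv")

for (s in cohort$subjects) {
  wfc <- estimate_windowed_fc(s$timecourses, cfg$window,
                              subject_id = s$subject_id,
                              seed = cfg$seed)
  write_windowed_fc(wfc, "results/fc")
}
n_w <- sliding_windows(nrow(cohort$subjects[[1]]$timecourses),
                       cfg$window$width_tr, cfg$window$step_tr)$n
message(sprintf(
  "windowed FC for %d subjects: %d windows x %d pairs each (%s estimator)",
  length(cohort$subjects), n_w,
  ncol(cohort$subjects[[1]]$timecourses) *
    (ncol(cohort$subjects[[1]]$timecourses) - 1) / 2,
  cfg$window$estimator))
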