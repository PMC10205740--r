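#!/usr/bin/env Rscript
# Training-free annotation statistics of the synthetic cohort: how well the
# area score S_area (recomputed from every mask) agrees with the noisy
# nuclei score S_nuclei, overall and on the critical mid-range subset
# (0.1 <= S_nuclei <= 0.9) where interobserver noise concentrates, plus
# the disagreement between the two simulated annotators. Run
# 01_generate_cohort.R first.

suppressPackageStartupMessages(library(epiderm))

stats <- deposit_statistics("scratch/synthetic/cohort")
cat(sprintf("masked samples:                 %d\n", stats$n_masked))
cat(sprintf("S_area vs S_nuclei MAE (all):   %.3f +/- %.3f\n",
            stats$area_vs_nuclei$mean, stats$area_vs_nuclei$sd))
cat(sprintf("S_area vs S_nuclei MAE (crit):  %.3f +/- %.3f  (n = %d)\n",
            stats$area_vs_nuclei_critical$mean,
            stats$area_vs_nuclei_critical$sd, stats$n_critical))
cat(sprintf("annotator 1 vs annotator 2 MAE: %.3f +/- %.3f\n",
            stats$pathologist_vs_pathologist$mean,
            stats$pathologist_vs_pathologist$sd))

jsonlite::write_json(
  list(n_masked = stats$n_masked,
       area_vs_nuclei = stats$area_vs_nuclei,
       area_vs_nuclei_critical = stats$area_vs_nuclei_critical,
       n_critical = stats$n_critical,
       annotator_pair = stats$pathologist_vs_pathologist),
  "results/annotation_statistics.json", auto_unbox = TRUE, digits = NA)
utils::write.csv(stats$s_area, "results/per_sample_scores.csv",
                 row.names = FALSE)
cat("written: results/annotation_statistics.json, results/per_sample_scores.csv\n")
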