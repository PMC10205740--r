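#!/usr/bin/env Rscript
# Generate the synthetic study cohorts used by the downstream analyses.
#
# Three datasets are written under scratch/ (regenerable, not versioned):
#   - cohort/     160 samples, 256x256, half with pixel-wise masks, with two
#                 simulated annotators; stands in for the deposited dataset
#   - seg/        75 fully annotated samples for the segmentation benchmark
#   - reg/        95 samples for the regression benchmark
# A composition summary goes to results/dataset_composition.json.

suppressPackageStartupMessages(library(epiderm))
seed <- 42L
dir.create("results", showWarnings = FALSE)

strata <- strata_epidermis_cohort()
strata$has_segmentation <- 0.5
cat("generating main cohort (160 samples)...\n")
man <- generate_dataset(160, "scratch/synthetic/cohort", strata,
                        generator_config(), seed = seed, annotate = TRUE)

strata$has_segmentation <- 1
cat("generating segmentation benchmark cohort (75 samples)...\n")
invisible(generate_dataset(75, "scratch/synthetic/seg", strata,
                           generator_config(), seed = seed + 21L))

strata$has_segmentation <- 0.5
cat("generating regression benchmark cohort (95 samples)...\n")
invisible(generate_dataset(95, "scratch/synthetic/reg", strata,
                           generator_config(), seed = seed + 31L))

rep <- validate_dataset(man)
jsonlite::write_json(
  list(n = rep$n, by_tissue = as.list(rep$by_tissue),
       by_staining = as.list(rep$by_staining),
       n_with_segmentation = rep$n_with_segmentation),
  "results/dataset_composition.json", auto_unbox = TRUE)
cat("cohort composition:", rep$n, "samples;",
    rep$n_with_segmentation, "with masks\n")
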