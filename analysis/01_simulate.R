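#!/usr/bin/env Rscript
# Generate the synthetic discovery cohort: four racialized strata of 422 AD
# cases each, a 5x candidate-control pool, and ICD diagnoses whose per-
# phenotype odds ratios are known ground truth. Writes OMOP-lite tables and
# the effect table under results/cohort/.

suppressPackageStartupMessages(library(adcomorbid))

seed <- 20240924L
cfg <- sim_config(n_cases_per_stratum = 422, control_pool_multiplier = 5,
                  n_phenotypes = 24, fraction_null = 0.5, seed = seed)
effects <- draw_effects(cfg)
cohort <- generate_cohort(cfg, effects)
diagnoses <- generate_diagnoses(cohort$patients, effects, cfg)

dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)
paths <- write_omop_lite(cohort$patients, diagnoses, "results/cohort")
jsonlite::write_json(effects, "results/cohort/ground_truth_effects.json",
                     digits = NA)

tab <- table(cohort$patients$race_ethnicity, cohort$patients$is_case)
cat("Cohort generated:\n")
print(tab)
cat(sprintf("%d diagnosis events over %d phenotypes (%d with OR > 1)\n",
            nrow(diagnoses), length(unique(effects$phenotype)),
            length(unique(effects$phenotype[effects$odds_ratio > 1]))))
cat("Files:", paths, sep = "\n  ")
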