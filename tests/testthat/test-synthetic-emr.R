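test_that("cohort generation respects counts, inclusion age, and determinism", {
  cfg <- sim_config(n_cases_per_stratum = 60, control_pool_multiplier = 5,
                    n_phenotypes = 8, seed = 7)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1, g2)
  p <- g1$patients
  expect_false(any(duplicated(p$person_id)))
  expect_true(all(p$estimated_age >= 65))
  tab <- table(p$race_ethnicity, p$is_case)
  expect_equal(unname(tab[, "TRUE"]), rep(60, 4))
  expect_equal(unname(tab[, "FALSE"]), rep(300, 4))
})

test_that("configured study-scale arithmetic: 422 cases/stratum, x5 pool", {
  cfg <- sim_config(n_cases_per_stratum = 422, control_pool_multiplier = 5,
                    n_phenotypes = 0, seed = 7)
  g <- generate_cohort(cfg)
  expect_equal(sum(g$patients$is_case), 1688)
  expect_equal(sum(!g$patients$is_case), 8440)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_cases_per_stratum = 0), "n_cases_per_stratum")
  expect_error(sim_config(control_pool_multiplier = 1), "control_pool_multiplier")
  expect_error(sim_config(effect_or_range = c(-1, 2)), "effect_or_range")
  expect_error(sim_config(fraction_null = 2), "fraction_null")
})

test_that("zero confounding yields balanced case/control covariates", {
  cfg <- sim_config(n_cases_per_stratum = 422, control_pool_multiplier = 3,
                    n_phenotypes = 0, confounding_strength = 0, seed = 21)
  p <- generate_cohort(cfg)$patients
  p <- p[p$race_ethnicity == "Asian", ]
  ca <- p[p$is_case, ]; co <- p[!p$is_case, ]
  smd_age <- abs(mean(ca$estimated_age) - mean(co$estimated_age)) /
    sqrt((var(ca$estimated_age) + var(co$estimated_age)) / 2)
  smd_sex <- {
    p1 <- mean(ca$sex == "female"); p2 <- mean(co$sex == "female")
    abs(p1 - p2) / sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  }
  expect_lt(smd_age, 0.1)
  expect_lt(smd_sex, 0.1)
})

test_that("diagnosis prevalences follow the logistic effect model", {
  cfg <- sim_config(n_cases_per_stratum = 200, control_pool_multiplier = 3,
                    strata = "Asian", confounding_strength = 0, seed = 99,
                    n_phenotypes = 2)
  # null phenotype at baseline 0.3 and an OR=4 phenotype at baseline 0.1
  eff <- data.frame(phenotype = rep(c("Anemia NOS", "Bipolar"), each = 1),
                    stratum = "Asian",
                    baseline_prevalence = c(0.3, 0.1),
                    odds_ratio = c(1, 4),
                    shared_across_sites = TRUE)
  g <- generate_cohort(cfg, eff)
  pat <- g$patients
  ctrl200 <- pat$person_id[!pat$is_case][1:200]
  keep <- pat$person_id %in% c(pat$person_id[pat$is_case], ctrl200)
  dx <- generate_diagnoses(pat, eff, cfg)
  map <- load_phecode_map(fixture_map_path())
  asg <- map_diagnoses(dx, map)$assignments
  carriers <- function(ph, ids) sum(asg$phenotype == ph & asg$person_id %in% ids)
  cases <- pat$person_id[pat$is_case]
  # null phenotype: both groups inside the exact binomial 99% CI of 0.3
  ci1 <- qbinom(c(0.005, 0.995), 200, 0.3)
  expect_gte(carriers("Anemia NOS", cases), ci1[1])
  expect_lte(carriers("Anemia NOS", cases), ci1[2])
  expect_gte(carriers("Anemia NOS", ctrl200), ci1[1])
  expect_lte(carriers("Anemia NOS", ctrl200), ci1[2])
  # OR=4 phenotype: case prevalence at plogis(qlogis(0.1) + log(4)) = 0.3077
  p_case <- plogis(qlogis(0.1) + log(4))
  ci2 <- qbinom(c(0.005, 0.995), 200, p_case)
  expect_gte(carriers("Bipolar", cases), ci2[1])
  expect_lte(carriers("Bipolar", cases), ci2[2])
})

test_that("prevalence calibration at n = 5000 within 3 binomial SE", {
  cfg <- sim_config(n_cases_per_stratum = 5000, control_pool_multiplier = 3,
                    strata = "White", confounding_strength = 0, seed = 17,
                    n_phenotypes = 1)
  eff <- data.frame(phenotype = "GERD", stratum = "White",
                    baseline_prevalence = 0.2, odds_ratio = 2.5,
                    shared_across_sites = TRUE)
  g <- generate_cohort(cfg, eff)
  dx <- generate_diagnoses(g$patients, eff, cfg)
  asg <- map_diagnoses(dx, load_phecode_map(fixture_map_path()))$assignments
  cases <- g$patients$person_id[g$patients$is_case]
  p_hat <- mean(cases %in% asg$person_id[asg$phenotype == "GERD"])
  p_exp <- plogis(qlogis(0.2) + log(2.5))
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 5000))
})

test_that("zero phenotypes produce an AD-codes-only diagnosis table", {
  cfg <- sim_config(n_cases_per_stratum = 10, control_pool_multiplier = 3,
                    n_phenotypes = 0, seed = 2)
  g <- generate_cohort(cfg)
  eff <- g$effects
  expect_equal(nrow(eff), 0)
  dx <- generate_diagnoses(g$patients, eff, cfg)
  expect_true(all(dx$code %in% c("G30.1", "G30.8", "G30.9")))
  expect_setequal(dx$person_id, g$patients$person_id[g$patients$is_case])
})

test_that("unknown phenotypes in the effect table are a generation error", {
  cfg <- sim_config(n_cases_per_stratum = 5, n_phenotypes = 1, seed = 2)
  g <- generate_cohort(cfg)
  eff <- data.frame(phenotype = "Imaginary disease", stratum = "Asian",
                    baseline_prevalence = 0.2, odds_ratio = 1,
                    shared_across_sites = TRUE)
  expect_error(generate_diagnoses(g$patients, eff, cfg), "Imaginary disease")
})

test_that("OMOP-lite files round-trip losslessly and support de-duplication", {
  cfg <- sim_config(n_cases_per_stratum = 25, n_phenotypes = 10, seed = 13)
  g <- generate_cohort(cfg)
  dx <- generate_diagnoses(g$patients, g$effects, cfg)
  dir <- withr::local_tempdir()
  write_omop_lite(g$patients, dx, dir)
  back <- read_omop_lite(dir)
  expect_equal(back$patients, g$patients)
  expect_equal(back$diagnoses, dx, ignore_attr = TRUE)
  # dedup flag: each (person, code_system, code) at most once
  write_omop_lite(g$patients, rbind(dx, dx), dir, dedup = TRUE)
  dd <- read_omop_lite(dir)$diagnoses
  expect_false(any(duplicated(dd)))
  # empty cohort writes header-only files
  write_omop_lite(g$patients[0, ], dx[0, ], dir)
  empty <- read_omop_lite(dir)
  expect_equal(nrow(empty$patients), 0)
  expect_equal(nrow(empty$diagnoses), 0)
})
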