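make_patients <- function(n_case, n_ctrl, stratum = "Asian", seed = 1) {
  set.seed(seed)
  n <- n_case + n_ctrl
  data.frame(
    person_id = sprintf("%s_%04d", stratum, seq_len(n)),
    sex = sample(c("female", "male"), n, TRUE),
    estimated_age = sample(65:95, n, TRUE),
    race_ethnicity = stratum,
    death_status = sample(c("alive", "deceased"), n, TRUE),
    site = "siteA",
    is_case = rep(c(TRUE, FALSE), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
}

test_that("propensity model is monotone in a predictive covariate", {
  p <- make_patients(50, 100)
  p$sex[p$is_case] <- "female"
  p$sex[!p$is_case] <- rep(c("female", "male"), 50)
  ps <- estimate_propensity(p, "sex")
  expect_gt(min(ps[p$person_id[p$sex == "female"]]),
            max(ps[p$person_id[p$sex == "male"]]))
})

test_that("uninformative covariates give scores near the case fraction", {
  p <- make_patients(500, 1500, seed = 4)
  ps <- estimate_propensity(p, "sex")
  expect_lt(max(abs(ps - mean(p$is_case))), 0.02)
})

test_that("degenerate propensity inputs error or warn as documented", {
  p <- make_patients(20, 40)
  expect_error(estimate_propensity(p[p$is_case, ], "sex"), "control")
  p$death_status <- "alive"
  expect_warning(estimate_propensity(p, c("sex", "death_status")),
                 "constant covariate")
  # perfect separation
  p2 <- make_patients(30, 30)
  p2$estimated_age <- ifelse(p2$is_case, 90L, 70L)
  expect_error(suppressWarnings(estimate_propensity(p2, "estimated_age")),
               "separation")
})

test_that("greedy nearest-neighbor picks the closest remaining controls", {
  scores <- c(case1 = 0.50, c1 = 0.10, c2 = 0.49, c3 = 0.52, c4 = 0.90)
  m <- nearest_neighbor_match("case1", paste0("c", 1:4), scores, ratio = 2)
  expect_setequal(m$links[["case1"]], c("c2", "c3"))
})

test_that("matching arithmetic, tie handling, and pool exhaustion", {
  p <- make_patients(422, 2110, seed = 9)
  ps <- estimate_propensity(p, c("sex", "estimated_age", "death_status"))
  m <- nearest_neighbor_match(p$person_id[p$is_case], p$person_id[!p$is_case],
                              ps, ratio = 2)
  expect_equal(length(unique(m$control_ids)), 844)
  expect_true(all(lengths(m$links) == 2))
  # identical scores: deterministic ties, exact count
  const <- setNames(rep(0.5, 30), paste0("x", 1:30))
  m2 <- nearest_neighbor_match(paste0("x", 1:10), paste0("x", 11:30), const,
                               ratio = 2)
  m3 <- nearest_neighbor_match(paste0("x", 1:10), paste0("x", 11:30), const,
                               ratio = 2)
  expect_identical(m2$links, m3$links)
  expect_equal(length(m2$control_ids), 20)
  # exhausted pool warns and matches partially
  expect_warning(
    m4 <- nearest_neighbor_match(paste0("x", 1:10), paste0("x", 11:15), const,
                                 ratio = 2),
    "exhausted")
  expect_equal(length(m4$control_ids), 5)
})

test_that("no control is reused and patient fields are untouched", {
  cfg <- sim_config(n_cases_per_stratum = 80, n_phenotypes = 0, seed = 5)
  g <- generate_cohort(cfg)
  ms <- stratified_match(g$patients, seed = 3)
  all_ctrl <- unlist(lapply(ms, `[[`, "control_ids"))
  expect_false(any(duplicated(all_ctrl)))
  all_case <- unlist(lapply(ms, `[[`, "case_ids"))
  expect_length(intersect(all_case, all_ctrl), 0)
  expect_true(all(g$patients$is_case[match(all_case, g$patients$person_id)]))
  expect_false(any(g$patients$is_case[match(all_ctrl, g$patients$person_id)]))
})

test_that("common support trims non-overlapping scores before matching", {
  scores <- c(k1 = 0.05, k2 = 0.4, k3 = 0.6, j1 = 0.35, j2 = 0.5, j3 = 0.95)
  m <- nearest_neighbor_match(c("k1", "k2", "k3"), c("j1", "j2", "j3"),
                              scores, ratio = 1, common_support = TRUE)
  # overlap is [0.35, 0.6]: case k1 (0.05) and control j3 (0.95) are dropped
  expect_equal(unname(m$dropped_common_support), c(1L, 1L))
  expect_false("k1" %in% m$case_ids)
  expect_false("j3" %in% m$control_ids)
  # control-only discard policy retains every case (pool of 2 for 3 cases,
  # so the exhaustion warning is expected)
  expect_warning(
    m2 <- nearest_neighbor_match(c("k1", "k2", "k3"), c("j1", "j2", "j3"),
                                 scores, ratio = 1, common_support = TRUE,
                                 common_support_discard = "control"),
    "exhausted")
  expect_setequal(m2$case_ids, c("k1", "k2", "k3"))
  expect_false("j3" %in% m2$control_ids)
  expect_equal(unname(m2$dropped_common_support), c(0L, 1L))
})

test_that("stratum equalization subsamples to the minimum complete count", {
  set.seed(12)
  pats <- do.call(rbind, lapply(c("Asian", "Black", "Latine", "White"),
                                function(st)
    make_patients(sample(60:80, 1), 400, stratum = st,
                  seed = match(st, c("Asian", "Black", "Latine", "White")))))
  ms <- stratified_match(pats, seed = 77)
  n_cases <- vapply(ms, function(m) length(m$case_ids), integer(1))
  n_ctrl <- vapply(ms, function(m) length(m$control_ids), integer(1))
  expect_true(all(n_cases == min(table(pats$race_ethnicity[pats$is_case]))))
  expect_true(all(n_ctrl == 2 * n_cases))
  # seeded determinism of the subsample
  ms2 <- stratified_match(pats, seed = 77)
  expect_identical(lapply(ms, `[[`, "case_ids"), lapply(ms2, `[[`, "case_ids"))
  # equalize off leaves per-stratum sizes unchanged
  ms3 <- stratified_match(pats, seed = 77, equalize = FALSE)
  expect_equal(vapply(ms3, function(m) length(m$case_ids), integer(1)),
               table(pats$race_ethnicity[pats$is_case])[names(ms3)],
               ignore_attr = TRUE)
})

test_that("balance table: identity gives SMD 0; matching removes confounding", {
  p <- make_patients(50, 50, seed = 6)
  p$is_case <- rep(c(TRUE, FALSE), 50)  # interleave so groups are identical
  p2 <- p
  p2$estimated_age <- rep(p$estimated_age[p$is_case], each = 2)
  p2$sex <- rep(p$sex[p$is_case], each = 2)
  p2$death_status <- rep(p$death_status[p$is_case], each = 2)
  fake <- structure(list(case_ids = p2$person_id[p2$is_case],
                         control_ids = p2$person_id[!p2$is_case],
                         links = list(), ratio = 1), class = "matched_cohort")
  bt <- balance_table(fake, p2, c("sex", "estimated_age", "death_status"))
  expect_equal(bt$smd_after, rep(0, 3))
  # confounded synthetic cohort: post-match < pre-match and < 0.1
  cfg <- sim_config(n_cases_per_stratum = 422, n_phenotypes = 0, seed = 44)
  g <- generate_cohort(cfg)
  ms <- stratified_match(g$patients, seed = 2)
  bt2 <- balance_table(ms, g$patients, c("sex", "estimated_age", "death_status"))
  expect_true(all(bt2$smd_after < bt2$smd_before))
  expect_true(all(bt2$smd_after < 0.1))
})
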