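#' Simulation configuration for the synthetic EMR generator
#'
#' Bundles the knobs of the synthetic OMOP-lite cohort generator: how many
#' Alzheimer's dementia (AD) cases per racialized stratum, how large the
#' candidate-control pool is relative to the cases, how many phenotypes carry
#' injected effects, and how strongly demographic covariates confound both
#' case status and phenotype prevalence.
#'
#' @param n_cases_per_stratum AD cases generated in each of the four strata.
#' @param control_pool_multiplier candidate controls per case (>= 3 so that
#'   1:2 matching always has slack).
#' @param n_phenotypes number of comorbidity phenotypes simulated. Capped at
#'   the number of non-excluded, non-AD phenotypes in the phecode map used.
#' @param fraction_null proportion of phenotypes simulated with odds ratio 1.
#' @param effect_or_range length-2 numeric, the (low, high) range from which
#'   non-null case odds ratios are drawn.
#' @param baseline_prev_range length-2 numeric, range of control ("baseline")
#'   prevalences.
#' @param confounding_strength coefficient linking age/sex/death status both
#'   to case probability and to phenotype prevalence; 0 means no confounding.
#' @param sites character vector of care sites over which patients spread.
#' @param strata character vector of the racialized strata.
#' @param seed integer; fully determines the generator's output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cases_per_stratum = 422,
                       control_pool_multiplier = 5,
                       n_phenotypes = 20,
                       fraction_null = 0.5,
                       effect_or_range = c(1.5, 4),
                       baseline_prev_range = c(0.05, 0.4),
                       confounding_strength = 1,
                       sites = "siteA",
                       strata = c("Asian", "Black", "Latine", "White"),
                       seed = 1L) {
  if (!is.numeric(n_cases_per_stratum) || n_cases_per_stratum < 1)
    stop_config("n_cases_per_stratum", "must be a positive count")
  if (!is.numeric(control_pool_multiplier) || control_pool_multiplier < 3)
    stop_config("control_pool_multiplier", "must be >= 3")
  if (!is.numeric(n_phenotypes) || n_phenotypes < 0)
    stop_config("n_phenotypes", "must be a non-negative count")
  if (fraction_null < 0 || fraction_null > 1)
    stop_config("fraction_null", "must be in [0, 1]")
  if (length(effect_or_range) != 2 || any(effect_or_range <= 0))
    stop_config("effect_or_range", "must be two positive odds ratios")
  if (any(baseline_prev_range <= 0) || any(baseline_prev_range >= 1))
    stop_config("baseline_prev_range", "must lie in (0, 1)")
  if (length(sites) < 1) stop_config("sites", "must name at least one site")
  if (!is.numeric(seed)) stop_config("seed", "must be an integer")
  structure(list(
    n_cases_per_stratum = as.integer(n_cases_per_stratum),
    control_pool_multiplier = control_pool_multiplier,
    n_phenotypes = as.integer(n_phenotypes),
    fraction_null = fraction_null,
    effect_or_range = effect_or_range,
    baseline_prev_range = baseline_prev_range,
    confounding_strength = confounding_strength,
    sites = sites,
    strata = strata,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw a ground-truth effect table for the simulator
#'
#' One row per (phenotype, stratum): the baseline (control) prevalence and
#' the case odds ratio injected on the logit scale. A per-phenotype
#' `shared_across_sites` flag records whether a validation site reuses the
#' effect (TRUE) or reverts to the null OR = 1 (FALSE).
#'
#' @param config a [sim_config()].
#' @param phenotypes character vector of phenotype names to simulate; defaults
#'   to the non-AD, non-excluded phenotypes of the bundled synthetic map.
#' @param shared_fraction proportion of phenotypes whose effect carries over
#'   to a validation site.
#' @return data.frame with columns phenotype, stratum, baseline_prevalence,
#'   odds_ratio, shared_across_sites.
#' @export
draw_effects <- function(config, phenotypes = NULL, shared_fraction = 1) {
  if (is.null(phenotypes)) {
    map <- load_phecode_map(system.file("extdata", "phecode_map_synthetic.csv",
                                        package = "adcomorbid"))
    keep <- map$category != "" & map$phenotype != "Alzheimer's disease"
    phenotypes <- sort(unique(map$phenotype[keep]))
  }
  if (config$n_phenotypes > length(phenotypes))
    stop_config("n_phenotypes", sprintf(
      "exceeds the %d phenotypes available in the map", length(phenotypes)))
  phenotypes <- phenotypes[seq_len(config$n_phenotypes)]
  if (length(phenotypes) == 0L) {
    return(data.frame(phenotype = character(), stratum = character(),
                      baseline_prevalence = numeric(), odds_ratio = numeric(),
                      shared_across_sites = logical()))
  }
  set.seed(child_seed(config$seed, "effects"))
  n_null <- round(config$fraction_null * length(phenotypes))
  is_null <- seq_along(phenotypes) <= n_null
  shared <- stats::runif(length(phenotypes)) < shared_fraction
  eff <- expand.grid(phenotype = phenotypes, stratum = config$strata,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff$baseline_prevalence <- stats::runif(nrow(eff),
                                          config$baseline_prev_range[1],
                                          config$baseline_prev_range[2])
  or <- ifelse(is_null, 1,
               stats::runif(length(phenotypes),
                            config$effect_or_range[1], config$effect_or_range[2]))
  eff$odds_ratio <- rep(or, times = length(config$strata))
  eff$shared_across_sites <- rep(shared, times = length(config$strata))
  bad <- eff$odds_ratio <= 0
  if (any(bad)) stop_config("odds_ratio", "must be > 0")
  eff
}

#' Generate a synthetic OMOP-lite patient cohort
#'
#' Builds, for each racialized stratum, `n_cases_per_stratum` AD cases and
#' `n_cases_per_stratum * control_pool_multiplier` candidate controls aged
#' 65+. When `confounding_strength > 0`, case status is sampled with
#' probability increasing in age, female sex, and death status, so cases and
#' the raw control pool are demographically imbalanced and matching is
#' non-trivial; at 0 the assignment is uniform.
#'
#' @param config a [sim_config()].
#' @param effects optional effect table from [draw_effects()]; drawn with
#'   defaults when NULL.
#' @return list with `patients` (data.frame: person_id, sex, estimated_age,
#'   race_ethnicity, death_status, site, is_case) and `effects`.
#' @export
generate_cohort <- function(config, effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(effects)) effects <- draw_effects(config)
  set.seed(child_seed(config$seed, "cohort"))
  n_per_stratum <- config$n_cases_per_stratum *
    (1 + config$control_pool_multiplier)
  out <- vector("list", length(config$strata))
  for (k in seq_along(config$strata)) {
    n <- n_per_stratum
    sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.6, 0.4))
    age <- pmin(100L, pmax(65L, as.integer(round(stats::rnorm(n, 80, 7)))))
    death <- sample(c("alive", "deceased"), n, replace = TRUE, prob = c(0.7, 0.3))
    site <- sample(config$sites, n, replace = TRUE)
    # linear predictor shifting case probability with the covariates
    z <- config$confounding_strength *
      (0.08 * (age - 80) + 0.5 * (sex == "female") + 0.7 * (death == "deceased"))
    w <- exp(z - max(z))
    case_idx <- sample.int(n, config$n_cases_per_stratum, prob = w)
    is_case <- logical(n)
    is_case[case_idx] <- TRUE
    out[[k]] <- data.frame(
      person_id = sprintf("%s_%05d", config$strata[k], seq_len(n)),
      sex = sex, estimated_age = age,
      race_ethnicity = config$strata[k],
      death_status = death, site = site,
      is_case = is_case, stringsAsFactors = FALSE)
  }
  patients <- do.call(rbind, out)
  rownames(patients) <- NULL
  list(patients = patients, effects = effects)
}

#' Generate synthetic ICD diagnosis events
#'
#' Each patient acquires each phenotype independently with probability
#' `plogis(qlogis(baseline) + is_case * log(OR) + confounding)`, so the
#' injected odds ratio is exactly the estimand of the downstream 2x2 analysis.
#' A patient carrying a phenotype emits 1-3 of its ICD codes drawn from the
#' phecode map, which exercises code-level de-duplication downstream. AD cases
#' always emit one of the AD-defining ICD-10 codes.
#'
#' @param patients patient table from [generate_cohort()].
#' @param effects effect table from [draw_effects()].
#' @param config the [sim_config()] used.
#' @param map a phecode map table; defaults to the bundled synthetic map.
#' @param validation_site logical; when TRUE, phenotypes with
#'   `shared_across_sites = FALSE` are simulated at OR = 1 (their effect does
#'   not carry to this site).
#' @return data.frame with columns person_id, code_system, code.
#' @export
generate_diagnoses <- function(patients, effects, config, map = NULL,
                               validation_site = FALSE) {
  if (is.null(map)) {
    map <- load_phecode_map(system.file("extdata", "phecode_map_synthetic.csv",
                                        package = "adcomorbid"))
  }
  phenos <- unique(effects$phenotype)
  missing <- setdiff(phenos, map$phenotype)
  if (length(missing) > 0)
    stop("phenotype(s) with no ICD code in the map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  set.seed(child_seed(config$seed, paste0("diagnoses", if (validation_site) "_v")))
  rows <- list()
  # AD-defining codes for every case
  cases <- patients[patients$is_case, , drop = FALSE]
  if (nrow(cases) > 0) {
    ad_codes <- c("G30.1", "G30.8", "G30.9")
    rows[["ad"]] <- data.frame(
      person_id = cases$person_id, code_system = "ICD10CM",
      code = sample(ad_codes, nrow(cases), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  conf <- config$confounding_strength *
    (0.04 * (patients$estimated_age - 80) + 0.25 * (patients$sex == "female") +
       0.35 * (patients$death_status == "deceased"))
  for (ph in phenos) {
    codes <- map[map$phenotype == ph, c("code_system", "icd_code")]
    for (st in unique(patients$race_ethnicity)) {
      e <- effects[effects$phenotype == ph & effects$stratum == st, ]
      if (nrow(e) == 0) next
      idx <- which(patients$race_ethnicity == st)
      or <- if (validation_site && !e$shared_across_sites[1]) 1 else e$odds_ratio[1]
      p <- inv_logit(logit(e$baseline_prevalence[1]) +
                       patients$is_case[idx] * log(or) + conf[idx])
      has <- stats::runif(length(idx)) < p
      carriers <- idx[has]
      if (length(carriers) == 0) next
      n_codes <- sample.int(min(3L, nrow(codes)), length(carriers), replace = TRUE)
      picked <- lapply(n_codes, function(m) sample.int(nrow(codes), m))
      rows[[paste(ph, st)]] <- data.frame(
        person_id = rep(patients$person_id[carriers], lengths(picked)),
        code_system = codes$code_system[unlist(picked)],
        code = codes$icd_code[unlist(picked)],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(person_id = character(), code_system = character(),
                      code = character(), stringsAsFactors = FALSE))
  }
  dx <- do.call(rbind, rows)
  rownames(dx) <- NULL
  dx[order(dx$person_id, dx$code_system, dx$code), ]
}

#' Write an OMOP-lite cohort to delimited text files
#'
#' Emits a `person.csv` (person_id, sex, estimated_age, race_ethnicity,
#' death_status, site, is_case) and a `condition_occurrence.csv` (person_id,
#' code_system, code) in `directory`. The pair round-trips losslessly through
#' [read_omop_lite()].
#'
#' @param patients,diagnoses tables from the generator (or the same schema).
#' @param directory output directory, created if absent.
#' @param dedup drop duplicate (person_id, code_system, code) rows before
#'   writing.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_omop_lite <- function(patients, diagnoses, directory, dedup = FALSE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  if (dedup && nrow(diagnoses) > 0) diagnoses <- unique(diagnoses)
  person_path <- file.path(directory, "person.csv")
  cond_path <- file.path(directory, "condition_occurrence.csv")
  utils::write.csv(patients, person_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(diagnoses, cond_path, row.names = FALSE, quote = TRUE)
  invisible(c(person = person_path, condition_occurrence = cond_path))
}

#' Read an OMOP-lite cohort written by [write_omop_lite()]
#'
#' @param directory directory containing person.csv and
#'   condition_occurrence.csv.
#' @return list with `patients` and `diagnoses` data.frames.
#' @export
read_omop_lite <- function(directory) {
  person_path <- file.path(directory, "person.csv")
  cond_path <- file.path(directory, "condition_occurrence.csv")
  for (p in c(person_path, cond_path))
    if (!file.exists(p)) stop("missing OMOP-lite file: ", p, call. = FALSE)
  patients <- utils::read.csv(person_path, stringsAsFactors = FALSE,
                              colClasses = c(estimated_age = "integer"))
  patients$is_case <- as.logical(patients$is_case)
  diagnoses <- utils::read.csv(cond_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  list(patients = patients, diagnoses = diagnoses)
}
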