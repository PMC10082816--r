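#' Estimate propensity scores by logistic regression
#'
#' Fits a main-effects maximum-likelihood logistic model of case status on
#' the given covariates (categoricals one-hot expanded against a fixed
#' first-level reference) and returns the fitted case probabilities.
#'
#' @param patients patient table with an `is_case` column.
#' @param covariates character vector of column names to adjust on.
#' @return named numeric vector of scores in (0, 1), names = person_id.
#' @export
estimate_propensity <- function(patients, covariates) {
  if (!any(patients$is_case) || !any(!patients$is_case))
    stop("propensity estimation needs at least one case and one control",
         call. = FALSE)
  stopifnot(all(covariates %in% names(patients)))
  dat <- patients[, covariates, drop = FALSE]
  constant <- vapply(dat, function(x) length(unique(x)) < 2L, logical(1))
  if (any(constant)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "), call. = FALSE)
    dat <- dat[, !constant, drop = FALSE]
  }
  for (j in seq_along(dat)) {
    if (is.character(dat[[j]])) dat[[j]] <- factor(dat[[j]], sort(unique(dat[[j]])))
  }
  dat$.case <- as.integer(patients$is_case)
  fit <- stats::glm(.case ~ ., data = dat, family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-10
  if (all(p < eps | p > 1 - eps))
    stop("perfect separation in the propensity model; review covariates ",
         "or enable common support", call. = FALSE)
  stats::setNames(as.numeric(p), patients$person_id)
}

#' Greedy 1:k nearest-neighbor matching without replacement
#'
#' Cases are processed in descending propensity-score order; matching runs
#' one round per ratio unit (every case takes its nearest remaining control
#' by absolute score difference before any case takes a second), without
#' replacement. Ties in |score difference| are broken by (control score,
#' stable person_id order). With `common_support`, cases and controls outside
#' the overlap `[max(min PS per group), min(max PS per group)]` are discarded
#' before matching and the counts recorded.
#'
#' @param case_ids,control_ids person_id vectors.
#' @param scores named score vector covering all ids.
#' @param ratio controls per case (>= 1).
#' @param common_support trim to the overlapping score range first.
#' @param common_support_discard which group(s) trimming may remove:
#'   `"both"` (default) or `"control"` (retain every case, the option used
#'   when the full case series must be preserved).
#' @return a `matched_cohort` list: case_ids, control_ids, links (named list
#'   case_id -> matched control ids), dropped_common_support (named counts),
#'   ratio.
#' @export
nearest_neighbor_match <- function(case_ids, control_ids, scores, ratio = 2,
                                   common_support = FALSE,
                                   common_support_discard = c("both",
                                                              "control")) {
  common_support_discard <- match.arg(common_support_discard)
  if (ratio < 1) stop_config("ratio", "must be >= 1")
  ids <- c(case_ids, control_ids)
  if (!all(ids %in% names(scores)))
    stop("scores must cover all case and control ids", call. = FALSE)
  dropped <- c(cases = 0L, controls = 0L)
  if (common_support) {
    lo <- max(min(scores[case_ids]), min(scores[control_ids]))
    hi <- min(max(scores[case_ids]), max(scores[control_ids]))
    keep_case <- scores[case_ids] >= lo & scores[case_ids] <= hi
    if (common_support_discard == "control") keep_case[] <- TRUE
    keep_ctrl <- scores[control_ids] >= lo & scores[control_ids] <= hi
    dropped <- c(cases = sum(!keep_case), controls = sum(!keep_ctrl))
    case_ids <- case_ids[keep_case]
    control_ids <- control_ids[keep_ctrl]
  }
  cs <- scores[case_ids]
  case_ord <- order(-cs, match(case_ids, case_ids))
  case_ids <- case_ids[case_ord]
  cs <- cs[case_ord]
  # controls kept sorted by (score, original order) for deterministic ties
  ctrl_ord <- order(scores[control_ids], seq_along(control_ids))
  pool_ids <- control_ids[ctrl_ord]
  pool_sc <- scores[control_ids][ctrl_ord]
  avail <- rep(TRUE, length(pool_ids))
  links <- stats::setNames(vector("list", length(case_ids)), case_ids)
  n_avail <- length(pool_ids)
  for (round in seq_len(ratio)) {
    for (i in seq_along(case_ids)) {
      if (n_avail == 0L) break
      s <- cs[i]
      live <- which(avail)
      pos <- findInterval(s, pool_sc[live])
      cand <- live[unique(pmin(pmax(c(pos, pos + 1L), 1L), length(live)))]
      d <- abs(pool_sc[cand] - s)
      pick <- cand[order(d, pool_sc[cand], cand)][1]
      links[[case_ids[i]]] <- c(links[[case_ids[i]]], pool_ids[pick])
      avail[pick] <- FALSE
      n_avail <- n_avail - 1L
    }
  }
  if (n_avail < 0 || any(lengths(links) < ratio))
    warning("control pool exhausted: some cases matched to fewer than ",
            ratio, " controls", call. = FALSE)
  matched_controls <- unlist(links, use.names = FALSE)
  structure(list(case_ids = case_ids,
                 control_ids = matched_controls,
                 links = links,
                 dropped_common_support = dropped,
                 ratio = ratio),
            class = "matched_cohort")
}

#' Stratified second-round matching with optional size equalization
#'
#' Re-estimates propensity scores within each racialized stratum (excluding
#' race/ethnicity from the covariates) and matches 1:`ratio` within stratum.
#' With `equalize`, each stratum's fully matched cases are subsampled
#' (seeded) to the minimum complete-match count across strata and controls
#' restricted to their links, yielding equal case and control counts in
#' every stratum.
#'
#' @param patients patient table with is_case and race_ethnicity.
#' @param covariates covariates for the within-stratum propensity model
#'   (race_ethnicity is removed if present).
#' @param ratio controls per case.
#' @param common_support,common_support_discard passed to
#'   [nearest_neighbor_match()].
#' @param equalize subsample strata to a common size.
#' @param seed seed for the equalization subsample.
#' @return named list of `matched_cohort`, one per stratum.
#' @export
stratified_match <- function(patients, covariates = c("sex", "estimated_age",
                                                      "death_status"),
                             ratio = 2, common_support = FALSE,
                             common_support_discard = "both",
                             equalize = TRUE, seed = 1L) {
  covariates <- setdiff(covariates, "race_ethnicity")
  strata <- sort(unique(patients$race_ethnicity))
  res <- list()
  for (st in strata) {
    sub <- patients[patients$race_ethnicity == st, , drop = FALSE]
    if (nrow(sub) == 0 || !any(sub$is_case) || !any(!sub$is_case))
      stop("stratum '", st, "' lacks cases or controls", call. = FALSE)
    ps <- estimate_propensity(sub, covariates)
    res[[st]] <- nearest_neighbor_match(
      sub$person_id[sub$is_case], sub$person_id[!sub$is_case],
      ps, ratio = ratio, common_support = common_support,
      common_support_discard = common_support_discard)
  }
  if (equalize) {
    complete <- lapply(res, function(m)
      names(m$links)[lengths(m$links) == ratio])
    n_min <- min(lengths(complete))
    set.seed(child_seed(seed, "equalize"))
    for (st in strata) {
      keep <- sort(sample(complete[[st]], n_min))
      links <- res[[st]]$links[keep]
      res[[st]]$case_ids <- keep
      res[[st]]$links <- links
      res[[st]]$control_ids <- unlist(links, use.names = FALSE)
    }
  }
  res
}

#' Covariate balance diagnostics (standardized mean differences)
#'
#' Computes, for each covariate, the standardized mean difference between
#' cases and controls before matching (cases vs the full candidate pool) and
#' after (matched cases vs matched controls). Continuous covariates use
#' `|m1 - m2| / sqrt((v1 + v2)/2)`; categorical covariates report the maximum
#' level-wise SMD over indicator variables. Zero variance in both groups
#' yields SMD 0.
#'
#' @param matched a `matched_cohort` (or list of them, pooled).
#' @param patients the patient table the ids refer to.
#' @param covariates covariate column names.
#' @return data.frame covariate, smd_before, smd_after.
#' @export
balance_table <- function(matched, patients, covariates) {
  if (inherits(matched, "matched_cohort")) matched <- list(matched)
  case_ids <- unlist(lapply(matched, `[[`, "case_ids"), use.names = FALSE)
  ctrl_ids <- unlist(lapply(matched, `[[`, "control_ids"), use.names = FALSE)
  if (length(case_ids) == 0 || length(ctrl_ids) == 0)
    stop("matched cohort is empty", call. = FALSE)
  rownames(patients) <- patients$person_id
  pre_case <- patients[patients$is_case, , drop = FALSE]
  pre_ctrl <- patients[!patients$is_case, , drop = FALSE]
  post_case <- patients[case_ids, , drop = FALSE]
  post_ctrl <- patients[ctrl_ids, , drop = FALSE]
  smd1 <- function(ca, co, v) {
    if (is.numeric(ca[[v]])) smd_numeric(ca[[v]], co[[v]])
    else smd_categorical(ca[[v]], co[[v]])
  }
  data.frame(
    covariate = covariates,
    smd_before = vapply(covariates, function(v) smd1(pre_case, pre_ctrl, v),
                        numeric(1)),
    smd_after = vapply(covariates, function(v) smd1(post_case, post_ctrl, v),
                       numeric(1)),
    row.names = NULL)
}
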