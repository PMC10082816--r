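#' Per-phenotype 2x2 contingency tables for a stratum cohort
#'
#' Counts, for every tested phenotype, cases with/without and controls
#' with/without it. Tested phenotypes default to all columns with at least
#' one carrier among the stratum's cases and controls; the number of tables
#' defines the Bonferroni family size for the stratum.
#'
#' @param matrix binary patient-by-phenotype matrix.
#' @param case_ids,control_ids disjoint row-name subsets of `matrix`.
#' @param tested_phenotypes optional explicit phenotype set.
#' @return data.frame phenotype, a, b, c, d.
#' @export
contingency_tables <- function(matrix, case_ids, control_ids,
                               tested_phenotypes = NULL) {
  if (length(intersect(case_ids, control_ids)) > 0)
    stop("case and control ids overlap", call. = FALSE)
  stopifnot(all(c(case_ids, control_ids) %in% rownames(matrix)))
  mc <- matrix[case_ids, , drop = FALSE]
  mk <- matrix[control_ids, , drop = FALSE]
  a <- colSums(mc)
  c_ <- colSums(mk)
  if (is.null(tested_phenotypes)) {
    tested_phenotypes <- colnames(matrix)[a + c_ >= 1]
  }
  idx <- match(tested_phenotypes, colnames(matrix))
  stopifnot(!anyNA(idx))
  data.frame(phenotype = tested_phenotypes,
             a = as.integer(a[idx]), b = length(case_ids) - as.integer(a[idx]),
             c = as.integer(c_[idx]), d = length(control_ids) - as.integer(c_[idx]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the Bonferroni family correction and significance flag
#'
#' @param results data.frame with a `p_value` column.
#' @param family_size number of phenotypes tested in the stratum.
#' @param alpha significance level on the corrected scale.
#' @return `results` with p_bonferroni (capped at 1) and significant columns.
#' @export
bonferroni_flag <- function(results, family_size, alpha = 0.05) {
  if (family_size < nrow(results))
    stop("family_size smaller than the number of results", call. = FALSE)
  results$p_bonferroni <- pmin(1, results$p_value * family_size)
  results$significant <- results$p_bonferroni < alpha
  results
}

#' Stratified AD-vs-control differential comorbidity analysis
#'
#' For one stratum cohort: builds the 2x2 table per tested phenotype, routes
#' each to Fisher's exact test (any cell < 5) or the chi-squared test,
#' computes the Haldane-corrected odds ratio, and Bonferroni-corrects over
#' the stratum's tested-phenotype family.
#'
#' @inheritParams contingency_tables
#' @param stratum label recorded in the output.
#' @param alpha corrected-scale significance level.
#' @return data.frame phenotype, stratum, a, b, c, d, test_used, p_value,
#'   p_bonferroni, odds_ratio, significant.
#' @export
run_differential <- function(matrix, case_ids, control_ids, stratum = NA_character_,
                             tested_phenotypes = NULL, alpha = 0.05) {
  tab <- contingency_tables(matrix, case_ids, control_ids, tested_phenotypes)
  n <- nrow(tab)
  test_used <- character(n); p <- or <- numeric(n)
  for (i in seq_len(n)) {
    a <- tab$a[i]; b <- tab$b[i]; c_ <- tab$c[i]; d <- tab$d[i]
    test_used[i] <- select_test(a, b, c_, d)
    p[i] <- if (test_used[i] == "fisher") fisher_exact_two_sided(a, b, c_, d)
            else chi2_test(a, b, c_, d)$p_value
    or[i] <- odds_ratio_2x2(a, b, c_, d)
  }
  res <- data.frame(phenotype = tab$phenotype, stratum = stratum,
                    a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                    test_used = test_used, p_value = p, odds_ratio = or,
                    stringsAsFactors = FALSE)
  bonferroni_flag(res, family_size = n, alpha = alpha)
}

#' Exact-subset intersection partition of per-stratum significant sets
#'
#' UpSet-plot semantics: a phenotype significant in exactly the strata
#' {A, B} appears only in the {A, B} block, not in {A} or {B}.
#'
#' @param sig_sets named list, stratum -> character vector of significant
#'   phenotypes.
#' @return data.frame strata (comma-joined sorted subset label), n_strata,
#'   phenotypes (list column), n; one row per non-empty block.
#' @export
intersect_significant <- function(sig_sets) {
  stopifnot(!is.null(names(sig_sets)))
  all_ph <- sort(unique(unlist(sig_sets, use.names = FALSE)))
  if (length(all_ph) == 0) {
    return(data.frame(strata = character(), n_strata = integer(), n = integer(),
                      phenotypes = I(list()), stringsAsFactors = FALSE))
  }
  membership <- vapply(sig_sets, function(s) all_ph %in% s,
                       logical(length(all_ph)))
  if (length(all_ph) == 1) membership <- matrix(membership, nrow = 1,
                                                dimnames = list(NULL, names(sig_sets)))
  key <- apply(membership, 1, function(row)
    paste(sort(names(sig_sets)[row]), collapse = ","))
  blocks <- split(all_ph, key)
  data.frame(strata = names(blocks),
             n_strata = lengths(strsplit(names(blocks), ",", fixed = TRUE)),
             n = lengths(blocks),
             phenotypes = I(unname(blocks)),
             stringsAsFactors = FALSE, row.names = NULL)
}
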