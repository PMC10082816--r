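#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a child seed from a global seed and a stage label
#'
#' All stochastic stages of the pipeline derive their own seed
#' deterministically from one global integer seed, so that a single seed
#' fully determines every output while stages stay independently
#' re-runnable.
#'
#' @param seed global integer seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 69069 + h * 9973) %% (2^31 - 1))
}

#' @keywords internal
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# standardized mean difference for a numeric covariate
#' @keywords internal
smd_numeric <- function(x_case, x_ctrl) {
  v <- (stats::var(x_case) + stats::var(x_ctrl)) / 2
  if (!is.finite(v) || v == 0) return(0)
  abs(mean(x_case) - mean(x_ctrl)) / sqrt(v)
}

# SMD for a categorical covariate: max level-wise SMD over indicator variables
#' @keywords internal
smd_categorical <- function(x_case, x_ctrl) {
  levs <- sort(unique(c(as.character(x_case), as.character(x_ctrl))))
  if (length(levs) < 2L) return(0)
  max(vapply(levs, function(l) {
    p1 <- mean(x_case == l)
    p2 <- mean(x_ctrl == l)
    v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
    if (v == 0) 0 else abs(p1 - p2) / sqrt(v)
  }, numeric(1)))
}
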