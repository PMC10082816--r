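#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Enumerates every table compatible with the observed margins over the
#' feasible range of the top-left cell and sums the hypergeometric point
#' probabilities of all tables whose point probability does not exceed the
#' observed one. A relative tolerance of 1e-7 guards against floating-point
#' ties in the point probabilities. A zero margin on either axis yields p = 1
#' by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (cases with/without,
#'   controls with/without the phenotype).
#' @return two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Pearson statistic without continuity correction, 1 degree of freedom,
#' upper-tail p. Small-cell tables are meant to be routed to Fisher's test by
#' [select_test()]; a zero expected count here is therefore an error, not a
#' convention.
#'
#' @inheritParams fisher_exact_two_sided
#' @return list with `statistic` and `p_value`.
#' @export
chi2_test <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  if (any(e == 0))
    stop("zero expected count: this table should be tested with ",
         "fisher_exact_two_sided", call. = FALSE)
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Choose the significance test for a 2x2 table
#'
#' Fisher's exact test when any cell holds fewer than 5 patients, the
#' chi-squared test otherwise.
#'
#' @inheritParams fisher_exact_two_sided
#' @return `"fisher"` or `"chi2"`.
#' @export
select_test <- function(a, b, c, d) {
  if (min(a, b, c, d) < 5) "fisher" else "chi2"
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' `(a*d)/(b*c)`; when any cell is zero, 0.5 is added to all four cells
#' first.
#'
#' @inheritParams fisher_exact_two_sided
#' @return positive odds ratio.
#' @export
odds_ratio_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

# midranks plus the tie-correction term sum(t^3 - t) over tie groups
#' @keywords internal
midrank_info <- function(values) {
  r <- rank(values)
  t <- tabulate(match(r, unique(r)))
  list(ranks = r, tie_term = sum(t^3 - t))
}

#' Two-sided Mann-Whitney U test
#'
#' U from rank sums with midranks for ties; two-sided p from the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction. The reported U is for the first sample (number of (x, y)
#' pairs with x > y, counting ties as 1/2).
#'
#' @param x,y numeric samples.
#' @return list with `U` and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  mi <- midrank_info(c(x, y))
  r1 <- sum(mi$ranks[seq_len(n1)])
  U <- r1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - mi$tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U, p_value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with p from the chi-squared distribution on
#' k - 1 degrees of freedom.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  n <- length(values)
  mi <- midrank_info(values)
  rs <- tapply(mi$ranks, groups, sum)
  ns <- tapply(values, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  corr <- 1 - mi$tie_term / (n^3 - n)
  if (corr > 0) h <- h / corr
  df <- length(levs) - 1
  list(H = h, df = df,
       p_value = stats::pchisq(h, df = df, lower.tail = FALSE))
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' For groups i, j the statistic is
#' `z = (meanrank_i - meanrank_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`
#' with midranks over the pooled sample and the tie term summed over tie
#' groups. Two-sided p-values are Bonferroni-multiplied by the number of
#' pairs and capped at 1.
#'
#' @inheritParams kruskal_wallis
#' @param correction only "bonferroni" is implemented.
#' @return data.frame group_i, group_j, z, p_unadjusted, p_bonferroni with
#'   one row per unordered pair (groups in sorted order).
#' @export
dunn_posthoc <- function(values, groups, correction = "bonferroni") {
  stopifnot(correction == "bonferroni")
  groups <- as.character(groups)
  levs <- sort(unique(groups))
  if (any(!levs %in% groups)) stop("empty group", call. = FALSE)
  n <- length(values)
  mi <- midrank_info(values)
  mr <- tapply(mi$ranks, groups, mean)[levs]
  ns <- tapply(values, groups, length)[levs]
  var_base <- n * (n + 1) / 12 - mi$tie_term / (12 * (n - 1))
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / ns[[i]] + 1 / ns[[j]]))
    z[k] <- if (se == 0) 0 else (mr[[i]] - mr[[j]]) / se
    p[k] <- 2 * stats::pnorm(abs(z[k]), lower.tail = FALSE)
  }
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], z = z,
             p_unadjusted = p, p_bonferroni = pmin(1, p * m),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranks; the two-sided p comes from
#' the t approximation with n - 2 degrees of freedom. A constant vector
#' leaves rho undefined (NA).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `rho` and `p_value` (NA when undefined).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho,
       p_value = 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
}
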