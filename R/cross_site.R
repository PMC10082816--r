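#' Pair discovery-site differential results with a validation site
#'
#' For each stratum, restricts to phenotypes significant at the discovery
#' site and tested at both sites, flags replication (significant at the
#' validation site), and computes per-stratum replication fractions.
#'
#' @param discovery,validation data.frames from [run_differential()] (rows
#'   for all tested phenotypes, possibly several strata each).
#' @return list with `pairs` (stratum, phenotype, OR_discovery,
#'   OR_validation, significant_discovery, significant_validation,
#'   replicated) and `summary` (stratum, n_sig_discovery, n_replicated,
#'   replication_fraction; fraction NA with a warning when a stratum has no
#'   discovery-significant phenotype).
#' @export
pair_site_results <- function(discovery, validation) {
  s1 <- sort(unique(discovery$stratum)); s2 <- sort(unique(validation$stratum))
  if (!identical(s1, s2))
    stop("strata differ between sites: ",
         paste(union(setdiff(s1, s2), setdiff(s2, s1)), collapse = ", "),
         call. = FALSE)
  pairs <- list(); summ <- list()
  for (st in s1) {
    d <- discovery[discovery$stratum == st & discovery$significant, ]
    v <- validation[validation$stratum == st, ]
    m <- match(d$phenotype, v$phenotype)
    tested_both <- !is.na(m)
    d <- d[tested_both, ]; m <- m[tested_both]
    if (nrow(d) == 0) {
      warning("stratum '", st, "': no discovery-significant phenotype; ",
              "replication fraction undefined", call. = FALSE)
      summ[[st]] <- data.frame(stratum = st, n_sig_discovery = 0L,
                               n_replicated = 0L,
                               replication_fraction = NA_real_)
      next
    }
    rep_flag <- v$significant[m]
    pairs[[st]] <- data.frame(
      stratum = st, phenotype = d$phenotype,
      OR_discovery = d$odds_ratio, OR_validation = v$odds_ratio[m],
      significant_discovery = TRUE, significant_validation = rep_flag,
      replicated = rep_flag, stringsAsFactors = FALSE)
    summ[[st]] <- data.frame(stratum = st,
                             n_sig_discovery = nrow(d),
                             n_replicated = sum(rep_flag),
                             replication_fraction = mean(rep_flag))
  }
  list(pairs = if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
       else NULL,
       summary = do.call(rbind, c(summ, make.row.names = FALSE)))
}

#' Cross-site odds-ratio concordance (Spearman on log odds ratios)
#'
#' For each stratum, the Spearman rank correlation between the two sites'
#' log odds ratios over either the replicated subset or the
#' discovery-only subset (significant at discovery but not validation).
#' Strata with fewer than 3 pairs are reported as not computable (NA).
#'
#' @param paired result of [pair_site_results()].
#' @param subset `"replicated"` or `"discovery_only"`.
#' @return data.frame stratum, n, rho, p_value, plus the log-OR pair table
#'   in attribute `plot_data` (log-log plot input).
#' @export
or_concordance <- function(paired, subset = c("replicated", "discovery_only")) {
  subset <- match.arg(subset)
  p <- paired$pairs
  if (is.null(p)) stop("no paired phenotypes", call. = FALSE)
  sel <- if (subset == "replicated") p$replicated else !p$replicated
  p <- p[sel, , drop = FALSE]
  out <- lapply(sort(unique(paired$summary$stratum)), function(st) {
    q <- p[p$stratum == st, , drop = FALSE]
    if (nrow(q) < 3) {
      return(data.frame(stratum = st, n = nrow(q), rho = NA_real_,
                        p_value = NA_real_))
    }
    sr <- spearman_rho(log(q$OR_discovery), log(q$OR_validation))
    data.frame(stratum = st, n = nrow(q), rho = sr$rho, p_value = sr$p_value)
  })
  res <- do.call(rbind, out)
  attr(res, "plot_data") <- data.frame(
    stratum = p$stratum, phenotype = p$phenotype,
    log_OR_discovery = log(p$OR_discovery),
    log_OR_validation = log(p$OR_validation), stringsAsFactors = FALSE)
  res
}

#' Cross-site concordance of network topology metrics
#'
#' Reduces each network's node-level metric values to one summary value
#' (median over nodes by default), z-scores each metric across the networks
#' within each site ("standard normalized to the metric"), and correlates
#' the two sites' standardized (network, metric) cells by Spearman rank
#' correlation.
#'
#' @param metric_tables_site1,metric_tables_site2 named lists of
#'   [node_metrics()] tables; the two sites must share network labels.
#' @param summary_fn `"median"` (default) or `"mean"` node-level reduction.
#' @return list with `cells` (network, metric, z_site1, z_site2), `rho`,
#'   `p_value`.
#' @export
metric_concordance <- function(metric_tables_site1, metric_tables_site2,
                               summary_fn = c("median", "mean")) {
  summary_fn <- match.arg(summary_fn)
  f <- if (summary_fn == "median") stats::median else mean
  labels <- names(metric_tables_site1)
  missing <- setdiff(labels, names(metric_tables_site2))
  if (length(missing) > 0 || length(labels) != length(metric_tables_site2))
    stop("network labels differ between sites", call. = FALSE)
  metrics <- setdiff(names(metric_tables_site1[[1]]), "phenotype")
  site_summary <- function(tables) {
    sapply(metrics, function(m)
      vapply(tables[labels], function(tb) f(tb[[m]]), numeric(1)))
  }
  z_by_metric <- function(s) {
    apply(s, 2, function(col) {
      sdv <- stats::sd(col)
      if (is.na(sdv) || sdv == 0) rep(0, length(col))
      else (col - mean(col)) / sdv
    })
  }
  z1 <- z_by_metric(site_summary(metric_tables_site1))
  z2 <- z_by_metric(site_summary(metric_tables_site2))
  cells <- data.frame(network = rep(labels, times = length(metrics)),
                      metric = rep(metrics, each = length(labels)),
                      z_site1 = as.numeric(z1), z_site2 = as.numeric(z2),
                      stringsAsFactors = FALSE)
  sr <- spearman_rho(cells$z_site1, cells$z_site2)
  list(cells = cells, rho = sr$rho, p_value = sr$p_value)
}
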