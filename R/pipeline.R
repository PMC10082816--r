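#' Build and validate a pipeline configuration
#'
#' Fills defaults and checks invariants for a full pipeline run. `config`
#' may be a named list or a path to a JSON file with the same fields. All
#' validation failures are aggregated into one error message.
#'
#' @param config named list or JSON file path. Recognized fields:
#'   input_mode ("synthetic" or "omop_lite_files"), input_dir, phecode_map
#'   (path or NULL for the bundled fixture), n_cases_per_stratum,
#'   control_pool_multiplier, n_phenotypes, fraction_null, effect_or_range,
#'   confounding_strength, ratio, common_support, node_threshold,
#'   edge_threshold, vis_threshold, alpha, exclude_phenotypes, sites,
#'   validation_site (logical: simulate and analyze a second site),
#'   shared_fraction, seed, out_dir.
#' @return validated config list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  defaults <- list(input_mode = "synthetic", input_dir = NULL,
                   phecode_map = NULL,
                   n_cases_per_stratum = 422, control_pool_multiplier = 5,
                   n_phenotypes = 20, fraction_null = 0.5,
                   effect_or_range = c(1.5, 4), confounding_strength = 1,
                   ratio = 2, common_support = FALSE,
                   node_threshold = 0.05, edge_threshold = 0.05,
                   vis_threshold = 0.25, alpha = 0.05,
                   exclude_phenotypes = "Alzheimer's disease",
                   sites = "siteA", validation_site = FALSE,
                   shared_fraction = 1, seed = 1L, out_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  errors <- character()
  if (length(unknown) > 0)
    errors <- c(errors, paste("unknown field(s):", paste(unknown, collapse = ", ")))
  if (!cfg$input_mode %in% c("synthetic", "omop_lite_files"))
    errors <- c(errors, "input_mode must be 'synthetic' or 'omop_lite_files'")
  if (cfg$input_mode == "omop_lite_files" && is.null(cfg$input_dir))
    errors <- c(errors, "input_dir required for omop_lite_files mode")
  if (!(cfg$alpha > 0 && cfg$alpha < 1))
    errors <- c(errors, "alpha must be in (0, 1)")
  for (f in c("node_threshold", "edge_threshold", "vis_threshold")) {
    if (!(cfg[[f]] >= 0 && cfg[[f]] < 1))
      errors <- c(errors, paste(f, "must be in [0, 1)"))
  }
  if (cfg$ratio < 1) errors <- c(errors, "ratio must be >= 1")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errors <- c(errors, "seed must be a single integer")
  if (length(errors) > 0)
    stop("configuration errors:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' @keywords internal
stage_log <- function(logs, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(logs, stats::setNames(msg, stage))
}

# analyze one site's cohort: match, matrix, embedding, differential, networks
#' @keywords internal
analyze_site <- function(patients, diagnoses, map, cfg, site_tag) {
  res <- list()
  parsed <- map_diagnoses(diagnoses, map)
  matched <- stratified_match(
    patients, covariates = c("sex", "estimated_age", "death_status",
                             if (length(cfg$sites) > 1) "site"),
    ratio = cfg$ratio, common_support = cfg$common_support,
    equalize = TRUE, seed = child_seed(cfg$seed, paste0("match_", site_tag)))
  res$matched <- matched
  res$balance <- balance_table(matched, patients,
                               c("sex", "estimated_age", "death_status"))
  cohort_ids <- unlist(lapply(matched, function(m) c(m$case_ids, m$control_ids)),
                       use.names = FALSE)
  mat <- build_phenotype_matrix(
    parsed$assignments[parsed$assignments$person_id %in% cohort_ids, ],
    cohort_ids, exclude_phenotypes = cfg$exclude_phenotypes)
  res$matrix <- mat
  res$unmapped <- parsed$unmapped
  rownames(patients) <- patients$person_id
  # embedding + comparisons
  emb <- embed_2d(mat, seed = child_seed(cfg$seed, paste0("umap_", site_tag)))
  ad_status <- ifelse(patients[rownames(mat), "is_case"], "AD", "control")
  stratum_lab <- patients[rownames(mat), "race_ethnicity"]
  res$embedding <- emb
  res$embedding_comparisons <- list(
    AD_status = compare_embedding(emb, stats::setNames(ad_status, rownames(mat))),
    stratum = compare_embedding(emb, stats::setNames(stratum_lab, rownames(mat))))
  if (length(cfg$sites) > 1) {
    site_lab <- patients[rownames(mat), "site"]
    res$embedding_comparisons$site <-
      compare_embedding(emb, stats::setNames(site_lab, rownames(mat)))
  }
  # per-stratum differential + networks
  res$differential <- list(); res$networks <- list(); res$metrics <- list()
  for (st in names(matched)) {
    m <- matched[[st]]
    res$differential[[st]] <- run_differential(mat, m$case_ids, m$control_ids,
                                               stratum = st, alpha = cfg$alpha)
    for (grp in c("AD", "control")) {
      ids <- if (grp == "AD") m$case_ids else m$control_ids
      lab <- paste(st, grp, sep = "_")
      net <- build_network(mat, ids, cfg$node_threshold, cfg$edge_threshold,
                           label = lab)
      res$networks[[lab]] <- net
      res$metrics[[lab]] <- node_metrics(net)
    }
  }
  res$differential_all <- do.call(rbind, c(res$differential,
                                           make.row.names = FALSE))
  res$significant_sets <- lapply(res$differential, function(d)
    d$phenotype[d$significant])
  res$intersections <- intersect_significant(res$significant_sets)
  res
}

#' Run the full stratified comorbidity pipeline
#'
#' Executes, in order: cohort generation (or OMOP-lite loading), phecode
#' mapping, two-round stratified 1:2 propensity matching with balance
#' diagnostics, phenotype-matrix construction, UMAP embedding comparisons,
#' per-stratum differential analysis with intersection partitioning, the 8
#' co-occurrence networks (4 strata x AD/control) with node metrics and
#' network comparisons, and — when a validation site is configured — the
#' cross-site replication and concordance analyses. When `out_dir` is set,
#' stage outputs are written as plain files with a run manifest.
#'
#' @param config a [validate_config()] input.
#' @return a `report_bundle` list with elements: config, discovery (per-site
#'   analysis), validation (or NULL), network_comparisons, cross_site (or
#'   NULL), manifest, logs.
#' @export
run_full <- function(config = list()) {
  cfg <- validate_config(config)
  logs <- character()
  map_path <- if (is.null(cfg$phecode_map))
    system.file("extdata", "phecode_map_synthetic.csv", package = "adcomorbid")
  else cfg$phecode_map
  map <- load_phecode_map(map_path)
  logs <- stage_log(logs, "map", "phecode map: %d rows", nrow(map))
  if (cfg$input_mode == "synthetic") {
    sc <- sim_config(n_cases_per_stratum = cfg$n_cases_per_stratum,
                     control_pool_multiplier = cfg$control_pool_multiplier,
                     n_phenotypes = cfg$n_phenotypes,
                     fraction_null = cfg$fraction_null,
                     effect_or_range = cfg$effect_or_range,
                     confounding_strength = cfg$confounding_strength,
                     sites = cfg$sites, seed = cfg$seed)
    effects <- draw_effects(sc, shared_fraction = cfg$shared_fraction)
    gen <- generate_cohort(sc, effects)
    patients <- gen$patients
    diagnoses <- generate_diagnoses(patients, effects, sc, map)
    ground_truth <- effects
  } else {
    loaded <- read_omop_lite(cfg$input_dir)
    patients <- loaded$patients; diagnoses <- loaded$diagnoses
    ground_truth <- NULL
  }
  logs <- stage_log(logs, "input", "%d patients, %d diagnosis events",
                    nrow(patients), nrow(diagnoses))
  discovery <- analyze_site(patients, diagnoses, map, cfg, "discovery")
  logs <- stage_log(logs, "discovery",
                    "%d networks, %d strata, %d tested phenotypes",
                    length(discovery$networks), length(discovery$matched),
                    length(unique(discovery$differential_all$phenotype)))
  # network comparisons within the discovery site
  ad_tables <- discovery$metrics[grepl("_AD$", names(discovery$metrics))]
  ctrl_tables <- discovery$metrics[grepl("_control$", names(discovery$metrics))]
  metric_names <- setdiff(names(discovery$metrics[[1]]), "phenotype")
  network_comparisons <- list(
    ad_networks = lapply(stats::setNames(metric_names, metric_names),
                         function(m) compare_networks_kw(ad_tables, m)),
    control_networks = lapply(stats::setNames(metric_names, metric_names),
                              function(m) compare_networks_kw(ctrl_tables, m)),
    ad_vs_control = lapply(stats::setNames(names(ad_tables), names(ad_tables)),
                           function(lab) {
      ctrl_lab <- sub("_AD$", "_control", lab)
      lapply(stats::setNames(metric_names, metric_names), function(m)
        compare_ad_vs_control(discovery$metrics[[lab]],
                              discovery$metrics[[ctrl_lab]], m))
    }))
  validation <- NULL; cross_site <- NULL
  if (isTRUE(cfg$validation_site) && cfg$input_mode == "synthetic") {
    vcfg <- cfg; vcfg$seed <- child_seed(cfg$seed, "validation_cohort")
    vsc <- sim_config(n_cases_per_stratum = cfg$n_cases_per_stratum,
                      control_pool_multiplier = cfg$control_pool_multiplier,
                      n_phenotypes = cfg$n_phenotypes,
                      fraction_null = cfg$fraction_null,
                      effect_or_range = cfg$effect_or_range,
                      confounding_strength = cfg$confounding_strength,
                      sites = "validation", seed = vcfg$seed)
    vpat <- generate_cohort(vsc, ground_truth)$patients
    vdx <- generate_diagnoses(vpat, ground_truth, vsc, map,
                              validation_site = TRUE)
    validation <- analyze_site(vpat, vdx, map, vcfg, "validation")
    logs <- stage_log(logs, "validation", "%d networks",
                      length(validation$networks))
    paired <- pair_site_results(discovery$differential_all,
                                validation$differential_all)
    cross_site <- list(
      paired = paired,
      or_concordance_replicated = or_concordance(paired, "replicated"),
      metric_concordance = metric_concordance(discovery$metrics,
                                              validation$metrics))
    disc_only <- tryCatch(or_concordance(paired, "discovery_only"),
                          error = function(e) NULL)
    cross_site$or_concordance_discovery_only <- disc_only
  } else {
    logs <- stage_log(logs, "cross_site", "skipped (single site)")
  }
  bundle <- list(config = cfg, ground_truth = ground_truth,
                 discovery = discovery, validation = validation,
                 network_comparisons = network_comparisons,
                 cross_site = cross_site, logs = logs)
  bundle$manifest <- list(
    seed = cfg$seed,
    n_patients = nrow(patients),
    n_networks = length(discovery$networks),
    networks = names(discovery$networks),
    strata = names(discovery$matched),
    has_validation_site = !is.null(validation))
  if (!is.null(cfg$out_dir)) bundle$manifest$files <- write_bundle(bundle, cfg$out_dir)
  class(bundle) <- "report_bundle"
  bundle
}

# write the plain-file artifacts of a run; returns the file list
#' @keywords internal
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (is.data.frame(obj)) utils::write.csv(obj, p, row.names = FALSE)
    else jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                              force = TRUE)
    files <<- c(files, p)
    p
  }
  wr(bundle$discovery$balance, "balance_table.csv")
  wr(bundle$discovery$differential_all, "differential_discovery.csv")
  inter <- bundle$discovery$intersections
  inter$phenotypes <- vapply(inter$phenotypes, paste, character(1), collapse = ";")
  wr(inter, "intersections_discovery.csv")
  wr(bundle$discovery$embedding$coords, "embedding_discovery.csv")
  for (lab in names(bundle$discovery$metrics))
    wr(bundle$discovery$metrics[[lab]], sprintf("metrics_%s.csv", lab))
  if (!is.null(bundle$cross_site)) {
    wr(bundle$cross_site$paired$summary, "replication_summary.csv")
    wr(bundle$cross_site$or_concordance_replicated, "or_concordance.csv")
    wr(bundle$cross_site$metric_concordance$cells, "metric_concordance_cells.csv")
  }
  wr(bundle$manifest[setdiff(names(bundle$manifest), "files")], "manifest.json")
  files
}
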