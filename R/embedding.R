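#' 2-D UMAP embedding of one-hot phenotype profiles
#'
#' Embeds the binary patient-by-phenotype matrix in two dimensions with
#' UMAP (via uwot). The AD-defining phenotype must already be excluded from
#' the columns: its presence would encode case status directly into the
#' profile being visualized. Runs single-threaded with a fixed seed so the
#' same input always yields the same coordinates.
#'
#' @param matrix binary patient-by-phenotype matrix (rownames = person_id).
#' @param n_neighbors,min_dist UMAP hyperparameters (uwot defaults).
#' @param seed integer seed.
#' @param ad_phenotype column name that must be absent.
#' @return list with `coords` (data.frame person_id, comp1, comp2),
#'   `feature_count`, and `params`.
#' @export
embed_2d <- function(matrix, n_neighbors = 15, min_dist = 0.1, seed = 1L,
                     ad_phenotype = "Alzheimer's disease") {
  if (ad_phenotype %in% colnames(matrix))
    stop("the AD phenotype column must be excluded before embedding",
         call. = FALSE)
  if (nrow(matrix) < 10)
    stop("need at least 10 patients to embed", call. = FALSE)
  set.seed(seed)
  emb <- uwot::umap(matrix * 1, n_components = 2,
                    n_neighbors = min(n_neighbors, nrow(matrix) - 1),
                    min_dist = min_dist,
                    n_threads = 1, n_sgd_threads = 0)
  list(coords = data.frame(person_id = rownames(matrix),
                           comp1 = emb[, 1], comp2 = emb[, 2],
                           stringsAsFactors = FALSE, row.names = NULL),
       feature_count = ncol(matrix),
       params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                     seed = seed))
}

#' Compare embedding component distributions across patient groups
#'
#' For each embedding component: a two-sided Mann-Whitney U test when the
#' grouping has two levels, a Kruskal-Wallis test followed by Dunn's post hoc
#' pairwise tests (Bonferroni-corrected over the pairs) when it has more.
#' Empty levels are dropped with a warning.
#'
#' @param embedding result of [embed_2d()].
#' @param labels named vector (names = person_id) or vector aligned with the
#'   embedding rows, giving each patient's group (AD status, stratum, site).
#' @return list of per-component results: `test` ("MWU" or "KW"),
#'   `statistic`, `p_value`, and `posthoc` (data.frame or NULL).
#' @export
compare_embedding <- function(embedding, labels) {
  coords <- embedding$coords
  if (!is.null(names(labels))) {
    stopifnot(all(coords$person_id %in% names(labels)))
    labels <- labels[coords$person_id]
  }
  stopifnot(length(labels) == nrow(coords))
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab == 0)) {
    warning("dropping empty group level(s)", call. = FALSE)
    keep <- labels %in% names(tab)[tab > 0]
    coords <- coords[keep, ]; labels <- labels[keep]
  }
  levs <- sort(unique(labels))
  out <- list()
  for (comp in c("comp1", "comp2")) {
    v <- coords[[comp]]
    if (length(levs) == 2) {
      mw <- mann_whitney_u(v[labels == levs[1]], v[labels == levs[2]])
      out[[comp]] <- list(test = "MWU", statistic = mw$U,
                          p_value = mw$p_value, posthoc = NULL)
    } else {
      kw <- kruskal_wallis(v, labels)
      out[[comp]] <- list(test = "KW", statistic = kw$H,
                          p_value = kw$p_value,
                          posthoc = dunn_posthoc(v, labels))
    }
  }
  out
}
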