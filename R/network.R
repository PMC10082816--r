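#' Build a prevalence-thresholded disease co-occurrence network
#'
#' Nodes are phenotypes carried by strictly more than `node_threshold` of the
#' cohort; edges are phenotype pairs carried jointly by strictly more than
#' `edge_threshold` of the cohort. Since a pair's co-prevalence cannot exceed
#' either marginal prevalence, both endpoints of every edge are nodes
#' whenever the edge threshold is at least the node threshold. Graphs are
#' simple and unweighted; prevalences are attributes.
#'
#' @param matrix binary patient-by-phenotype matrix.
#' @param cohort_ids rows of `matrix` forming this network's cohort.
#' @param node_threshold,edge_threshold prevalence fractions in `[0, 1)`.
#' @param label free-form identifier, e.g. `"White_AD"`.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (phenotype, prevalence), `edges` (p1, p2, coprevalence), thresholds,
#'   `cohort_size`, `label`.
#' @export
build_network <- function(matrix, cohort_ids, node_threshold = 0.05,
                          edge_threshold = 0.05, label = NA_character_) {
  if (length(cohort_ids) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(all(cohort_ids %in% rownames(matrix)),
            node_threshold >= 0, node_threshold < 1,
            edge_threshold >= 0, edge_threshold < 1)
  m <- matrix[cohort_ids, , drop = FALSE]
  n <- nrow(m)
  prev <- colSums(m) / n
  keep <- prev > node_threshold
  phenos <- sort(colnames(m)[keep])
  nodes <- data.frame(phenotype = phenos,
                      prevalence = prev[phenos],
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- data.frame(p1 = character(), p2 = character(),
                      coprevalence = numeric(), stringsAsFactors = FALSE)
  if (length(phenos) >= 2) {
    co <- crossprod(m[, phenos, drop = FALSE]) / n
    pair <- which(upper.tri(co) & co > edge_threshold, arr.ind = TRUE)
    if (nrow(pair) > 0) {
      edges <- data.frame(p1 = phenos[pair[, 1]], p2 = phenos[pair[, 2]],
                          coprevalence = co[pair], stringsAsFactors = FALSE)
      edges <- edges[order(edges$p1, edges$p2), ]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 node_threshold = node_threshold,
                 edge_threshold = edge_threshold,
                 cohort_size = n, label = label),
            class = "cooccurrence_network")
}

#' @keywords internal
network_adjacency <- function(network) {
  phenos <- network$nodes$phenotype
  a <- matrix(0L, length(phenos), length(phenos),
              dimnames = list(phenos, phenos))
  if (nrow(network$edges) > 0) {
    i <- match(network$edges$p1, phenos)
    j <- match(network$edges$p2, phenos)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

# all-pairs shortest-path counts by level-wise dynamic programming
#' @keywords internal
shortest_path_counts <- function(adj, d) {
  nv <- nrow(adj)
  sigma <- matrix(0, nv, nv)
  for (s in seq_len(nv)) {
    sigma[s, s] <- 1
    ds <- d[s, ]
    finite <- ds[is.finite(ds)]
    if (max(finite) < 1) next
    for (lev in seq_len(max(finite))) {
      prev <- which(ds == lev - 1)
      cur <- which(ds == lev)
      if (length(cur) == 0) break
      sigma[s, cur] <- as.numeric(
        sigma[s, prev, drop = FALSE] %*% adj[prev, cur, drop = FALSE])
    }
  }
  sigma
}

#' Ten node-topology metrics of a co-occurrence network
#'
#' Computes, per node: degree; clustering coefficient `2e/(k(k-1))` (0 for
#' degree <= 1); neighborhood connectivity (mean neighbor degree, 0 if
#' isolated); topological coefficient (mean over nodes sharing a neighbor of
#' (shared neighbors + adjacency) / degree, 0 for degree <= 1); and the
#' path-based metrics within each connected component — average
#' shortest-path length, closeness (1/aspl), eccentricity, radiality
#' `(diameter + 1 - aspl)/diameter`, stress (number of shortest paths
#' between other node pairs passing through the node), and betweenness
#' (Brandes ratio sum, normalized by `(Nc-1)(Nc-2)/2` within the component).
#' Isolated nodes take aspl 0, closeness 0, eccentricity 0, radiality 1.
#'
#' @param network a `cooccurrence_network` (or a bare adjacency matrix with
#'   dimnames, accepted for testing).
#' @return data.frame with one row per node and columns: phenotype, degree,
#'   average_shortest_path_length, closeness_centrality, eccentricity,
#'   radiality, stress, betweenness_centrality, clustering_coefficient,
#'   neighborhood_connectivity, topological_coefficient.
#' @export
node_metrics <- function(network) {
  adj <- if (inherits(network, "cooccurrence_network"))
    network_adjacency(network) else network
  nv <- nrow(adj)
  if (nv == 0) stop("network has no nodes", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(g)
  comp <- igraph::components(g)$membership
  k <- rowSums(adj)
  shared <- adj %*% adj          # shared-neighbor counts
  sigma <- shortest_path_counts(adj, d)
  aspl <- ecc <- radial <- closeness <- stress <- betw <- numeric(nv)
  clust <- nbc <- topo <- numeric(nv)
  for (cid in unique(comp)) {
    vs <- which(comp == cid)
    nc <- length(vs)
    dc <- d[vs, vs, drop = FALSE]
    diam <- max(dc)
    for (v in vs) {
      dv <- d[v, vs]
      aspl[v] <- if (nc > 1) mean(dv[vs != v]) else 0
      ecc[v] <- if (nc > 1) max(dv) else 0
      closeness[v] <- if (aspl[v] > 0) 1 / aspl[v] else 0
      radial[v] <- if (diam > 0) (diam + 1 - aspl[v]) / diam else 1
    }
    if (nc >= 3) {
      sc <- sigma[vs, vs, drop = FALSE]
      norm <- (nc - 1) * (nc - 2) / 2
      for (i in seq_len(nc)) {
        v <- vs[i]
        through <- outer(sc[, i], sc[i, ]) *
          (outer(dc[, i], dc[i, ], `+`) == dc)
        through[i, ] <- 0; through[, i] <- 0
        diag(through) <- 0
        stress[v] <- sum(through) / 2
        ratio <- through / ifelse(sc > 0, sc, 1)
        betw[v] <- (sum(ratio) / 2) / norm
      }
    }
  }
  for (v in seq_len(nv)) {
    nb <- which(adj[v, ] == 1)
    if (k[v] >= 2) {
      e <- sum(adj[nb, nb]) / 2
      clust[v] <- 2 * e / (k[v] * (k[v] - 1))
    }
    nbc[v] <- if (k[v] > 0) mean(k[nb]) else 0
    if (k[v] >= 2) {
      ms <- which(shared[v, ] > 0)
      ms <- ms[ms != v]
      if (length(ms) > 0)
        topo[v] <- mean((shared[v, ms] + adj[v, ms]) / k[v])
    }
  }
  data.frame(phenotype = rownames(adj), degree = as.integer(k),
             average_shortest_path_length = aspl,
             closeness_centrality = closeness, eccentricity = ecc,
             radiality = radial, stress = stress,
             betweenness_centrality = betw,
             clustering_coefficient = clust,
             neighborhood_connectivity = nbc,
             topological_coefficient = topo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare a node metric across three or more networks (Kruskal-Wallis + Dunn)
#'
#' Pools the node-level values of `metric_name` across networks and tests
#' whether their distributions differ, with Bonferroni-corrected Dunn post
#' hoc pairs.
#'
#' @param metric_tables named list of [node_metrics()] tables.
#' @param metric_name one of the ten metric column names.
#' @return list with `H`, `p_value`, `posthoc`.
#' @export
compare_networks_kw <- function(metric_tables, metric_name) {
  stopifnot(length(metric_tables) >= 3, !is.null(names(metric_tables)))
  for (nm in names(metric_tables)) {
    if (!metric_name %in% names(metric_tables[[nm]]))
      stop("metric '", metric_name, "' missing from network '", nm, "'",
           call. = FALSE)
  }
  values <- unlist(lapply(metric_tables, `[[`, metric_name), use.names = FALSE)
  groups <- rep(names(metric_tables),
                vapply(metric_tables, nrow, integer(1)))
  kw <- kruskal_wallis(values, groups)
  list(H = kw$H, p_value = kw$p_value,
       posthoc = dunn_posthoc(values, groups))
}

#' Compare one node metric between an AD and a control network (Mann-Whitney U)
#'
#' @param metric_table_ad,metric_table_ctrl [node_metrics()] tables.
#' @param metric_name metric column name.
#' @return list with `U` and `p_value`.
#' @export
compare_ad_vs_control <- function(metric_table_ad, metric_table_ctrl,
                                  metric_name) {
  if (nrow(metric_table_ad) == 0 || nrow(metric_table_ctrl) == 0)
    stop("empty metric table", call. = FALSE)
  mann_whitney_u(metric_table_ad[[metric_name]],
                 metric_table_ctrl[[metric_name]])
}

#' Top phenotype pairs by co-prevalence
#'
#' @param network a `cooccurrence_network`.
#' @param k number of pairs returned.
#' @return data.frame p1, p2, coprevalence sorted by descending
#'   co-prevalence, ties broken lexicographically by (p1, p2).
#' @export
top_pairs <- function(network, k = 10) {
  e <- network$edges
  if (nrow(e) == 0) {
    warning("network has no edges", call. = FALSE)
    return(e)
  }
  e <- e[order(-e$coprevalence, e$p1, e$p2), ]
  rownames(e) <- NULL
  utils::head(e, k)
}

#' Rebuild a network at the visualization threshold and export GraphML
#'
#' Rebuilds the co-occurrence network with both thresholds at `threshold`
#' (default 25%, the display cut) and optionally writes a GraphML file with
#' prevalence, co-prevalence, and phecode-category attributes.
#'
#' @inheritParams build_network
#' @param threshold node and edge prevalence cut for display.
#' @param graphml_path optional output path.
#' @param categories optional named vector phenotype -> phecode category,
#'   attached as a node attribute.
#' @return the rebuilt `cooccurrence_network`.
#' @export
visualization_subnetwork <- function(matrix, cohort_ids, threshold = 0.25,
                                     label = NA_character_,
                                     graphml_path = NULL, categories = NULL) {
  net <- build_network(matrix, cohort_ids, node_threshold = threshold,
                       edge_threshold = threshold, label = label)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("p1", "p2")], directed = FALSE,
      vertices = data.frame(name = net$nodes$phenotype))
    igraph::V(g)$prevalence <- net$nodes$prevalence[
      match(igraph::V(g)$name, net$nodes$phenotype)]
    if (!is.null(categories))
      igraph::V(g)$category <- unname(categories[igraph::V(g)$name])
    if (nrow(net$edges) > 0)
      igraph::E(g)$coprevalence <- net$edges$coprevalence
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  net
}
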