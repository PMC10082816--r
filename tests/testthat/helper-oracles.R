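# Independent brute-force oracles used to cross-check the implementation.
# Everything here is written from first principles (own BFS, explicit
# shortest-path enumeration, explicit midranks) and never calls package code.

oracle_bfs_distances <- function(adj, s) {
  nv <- nrow(adj)
  d <- rep(Inf, nv)
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer()
    for (v in frontier) {
      for (w in which(adj[v, ] == 1)) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

oracle_distance_matrix <- function(adj) {
  t(vapply(seq_len(nrow(adj)), function(s) oracle_bfs_distances(adj, s),
           numeric(nrow(adj))))
}

# all shortest s -> t paths as lists of vertex sequences (backtracking on d)
oracle_shortest_paths <- function(adj, d, s, t) {
  if (is.infinite(d[s, t])) return(list())
  if (s == t) return(list(s))
  preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
  out <- list()
  for (u in preds) {
    for (p in oracle_shortest_paths(adj, d, s, u)) out <- c(out, list(c(p, t)))
  }
  out
}

oracle_node_metrics <- function(adj) {
  nv <- nrow(adj)
  d <- oracle_distance_matrix(adj)
  deg <- rowSums(adj)
  res <- data.frame(degree = deg, average_shortest_path_length = 0,
                    closeness_centrality = 0, eccentricity = 0, radiality = 0,
                    stress = 0, betweenness_centrality = 0,
                    clustering_coefficient = 0, neighborhood_connectivity = 0,
                    topological_coefficient = 0)
  # component of each vertex from reachability
  comp_of <- integer(nv)
  cid <- 0
  for (v in seq_len(nv)) {
    if (comp_of[v] == 0) {
      cid <- cid + 1
      comp_of[is.finite(d[v, ])] <- cid
    }
  }
  # all shortest paths per component, enumerated once
  for (cc in seq_len(cid)) {
    vs <- which(comp_of == cc)
    diam <- if (length(vs) > 1) max(d[vs, vs]) else 0
    for (v in vs) {
      others <- setdiff(vs, v)
      res$average_shortest_path_length[v] <-
        if (length(others)) mean(d[v, others]) else 0
      res$eccentricity[v] <- if (length(others)) max(d[v, others]) else 0
      res$closeness_centrality[v] <-
        if (res$average_shortest_path_length[v] > 0)
          1 / res$average_shortest_path_length[v] else 0
      res$radiality[v] <- if (diam > 0)
        (diam + 1 - res$average_shortest_path_length[v]) / diam else 1
    }
    if (length(vs) >= 3) {
      norm <- (length(vs) - 1) * (length(vs) - 2) / 2
      for (i in seq_along(vs)) {
        for (j in seq_along(vs)) {
          if (j <= i) next
          s <- vs[i]; t <- vs[j]
          paths <- oracle_shortest_paths(adj, d, s, t)
          for (v in setdiff(vs, c(s, t))) {
            through <- sum(vapply(paths, function(p) v %in% p, logical(1)))
            res$stress[v] <- res$stress[v] + through
            res$betweenness_centrality[v] <-
              res$betweenness_centrality[v] + through / length(paths) / norm
          }
        }
      }
    }
  }
  for (v in seq_len(nv)) {
    nb <- which(adj[v, ] == 1)
    k <- length(nb)
    if (k >= 2) {
      e <- 0
      for (i in seq_len(k - 1)) for (j in (i + 1):k)
        e <- e + adj[nb[i], nb[j]]
      res$clustering_coefficient[v] <- 2 * e / (k * (k - 1))
    }
    res$neighborhood_connectivity[v] <- if (k > 0) mean(deg[nb]) else 0
    if (k >= 2) {
      js <- c()
      for (m in seq_len(nv)) {
        if (m == v) next
        sharedvm <- length(intersect(which(adj[v, ] == 1), which(adj[m, ] == 1)))
        if (sharedvm > 0) js <- c(js, (sharedvm + adj[v, m]) / k)
      }
      if (length(js) > 0) res$topological_coefficient[v] <- mean(js)
    }
  }
  res
}

# Dunn z-values with explicit midranks and explicit tie-group enumeration
oracle_dunn_z <- function(values, groups) {
  n <- length(values)
  ord <- order(values)
  r <- numeric(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && values[ord[j + 1]] == values[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  tie_term <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie_term <- tie_term + t^3 - t
  }
  levs <- sort(unique(as.character(groups)))
  pairs <- combn(levs, 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    gi <- as.character(groups) == pairs[1, k]
    gj <- as.character(groups) == pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term / (12 * (n - 1))) *
                 (1 / sum(gi) + 1 / sum(gj)))
    z[k] <- (mean(r[gi]) - mean(r[gj])) / se
  }
  z
}

# small random adjacency matrix with phenotype-like dimnames
random_adjacency <- function(nv, p) {
  adj <- matrix(0L, nv, nv)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < p]
  adj[on] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("P", seq_len(nv)), paste0("P", seq_len(nv)))
  adj
}

# tiny deterministic patient/matrix fixtures
toy_matrix <- function() {
  m <- matrix(0L, 6, 4,
              dimnames = list(paste0("p", 1:6), paste0("Ph", 1:4)))
  m["p1", c("Ph1", "Ph2")] <- 1L
  m["p2", c("Ph1", "Ph3")] <- 1L
  m["p3", "Ph1"] <- 1L
  m["p4", c("Ph2", "Ph3")] <- 1L
  m["p5", "Ph4"] <- 1L
  m
}

fixture_map_path <- function() {
  system.file("extdata", "phecode_map_synthetic.csv", package = "adcomorbid")
}
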