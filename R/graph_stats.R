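as_igraph <- function(adjacency) {
  igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!isTRUE(all.equal(unname(adjacency), unname(t(adjacency)))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  unname(adjacency)
}

#' Matching index matrix
#'
#' Jaccard-style overlap of two nodes' neighbourhoods excluding each other:
#' \deqn{M_{ij} = |N_{i/j} \cap N_{j/i}| / |N_{i/j} \cup N_{j/i}|}
#' with 0 when the union is empty.
#'
#' @param adjacency symmetric binary matrix, zero diagonal.
#' @return Symmetric matrix in `[0, 1]`, zero diagonal.
#' @export
matching_matrix <- function(adjacency) {
  A <- check_adjacency(adjacency)
  k <- rowSums(A)
  common <- A %*% A                      # |N_i \cap N_j|; never contains i or j
  un <- outer(k, k, "+") - 2 * A - common
  M <- ifelse(un > 0, common / un, 0)
  diag(M) <- 0
  M
}

#' Nodal topology statistics
#'
#' Per-node statistics of a binary undirected graph: degree, clustering
#' coefficient, betweenness centrality (unnormalized fractional shortest-path
#' counts), total Euclidean edge length, nodal efficiency (mean inverse
#' shortest path length, unreachable pairs contributing 0), mean matching
#' index, and — when `participation = TRUE` — the participation coefficient
#' over a Louvain community partition.
#'
#' @param net a [functional_network()], or a bare adjacency matrix if
#'   `distance_um` is supplied.
#' @param distance_um optional Euclidean distance matrix (required when `net`
#'   is a bare matrix).
#' @param participation compute the participation coefficient (needs a
#'   community detection run; default `FALSE`).
#' @param louvain_seed seed for the Louvain run when `participation = TRUE`.
#' @return Data frame with one row per node: `degree`, `clustering`,
#'   `betweenness`, `edge_length`, `efficiency`, `matching` (and
#'   `participation` if requested).
#' @export
nodal_statistics <- function(net, distance_um = NULL, participation = FALSE,
                             louvain_seed = 1L) {
  if (inherits(net, "functional_network")) {
    A <- net$adjacency
    D <- net$distance_um
  } else {
    A <- net
    D <- distance_um
    if (is.null(D)) stop("distance_um required when net is a bare matrix")
  }
  A <- check_adjacency(A)
  n <- nrow(A)
  g <- as_igraph(A)
  deg <- rowSums(A)
  clu <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  elen <- rowSums(A * D)
  sp <- igraph::distances(g)
  inv <- 1 / sp
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  eff <- if (n > 1) rowSums(inv) / (n - 1) else rep(0, n)
  M <- matching_matrix(A)
  mm <- if (n > 1) rowSums(M) / (n - 1) else rep(0, n)
  out <- data.frame(degree = deg, clustering = clu, betweenness = btw,
                    edge_length = elen, efficiency = eff, matching = mm)
  if (participation) {
    memb <- best_louvain(g, n_restarts = 10, seed = louvain_seed)$membership
    out$participation <- participation_coefficient(A, memb)
  }
  out
}

#' Participation coefficient
#'
#' Diversity of a node's connections across modules:
#' \eqn{p_i = 1 - \sum_s (k_{is}/k_i)^2}; 0 for isolated nodes.
#'
#' @param adjacency symmetric binary matrix.
#' @param membership integer module label per node.
#' @return Numeric vector in `[0, 1]`.
#' @export
participation_coefficient <- function(adjacency, membership) {
  A <- check_adjacency(adjacency)
  k <- rowSums(A)
  p <- numeric(nrow(A))
  for (s in unique(membership)) {
    ks <- rowSums(A[, membership == s, drop = FALSE])
    p <- p + ifelse(k > 0, (ks / k)^2, 0)
  }
  ifelse(k > 0, 1 - p, 0)
}

# Best-of-restarts Louvain at resolution 1. Louvain is stochastic; the
# maximum-modularity partition over n_restarts seeded runs is returned.
best_louvain <- function(g, n_restarts = 100, seed = 1L) {
  best <- NULL
  bq <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, resolution = 1)
    q <- igraph::modularity(cl)
    if (q > bq) { bq <- q; best <- cl }
  }
  list(membership = igraph::membership(best), modularity = bq)
}

#' Global topology statistics
#'
#' Network-level summary of a binary undirected graph: density, mean
#' clustering, characteristic path length (mean shortest path over reachable
#' pairs), global and local efficiency, modularity Q (best of repeated
#' Louvain runs at resolution 1), and small-worldness
#' \eqn{\sigma = (c/c_{rand}) / (l/l_{rand})} against the mean clustering
#' and path length of `n_null` same-size, same-density Erdős–Rényi
#' random graphs.
#'
#' @param net a [functional_network()] or adjacency matrix.
#' @param n_null number of random null networks for \eqn{\sigma}
#'   (default 1000).
#' @param seed seed for null generation and Louvain restarts.
#' @param n_louvain number of Louvain restarts for Q (default 100).
#' @return A list of class `global_stats` with `n_nodes`, `n_edges`,
#'   `density`, `mean_clustering`, `char_path_length`, `global_efficiency`,
#'   `local_efficiency`, `modularity`, `small_worldness`, `c_rand`, `l_rand`.
#'   All-`NA` statistics (with `n_nodes`/`n_edges` kept) for an empty graph.
#' @export
global_statistics <- function(net, n_null = 1000, seed = 1L, n_louvain = 100) {
  A <- if (inherits(net, "functional_network")) net$adjacency else net
  A <- check_adjacency(A)
  n <- nrow(A)
  m <- sum(A) / 2
  out <- list(n_nodes = n, n_edges = m,
              density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
              mean_clustering = NA_real_, char_path_length = NA_real_,
              global_efficiency = NA_real_, local_efficiency = NA_real_,
              modularity = NA_real_, small_worldness = NA_real_,
              c_rand = NA_real_, l_rand = NA_real_)
  class(out) <- "global_stats"
  if (n == 0 || m == 0) return(out)
  g <- as_igraph(A)
  cl_l <- clustering_and_length(g)
  out$mean_clustering <- cl_l$c
  out$char_path_length <- cl_l$l
  sp <- igraph::distances(g)
  inv <- 1 / sp; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  out$global_efficiency <- mean(rowSums(inv) / (n - 1))
  out$local_efficiency <- local_efficiency(A)
  lv <- best_louvain(g, n_restarts = n_louvain, seed = seed)
  out$modularity <- lv$modularity
  # same-size same-density Erdős–Rényi nulls
  set.seed(seed)
  cr <- lr <- numeric(n_null)
  for (b in seq_len(n_null)) {
    gr <- igraph::sample_gnm(n, m)
    cl <- clustering_and_length(gr)
    cr[b] <- cl$c; lr[b] <- cl$l
  }
  out$c_rand <- mean(cr, na.rm = TRUE)
  out$l_rand <- mean(lr, na.rm = TRUE)
  if (is.finite(out$c_rand) && out$c_rand > 0 && is.finite(out$l_rand) &&
      out$l_rand > 0 && is.finite(cl_l$l) && cl_l$l > 0)
    out$small_worldness <- (cl_l$c / out$c_rand) / (cl_l$l / out$l_rand)
  out
}

#' @export
print.global_stats <- function(x, ...) {
  cat(sprintf(paste0("<global_stats> n=%d m=%d density=%.3f C=%.3f L=%.3f ",
                     "Eglob=%.3f Q=%.3f sigma=%s\n"),
              x$n_nodes, x$n_edges, x$density, x$mean_clustering,
              x$char_path_length, x$global_efficiency, x$modularity,
              ifelse(is.na(x$small_worldness), "NA",
                     sprintf("%.2f", x$small_worldness))))
  invisible(x)
}

clustering_and_length <- function(g) {
  c_val <- mean(igraph::transitivity(g, type = "localundirected",
                                     isolates = "zero"))
  sp <- igraph::distances(g)
  sp <- sp[upper.tri(sp)]
  sp <- sp[is.finite(sp)]
  list(c = c_val, l = if (length(sp)) mean(sp) else NA_real_)
}

# Mean over nodes of the efficiency of each node's neighbourhood subgraph
# (paths restricted to the neighbours of i); 0 for nodes of degree < 2.
local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    sub <- A[nb, nb, drop = FALSE]
    sp <- igraph::distances(as_igraph(sub))
    inv <- 1 / sp; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    vals[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  mean(vals)
}

#' Modularity of a given partition
#'
#' Q for a fixed module assignment on a binary undirected graph.
#'
#' @param adjacency symmetric binary matrix.
#' @param membership integer module label per node.
#' @return Modularity Q.
#' @export
modularity_at_partition <- function(adjacency, membership) {
  A <- check_adjacency(adjacency)
  igraph::modularity(as_igraph(A), membership = as.integer(factor(membership)))
}
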