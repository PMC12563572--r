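# Independent brute-force oracles used to cross-check the implementation.
# Everything here is deliberately written from first principles (no igraph,
# no package internals).

# --- STTC oracle: direct interval arithmetic, per spike -----------------

oracle_tiled_fraction <- function(t, duration, dt) {
  if (length(t) == 0) return(0)
  lo <- pmax(t - dt, 0)
  hi <- pmin(t + dt, duration)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[k])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    }
  }
  (total + cur_hi - cur_lo) / duration
}

oracle_prop_within <- function(a, b, dt) {
  mean(vapply(a, function(t) any(abs(b - t) <= dt), TRUE))
}

oracle_sttc <- function(a, b, duration, dt) {
  ta <- oracle_tiled_fraction(a, duration, dt)
  tb <- oracle_tiled_fraction(b, duration, dt)
  pa <- oracle_prop_within(a, b, dt)
  pb <- oracle_prop_within(b, a, dt)
  0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
}

# --- graph oracles: BFS + shortest-path DAG enumeration -----------------

oracle_bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (w in which(A[u, ] == 1)) {
        if (is.infinite(d[w])) { d[w] <- d[u] + 1; nxt <- c(nxt, w) }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

# all shortest paths s -> t by DFS restricted to distance-decreasing moves
oracle_shortest_paths <- function(A, s, t, dist_to_t) {
  if (is.infinite(dist_to_t[s])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  for (w in which(A[s, ] == 1)) {
    if (dist_to_t[w] == dist_to_t[s] - 1) {
      for (p in oracle_shortest_paths(A, w, t, dist_to_t))
        paths[[length(paths) + 1]] <- c(s, p)
    }
  }
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      d_t <- oracle_bfs_dist(A, t)
      paths <- oracle_shortest_paths(A, s, t, d_t)
      if (length(paths) == 0) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner))
        for (v in inner) b[v] <- b[v] + 1 / length(paths)
    }
  }
  b
}

oracle_nodal_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- oracle_bfs_dist(A, i)[-i]
    sum(ifelse(is.finite(d) & d > 0, 1 / d, 0)) / (n - 1)
  }, 0)
}

oracle_modularity <- function(A, membership) {
  n <- nrow(A)
  k <- rowSums(A)
  l <- sum(A)  # 2m: each edge counted in both directions
  if (l == 0) return(NA_real_)
  q <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (membership[i] == membership[j])
        q <- q + A[i, j] - k[i] * k[j] / l
  q / l
}

oracle_matching <- function(A) {
  n <- nrow(A)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ni <- setdiff(which(A[i, ] == 1), j)
      nj <- setdiff(which(A[j, ] == 1), i)
      u <- union(ni, nj)
      M[i, j] <- M[j, i] <- if (length(u)) length(intersect(ni, nj)) / length(u) else 0
    }
  }
  M
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    t <- sum(A[nb, nb]) / 2
    2 * t / (k * (k - 1))
  }, 0)
}

oracle_ks <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 0))
}

# independent energy recomputation from first principles
oracle_energy <- function(A_obs, A_sim, D) {
  lengths_of <- function(A) {
    idx <- which(A == 1 & upper.tri(A))
    D[idx]
  }
  ks <- c(oracle_ks(rowSums(A_obs), rowSums(A_sim)),
          oracle_ks(oracle_clustering(A_obs), oracle_clustering(A_sim)),
          oracle_ks(oracle_betweenness(A_obs), oracle_betweenness(A_sim)),
          oracle_ks(lengths_of(A_obs), lengths_of(A_sim)))
  list(energy = max(ks), components = ks)
}

# --- shared fixtures ----------------------------------------------------

random_small_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.2, 0.8)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

random_positions <- function(n, width = 3850, height = 2100) {
  cbind(x_um = runif(n, 0, width), y_um = runif(n, 0, height))
}

poisson_train <- function(rate_hz, duration_s) {
  sort(runif(rpois(1, rate_hz * duration_s), 0, duration_s))
}

# small culture presets used across tests (scaled-down study conditions)
small_culture <- function(seed, ...) {
  culture_params(n_units = 25, duration_s = 120, burst_rate_hz = 0.2,
                 n_modules = 3, seed = seed, ...)
}
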