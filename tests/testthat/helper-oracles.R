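# independent reference implementations ("oracles") kept deliberately
# naive: Floyd-Warshall distances, matrix-power path counts, exhaustive
# path enumeration, shifted power iteration, fixed-point pagerank

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# sigma[i, j]: walks of length dist(i, j) are exactly the shortest paths
oracle_path_counts <- function(adj, d = oracle_distances(adj)) {
  n <- nrow(adj)
  maxd <- max(c(0, d[is.finite(d)]))
  powers <- vector("list", maxd + 1)
  powers[[1]] <- diag(n)
  for (L in seq_len(maxd)) powers[[L + 1]] <- powers[[L]] %*% adj
  sigma <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (is.finite(d[i, j])) sigma[i, j] <- powers[[d[i, j] + 1]][i, j]
  }
  sigma
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (nrow(adj) * (nrow(adj) - 1))
}

oracle_nodal_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

oracle_local_efficiency <- function(adj) {
  vapply(seq_len(nrow(adj)), function(i) {
    nbr <- which(adj[i, ] == 1)
    if (length(nbr) < 2) return(0)
    oracle_global_efficiency(adj[nbr, nbr, drop = FALSE])
  }, numeric(1))
}

# exhaustive enumeration of all shortest paths (small n only)
oracle_betweenness_enum <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  paths_between <- function(k, j) {
    found <- list()
    recurse <- function(path) {
      last <- path[length(path)]
      if (last == j) {
        found[[length(found) + 1L]] <<- path
        return()
      }
      if (length(path) - 1 >= d[k, j]) return()
      for (nx in which(adj[last, ] == 1)) {
        if (!(nx %in% path)) recurse(c(path, nx))
      }
    }
    recurse(k)
    found[vapply(found, length, integer(1)) == d[k, j] + 1]
  }
  bc <- numeric(n)
  for (k in 1:n) for (j in 1:n) {
    if (k == j || !is.finite(d[k, j])) next
    sp <- paths_between(k, j)
    if (length(sp) == 0) next
    interior <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    for (i in seq_len(n)) {
      if (i != k && i != j) bc[i] <- bc[i] + sum(interior == i) / length(sp)
    }
  }
  bc
}

# betweenness via the distance/count combination identity, fed by the
# matrix-power counts (usable at any n)
oracle_betweenness_counts <- function(adj) {
  d <- oracle_distances(adj)
  sigma <- oracle_path_counts(adj, d)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    total <- 0
    for (k in 1:n) for (j in 1:n) {
      if (k == j || k == i || j == i) next
      if (sigma[k, j] > 0 && is.finite(d[k, i]) && is.finite(d[i, j]) &&
          d[k, i] + d[i, j] == d[k, j]) {
        total <- total + sigma[k, i] * sigma[i, j] / sigma[k, j]
      }
    }
    total
  }, numeric(1))
}

# shifted power iteration: A + nI has the same leading eigenvector with a
# guaranteed spectral gap on connected graphs
oracle_eigenvector <- function(adj, iters = 20000, tol = 1e-13) {
  n <- nrow(adj)
  B <- adj + n * diag(n)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(iters)) {
    w <- as.numeric(B %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  if (sum(v) < 0) v <- -v
  v
}

oracle_pagerank <- function(adj, d = 0.85, iters = 100000, tol = 1e-14) {
  deg <- rowSums(adj)
  r <- rep(1, nrow(adj))
  for (it in seq_len(iters)) {
    r_new <- (1 - d) + d * as.numeric(adj %*% (r / deg))
    if (max(abs(r_new - r)) < tol) break
    r <- r_new
  }
  r
}

# step-up BH exactly as defined, by explicit search over thresholds
oracle_bh_flags <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= q * seq_len(m) / m)
  flags <- rep(FALSE, m)
  if (length(ok) > 0) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

# least squares through explicit normal equations
oracle_lm_beta <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)
}

# direct binning loop matching the declared convention: right-closed
# bins, first bin also left-closed
oracle_bin_counts <- function(v, edges) {
  nb <- length(edges) - 1
  counts <- integer(nb)
  for (x in v) {
    for (b in seq_len(nb)) {
      lower_ok <- if (b == 1) x >= edges[1] else x > edges[b]
      if (lower_ok && x <= edges[b + 1]) {
        counts[b] <- counts[b] + 1L
        break
      }
    }
  }
  counts
}

# weighted global efficiency via igraph shortest paths on 1/w distances
oracle_gce <- function(edges, sim) {
  n <- nrow(sim)
  total <- sum(sim[upper.tri(sim)])
  if (is.null(edges) || nrow(edges) == 0) return(list(cost = 0, gce = 0))
  w <- sim[cbind(edges[, 1], edges[, 2])]
  g <- igraph::graph_from_edgelist(cbind(edges[, 1], edges[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  sp <- igraph::distances(g, weights = 1 / w)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  eff <- sum(inv) / (n * (n - 1))
  list(cost = sum(w) / total, gce = eff - sum(w) / total)
}

small_parcels <- function(k = 6, vertex_count = 60) {
  tibble::tibble(
    parcel_name = sprintf("P%02d", seq_len(k)),
    hemisphere = rep(c("LH", "RH"), length.out = k),
    network = rep(c("Vis", "Default", "Cont"), length.out = k),
    vertex_count = as.integer(rep(vertex_count, length.out = k))
  )
}

small_config <- function(n_subjects = 10, k = 6, seed = 11, ...) {
  simulation_config(n_subjects = n_subjects, parcels = small_parcels(k),
                    seed = seed, ...)
}
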