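#' Breadth-first shortest-path structure
#'
#' Hop distances and shortest-path counts for every ordered node pair of
#' a binary undirected graph, the common substrate of the efficiency and
#' betweenness measures. Unreachable pairs get distance `Inf` (and later
#' contribute 0 to efficiency sums).
#'
#' @param adj Symmetric 0/1 adjacency matrix with zero diagonal.
#' @return Object of class `sp_structure`: list with `n`, `adjacency`,
#'   `L` (distance matrix, hops) and `sigma` (number of distinct shortest
#'   paths per pair; `sigma[i, i] = 1`).
#' @export
shortest_paths <- function(adj) {
  adj <- validate_adjacency(adj)
  n <- nrow(adj)
  L <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    cnt <- numeric(n); cnt[s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      contrib <- as.numeric(cnt[frontier] %*% adj[frontier, , drop = FALSE])
      new <- which(is.infinite(dist) & contrib > 0)
      dist[new] <- d + 1
      cnt[new] <- contrib[new]
      frontier <- new
      d <- d + 1
    }
    L[s, ] <- dist
    sigma[s, ] <- cnt
  }
  structure(list(n = n, adjacency = adj, L = L, sigma = sigma),
            class = "sp_structure")
}

validate_adjacency <- function(adj) {
  if (inherits(adj, "wb_network")) adj <- adj$adjacency
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  if (!all(adj %in% c(0, 1)) || any(diag(adj) != 0) ||
      !identical(unname(adj), unname(t(adj)))) {
    ct_abort("adjacency must be symmetric 0/1 with zero diagonal", "bad_adjacency")
  }
  adj
}

inv_or_zero <- function(L) {
  inv <- 1 / L
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  inv
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' \eqn{E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/L_{ij}}; unreachable
#' pairs contribute 0. Equals 1 on a complete graph and equals the mean
#' of the nodal efficiencies.
#'
#' @param sp An `sp_structure` (or adjacency matrix, converted on the fly).
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(sp) {
  sp <- as_sp(sp)
  if (sp$n < 2) ct_abort("global efficiency needs at least 2 nodes", "bad_graph")
  sum(inv_or_zero(sp$L)) / (sp$n * (sp$n - 1))
}

as_sp <- function(x) if (inherits(x, "sp_structure")) x else shortest_paths(x)

#' Nodal efficiency
#'
#' \eqn{E_{nodal}(i) = \frac{1}{N-1} \sum_{j \ne i} 1/L_{ij}}: how
#' efficiently node `i` reaches the rest of the network.
#'
#' @param sp An `sp_structure` or adjacency matrix.
#' @param i Node index; `NULL` returns the vector for all nodes.
#' @return Efficiency value(s) in `[0, 1]`.
#' @export
nodal_efficiency <- function(sp, i = NULL) {
  sp <- as_sp(sp)
  e <- rowSums(inv_or_zero(sp$L)) / (sp$n - 1)
  if (is.null(i)) e else e[i]
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by the neighbours of node
#' `i` (node `i` itself excluded): how well information flows around `i`
#' if it is removed. Zero by convention for nodes with fewer than 2
#' neighbours, whose neighbour subgraph is degenerate.
#'
#' @param adj Adjacency matrix (or `wb_network`).
#' @param i Node index; `NULL` returns the vector for all nodes.
#' @return Efficiency value(s) in `[0, 1]`.
#' @export
local_efficiency <- function(adj, i = NULL) {
  adj <- validate_adjacency(adj)
  one <- function(i) {
    nbr <- which(adj[i, ] == 1)
    if (length(nbr) < 2) return(0)
    global_efficiency(adj[nbr, nbr, drop = FALSE])
  }
  if (is.null(i)) vapply(seq_len(nrow(adj)), one, numeric(1)) else one(i)
}

#' Degree centrality
#'
#' Number of links of a node, \eqn{DC(i) = \sum_j a_{ij}}.
#'
#' @inheritParams local_efficiency
#' @return Integer degree(s).
#' @export
degree_centrality <- function(adj, i = NULL) {
  adj <- validate_adjacency(adj)
  d <- rowSums(adj)
  if (is.null(i)) d else d[i]
}

#' Betweenness centrality
#'
#' Sum over ordered pairs `(k, j)` with `k`, `j` and `i` all distinct of
#' the fraction of shortest `k`-to-`j` paths passing through `i`. The sum
#' runs over ordered pairs and is not halved or normalised, so on an
#' undirected graph each unordered pair contributes twice; pairs with no
#' connecting path contribute 0.
#'
#' @param sp An `sp_structure` or adjacency matrix.
#' @param i Node index; `NULL` returns the vector for all nodes.
#' @return Nonnegative value(s).
#' @export
betweenness_centrality <- function(sp, i = NULL) {
  sp <- as_sp(sp)
  one <- function(i) {
    on_path <- outer(sp$L[, i], sp$L[i, ], "+") == sp$L & sp$sigma > 0
    frac <- outer(sp$sigma[, i], sp$sigma[i, ]) / sp$sigma
    frac[!on_path] <- 0
    frac[i, ] <- 0; frac[, i] <- 0; diag(frac) <- 0
    sum(frac)
  }
  if (is.null(i)) vapply(seq_len(sp$n), one, numeric(1)) else one(i)
}

#' Eigenvector centrality
#'
#' Leading eigenvector of the adjacency matrix, oriented nonnegative
#' (Perron orientation, valid on connected graphs) and scaled to unit
#' Euclidean norm: a node is central when it connects to other central
#' nodes.
#'
#' @param adj Adjacency matrix of a connected graph (or `wb_network`).
#' @param tol Residual tolerance on the eigen equation (default 1e-10).
#' @return List with `vector` (centralities), `lambda` (leading
#'   eigenvalue).
#' @export
eigenvector_centrality <- function(adj, tol = 1e-10) {
  adj <- validate_adjacency(adj)
  e <- eigen(adj, symmetric = TRUE)
  lambda <- e$values[1]
  v <- e$vectors[, 1]
  s <- sign(sum(v))
  if (s == 0) s <- sign(v[which(v != 0)[1]])
  v <- s * v / sqrt(sum(v^2))
  resid <- max(abs(adj %*% v - lambda * v))
  if (resid > tol) {
    ct_abort(paste0("eigenvector centrality did not satisfy the eigen equation; residual ",
                    format(resid)), "no_convergence")
  }
  list(vector = pmax(v, 0), lambda = lambda)
}

#' Pagerank centrality
#'
#' Fixed point of \eqn{r(i) = 1 - d + d \sum_j a_{ij} r(j) / DC(j)} with
#' damping `d = 0.85`: damped random-walk importance. On this scaling the
#' centralities sum to `N`, and any regular graph is uniformly 1. Solved
#' as a dense linear system (exact to solver precision, checked against a
#' 1e-12 residual).
#'
#' @param adj Adjacency matrix without zero-degree nodes.
#' @param d Damping factor in (0, 1), default 0.85.
#' @return Numeric vector of centralities summing to `N`.
#' @export
pagerank_centrality <- function(adj, d = 0.85) {
  adj <- validate_adjacency(adj)
  deg <- rowSums(adj)
  if (any(deg == 0)) {
    ct_abort("pagerank is undefined with zero-degree nodes", "bad_graph")
  }
  n <- nrow(adj)
  M <- diag(n) - d * adj %*% diag(1 / deg)
  r <- as.numeric(solve(M, rep(1 - d, n)))
  resid <- max(abs(r - ((1 - d) + d * as.numeric(adj %*% (r / deg)))))
  if (resid > 1e-12) {
    ct_abort(paste0("pagerank residual too large: ", format(resid)),
             "no_convergence")
  }
  r
}

#' All topology measures of one binary network
#'
#' Computes the six node-level measures (nodal, local efficiency; degree,
#' betweenness, eigenvector, pagerank centrality) for every node plus the
#' graph-level global efficiency, as a long tidy table.
#'
#' @param network A `wb_network` from [omst_threshold()], or a bare
#'   adjacency matrix.
#' @param subject_id Overrides the subject id recorded in `network`.
#' @return Tibble with columns `subject_id`, `parcel`, `metric`, `value`:
#'   one row per node per node-level metric, plus a single `Eglob` row
#'   with `parcel = NA`.
#' @export
compute_all_metrics <- function(network, subject_id = NULL) {
  if (is.null(subject_id)) {
    subject_id <- if (inherits(network, "wb_network")) network$subject_id else NA_character_
  }
  adj <- validate_adjacency(network)
  nm <- rownames(adj)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(adj)))
  sp <- shortest_paths(adj)
  node <- tibble::tibble(
    parcel = rep(nm, 6L),
    metric = rep(c("Enodal", "Elocal", "DC", "BC", "EC", "PC"),
                 each = nrow(adj)),
    value = unname(c(nodal_efficiency(sp),
                     local_efficiency(adj),
                     degree_centrality(adj),
                     betweenness_centrality(sp),
                     eigenvector_centrality(adj)$vector,
                     pagerank_centrality(adj)))
  )
  out <- dplyr::bind_rows(
    node,
    tibble::tibble(parcel = NA_character_, metric = "Eglob",
                   value = global_efficiency(sp))
  )
  dplyr::mutate(out, subject_id = subject_id, .before = 1)
}
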