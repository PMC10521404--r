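#' Similarity-to-distance transform
#'
#' Minimum spanning trees are defined on distances, so similarities are
#' inverted: `d = 1/w` for `w > 0` (the default, usual in the OMST
#' literature) or `d = 1 - w` behind the `method` flag for sensitivity
#' analysis. Zero similarities mark absent edges and map to `Inf`. Both
#' transforms are strictly decreasing in `w`, so stronger connections are
#' always shorter.
#'
#' @param sim Symmetric similarity matrix with entries in `[0, 1]`.
#' @param method `"reciprocal"` (default) or `"one_minus"`.
#' @return Distance matrix of the same shape; `Inf` where `sim == 0`.
#' @export
weight_to_distance <- function(sim, method = c("reciprocal", "one_minus")) {
  method <- match.arg(method)
  d <- if (method == "reciprocal") 1 / sim else 1 - sim
  d[sim == 0] <- Inf
  diag(d) <- Inf
  d
}

# minimal union-find; graphs here are tiny, no compression needed
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

# Kruskal spanning forest over the given candidate edges (rows of `edges`
# ordered by increasing distance with lexicographic (i, j) tie-break).
# Returns the row indices of accepted edges.
kruskal_forest <- function(edges, n) {
  parent <- seq_len(n)
  accepted <- integer(0)
  for (row in seq_len(nrow(edges))) {
    ri <- uf_find(parent, edges[row, 1])
    rj <- uf_find(parent, edges[row, 2])
    if (ri != rj) {
      parent[ri] <- rj
      accepted <- c(accepted, row)
      if (length(accepted) == n - 1L) break
    }
  }
  accepted
}

#' Orthogonal minimum spanning trees
#'
#' Extracts successive edge-disjoint minimum spanning trees: round m is a
#' minimum spanning tree (or forest, once edge removal disconnects the
#' graph) of the graph with all edges of rounds < m removed. Construction
#' is Kruskal with a lexicographic node-pair tie-break, so equal-weight
#' ties resolve identically on every run.
#'
#' @param dist Symmetric distance matrix (`Inf` = absent edge), as from
#'   [weight_to_distance()].
#' @param max_rounds Maximum number of trees to extract (default `N - 1`).
#' @return List of integer edge matrices (columns `i`, `j` with `i < j`),
#'   pairwise disjoint, in extraction order.
#' @export
extract_orthogonal_msts <- function(dist, max_rounds = nrow(dist) - 1L) {
  n <- nrow(dist)
  ut <- which(upper.tri(dist) & is.finite(dist), arr.ind = TRUE)
  if (nrow(ut) == 0) ct_abort("distance graph has no edges", "empty_graph")
  d <- dist[ut]
  ord <- order(d, ut[, 1], ut[, 2])
  edges <- ut[ord, , drop = FALSE]
  rounds <- list()
  while (length(rounds) < max_rounds && nrow(edges) > 0) {
    acc <- kruskal_forest(edges, n)
    if (length(acc) == 0) break
    rounds[[length(rounds) + 1L]] <- edges[acc, , drop = FALSE]
    edges <- edges[-acc, , drop = FALSE]
  }
  rounds
}

# all-pairs shortest path distances by Floyd-Warshall on a dense
# (possibly Inf-entried) distance matrix
floyd_warshall <- function(d) {
  diag(d) <- 0
  for (k in seq_len(nrow(d))) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

weighted_global_efficiency <- function(dist_full) {
  n <- nrow(dist_full)
  sp <- floyd_warshall(dist_full)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global cost efficiency of an edge selection
#'
#' The OMST selection criterion: `gce = Eglob_w - cost`, where `cost` is
#' the fraction of total similarity weight retained by the selected edges
#' and `Eglob_w` is the weighted global efficiency of the selected
#' subgraph (mean inverse shortest-path distance over ordered node pairs,
#' path lengths on `1/w` edge distances, unreachable pairs contributing
#' 0). Dense selections are efficient but costly; the spanning-tree
#' aggregation that maximises gce balances the two.
#'
#' @param edges Integer edge matrix (columns `i`, `j`), possibly empty.
#' @param sim Similarity matrix the edges index into.
#' @param distance Distance transform passed to [weight_to_distance()].
#' @return List with `cost`, `efficiency`, `gce`.
#' @export
global_cost_efficiency <- function(edges, sim,
                                   distance = c("reciprocal", "one_minus")) {
  distance <- match.arg(distance)
  n <- nrow(sim)
  total_w <- sum(sim[upper.tri(sim)])
  if (is.null(edges) || nrow(edges) == 0) {
    return(list(cost = 0, efficiency = 0, gce = 0))
  }
  sel_w <- sim[cbind(edges[, 1], edges[, 2])]
  cost <- sum(sel_w) / total_w
  d <- matrix(Inf, n, n)
  dvals <- weight_to_distance(sim, method = distance)[cbind(edges[, 1], edges[, 2])]
  d[cbind(edges[, 1], edges[, 2])] <- dvals
  d[cbind(edges[, 2], edges[, 1])] <- dvals
  eff <- weighted_global_efficiency(d)
  list(cost = cost, efficiency = eff, gce = eff - cost)
}

#' Threshold-free sparsification by orthogonal MSTs
#'
#' Sparsifies a similarity matrix without an arbitrary density threshold:
#' successive edge-disjoint minimum spanning trees (see
#' [extract_orthogonal_msts()]) are aggregated cumulatively, global cost
#' efficiency is evaluated after each round, and the aggregation with
#' maximal gce (first maximum on ties) is kept and binarized. The first
#' tree guarantees the result is connected.
#'
#' @param sim Symmetric similarity matrix, entries in `[0, 1]`, zero
#'   diagonal; its positive entries must form a connected graph.
#' @param max_rounds Cap on OMST rounds (default `N - 1`).
#' @param decline_stop Stop early after this many consecutive declining
#'   gce rounds (default 3); the maximum found so far is unaffected.
#' @param distance Distance transform, see [weight_to_distance()].
#' @return Object of class `wb_network`: list with `adjacency` (0/1
#'   matrix, parcel dimnames), `subject_id`, `n_omsts_selected`,
#'   `n_edges`, and `gce_curve` (tibble: `round`, `n_edges`, `cost`,
#'   `efficiency`, `gce`).
#' @export
omst_threshold <- function(sim, max_rounds = nrow(sim) - 1L, decline_stop = 3L,
                           distance = c("reciprocal", "one_minus")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (max(abs(sim - t(sim))) > 1e-12 || any(sim < 0) || any(sim > 1)) {
    ct_abort("similarity matrix must be symmetric with entries in [0, 1]",
             "bad_similarity")
  }
  n <- nrow(sim)
  if (!is_connected_adjacency(sim > 0)) {
    ct_abort("positive entries of the similarity matrix form a disconnected graph; inspect input",
             "disconnected")
  }
  d <- weight_to_distance(sim, method = distance)
  rounds <- extract_orthogonal_msts(d, max_rounds = max_rounds)
  cum_edges <- NULL
  curve <- vector("list", length(rounds))
  declines <- 0L
  last_gce <- -Inf
  used <- 0L
  for (m in seq_along(rounds)) {
    cum_edges <- rbind(cum_edges, rounds[[m]])
    g <- global_cost_efficiency(cum_edges, sim, distance = distance)
    curve[[m]] <- tibble::tibble(round = m, n_edges = nrow(cum_edges),
                                 cost = g$cost, efficiency = g$efficiency,
                                 gce = g$gce)
    used <- m
    declines <- if (g$gce < last_gce) declines + 1L else 0L
    last_gce <- g$gce
    if (declines >= decline_stop) break
  }
  gce_curve <- dplyr::bind_rows(curve[seq_len(used)])
  best <- which.max(gce_curve$gce)
  sel <- do.call(rbind, rounds[seq_len(best)])
  adj <- matrix(0L, n, n, dimnames = dimnames(sim))
  adj[cbind(sel[, 1], sel[, 2])] <- 1L
  adj[cbind(sel[, 2], sel[, 1])] <- 1L
  structure(list(adjacency = adj,
                 subject_id = attr(sim, "subject_id"),
                 n_omsts_selected = best,
                 n_edges = nrow(sel),
                 gce_curve = gce_curve),
            class = "wb_network")
}

is_connected_adjacency <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(FALSE)
  reached <- logical(n)
  frontier <- 1L
  reached[1L] <- TRUE
  while (length(frontier) > 0) {
    nbr <- which(colSums(adj[frontier, , drop = FALSE] != 0) > 0 & !reached)
    reached[nbr] <- TRUE
    frontier <- nbr
  }
  all(reached)
}

#' @export
print.wb_network <- function(x, ...) {
  cat("OMST-thresholded binary network",
      if (!is.null(x$subject_id)) paste0(" (subject ", x$subject_id, ")"), "\n",
      sep = "")
  cat("  nodes: ", nrow(x$adjacency), ", edges: ", x$n_edges,
      ", OMST rounds kept: ", x$n_omsts_selected, "\n", sep = "")
  cat("  gce at selection: ",
      signif(x$gce_curve$gce[x$n_omsts_selected], 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.wb_network <- function(x, ...) {
  k <- x$n_omsts_selected
  tibble::tibble(n_nodes = nrow(x$adjacency), n_edges = x$n_edges,
                 n_omsts_selected = k,
                 cost = x$gce_curve$cost[k],
                 efficiency = x$gce_curve$efficiency[k],
                 gce = x$gce_curve$gce[k])
}

#' Plot the global cost-efficiency curve of an OMST selection
#'
#' @param object A `wb_network` from [omst_threshold()].
#' @param ... Unused.
#' @return A ggplot of gce against cost across cumulative OMST rounds,
#'   with the selected round marked.
#' @export
autoplot.wb_network <- function(object, ...) {
  sel <- object$gce_curve[object$n_omsts_selected, ]
  ggplot2::ggplot(object$gce_curve, ggplot2::aes(x = .data$cost, y = .data$gce)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(data = sel, colour = "red", size = 2) +
    ggplot2::labs(x = "cost (fraction of total similarity retained)",
                  y = "global cost efficiency",
                  title = "OMST aggregation: cost vs. gce",
                  subtitle = paste0("selected rounds: ", object$n_omsts_selected,
                                    ", edges: ", object$n_edges)) +
    ggplot2::theme_minimal()
}
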