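# small named graphs and generators used across the topology tests

graph_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  adj
}

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

complete_graph <- function(n) {
  adj <- matrix(1L, n, n); diag(adj) <- 0L
  adj
}

cycle_graph <- function(n) {
  graph_from_edges(n, c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                        list(c(n, 1))))
}

star_graph <- function(n) { # node 1 is the hub
  graph_from_edges(n, lapply(2:n, function(i) c(1, i)))
}

adjacency_is_connected <- function(adj) {
  n <- nrow(adj)
  reached <- logical(n); reached[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nbr <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !reached)
    reached[nbr] <- TRUE
    frontier <- nbr
  }
  all(reached)
}

random_connected_graph <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- upper.tri(adj)
    adj[up] <- as.integer(stats::runif(sum(up)) < p)
    adj <- adj + t(adj)
    if (adjacency_is_connected(adj)) return(adj)
  }
}

# every labelled connected graph on n nodes (feasible for n <= 5)
all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m) - 1L) {
    bits <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L)
    adj <- matrix(0L, n, n)
    adj[pairs[bits == 1L, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    if (adjacency_is_connected(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

# random symmetric similarity matrix with connected positive part
random_similarity <- function(n, density = 1) {
  s <- matrix(0, n, n)
  up <- upper.tri(s)
  vals <- stats::runif(sum(up), 0.05, 1)
  vals[stats::runif(sum(up)) > density] <- 0
  s[up] <- vals
  s <- s + t(s)
  diag(s) <- 0
  s
}
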