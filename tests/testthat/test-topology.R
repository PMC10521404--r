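test_that("closed-form values on canonical small graphs", {
  k4 <- complete_graph(4)
  p3 <- path_graph(3)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(p3), 5 / 6)

  two_pairs <- graph_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_equal(global_efficiency(two_pairs), 1 / 3)

  star <- star_graph(4)
  expect_equal(nodal_efficiency(star, 1), 1)
  expect_equal(nodal_efficiency(p3, 1), 3 / 4)
  iso <- graph_from_edges(3, list(c(1, 2)))
  expect_equal(nodal_efficiency(iso, 3), 0)

  expect_equal(local_efficiency(complete_graph(3), 1), 1)
  expect_equal(local_efficiency(star, 1), 0)     # leaves mutually non-adjacent
  expect_equal(local_efficiency(p3, 1), 0)       # degree-1 convention

  expect_equal(degree_centrality(k4, 2), 3)
  expect_equal(degree_centrality(iso, 3), 0)

  expect_equal(betweenness_centrality(p3, 2), 2) # ordered pairs, no halving
  expect_equal(betweenness_centrality(k4), rep(0, 4))

  ec5 <- eigenvector_centrality(complete_graph(5))
  expect_equal(ec5$vector, rep(1 / sqrt(5), 5))
  ec_star <- eigenvector_centrality(star)
  expect_gt(ec_star$vector[1], max(ec_star$vector[-1]))

  expect_equal(pagerank_centrality(cycle_graph(5)), rep(1, 5))
  pr_star <- pagerank_centrality(star)
  expect_gt(pr_star[1], pr_star[2])
})

test_that("handshake identity and efficiency monotonicity hold on random graphs", {
  set.seed(19)
  for (rep in 1:15) {
    adj <- random_connected_graph(8, 0.35)
    expect_equal(sum(degree_centrality(adj)), sum(adj))
    missing <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(missing) > 0) {
      e <- missing[sample(nrow(missing), 1), ]
      adj2 <- adj
      adj2[e[1], e[2]] <- adj2[e[2], e[1]] <- 1L
      expect_gte(global_efficiency(adj2), global_efficiency(adj))
    }
  }
})

test_that("all measures agree with brute-force oracles on every small connected graph", {
  for (n in 2:4) {
    for (adj in all_connected_graphs(n)) {
      sp <- shortest_paths(adj)
      d <- oracle_distances(adj)
      expect_equal(sp$L, d)
      expect_equal(sp$sigma, oracle_path_counts(adj, d))
      expect_equal(global_efficiency(sp), oracle_global_efficiency(adj),
                   tolerance = 1e-9)
      expect_equal(nodal_efficiency(sp), oracle_nodal_efficiency(adj),
                   tolerance = 1e-9)
      expect_equal(local_efficiency(adj), oracle_local_efficiency(adj),
                   tolerance = 1e-9)
      expect_equal(betweenness_centrality(sp), oracle_betweenness_enum(adj),
                   tolerance = 1e-9)
      ec <- eigenvector_centrality(adj)
      expect_equal(ec$vector, oracle_eigenvector(adj), tolerance = 1e-8)
      expect_equal(pagerank_centrality(adj), oracle_pagerank(adj),
                   tolerance = 1e-9)
    }
  }
})

test_that("centralities satisfy their defining equations on random graphs", {
  set.seed(23)
  for (rep in 1:20) {
    adj <- random_connected_graph(8, 0.4)
    ec <- eigenvector_centrality(adj)
    expect_lt(max(abs(adj %*% ec$vector - ec$lambda * ec$vector)), 1e-10)
    expect_equal(sum(ec$vector^2), 1)
    expect_true(all(ec$vector >= 0))
    pr <- pagerank_centrality(adj)
    deg <- rowSums(adj)
    expect_lt(max(abs(pr - (0.15 + 0.85 * as.numeric(adj %*% (pr / deg))))),
              1e-12)
    expect_equal(sum(pr), 8)
  }
})

test_that("global efficiency equals the mean nodal efficiency", {
  set.seed(29)
  for (rep in 1:10) {
    adj <- random_connected_graph(7, 0.4)
    sp <- shortest_paths(adj)
    expect_equal(global_efficiency(sp), mean(nodal_efficiency(sp)))
  }
})

test_that("metrics are equivariant under node relabelling", {
  set.seed(31)
  adj <- random_connected_graph(8, 0.4)
  perm <- sample(8)
  adj_p <- adj[perm, perm]
  expect_equal(nodal_efficiency(adj_p), nodal_efficiency(adj)[perm])
  expect_equal(local_efficiency(adj_p), local_efficiency(adj)[perm])
  expect_equal(degree_centrality(adj_p), degree_centrality(adj)[perm])
  expect_equal(betweenness_centrality(adj_p), betweenness_centrality(adj)[perm])
  expect_equal(pagerank_centrality(adj_p), pagerank_centrality(adj)[perm])
  expect_equal(eigenvector_centrality(adj_p)$vector,
               eigenvector_centrality(adj)$vector[perm])
})

test_that("the long metric table has the contracted shape and hand values", {
  p3 <- path_graph(3)
  rownames(p3) <- colnames(p3) <- c("a", "b", "c")
  tab <- compute_all_metrics(p3, subject_id = "s1")
  expect_equal(nrow(tab), 3 * 6 + 1)
  get <- function(m, p) tab$value[tab$metric == m & (!is.na(tab$parcel) & tab$parcel == p)]
  expect_equal(get("Enodal", "a"), 3 / 4)
  expect_equal(get("Enodal", "b"), 1)
  expect_equal(get("Elocal", "b"), 0)  # neighbours a, c are not adjacent
  expect_equal(get("DC", "b"), 2)
  expect_equal(get("BC", "b"), 2)
  expect_equal(get("BC", "a"), 0)
  expect_equal(tab$value[tab$metric == "Eglob"], 5 / 6)

  cfg <- small_config(n_subjects = 8, k = 6)
  coh <- simulate_cohort(cfg)
  sims <- build_similarity_matrices(coh$thickness, cfg$parcels)
  mets <- purrr::map_dfr(names(sims),
                         function(id) compute_all_metrics(omst_threshold(sims[[id]]), id))
  node <- dplyr::filter(mets, metric != "Eglob")
  expect_equal(nrow(node), 8 * 6 * 6)
  expect_equal(nrow(mets) - nrow(node), 8)
})
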