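test_that("paired histograms share support, conserve counts and match a direct binning loop", {
  x <- c(2.0, 2.1, 2.2, 2.9)
  h <- pair_histograms(x, x, n_bins = 10)
  expect_equal(h$freq_x, h$freq_y)
  expect_equal(sum(h$freq_x), length(x))
  expect_equal(range(h$bin_edges), range(x))

  # disjoint-support construction: x fills the lower half, y the upper
  x2 <- seq(2.0, 2.45, length.out = 40)
  y2 <- seq(2.55, 3.0, length.out = 40)
  h2 <- pair_histograms(x2, y2)
  expect_true(all(which(h2$freq_x > 0) <= 15))
  expect_true(all(which(h2$freq_y > 0) >= 16))

  # simulator draws against the naive per-value loop
  cfg <- small_config()
  v1 <- simulate_parcel_thickness("P01", 0, cfg, seed = 1)
  v2 <- simulate_parcel_thickness("P02", 0, cfg, seed = 2)
  h3 <- pair_histograms(v1, v2)
  expect_equal(h3$freq_x, oracle_bin_counts(v1, h3$bin_edges))
  expect_equal(h3$freq_y, oracle_bin_counts(v2, h3$bin_edges))

  expect_error(pair_histograms(rep(2, 5), rep(2, 9)),
               class = "ctnetwb_degenerate_pair")
})

test_that("histogram similarity is the Pearson correlation of the count vectors", {
  x <- rnorm(300, 2.5, 0.2)
  h <- pair_histograms(x, x)
  expect_equal(histogram_similarity(h), 1)

  mono <- structure(list(bin_edges = seq(0, 1, length.out = 31),
                         freq_x = 1:30, freq_y = 30:1),
                    class = "pair_histograms")
  expect_equal(histogram_similarity(mono), -1)

  toy <- structure(list(bin_edges = seq(0, 1, length.out = 31),
                        freq_x = c(5, 9, 2, rep(1, 27)),
                        freq_y = c(4, 7, 8, rep(2, 27))),
                   class = "pair_histograms")
  expect_equal(histogram_similarity(toy), cor(toy$freq_x, toy$freq_y))

  degen <- structure(list(bin_edges = seq(0, 1, length.out = 31),
                          freq_x = rep(2, 30), freq_y = 1:30),
                     class = "pair_histograms")
  expect_error(histogram_similarity(degen), class = "ctnetwb_degenerate_pair")
})

test_that("similarity matrix matches an independent pairwise loop and its invariants", {
  parcels <- small_parcels(4, vertex_count = c(50L, 60L, 70L, 80L))
  set.seed(21)
  vals <- list(P01 = rnorm(50, 2.3, 0.25), P02 = rnorm(60, 2.6, 0.3),
               P03 = c(rnorm(35, 2.1, 0.1), rnorm(35, 2.9, 0.1)),
               P04 = rnorm(80, 2.5, 0.2))
  sim <- build_similarity_matrix(vals, parcels)

  for (i in 1:3) for (j in (i + 1):4) {
    h <- pair_histograms(vals[[i]], vals[[j]])
    expect_equal(sim[i, j], abs(cor(oracle_bin_counts(vals[[i]], h$bin_edges),
                                    oracle_bin_counts(vals[[j]], h$bin_edges))))
  }
  expect_equal(sim, t(sim))
  expect_true(all(sim >= 0 & sim <= 1))
  expect_equal(unname(diag(sim)), rep(0, 4))

  # all parcels copies of one vector: every off-diagonal similarity is 1
  eq <- small_parcels(4, vertex_count = 50L)
  base <- rnorm(50, 2.5, 0.3)
  copies <- list(P01 = base, P02 = base, P03 = base, P04 = base)
  sim1 <- build_similarity_matrix(copies, eq)
  expect_equal(unname(sim1[upper.tri(sim1)]), rep(1, 6))
})

test_that("absolute value is taken after the correlation, not before", {
  parcels <- small_parcels(2, vertex_count = c(60L, 60L))
  # deterministic monotone profiles: decreasing counts vs increasing
  centers <- seq(2 + 1 / 60, 3 - 1 / 60, length.out = 30)
  times <- c(rep(3, 10), rep(2, 10), rep(1, 10))
  vals <- list(P01 = rep(centers, times = times),
               P02 = rep(centers, times = rev(times)))
  h <- pair_histograms(vals$P01, vals$P02)
  raw <- histogram_similarity(h)
  expect_lt(raw, 0)
  sim <- build_similarity_matrix(vals, parcels)
  expect_equal(sim[1, 2], abs(raw))
  expect_equal(attr(sim, "frac_negative"), 1)
})

test_that("similarity is equivariant to parcel order and invariant to a common shift", {
  cfg <- small_config()
  coh <- simulate_cohort(cfg)
  vals <- coh$thickness[[1]]
  sim <- build_similarity_matrix(vals, cfg$parcels)

  perm <- c(3, 1, 6, 2, 5, 4)
  parcels_p <- cfg$parcels[perm, ]
  vals_p <- vals[perm]
  attr(vals_p, "subject_id") <- attr(vals, "subject_id")
  sim_p <- build_similarity_matrix(vals_p, parcels_p)
  expect_equal(as.vector(sim_p), as.vector(sim[perm, perm]))
  expect_equal(rownames(sim_p), rownames(sim)[perm])

  h <- pair_histograms(vals$P01, vals$P02)
  h_shift <- pair_histograms(vals$P01 + 0.7, vals$P02 + 0.7)
  expect_equal(h_shift$freq_x, h$freq_x)
  expect_equal(h_shift$freq_y, h$freq_y)
})

test_that("degenerate pairs fall back to zero with a warning, many degenerate pairs abort", {
  # two identical constant parcels give one zero-range pair among 210
  parcels <- small_parcels(21, vertex_count = 50L)
  set.seed(31)
  vals <- lapply(seq_len(21), function(i) rnorm(50, 2.5, 0.2))
  names(vals) <- parcels$parcel_name
  vals$P01 <- rep(2.5, 50)
  vals$P02 <- rep(2.5, 50)
  expect_warning(sim <- build_similarity_matrix(vals, parcels), "degenerate")
  expect_equal(sim[1, 2], 0)

  three <- small_parcels(3, vertex_count = 50L)
  all_flat <- list(P01 = rep(2.5, 50), P02 = rep(2.5, 50), P03 = rep(2.5, 50))
  expect_error(suppressWarnings(build_similarity_matrix(all_flat, three)),
               class = "ctnetwb_data_pathology")
})
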