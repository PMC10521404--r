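make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                 age = rnorm(n, 37, 13), sex = rbinom(n, 1, 0.5),
                 education_years = rnorm(n, 15, 3),
                 icv_mm3 = rnorm(n, 1.45e6, 1.3e5),
                 mean_ct = rnorm(n, 2.5, 0.1))
}

test_that("a noiseless linear outcome is recovered with |partial r| = 1", {
  cov <- make_covariates(30)
  metric <- rnorm(30)
  y <- 0.2 * cov$age - 1.5 * cov$sex + 3 * metric + 7 + rnorm(30, sd = 1e-8)
  f <- fit_glm(y, metric, cov)
  expect_equal(f$partial_r, 1, tolerance = 1e-6)
  expect_lt(f$p_value, 1e-12)
  expect_equal(f$beta, 3, tolerance = 1e-5)
  f_neg <- fit_glm(-y, metric, cov)
  expect_equal(f_neg$partial_r, -1, tolerance = 1e-6)
})

test_that("an 8-row integer toy matches the normal-equations oracle", {
  cov <- tibble::tibble(subject_id = sprintf("s%d", 1:8),
                        age = c(20, 30, 40, 25, 35, 45, 50, 28),
                        sex = c(0, 1, 0, 1, 0, 1, 0, 1),
                        education_years = c(12, 16, 14, 18, 12, 20, 15, 13),
                        icv_mm3 = c(14, 15, 13, 16, 14, 15, 17, 13),
                        mean_ct = c(24, 25, 26, 23, 27, 25, 24, 26) / 10)
  metric <- c(1, 3, 2, 5, 4, 7, 6, 8)
  y <- c(10, 14, 11, 19, 12, 22, 15, 23)
  f <- fit_glm(y, metric, cov)
  X <- cbind(1, cov$age, cov$sex, cov$education_years, cov$icv_mm3,
             cov$mean_ct, metric)
  beta_oracle <- oracle_lm_beta(y, X)
  expect_equal(f$beta, beta_oracle[7], tolerance = 1e-9)
  resid <- y - X %*% beta_oracle
  df <- 8 - 7
  sigma2 <- sum(resid^2) / df
  se_oracle <- sqrt(sigma2 * solve(t(X) %*% X)[7, 7])
  expect_equal(f$beta_se, se_oracle, tolerance = 1e-9)
  expect_equal(f$partial_r,
               sign(f$t_stat) * sqrt(f$t_stat^2 / (f$t_stat^2 + df)))
})

test_that("the partial-r identity holds and orthogonal covariates reduce to simple r", {
  set.seed(44)
  for (rep in 1:10) {
    cov <- make_covariates(40, seed = rep)
    metric <- rnorm(40)
    y <- rnorm(40, sd = 2) + 0.5 * metric
    f <- fit_glm(y, metric, cov)
    expect_equal(f$partial_r^2 * (f$t_stat^2 + f$df_resid), f$t_stat^2)
  }
  # residualized variables: covariates orthogonal to metric and outcome
  n <- 200
  cov <- make_covariates(n, seed = 99)
  Z <- cbind(1, cov$age, cov$sex, cov$education_years, cov$icv_mm3, cov$mean_ct)
  P <- diag(n) - Z %*% solve(t(Z) %*% Z, t(Z))
  metric <- as.numeric(P %*% rnorm(n))
  y <- as.numeric(P %*% rnorm(n)) + 0.3 * metric
  f <- fit_glm(y, metric, cov)
  expect_equal(f$partial_r, cor(y, metric), tolerance = 1e-6)
})

test_that("degenerate designs are rejected with a useful message", {
  cov <- make_covariates(20)
  expect_error(fit_glm(rep(1, 20), rnorm(20), cov), class = "ctnetwb_degenerate")
  expect_error(fit_glm(rnorm(20), cov$age, cov), class = "ctnetwb_rank_deficient")
  expect_error(fit_glm(rnorm(7), rnorm(7), cov[1:7, ]), class = "ctnetwb_bad_input")
})

test_that("BH correction matches brute-force step-up evaluation", {
  p_seq <- seq(0.01, 0.32, by = 0.01)
  got <- fdr_bh(p_seq)
  expect_equal(got$significant, oracle_bh_flags(p_seq))
  expect_true(all(got$q_values >= p_seq))

  expect_equal(fdr_bh(0.031)$q_values, 0.031)
  expect_true(all(fdr_bh(rep(0, 5))$significant))

  set.seed(52)
  for (m in c(3, 10, 32, 64)) {
    p <- runif(m)^2
    got <- fdr_bh(p)
    expect_equal(got$significant, oracle_bh_flags(p))
    ord <- order(p)
    expect_true(all(diff(got$q_values[ord]) >= -1e-12))
  }
  expect_error(fdr_bh(c(0.1, 1.2)), class = "ctnetwb_bad_input")
})

test_that("association table covers all families with consistent flags", {
  cfg <- small_config(n_subjects = 16, k = 6)
  coh <- simulate_cohort(cfg)
  sims <- build_similarity_matrices(coh$thickness, cfg$parcels)
  mets <- purrr::map_dfr(names(sims),
                         function(id) compute_all_metrics(omst_threshold(sims[[id]]), id))
  scores <- score_mhcsf(coh$behavior)
  cov <- coh$covariates
  cov$mean_ct <- vapply(coh$thickness, mean_cortical_thickness, numeric(1))
  assoc <- run_association(mets, scores, cov)
  node <- dplyr::filter(assoc, metric != "Eglob")
  expect_equal(nrow(node), 6 * 4 * 6)
  expect_equal(nrow(dplyr::filter(assoc, metric == "Eglob")), 4)
  expect_true(all(assoc$q >= assoc$p - 1e-12, na.rm = TRUE))
  expect_equal(assoc$significant, assoc$q < 0.05)
  expect_equal(sign(assoc$partial_r), sign(assoc$beta))
  # within-family q-values equal a direct BH pass (constant-metric cells
  # are excluded from the family)
  fam <- dplyr::filter(node, metric == "Elocal", dimension == "total",
                       !is.na(p))
  expect_equal(fam$q, fdr_bh(fam$p)$q_values)
})

test_that("permuting the outcome destroys the planted association", {
  cfg <- simulation_config(seed = 2, effect_parcel = "RH_Default_PCC",
                           effect_size = 0.5)
  coh <- simulate_cohort(cfg)
  sims <- build_similarity_matrices(coh$thickness, cfg$parcels)
  el <- vapply(sims, function(sm) {
    adj <- omst_threshold(sm)$adjacency
    local_efficiency(adj, which(rownames(adj) == "RH_Default_PCC"))
  }, numeric(1))
  scores <- score_mhcsf(coh$behavior)
  cov <- coh$covariates
  cov$mean_ct <- vapply(coh$thickness, mean_cortical_thickness, numeric(1))
  f <- fit_glm(scores$total, el, cov)
  expect_lt(f$p_value, 0.01)
  set.seed(1)
  f_perm <- fit_glm(sample(scores$total), el, cov)
  expect_gt(f_perm$p_value, 0.05)
})
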