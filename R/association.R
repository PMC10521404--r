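#' Covariate-adjusted linear model for one parcel metric
#'
#' Ordinary least squares fit of
#' `wellbeing ~ age + sex + education + ICV + meanCT + metric`.
#' The quantity of interest is the metric term: its coefficient, the
#' two-sided t-test p-value, and the partial correlation of metric and
#' outcome given the covariates, recovered from the t statistic as
#' `partial_r = sign(t) * sqrt(t^2 / (t^2 + df))`.
#'
#' @param outcome Numeric well-being score vector.
#' @param metric Numeric per-subject metric vector.
#' @param covariates Data frame with numeric columns `age`, `sex` (0/1 or
#'   a two-level factor), `education_years`, `icv_mm3`, `mean_ct`,
#'   aligned with `outcome`.
#' @return Object of class `wb_glm` with elements `coefficients` (named,
#'   covariates then metric then intercept), `beta`, `beta_se`, `t_stat`,
#'   `p_value`, `partial_r`, `df_resid`, `n`.
#' @export
fit_glm <- function(outcome, metric, covariates) {
  need <- c("age", "sex", "education_years", "icv_mm3", "mean_ct")
  missing <- setdiff(need, names(covariates))
  if (length(missing) > 0) {
    ct_abort(paste0("covariates missing column(s): ",
                    paste(missing, collapse = ", ")), "bad_covariates")
  }
  n <- length(outcome)
  if (length(metric) != n || nrow(covariates) != n) {
    ct_abort("outcome, metric and covariates must align subject-wise", "bad_input")
  }
  if (n < 8) ct_abort("need n > 7 subjects for the 6-predictor model", "bad_input")
  sex <- covariates$sex
  if (is.factor(sex) || is.character(sex)) {
    sex <- as.integer(factor(sex)) - 1L
  }
  if (stats::sd(outcome) == 0) {
    ct_abort("outcome is constant; model undefined", "degenerate")
  }
  dat <- data.frame(outcome = outcome, age = covariates$age, sex = sex,
                    education_years = covariates$education_years,
                    icv_mm3 = covariates$icv_mm3, mean_ct = covariates$mean_ct,
                    metric = metric)
  fit <- stats::lm(outcome ~ age + sex + education_years + icv_mm3 +
                     mean_ct + metric, data = dat)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    ct_abort(paste0("design matrix is rank deficient; offending column(s): ",
                    paste(names(co)[is.na(co)], collapse = ", ")),
             "rank_deficient")
  }
  sm <- stats::summary.lm(fit)$coefficients
  beta <- sm["metric", "Estimate"]
  t_stat <- sm["metric", "t value"]
  df_resid <- fit$df.residual
  structure(list(coefficients = co,
                 beta = beta,
                 beta_se = sm["metric", "Std. Error"],
                 t_stat = t_stat,
                 p_value = sm["metric", "Pr(>|t|)"],
                 partial_r = sign(t_stat) * sqrt(t_stat^2 / (t_stat^2 + df_resid)),
                 df_resid = df_resid,
                 n = n),
            class = "wb_glm")
}

#' @export
print.wb_glm <- function(x, ...) {
  cat("Covariate-adjusted metric association (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  beta = %.4g (se %.3g), t(%d) = %.3f, p = %.4g, partial r = %.4f\n",
              x$beta, x$beta_se, x$df_resid, x$t_stat, x$p_value, x$partial_r))
  invisible(x)
}

#' @export
tidy.wb_glm <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.wb_glm <- function(x, ...) {
  tibble::tibble(beta = x$beta, beta_se = x$beta_se, t_stat = x$t_stat,
                 p_value = x$p_value, partial_r = x$partial_r,
                 df_resid = x$df_resid, n = x$n)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment of a family of p-values; a test is flagged
#' significant when its adjusted q-value falls below `q`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `q_values` (monotone BH-adjusted values) and
#'   `significant` (logical flags, `q_values < q`).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    ct_abort("p-values must lie in [0, 1]", "bad_input")
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, significant = qv < q)
}

#' Association of network topology with well-being
#'
#' Fits the covariate-adjusted model of [fit_glm()] for every
#' combination of node-level topology metric, well-being dimension
#' (emotional, psychological, social, total) and parcel, applying
#' Benjamini-Hochberg FDR within each (metric x dimension) family of 32
#' parcel tests. The graph-level global efficiency, one value per
#' subject, is tested once per dimension without parcel looping or FDR.
#'
#' @param metrics Long metric table from [compute_all_metrics()] /
#'   [run_pipeline()]: `subject_id`, `parcel`, `metric`, `value`.
#' @param scores Well-being scores from [score_mhcsf()].
#' @param covariates Tibble with `subject_id`, `age`, `sex`,
#'   `education_years`, `icv_mm3`, `mean_ct`.
#' @param q FDR level (default 0.05).
#' @param pool_metrics If `TRUE`, one FDR family pools all node-level
#'   metrics per dimension instead of the default per-(metric, dimension)
#'   families of 32 (sensitivity analysis).
#' @param zero_order If `TRUE`, adds the unadjusted Pearson correlation
#'   of metric and outcome as a `zero_order_r` column.
#' @return A tibble of class `wb_assoc`: `metric`, `dimension`, `parcel`,
#'   `beta`, `partial_r`, `p`, `q`, `significant` (plus `n`, `df_resid`).
#' @export
run_association <- function(metrics, scores, covariates, q = 0.05,
                            pool_metrics = FALSE, zero_order = FALSE) {
  ids <- scores$subject_id
  if (!setequal(ids, covariates$subject_id)) {
    ct_abort("scores and covariates cover different subjects", "bad_input")
  }
  covariates <- covariates[match(ids, covariates$subject_id), ]
  dims <- c("emotional", "psychological", "social", "total")
  node <- dplyr::filter(metrics, .data$metric != "Eglob")
  wide <- tidyr::pivot_wider(node, names_from = "parcel", values_from = "value")
  rows <- purrr::map_dfr(unique(node$metric), function(m) {
    mw <- dplyr::filter(wide, .data$metric == m)
    mw <- mw[match(ids, mw$subject_id), ]
    parcels <- setdiff(names(mw), c("subject_id", "metric"))
    purrr::map_dfr(dims, function(dm) {
      purrr::map_dfr(parcels, function(pc) {
        # a metric constant across subjects carries no information; keep
        # the row (NA statistics) but leave it out of the FDR family
        if (stats::sd(mw[[pc]]) == 0) {
          return(tibble::tibble(metric = m, dimension = dm, parcel = pc,
                                n = length(ids), df_resid = NA_integer_,
                                beta = NA_real_, t_stat = NA_real_,
                                partial_r = NA_real_, p = NA_real_))
        }
        f <- fit_glm(scores[[dm]], mw[[pc]], covariates)
        out <- tibble::tibble(metric = m, dimension = dm, parcel = pc,
                              n = f$n, df_resid = f$df_resid, beta = f$beta,
                              t_stat = f$t_stat, partial_r = f$partial_r,
                              p = f$p_value)
        if (zero_order) out$zero_order_r <- stats::cor(scores[[dm]], mw[[pc]])
        out
      })
    })
  })
  fam <- if (pool_metrics) paste(rows$dimension) else paste(rows$metric, rows$dimension)
  rows$q <- NA_real_
  rows$significant <- NA
  for (f in unique(fam)) {
    sel <- fam == f & !is.na(rows$p)
    if (!any(sel)) next
    adj <- fdr_bh(rows$p[sel], q = q)
    rows$q[sel] <- adj$q_values
    rows$significant[sel] <- adj$significant
  }
  eglob <- dplyr::filter(metrics, .data$metric == "Eglob")
  if (nrow(eglob) > 0) {
    eg <- eglob[match(ids, eglob$subject_id), ]
    ge <- purrr::map_dfr(dims, function(dm) {
      f <- fit_glm(scores[[dm]], eg$value, covariates)
      tibble::tibble(metric = "Eglob", dimension = dm, parcel = NA_character_,
                     n = f$n, df_resid = f$df_resid, beta = f$beta,
                     t_stat = f$t_stat, partial_r = f$partial_r, p = f$p_value,
                     q = f$p_value, significant = f$p_value < q)
    })
    if (zero_order) ge$zero_order_r <- purrr::map_dbl(dims, ~stats::cor(scores[[.x]], eg$value))
    rows <- dplyr::bind_rows(rows, ge)
  }
  class(rows) <- c("wb_assoc", class(rows))
  attr(rows, "q") <- q
  rows
}

#' Per-dimension effect sizes at parcels significant for the total score
#'
#' For every (metric, parcel) flagged significant in the total-score
#' family, reports the partial correlation of each of the three
#' well-being dimensions with that parcel's metric under the same
#' covariate-adjusted model -- the per-dimension effect-size breakdown of
#' a total-score finding.
#'
#' @param assoc A `wb_assoc` table from [run_association()].
#' @return Tibble: `metric`, `parcel`, `dimension`, `partial_r`.
#' @export
effect_sizes <- function(assoc) {
  hits <- dplyr::filter(assoc, .data$dimension == "total",
                        .data$significant, .data$metric != "Eglob")
  dplyr::semi_join(
    dplyr::filter(assoc, .data$dimension != "total"),
    hits, by = c("metric", "parcel")
  ) |>
    dplyr::select("metric", "parcel", "dimension", "partial_r")
}

#' Plot an association table
#'
#' @param object A `wb_assoc` from [run_association()].
#' @param ... Unused.
#' @return A ggplot: partial correlation per parcel, faceted by metric
#'   and well-being dimension, FDR-significant parcels highlighted.
#' @export
autoplot.wb_assoc <- function(object, ...) {
  node <- dplyr::filter(object, !is.na(.data$parcel))
  ggplot2::ggplot(node, ggplot2::aes(x = .data$partial_r, y = .data$parcel,
                                     colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(ggplot2::vars(.data$dimension),
                        ggplot2::vars(.data$metric)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "partial correlation (covariate-adjusted)", y = NULL,
                  colour = paste0("q < ", attr(object, "q"))) +
    ggplot2::theme_minimal(base_size = 8)
}
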