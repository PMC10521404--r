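#' Default MHC-SF subscale map
#'
#' The Mental Health Continuum Short Form has 14 items: 3 emotional
#' (hedonic) well-being items, 5 social well-being items and 6
#' psychological well-being items, in that order in the standard form.
#' The map is an explicit argument of [score_mhcsf()] so translated or
#' reordered forms can be scored by supplying their own partition.
#'
#' @return A named list of integer item indices partitioning 1..14 into
#'   `emotional` (3), `social` (5), `psychological` (6).
#' @export
mhcsf_subscales <- function() {
  list(emotional = 1:3, social = 4:8, psychological = 9:14)
}

item_cols <- function() sprintf("item_%02d", 1:14)

#' Score the MHC-SF
#'
#' Sums item responses into emotional, social, psychological and total
#' well-being. Item responses are expected on a 0--5 numeric coding
#' ("never" = 0 ... "every day" = 5), which gives the familiar subscale
#' ranges 0--15 (emotional), 0--25 (social), 0--30 (psychological) and
#' 0--70 (total); set `item_range = c(1, 6)` for forms coded 1--6.
#' Missing or out-of-range responses are an error naming the item and
#' subject, never silently imputed.
#'
#' @param responses Data frame with a `subject_id` column and item columns
#'   `item_01` ... `item_14`.
#' @param subscales Partition of items 1..14, see [mhcsf_subscales()].
#' @param item_range Length-2 numeric, inclusive admissible response range.
#' @return A tibble with columns `subject_id`, `emotional`, `social`,
#'   `psychological`, `total`.
#' @export
#' @examples
#' resp <- tibble::tibble(subject_id = "s1")
#' resp[sprintf("item_%02d", 1:14)] <- as.list(rep(5, 14))
#' score_mhcsf(resp)
score_mhcsf <- function(responses, subscales = mhcsf_subscales(),
                        item_range = c(0, 5)) {
  cols <- item_cols()
  missing <- setdiff(cols, names(responses))
  if (length(missing) > 0) {
    ct_abort(paste0("missing item column(s): ", paste(missing, collapse = ", ")),
             "bad_items")
  }
  idx <- sort(unlist(subscales, use.names = FALSE))
  if (!identical(idx, 1:14) ||
      !setequal(names(subscales), c("emotional", "social", "psychological")) ||
      length(subscales$emotional) != 3 || length(subscales$social) != 5 ||
      length(subscales$psychological) != 6) {
    ct_abort("subscales must partition items 1..14 into emotional (3), social (5), psychological (6)",
             "bad_subscales")
  }
  items <- as.matrix(responses[cols])
  bad <- which(!is.finite(items) | items < item_range[1] | items > item_range[2],
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ct_abort(paste0("missing or out-of-range response in ", cols[bad[1, 2]],
                    " (row ", bad[1, 1], ")"), "bad_items")
  }
  sums <- function(which) {
    m <- items[, cols[subscales[[which]]], drop = FALSE]
    as.numeric(rowSums(m))
  }
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(responses)) responses$subject_id
                 else seq_len(nrow(responses)),
    emotional = sums("emotional"),
    social = sums("social"),
    psychological = sums("psychological")
  )
  out$total <- out$emotional + out$social + out$psychological
  out
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i s_i^2}{s_t^2}\right)}
#' where \eqn{k} is the number of items, \eqn{s_i^2} the sample variance of
#' item \eqn{i} and \eqn{s_t^2} the sample variance of the total score.
#' All variances use the n-1 denominator.
#'
#' @param items Numeric matrix or data frame, subjects in rows, items in
#'   columns (>= 2 items, >= 2 subjects).
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (!is.numeric(items) || ncol(items) < 2 || nrow(items) < 2) {
    ct_abort("cronbach_alpha needs a numeric matrix with >= 2 items and >= 2 subjects",
             "bad_items")
  }
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    ct_abort("total-score variance is zero; alpha is undefined", "degenerate")
  }
  item_var <- sum(apply(items, 2, stats::var))
  (k / (k - 1)) * (1 - item_var / total_var)
}

#' Cohort descriptives and inter-variable correlations
#'
#' Per-variable mean, sd and range plus the pairwise Pearson correlation
#' matrix with two-sided p-values and the conventional significance stars
#' (* p < 0.05, ** p < 0.01), in the layout used for participant tables.
#' Constant variables get `NA` correlations with a `degenerate` flag;
#' correlations are suppressed entirely below 3 subjects.
#'
#' @param scores Data frame of well-being scores (see [score_mhcsf()]).
#' @param covariates Data frame with `subject_id` plus numeric covariates
#'   (e.g. `age`, `education_years`); joined to `scores` by `subject_id`.
#' @return A list of class `wb_descriptives` with tibbles `descriptives`
#'   (`variable`, `mean`, `sd`, `min`, `max`) and `correlations`
#'   (`var1`, `var2`, `r`, `p`, `stars`).
#' @export
describe_cohort <- function(scores, covariates = NULL) {
  dat <- tibble::as_tibble(scores)
  if (!is.null(covariates)) {
    dat <- dplyr::inner_join(dat, tibble::as_tibble(covariates), by = "subject_id")
  }
  num <- dat[vapply(dat, is.numeric, logical(1))]
  desc <- purrr::map_dfr(names(num), function(v) {
    x <- num[[v]]
    tibble::tibble(variable = v, mean = mean(x), sd = stats::sd(x),
                   min = min(x), max = max(x))
  })
  n <- nrow(num)
  if (n < 3) {
    cors <- tibble::tibble(var1 = character(), var2 = character(),
                           r = numeric(), p = numeric(), stars = character())
  } else {
    pairs <- utils::combn(names(num), 2)
    cors <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      x <- num[[pairs[1, j]]]; y <- num[[pairs[2, j]]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        tibble::tibble(var1 = pairs[1, j], var2 = pairs[2, j],
                       r = NA_real_, p = NA_real_, stars = "degenerate")
      } else {
        ct <- stats::cor.test(x, y)
        tibble::tibble(var1 = pairs[1, j], var2 = pairs[2, j],
                       r = unname(ct$estimate), p = ct$p.value,
                       stars = if (ct$p.value < 0.01) "**"
                               else if (ct$p.value < 0.05) "*" else "")
      }
    })
  }
  structure(list(descriptives = desc, correlations = cors, n = n),
            class = "wb_descriptives")
}

#' @export
print.wb_descriptives <- function(x, ...) {
  cat("Cohort descriptives (n = ", x$n, ")\n", sep = "")
  print(x$descriptives)
  cat("\nPairwise Pearson correlations\n")
  print(x$correlations)
  invisible(x)
}
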