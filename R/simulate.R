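#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate
#' the study conditions the pipeline is designed for: 65 subjects, the
#' bundled 32-parcel Yeo-7 table with its fsaverage5 vertex counts,
#' vertex thickness around 2.5 mm, an age/education correlation of
#' -0.401, and MHC-SF items on a 6-point frequency scale driven by one
#' latent well-being factor.
#'
#' The planted effect, when `effect_parcel` is set and `effect_size` is
#' nonzero, couples the thickness-distribution shape of that parcel (and
#' a designated neighbour set, by default the other parcels of its
#' hemisphere and network) to the latent factor, so that
#' similarity edges -- and hence topology -- co-vary with well-being.
#' `effect_size` is the target magnitude of the partial correlation the
#' downstream association stage should recover; the internal coupling
#' gain was calibrated by simulation at the default cohort size.
#'
#' @param n_subjects Number of subjects (default 65).
#' @param parcels Parcel table (see [yeo32_parcels()]).
#' @param thickness_mean,thickness_sd Vertex thickness distribution (mm).
#' @param parcel_mean_sd Between-parcel sd of parcel mean thickness (mm).
#' @param subject_mean_sd Subject-by-parcel jitter of mean thickness (mm).
#' @param age_mean,age_sd,education_mean,education_sd,icv_mean,icv_sd
#'   Covariate moments (years, years, mm^3).
#' @param age_education_cor,age_icv_cor,education_icv_cor Target Pearson
#'   correlations of the Gaussian covariate copula.
#' @param sex_p Probability of sex code 1.
#' @param effect_parcel Parcel name carrying the planted effect, or `NULL`.
#' @param effect_neighbors Character vector of neighbour parcels; `NULL`
#'   selects up to 4 same-hemisphere, same-network parcels.
#' @param effect_size Target partial correlation in `[-1, 1]`; 0 disables
#'   the effect.
#' @param neighbor_sep Separation (mm) of the bimodal thickness mixture
#'   given to the neighbour set; the effect parcel's separation moves
#'   between 0 (background shape) and this value with the latent.
#' @param effect_gain Logistic gain converting latent to mixture shape.
#' @param component_sd Sd (mm) of each mixture component.
#' @param latent_noise_sd Sd of the item-level noise added to the latent
#'   before thresholding.
#' @param cut_points Five increasing thresholds mapping latent + noise to
#'   item scores 0..5.
#' @param seed Integer master seed; every random stream derives from it.
#' @return A validated list of class `wb_sim_config`.
#' @export
simulation_config <- function(n_subjects = 65,
                              parcels = yeo32_parcels(),
                              thickness_mean = 2.5,
                              thickness_sd = 0.3,
                              parcel_mean_sd = 0.10,
                              subject_mean_sd = 0.10,
                              age_mean = 37.29, age_sd = 13.11,
                              education_mean = 15.37, education_sd = 3.19,
                              icv_mean = 1.45e6, icv_sd = 1.3e5,
                              age_education_cor = -0.401,
                              age_icv_cor = 0,
                              education_icv_cor = 0,
                              sex_p = 0.5,
                              effect_parcel = NULL,
                              effect_neighbors = NULL,
                              effect_size = 0,
                              neighbor_sep = 1.2,
                              effect_gain = 3.5,
                              component_sd = 0.15,
                              latent_noise_sd = 1,
                              cut_points = c(-3.3, -2.4, -1.5, -0.6, 0.3),
                              seed = 1L) {
  parcels <- validate_parcel_table(parcels)
  cfg <- list(n_subjects = n_subjects, parcels = parcels,
              thickness_mean = thickness_mean, thickness_sd = thickness_sd,
              parcel_mean_sd = parcel_mean_sd, subject_mean_sd = subject_mean_sd,
              age_mean = age_mean, age_sd = age_sd,
              education_mean = education_mean, education_sd = education_sd,
              icv_mean = icv_mean, icv_sd = icv_sd,
              age_education_cor = age_education_cor,
              age_icv_cor = age_icv_cor,
              education_icv_cor = education_icv_cor,
              sex_p = sex_p,
              effect_parcel = effect_parcel,
              effect_neighbors = effect_neighbors,
              effect_size = effect_size,
              neighbor_sep = neighbor_sep,
              effect_gain = effect_gain, component_sd = component_sd,
              latent_noise_sd = latent_noise_sd, cut_points = cut_points,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 7) {
    ct_abort("n_subjects must be an integer >= 7 (5 covariates + metric + intercept must be estimable)",
             "bad_config")
  }
  sds <- c(thickness_sd = cfg$thickness_sd, parcel_mean_sd = cfg$parcel_mean_sd,
           subject_mean_sd = cfg$subject_mean_sd, age_sd = cfg$age_sd,
           education_sd = cfg$education_sd, icv_sd = cfg$icv_sd,
           component_sd = cfg$component_sd, latent_noise_sd = cfg$latent_noise_sd)
  if (any(sds < 0)) {
    ct_abort(paste0("negative sd(s): ",
                    paste(names(sds)[sds < 0], collapse = ", ")), "bad_config")
  }
  if (abs(cfg$effect_size) > 1) {
    ct_abort("effect_size must lie in [-1, 1]", "bad_config")
  }
  if (!is.null(cfg$effect_parcel) &&
      !cfg$effect_parcel %in% cfg$parcels$parcel_name) {
    ct_abort(paste0("effect_parcel '", cfg$effect_parcel,
                    "' is not in the parcel table"), "bad_config")
  }
  if (is.unsorted(cfg$cut_points, strictly = TRUE) || length(cfg$cut_points) != 5) {
    ct_abort("cut_points must be 5 strictly increasing values", "bad_config")
  }
  if (!is.null(cfg$effect_neighbors)) {
    bad <- setdiff(cfg$effect_neighbors, cfg$parcels$parcel_name)
    if (length(bad) > 0) {
      ct_abort(paste0("unknown neighbour parcel(s): ", paste(bad, collapse = ", ")),
               "bad_config")
    }
  }
  structure(cfg, class = "wb_sim_config")
}

# default neighbour set: same hemisphere + network, padded with the
# nearest rows in canonical order, capped at 4
effect_neighbor_set <- function(cfg) {
  if (is.null(cfg$effect_parcel)) return(character(0))
  if (!is.null(cfg$effect_neighbors)) return(cfg$effect_neighbors)
  p <- cfg$parcels
  row <- match(cfg$effect_parcel, p$parcel_name)
  same <- p[p$hemisphere == p$hemisphere[row] & p$network == p$network[row], ]
  same <- same[order(-same$vertex_count), ]
  nbr <- setdiff(same$parcel_name, cfg$effect_parcel)
  if (length(nbr) < 2) {
    extra <- p$parcel_name[order(abs(seq_len(nrow(p)) - row))]
    nbr <- setdiff(unique(c(nbr, extra)), cfg$effect_parcel)
  }
  utils::head(nbr, 3)
}

# rng stream offsets: every draw type gets a disjoint child-seed index
# space so streams never overlap and adding subjects leaves existing
# subjects untouched
STREAM <- list(covariate = 0L, latent = 300000L, behavior = 600000L,
               parcel_offset = 900000L, thickness = 1200000L)

# Characteristic mean thickness offset per parcel. Real parcels have
# stable, anatomy-determined mean thickness (visual cortex thin, frontal
# regions thick), so the offsets are a fixed pattern scaled by
# parcel_mean_sd, not a per-cohort draw: every cohort shares the same
# anatomy and differs only in subjects.
parcel_mean_offsets <- function(cfg) {
  n <- nrow(cfg$parcels)
  z <- stats::qnorm(seq_len(n) / (n + 1))
  ord <- vapply(seq_len(n), function(p) {
    set.seed(child_seed(211L, STREAM$parcel_offset + p))
    stats::runif(1)
  }, numeric(1))
  stats::setNames(cfg$parcel_mean_sd * z[rank(ord)], cfg$parcels$parcel_name)
}

subject_ids <- function(n) sprintf("sub-%03d", seq_len(n))

#' Simulate cohort covariates
#'
#' Draws age, education and intracranial volume per subject from a
#' Gaussian copula with the configured means, sds and pairwise target
#' correlations, plus an independent binary sex. Subjects are drawn
#' independently from per-subject seed streams, so enlarging the cohort
#' never changes existing subjects.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return Tibble: `subject_id`, `age`, `sex` (0/1), `education_years`,
#'   `icv_mm3`.
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- cfg$age_education_cor
  R[1, 3] <- R[3, 1] <- cfg$age_icv_cor
  R[2, 3] <- R[3, 2] <- cfg$education_icv_cor
  ch <- tryCatch(chol(R), error = function(e) {
    ct_abort("target covariate correlations are not positive definite", "bad_config")
  })
  rows <- purrr::map_dfr(seq_len(cfg$n_subjects), function(i) {
    set.seed(child_seed(seed, STREAM$covariate + i))
    z <- as.numeric(t(ch) %*% stats::rnorm(3))
    tibble::tibble(
      age = cfg$age_mean + cfg$age_sd * z[1],
      sex = stats::rbinom(1, 1, cfg$sex_p),
      education_years = cfg$education_mean + cfg$education_sd * z[2],
      icv_mm3 = cfg$icv_mean + cfg$icv_sd * z[3]
    )
  })
  dplyr::bind_cols(tibble::tibble(subject_id = subject_ids(cfg$n_subjects)), rows)
}

simulate_latent <- function(config, seed = config$seed) {
  vapply(seq_len(config$n_subjects), function(i) {
    set.seed(child_seed(seed, STREAM$latent + i))
    stats::rnorm(1)
  }, numeric(1))
}

#' Simulate vertex thickness for one parcel of one subject
#'
#' Baseline parcels draw vertex thickness from a Gaussian around the
#' parcel's mean (a fixed per-parcel offset plus a small subject jitter).
#' Parcels in the planted neighbour set instead draw from a two-component
#' location mixture with fixed separation; the effect parcel's separation
#' interpolates with the subject's latent well-being, approaching the
#' neighbour shape at high latent and a wider, dissimilar shape at low
#' latent. All values are strictly positive (non-positive draws are
#' redrawn; at these defaults that is essentially never exercised).
#'
#' @param parcel Parcel name (must exist in `config$parcels`).
#' @param latent Subject's latent well-being (unitless).
#' @param config A [simulation_config()].
#' @param seed RNG seed for this subject-by-parcel stream.
#' @param common_shift Subject-level mean shift (mm) applied to every
#'   parcel of the effect set, so the set moves as a block relative to
#'   the background while staying internally aligned; [simulate_cohort()]
#'   draws it once per subject.
#' @return Numeric vector of length `vertex_count`, in mm.
#' @export
simulate_parcel_thickness <- function(parcel, latent, config, seed = config$seed,
                                      common_shift = 0) {
  cfg <- validate_sim_config(config)
  row <- match(parcel, cfg$parcels$parcel_name)
  if (is.na(row)) {
    ct_abort(paste0("unknown parcel: ", parcel), "bad_config")
  }
  effect_on <- !is.null(cfg$effect_parcel) && cfg$effect_size != 0
  neighbors <- if (effect_on) effect_neighbor_set(cfg) else character(0)
  sim_parcel_worker(parcel, row, latent, cfg, seed, common_shift,
                    parcel_mean_offsets(cfg), neighbors, effect_on)
}

# hot path shared by simulate_parcel_thickness and simulate_cohort;
# offsets and the neighbour set are precomputed by the caller
sim_parcel_worker <- function(parcel, row, latent, cfg, seed, common_shift,
                              offsets, neighbors, effect_on) {
  vc <- cfg$parcels$vertex_count[row]
  in_effect_set <- effect_on && parcel %in% c(cfg$effect_parcel, neighbors)
  set.seed(seed)
  if (in_effect_set) {
    # The effect set shares a common, jitter-free mean so its similarity
    # structure is carried purely by distribution shape. Neighbours hold
    # a fixed, sharply bimodal shape. The effect parcel draws each vertex
    # from that neighbour shape with probability plogis(gain * latent)
    # and otherwise from a wider bimodal shape: its histogram similarity
    # to the neighbour set rises with the latent, while both endpoint
    # shapes are about equally dissimilar to the unimodal background, so
    # the rest of the network barely sees the latent.
    mu <- cfg$thickness_mean + common_shift
    if (parcel == cfg$effect_parcel) {
      g <- cfg$effect_gain * cfg$effect_size
      q <- stats::plogis(g * latent)
      near <- stats::rbinom(vc, 1, q) == 1
      sep <- ifelse(near, cfg$neighbor_sep, 2 * cfg$neighbor_sep)
    } else {
      sep <- cfg$neighbor_sep
    }
    comp <- stats::rbinom(vc, 1, 0.5)
    v <- stats::rnorm(vc, mu + (comp - 0.5) * sep, cfg$component_sd)
  } else {
    mu <- cfg$thickness_mean + offsets[[parcel]] +
      stats::rnorm(1, 0, cfg$subject_mean_sd)
    v <- stats::rnorm(vc, mu, cfg$thickness_sd)
  }
  while (any(v <= 0)) {
    v[v <= 0] <- stats::rnorm(sum(v <= 0), mu, cfg$component_sd)
  }
  v
}

#' Simulate MHC-SF item responses from latent well-being
#'
#' Each of the 14 items is an independent noisy reading of the subject's
#' latent factor, graded through five fixed ordered cut points onto the
#' 0..5 response scale; higher latent gives stochastically higher scores.
#'
#' @param latent Numeric vector of latent well-being values.
#' @param config A [simulation_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @return Tibble: `subject_id`, `item_01` ... `item_14` (integers 0..5).
#' @export
simulate_behavior <- function(latent, config, seed = config$seed) {
  cfg <- validate_sim_config(config)
  stopifnot(all(is.finite(latent)))
  rows <- purrr::map_dfr(seq_along(latent), function(i) {
    set.seed(child_seed(seed, STREAM$behavior + i))
    x <- latent[i] + stats::rnorm(14, 0, cfg$latent_noise_sd)
    resp <- findInterval(x, cfg$cut_points)
    tibble::as_tibble(as.list(stats::setNames(as.integer(resp), item_cols())))
  })
  dplyr::bind_cols(tibble::tibble(subject_id = subject_ids(length(latent))), rows)
}

#' Simulate a full synthetic cohort
#'
#' Composes the covariate, latent, behaviour and thickness simulators
#' into one reproducible cohort object. Everything derives from
#' `config$seed` through per-subject child streams: the same config gives
#' a bitwise-identical cohort, and growing `n_subjects` leaves the
#' existing subjects unchanged.
#'
#' @param config A [simulation_config()].
#' @return Object of class `wb_cohort`: list with `parcels`, `covariates`
#'   (tibble), `behavior` (tibble of item responses), `latent` (tibble
#'   `subject_id`, `latent`; the generative ground truth, retained for
#'   recovery tests), `thickness` (named list: subject -> named list of
#'   per-parcel vectors) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  cfg <- validate_sim_config(config)
  ids <- subject_ids(cfg$n_subjects)
  covariates <- simulate_covariates(cfg)
  latent <- simulate_latent(cfg)
  behavior <- simulate_behavior(latent, cfg)
  offsets <- parcel_mean_offsets(cfg)
  effect_on <- !is.null(cfg$effect_parcel) && cfg$effect_size != 0
  neighbors <- if (effect_on) effect_neighbor_set(cfg) else character(0)
  thickness <- lapply(seq_len(cfg$n_subjects), function(i) {
    sub_seed <- child_seed(cfg$seed, STREAM$thickness + i)
    v <- lapply(seq_len(nrow(cfg$parcels)), function(p) {
      sim_parcel_worker(cfg$parcels$parcel_name[p], p, latent[i], cfg,
                        child_seed(sub_seed, p), 0, offsets, neighbors,
                        effect_on)
    })
    names(v) <- cfg$parcels$parcel_name
    attr(v, "subject_id") <- ids[i]
    v
  })
  names(thickness) <- ids
  structure(list(parcels = cfg$parcels, covariates = covariates,
                 behavior = behavior,
                 latent = tibble::tibble(subject_id = ids, latent = latent),
                 thickness = thickness, config = cfg),
            class = "wb_cohort")
}

#' @export
print.wb_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$thickness), " subjects, ",
      nrow(x$parcels), " parcels (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$config$effect_parcel) && x$config$effect_size != 0) {
    cat("  planted effect: ", x$config$effect_parcel,
        " (target partial r = ", x$config$effect_size, ")\n", sep = "")
  } else {
    cat("  no planted effect (null cohort)\n")
  }
  invisible(x)
}

#' Write a cohort to disk in the pipeline's interchange formats
#'
#' One thickness TSV per subject (`thickness/<subject_id>.tsv`), one
#' behaviour CSV (`behavior.csv`: items plus covariates), the parcel
#' table (`parcels.tsv`) and the generative ground truth
#' (`ground_truth.csv`).
#'
#' @param cohort A `wb_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wb_cohort"))
  dir.create(file.path(dir, "thickness"), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$parcels, file.path(dir, "parcels.tsv"), progress = FALSE)
  behavior <- dplyr::inner_join(cohort$behavior, cohort$covariates,
                                by = "subject_id")
  readr::write_csv(behavior, file.path(dir, "behavior.csv"), progress = FALSE)
  readr::write_csv(cohort$latent, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  for (id in names(cohort$thickness)) {
    write_subject_thickness(cohort$thickness[[id]],
                            file.path(dir, "thickness", paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read a behaviour table (items plus covariates)
#'
#' @param path CSV with `subject_id`, `item_01` ... `item_14` and the
#'   covariate columns `age`, `sex`, `education_years`, `icv_mm3`.
#' @return A tibble.
#' @export
read_behavior <- function(path) {
  if (!file.exists(path)) ct_abort(paste0("file not found: ", path), "io_error")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", item_cols())
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    ct_abort(paste0("behaviour table is missing column(s): ",
                    paste(missing, collapse = ", ")), "bad_behavior")
  }
  tab
}
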