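#' Pipeline configuration
#'
#' One object drives the full run: either a synthetic cohort (via
#' `simulation`) or a directory of real inputs (`input_dir` holding
#' `parcels.tsv`, `behavior.csv` and `thickness/<subject>.tsv`), exactly
#' one of the two, plus the scoring, network and association options.
#'
#' @param simulation A [simulation_config()], or `NULL` for real-input
#'   mode.
#' @param input_dir Directory of real inputs, or `NULL` for synthetic
#'   mode.
#' @param min_vertices Parcel retention threshold (see
#'   [filter_parcels()]).
#' @param n_bins Histogram bins per parcel pair.
#' @param distance OMST distance transform (`"reciprocal"` or
#'   `"one_minus"`).
#' @param item_range Admissible MHC-SF response range.
#' @param subscales Item-to-subscale map (see [mhcsf_subscales()]).
#' @param fdr_q FDR level.
#' @param pool_metrics Pool FDR families across metrics (see
#'   [run_association()]).
#' @param seed Integer seed for synthetic mode.
#' @return A validated list of class `wb_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(seed = seed),
                            input_dir = NULL,
                            min_vertices = 50, n_bins = 30,
                            distance = c("reciprocal", "one_minus"),
                            item_range = c(0, 5),
                            subscales = mhcsf_subscales(),
                            fdr_q = 0.05, pool_metrics = FALSE,
                            seed = 1L) {
  distance <- match.arg(distance)
  if (!is.null(input_dir)) simulation <- NULL
  if (is.null(simulation) && is.null(input_dir)) {
    ct_abort("exactly one of simulation / input_dir must be given", "bad_config")
  }
  if (!is.null(simulation)) simulation <- validate_sim_config(simulation)
  structure(list(simulation = simulation, input_dir = input_dir,
                 min_vertices = min_vertices, n_bins = n_bins,
                 distance = distance, item_range = item_range,
                 subscales = subscales, fdr_q = fdr_q,
                 pool_metrics = pool_metrics, seed = as.integer(seed)),
            class = "wb_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] fields; a `simulation`
#' section mirrors [simulation_config()] fields (the parcel table itself
#' stays the bundled default unless `parcels_file` points at a TSV).
#'
#' @param path YAML file.
#' @return A `wb_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (is.null(y$input_dir)) {
    sim_args <- y$simulation %||% list()
    if (!is.null(sim_args$parcels_file)) {
      sim_args$parcels <- read_parcel_table(sim_args$parcels_file)
      sim_args$parcels_file <- NULL
    }
    if (is.null(sim_args$seed) && !is.null(y$seed)) sim_args$seed <- y$seed
    sim <- do.call(simulation_config, sim_args)
  }
  args <- y[intersect(names(y), c("min_vertices", "n_bins", "distance",
                                  "item_range", "fdr_q", "pool_metrics", "seed"))]
  args$simulation <- sim
  args$input_dir <- y$input_dir
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Similarity matrices for every subject of a cohort
#'
#' @param thickness Named list (subject -> named list of per-parcel
#'   thickness vectors), e.g. `cohort$thickness`.
#' @param parcels Parcel table fixing node order.
#' @param n_bins Histogram bins per pair.
#' @return Named list of similarity matrices (see
#'   [build_similarity_matrix()]).
#' @export
build_similarity_matrices <- function(thickness, parcels, n_bins = 30) {
  lapply(thickness, build_similarity_matrix, parcels = parcels, n_bins = n_bins)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> score -> similarity networks -> OMST ->
#' topology metrics -> association in order, materialising every
#' intermediate artifact under `out_dir` together with a YAML manifest
#' (config snapshot, per-stage row counts, aggregated warnings).
#' Identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `association` (the `wb_assoc` table),
#'   `metrics`, `scores`, `covariates`, `networks`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ctnetwb_")) {
  stopifnot(inherits(config, "wb_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(stage, msg) {
    warnings_log <<- c(warnings_log, paste0("[", stage, "] ", msg))
  }

  # stage 1: inputs
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    input_dir <- file.path(out_dir, "input")
    write_cohort(cohort, input_dir)
    parcels <- cohort$parcels
    behavior <- dplyr::inner_join(cohort$behavior, cohort$covariates,
                                  by = "subject_id")
    thickness <- cohort$thickness
  } else {
    input_dir <- config$input_dir
    parcels <- read_parcel_table(file.path(input_dir, "parcels.tsv"))
    behavior <- read_behavior(file.path(input_dir, "behavior.csv"))
    files <- list.files(file.path(input_dir, "thickness"), pattern = "\\.tsv$",
                        full.names = TRUE)
    if (length(files) == 0) {
      ct_abort("no thickness files found under input_dir/thickness", "io_error")
    }
  }

  # stage 2: parcel filter
  parcels <- filter_parcels(parcels, min_vertices = config$min_vertices)
  if (is.null(config$simulation)) {
    thickness <- lapply(files, read_subject_thickness, parcels = parcels)
    names(thickness) <- vapply(thickness, attr, character(1), "subject_id")
    thickness <- thickness[intersect(behavior$subject_id, names(thickness))]
  } else {
    thickness <- lapply(thickness, function(v) {
      validate_subject_thickness(v[parcels$parcel_name], parcels,
                                 subject_id = attr(v, "subject_id"))
    })
  }
  ids <- names(thickness)
  behavior <- behavior[match(ids, behavior$subject_id), ]

  # stage 3: scoring
  scores <- score_mhcsf(behavior, subscales = config$subscales,
                        item_range = config$item_range)
  readr::write_csv(scores, file.path(out_dir, "scores.csv"), progress = FALSE)
  desc <- describe_cohort(scores,
                          behavior[c("subject_id", "age", "education_years")])
  readr::write_tsv(desc$descriptives, file.path(out_dir, "descriptives.tsv"),
                   progress = FALSE)
  readr::write_tsv(desc$correlations, file.path(out_dir, "correlations.tsv"),
                   progress = FALSE)

  # stage 4: similarity networks
  simdir <- file.path(out_dir, "simnet"); dir.create(simdir, showWarnings = FALSE)
  simmats <- withCallingHandlers(
    build_similarity_matrices(thickness, parcels, n_bins = config$n_bins),
    warning = function(w) {
      note("simnet", conditionMessage(w)); invokeRestart("muffleWarning")
    })
  for (id in ids) {
    readr::write_tsv(matrix_to_tsv(simmats[[id]]),
                     file.path(simdir, paste0(id, ".tsv")), progress = FALSE)
  }

  # stage 5: OMST sparsification
  netdir <- file.path(out_dir, "network"); dir.create(netdir, showWarnings = FALSE)
  networks <- lapply(ids, function(id) {
    net <- tryCatch(omst_threshold(simmats[[id]], distance = config$distance),
                    error = function(e) {
                      ct_abort(paste0("stage omst failed for subject ", id, ": ",
                                      conditionMessage(e)), "stage_failure")
                    })
    readr::write_tsv(matrix_to_tsv(net$adjacency),
                     file.path(netdir, paste0(id, ".tsv")), progress = FALSE)
    readr::write_csv(net$gce_curve, file.path(netdir, paste0(id, "_gce.csv")),
                     progress = FALSE)
    net
  })
  names(networks) <- ids

  # stage 6: topology metrics
  metrics <- purrr::map_dfr(ids, function(id) {
    compute_all_metrics(networks[[id]], subject_id = id)
  })
  readr::write_tsv(metrics, file.path(out_dir, "metrics.tsv"), progress = FALSE)

  # stage 7: association
  covariates <- behavior[c("subject_id", "age", "sex", "education_years",
                           "icv_mm3")]
  covariates$mean_ct <- vapply(thickness[ids], mean_cortical_thickness,
                               numeric(1))
  assoc <- run_association(metrics, scores, covariates, q = config$fdr_q,
                           pool_metrics = config$pool_metrics)
  readr::write_tsv(assoc, file.path(out_dir, "association.tsv"), progress = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctnetwb")),
    mode = if (is.null(config$simulation)) "real" else "synthetic",
    seed = config$seed,
    n_subjects = length(ids),
    n_parcels = nrow(parcels),
    stages = list(score = nrow(scores), simnet = length(simmats),
                  omst = length(networks), metrics = nrow(metrics),
                  association = nrow(assoc)),
    options = list(min_vertices = config$min_vertices, n_bins = config$n_bins,
                   distance = config$distance, fdr_q = config$fdr_q,
                   pool_metrics = config$pool_metrics),
    warnings = as.list(warnings_log)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(association = assoc, metrics = metrics, scores = scores,
                 covariates = covariates, networks = networks,
                 manifest = manifest, out_dir = out_dir))
}

matrix_to_tsv <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "parcel")
}

#' Sample exclusion accounting
#'
#' Tracks how an initial recruitment count shrinks to the analysed
#' sample: `final = initial - sum(counts)`, with one report line per
#' stated exclusion reason.
#'
#' @param initial_n Initial number of datasets.
#' @param exclusions Named integer vector or list, `reason = count`.
#' @return Object of class `wb_exclusions`: list with `initial_n`,
#'   `exclusions` (tibble `reason`, `count`), `final_n`.
#' @export
#' @examples
#' exclusion_report(67, c("absent from MRI scanning" = 1,
#'                        "failed mental health interview" = 1))$final_n
exclusion_report <- function(initial_n, exclusions = integer(0)) {
  counts <- unlist(exclusions)
  if (length(counts) > 0 && (any(counts < 0) || any(counts != round(counts)))) {
    ct_abort("exclusion counts must be nonnegative integers", "bad_input")
  }
  final_n <- initial_n - sum(counts)
  if (final_n < 0) {
    ct_abort("exclusions exceed the initial sample", "bad_input")
  }
  structure(list(initial_n = initial_n,
                 exclusions = tibble::tibble(
                   reason = if (length(counts)) names(counts) else character(0),
                   count = as.integer(counts)),
                 final_n = final_n),
            class = "wb_exclusions")
}

#' @export
print.wb_exclusions <- function(x, ...) {
  cat("Initial sample: ", x$initial_n, "\n", sep = "")
  for (k in seq_len(nrow(x$exclusions))) {
    cat("  - excluded (", x$exclusions$reason[k], "): ",
        x$exclusions$count[k], "\n", sep = "")
  }
  cat("Final sample: ", x$final_n, "\n", sep = "")
  invisible(x)
}
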