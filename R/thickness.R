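#' Read one subject's vertex thickness table
#'
#' The interchange format for vertex-level cortical thickness is one TSV
#' per subject with columns `parcel_name`, `vertex_index` (0-based within
#' parcel) and `thickness_mm`. Vectors are assembled in the parcel table's
#' canonical order and validated against its vertex counts.
#'
#' @param path Path to the subject's thickness TSV.
#' @param parcels Parcel table defining node order and vertex counts.
#' @param subject_id Identifier for the subject; defaults to the file name
#'   without extension.
#' @return A named list of numeric thickness vectors (mm), one per parcel
#'   in canonical order, with attribute `subject_id`.
#' @export
read_subject_thickness <- function(path, parcels,
                                   subject_id = sub("\\.[^.]*$", "", basename(path))) {
  parcels <- validate_parcel_table(parcels)
  if (!file.exists(path)) {
    ct_abort(paste0("thickness file not found: ", path), "io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("parcel_name", "vertex_index", "thickness_mm")
  if (!all(required %in% names(tab))) {
    ct_abort(paste0("thickness file must have columns: ",
                    paste(required, collapse = ", ")), "bad_thickness")
  }
  tab <- tab[order(match(tab$parcel_name, parcels$parcel_name), tab$vertex_index), ]
  values <- split(tab$thickness_mm, factor(tab$parcel_name, levels = parcels$parcel_name))
  validate_subject_thickness(values, parcels, subject_id = subject_id)
}

#' Write one subject's vertex thickness table
#'
#' Inverse of [read_subject_thickness()]; round-trips losslessly.
#'
#' @param values Named list of per-parcel thickness vectors (mm).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_thickness <- function(values, path) {
  tab <- tibble::tibble(
    parcel_name = rep(names(values), lengths(values)),
    vertex_index = unlist(lapply(lengths(values), function(n) seq_len(n) - 1L),
                          use.names = FALSE),
    thickness_mm = unlist(values, use.names = FALSE)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

validate_subject_thickness <- function(values, parcels, subject_id = NULL) {
  for (k in seq_len(nrow(parcels))) {
    p <- parcels$parcel_name[k]
    v <- values[[p]]
    if (is.null(v) || length(v) != parcels$vertex_count[k]) {
      ct_abort(paste0("parcel ", p, ": expected ", parcels$vertex_count[k],
                      " thickness values, got ", length(v)), "bad_thickness")
    }
    if (any(!is.finite(v)) || any(v <= 0)) {
      ct_abort(paste0("parcel ", p, ": thickness values must be finite and > 0"),
               "bad_thickness")
    }
  }
  values <- values[parcels$parcel_name]
  if (!is.null(subject_id)) attr(values, "subject_id") <- subject_id
  values
}

#' Mean cortical thickness of a subject
#'
#' The mean-CT nuisance covariate used in the association model. By
#' default every vertex contributes equally (vertex-weighted mean over all
#' retained parcels); `weighting = "parcel"` instead averages the per-parcel
#' means so each parcel contributes equally regardless of size.
#'
#' @param values Named list of per-parcel thickness vectors (mm).
#' @param weighting `"vertex"` (default) or `"parcel"`.
#' @return Mean thickness in mm.
#' @export
#' @examples
#' mean_cortical_thickness(list(a = c(2, 2), b = c(3, 3, 3, 3)))
mean_cortical_thickness <- function(values, weighting = c("vertex", "parcel")) {
  weighting <- match.arg(weighting)
  if (weighting == "vertex") {
    mean(unlist(values, use.names = FALSE))
  } else {
    mean(vapply(values, mean, numeric(1)))
  }
}
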