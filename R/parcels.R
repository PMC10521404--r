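#' Read a parcel table
#'
#' Reads the tab-separated parcel table that defines the nodes of every
#' morphological similarity network: one row per cortical parcel with its
#' hemisphere, Yeo-7 network label and surface vertex count. Row order is
#' preserved and becomes the canonical node order of all downstream
#' matrices and result tables.
#'
#' @param path Path to a TSV with columns `parcel_name`, `hemisphere`,
#'   `network`, `vertex_count`.
#' @return A tibble with the four columns above, validated: unique parcel
#'   names, integer vertex counts >= 1, hemispheres in `LH`/`RH`.
#' @seealso [yeo32_parcels()] for the bundled 32-parcel table,
#'   [filter_parcels()] for the vertex-count exclusion rule.
#' @export
#' @examples
#' parcels <- yeo32_parcels()
#' nrow(parcels)
read_parcel_table <- function(path) {
  if (!file.exists(path)) {
    ct_abort(paste0("parcel table not found: ", path), "io_error")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_parcel_table(tab)
}

validate_parcel_table <- function(tab) {
  required <- c("parcel_name", "hemisphere", "network", "vertex_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    ct_abort(paste0("parcel table is missing column(s): ",
                    paste(missing, collapse = ", ")), "bad_parcel_table")
  }
  if (nrow(tab) == 0) {
    ct_abort("parcel table has no rows", "bad_parcel_table")
  }
  dup <- unique(tab$parcel_name[duplicated(tab$parcel_name)])
  if (length(dup) > 0) {
    ct_abort(paste0("duplicated parcel name(s): ",
                    paste(dup, collapse = ", ")), "bad_parcel_table")
  }
  vc <- tab$vertex_count
  if (!is.numeric(vc) || any(!is.finite(vc)) || any(vc != round(vc)) || any(vc < 1)) {
    ct_abort("vertex_count must be integers >= 1", "bad_parcel_table")
  }
  if (!all(tab$hemisphere %in% c("LH", "RH"))) {
    ct_abort("hemisphere must be 'LH' or 'RH'", "bad_parcel_table")
  }
  tibble::as_tibble(tab[required])
}

#' Bundled 32-parcel Yeo-7 table
#'
#' The 32 cortical parcels retained for network construction (Yeo-7
#' networks, both hemispheres) with their fsaverage5 vertex counts, after
#' excluding parcels with fewer than 50 vertices from the original
#' 51-parcel whole-cortex parcellation. The smallest retained parcel
#' (RH_DorsAttn_PrCv) sits exactly on the 50-vertex boundary.
#'
#' @return A tibble with columns `parcel_name`, `hemisphere`, `network`,
#'   `vertex_count` (32 rows).
#' @export
yeo32_parcels <- function() {
  read_parcel_table(system.file("extdata", "parcels_yeo32.tsv",
                                package = "ctnetwb", mustWork = TRUE))
}

#' Exclude parcels with too few vertices
#'
#' Parcels whose thickness histogram would be built from too few surface
#' vertices carry unstable distribution estimates; they are removed before
#' network construction. The rule is strict: a parcel is dropped only when
#' its vertex count is strictly below `min_vertices`, so a count exactly at
#' the threshold is retained. Row order is preserved and the operation is
#' idempotent.
#'
#' @param parcels A parcel table (see [read_parcel_table()]).
#' @param min_vertices Minimum vertex count to retain a parcel (default 50).
#' @return The filtered parcel table.
#' @export
#' @examples
#' filter_parcels(yeo32_parcels())   # all 32 rows survive
filter_parcels <- function(parcels, min_vertices = 50) {
  parcels <- validate_parcel_table(parcels)
  kept <- dplyr::filter(parcels, .data$vertex_count >= min_vertices)
  if (nrow(kept) == 0) {
    ct_abort(paste0("no parcel has at least ", min_vertices,
                    " vertices; no network can be built"), "empty_parcel_table")
  }
  kept
}
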