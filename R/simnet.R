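# Shared-support histogram counts. Bins are right-closed, (e[k-1], e[k]],
# with the first bin additionally closed at the pooled minimum, so every
# value in [min, max] lands in exactly one bin and totals are conserved.
bin_counts_sorted <- function(v_sorted, edges) {
  diff(c(0L, findInterval(edges[-1], v_sorted)))
}

#' Paired thickness histograms on a shared support
#'
#' For one pair of parcels, bins both thickness vectors into `n_bins`
#' equal-width bins spanning the pooled range `[min, max]` of the two
#' vectors together. A shared support is what makes the bin-wise
#' frequency vectors comparable; the histogram shape, not the parcel
#' size, is what the similarity measure sees.
#'
#' @param x,y Numeric vectors of vertex thickness values (mm).
#' @param n_bins Number of bins (default 30).
#' @return List of class `pair_histograms` with `bin_edges` (length
#'   `n_bins + 1`), `freq_x`, `freq_y` (integer counts, conserving the
#'   vertex totals).
#' @export
pair_histograms <- function(x, y, n_bins = 30) {
  if (length(x) == 0 || length(y) == 0) {
    ct_abort("both thickness vectors must be nonempty", "bad_thickness")
  }
  lo <- min(x, y); hi <- max(x, y)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi) {
    ct_abort("pooled thickness range is degenerate (all values identical)",
             "degenerate_pair")
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  structure(list(bin_edges = edges,
                 freq_x = bin_counts_sorted(sort(x), edges),
                 freq_y = bin_counts_sorted(sort(y), edges)),
            class = "pair_histograms")
}

#' Histogram similarity of a parcel pair
#'
#' Pearson correlation of the two bin-frequency vectors of a
#' [pair_histograms()] object: +1 for identically shaped thickness
#' distributions, negative for anti-correlated shapes. Counts are used
#' directly; the correlation is invariant to normalising them to
#' proportions.
#'
#' @param h A `pair_histograms` object.
#' @return Correlation in `[-1, 1]`.
#' @export
histogram_similarity <- function(h) {
  if (stats::sd(h$freq_x) == 0 || stats::sd(h$freq_y) == 0) {
    ct_abort("a frequency vector has zero variance; similarity undefined",
             "degenerate_pair")
  }
  stats::cor(h$freq_x, h$freq_y)
}

#' Per-subject morphological similarity matrix
#'
#' Builds the symmetric parcel-by-parcel similarity matrix of one
#' subject: for every unordered parcel pair, the absolute value of the
#' Pearson correlation between their shared-support thickness histograms
#' (see [pair_histograms()], [histogram_similarity()]). The absolute
#' value is taken after the correlation, never on the inputs; the signed
#' negative fraction is recorded in the `frac_negative` attribute. The
#' diagonal is fixed at 0 (self-connections are excluded from topology).
#'
#' Degenerate pairs (identical pooled values or a zero-variance
#' histogram) get similarity 0 with one aggregated warning; more than 10
#' percent degenerate pairs is treated as a data pathology and raises an
#' error.
#'
#' @param values Named list of per-parcel thickness vectors for one
#'   subject, in canonical parcel order (see [read_subject_thickness()]).
#' @param parcels Parcel table fixing node order.
#' @param n_bins Histogram bins per pair (default 30).
#' @return An N x N numeric matrix with parcel-name dimnames, entries in
#'   `[0, 1]`, attributes `subject_id`, `n_degenerate`, `frac_negative`.
#' @export
build_similarity_matrix <- function(values, parcels, n_bins = 30) {
  parcels <- validate_parcel_table(parcels)
  values <- validate_subject_thickness(values, parcels,
                                       subject_id = attr(values, "subject_id"))
  nm <- parcels$parcel_name
  n <- length(nm)
  sorted <- lapply(values, sort)
  lo_p <- vapply(sorted, function(v) v[1], numeric(1))
  hi_p <- vapply(sorted, function(v) v[length(v)], numeric(1))
  sim <- matrix(0, n, n, dimnames = list(nm, nm))
  n_degenerate <- 0L
  n_negative <- 0L
  steps <- seq_len(n_bins) / n_bins
  for (i in seq_len(n - 1)) {
    vi <- sorted[[i]]
    for (j in seq((i + 1), n)) {
      lo <- min(lo_p[i], lo_p[j]); hi <- max(hi_p[i], hi_p[j])
      if (lo == hi) { n_degenerate <- n_degenerate + 1L; next }
      inner <- lo + (hi - lo) * steps
      fx <- diff(c(0L, findInterval(inner, vi)))
      fy <- diff(c(0L, findInterval(inner, sorted[[j]])))
      # inline Pearson correlation of the two count vectors
      sx <- sum(fx); sy <- sum(fy)
      vx <- sum(fx * fx) - sx * sx / n_bins
      vy <- sum(fy * fy) - sy * sy / n_bins
      if (vx == 0 || vy == 0) { n_degenerate <- n_degenerate + 1L; next }
      r <- (sum(fx * fy) - sx * sy / n_bins) / sqrt(vx * vy)
      if (r < 0) n_negative <- n_negative + 1L
      sim[i, j] <- sim[j, i] <- abs(r)
    }
  }
  n_pairs <- n * (n - 1) / 2
  if (n_degenerate > 0.10 * n_pairs) {
    ct_abort(paste0(n_degenerate, " of ", n_pairs,
                    " parcel pairs are degenerate (> 10%); inspect input"),
             "data_pathology")
  }
  if (n_degenerate > 0) {
    warn(paste0(n_degenerate, " degenerate parcel pair(s) set to similarity 0"))
  }
  attr(sim, "subject_id") <- attr(values, "subject_id")
  attr(sim, "n_degenerate") <- n_degenerate
  attr(sim, "frac_negative") <- n_negative / n_pairs
  sim
}
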