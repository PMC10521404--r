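#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# stop with a classed condition so tests can target specific failures
ct_abort <- function(msg, class) {
  abort(msg, class = paste0("ctnetwb_", class))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# derive a child RNG seed from a parent seed and an index; keeps every
# per-subject stream independent of cohort size (adding subjects never
# perturbs existing ones). Kept below .Machine$integer.max.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 104729) %% 2147483647)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
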