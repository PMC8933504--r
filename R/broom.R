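# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cascade result into its per-stage trace
#'
#' @param x An `scm_set` (see [run_filter_cascade()]).
#' @param ... Unused.
#' @return The filter-trace tibble (`stage`, `n_variants`, `n_candidates`).
#' @export
tidy.scm_set <- function(x, ...) {
  filter_trace(x)
}

#' One-row summary of a cascade result
#'
#' @param x An `scm_set`.
#' @param ... Unused.
#' @return Tibble with input size, accepted calls, distinct accepted
#'   variants, unknown-AF count and the thresholds used.
#' @export
glance.scm_set <- function(x, ...) {
  tr <- filter_trace(x)
  th <- attr(x, "thresholds")
  tibble(
    n_input = tr$n_variants[tr$stage == "input"],
    n_accepted_variants = length(unique(x$variant_id)),
    n_accepted_candidates = nrow(x),
    n_unknown_af = attr(x, "n_unknown_af"),
    max_af = th$max_af, min_strength = th$min_strength,
    min_delta = th$min_delta, intron_window = th$intron_window)
}
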