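# ggplot2 views of the main result types.

#' Plot the filter-cascade trace
#'
#' Bar chart of surviving variant counts per cascade stage, mirroring the
#' stepwise workflow display.
#'
#' @param x An `scm_set` (see [run_filter_cascade()]) or a trace tibble.
#' @return A ggplot object.
#' @export
plot_filter_trace <- function(x) {
  tr <- if (inherits(x, "scm_set")) filter_trace(x) else x
  tr$stage <- factor(tr$stage, levels = tr$stage)
  ggplot2::ggplot(tr, ggplot2::aes(x = stage, y = .data$n_variants)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_variants),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "variants surviving") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot the positional spectrum of accepted calls
#'
#' Stacked bars of call counts by signed boundary-relative position and
#' alternate base, faceted by site type. Exonic positions are negative for
#' donors; intronic positions are negative for acceptors.
#'
#' @param bins Spectrum tibble (see [bin_positions()]).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = position, y = .data$count,
                                     fill = alt_base)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~site_type, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position relative to annotated boundary (nt)",
                  y = "calls", fill = "alt base") +
    ggplot2::theme_minimal()
}

#' Plot per-position splice-site information content
#'
#' @param ic Information-content tibble (see [information_content()]), or a
#'   named list of them (one line per site type).
#' @return A ggplot object.
#' @export
plot_information_content <- function(ic) {
  if (is.data.frame(ic)) ic <- list(site = ic)
  tall <- bind_rows(lapply(names(ic), function(n) {
    mutate(ic[[n]], site_type = n)
  }))
  ggplot2::ggplot(tall, ggplot2::aes(x = position, y = .data$ic,
                                     colour = site_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 2) +
    ggplot2::labs(x = "window position", y = "information content (bits)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
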