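#' Turn a proliferation landscape into a tidy tibble
#'
#' @param x A `proliferation_landscape`.
#' @param ... Unused.
#' @return The tidy table: one row per stage x bin x marker with
#'   `mean_frequency`, `n_embryos` and `mean_length_um`.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.proliferation_landscape <- function(x, ...) x$table

#' One-row-per-cohort summary of a landscape
#'
#' @param x A `proliferation_landscape`.
#' @param ... Unused.
#' @return Tibble with per stage x marker totals: `stage_ss`, `marker`,
#'   `n_embryos`, `mean_length_um`, `n_bins`, `total_mean_frequency` and the
#'   de-normalised `total_labeled` (= total x n_embryos, an integer count).
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname glance
#' @export
glance.proliferation_landscape <- function(x, ...) {
  x$table %>%
    group_by(.data$stage_ss, .data$marker) %>%
    summarise(
      n_embryos = .data$n_embryos[1],
      mean_length_um = .data$mean_length_um[1],
      n_bins = n(),
      total_mean_frequency = sum(.data$mean_frequency),
      total_labeled = sum(.data$mean_frequency) * .data$n_embryos[1],
      .groups = "drop"
    )
}

#' Ridgeline-style plot of a proliferation landscape
#'
#' One frequency profile per somite stage, stacked by stage with the axial
#' position in um on the x axis, per marker. Rendering is cosmetic; the
#' underlying curve coordinates are `tidy(object)`.
#'
#' @param object A `proliferation_landscape`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proliferation_landscape <- function(object, ...) {
  tab <- object$table
  offset_unit <- max(tab$mean_frequency) * 1.1
  tab <- mutate(tab, y = .data$mean_frequency + .data$stage_ss * offset_unit)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$bin_start_um, y = .data$y,
                                    group = .data$stage_ss)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(ggplot2::aes(y = .data$y), alpha = 0.2,
                       position = "identity") +
    ggplot2::facet_wrap(~marker) +
    ggplot2::scale_y_continuous(
      breaks = sort(unique(tab$stage_ss)) * offset_unit,
      labels = paste0(sort(unique(tab$stage_ss)), " ss")) +
    ggplot2::labs(x = "Distance from anterior tip (um)", y = "Somite stage",
                  title = "Proliferation landscape") +
    ggplot2::theme_minimal()
}

#' Stacked-area plot of cohort fate-map profiles
#'
#' @param profiles Output of [cohort_profiles()].
#' @return A ggplot object: mean labelled-nucleus frequency per normalised
#'   axial bin, stacked by tissue (and facetted by condition when present).
#' @export
plot_fate_profiles <- function(profiles) {
  p <- ggplot2::ggplot(profiles,
                       ggplot2::aes(x = .data$bin, y = .data$mean_frequency,
                                    fill = .data$tissue)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "Normalised AP bin", y = "Mean labelled nuclei",
                  fill = "Tissue") +
    ggplot2::theme_minimal()
  if (!all(is.na(profiles$condition))) p <- p + ggplot2::facet_wrap(~condition)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
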