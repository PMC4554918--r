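# ggplot2 views of the main result types.

#' Plot a cryptic-donor scan
#'
#' Bar plot of donor-window score against exon position for every
#' GT-convertible dinucleotide, coloured by reading-frame compatibility
#' with the next exon, with horizontal lines at the validated-donor mean
#' and mean plus/minus one SD.
#'
#' @param scanned Scored candidates from [score_candidates()] /
#'   [mutation_scan()].
#' @param stats The [donor_score_stats()] row used for scoring.
#' @return A ggplot object.
#' @export
plot_mutation_scan <- function(scanned, stats) {
  dat <- filter(scanned, !is.na(.data$score))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$score,
                                    fill = .data$frame_compatible)) +
    ggplot2::geom_col(width = 1.5) +
    ggplot2::geom_hline(yintercept = stats$mean, linetype = "solid") +
    ggplot2::geom_hline(yintercept = stats$mean + c(-1, 1) * stats$sd,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#3366cc", `FALSE` = "#cc3333"),
      name = "in frame"
    ) +
    ggplot2::labs(x = "position in exon (bases)",
                  y = "donor score (bits)",
                  title = "GT-convertible sites vs validated donors") +
    ggplot2::theme_minimal()
}

#' Plot a GT survey track
#'
#' Position-by-strength lollipop plot of every GT dinucleotide across a
#' sequence window, optionally faceted by species when given a
#' conservation table.
#'
#' @param x A [window_gt_survey()] tibble, or a
#'   [site_conservation_table()] result (uses its `gt_survey` column).
#' @return A ggplot object.
#' @export
plot_gt_survey <- function(x) {
  if ("gt_survey" %in% names(x)) {
    dat <- tidyr::unnest(select(x, all_of(c("species", "gt_survey"))),
                         "gt_survey")
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$score)) +
      ggplot2::facet_wrap(~species)
  } else {
    p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$position, y = .data$score))
  }
  p +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$position, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window position (bases)", y = "donor score (bits)",
                  title = "GT dinucleotide survey") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-position base frequencies of a splice model
#'
#' @param object A `splice_model` (pwm or maxent).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_model <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$position), y = .data$freq,
                                    fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "window position", y = "frequency",
                  title = sprintf("%s donor model (n=%s)", object$kind,
                                  format(object$n %||% NA))) +
    ggplot2::theme_minimal()
}
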