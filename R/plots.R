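# ggplot2 output: allele-frequency trajectory panels and Kaplan-Meier
# curves.

#' Plot a subject's allele-frequency trajectory
#'
#' One line per tracked variant over collection day, with RECIST events
#' (in particular the first PD) marked as vertical lines and the
#' molecular-progression call day, when given, as a dashed line.
#'
#' @param trajectory Tibble with `day`, `variant`, `af`.
#' @param recist Optional tibble with `day`, `response`.
#' @param mp Optional `molecular_progression` call.
#' @return A ggplot object.
#' @export
plot_af_trajectory <- function(trajectory, recist = NULL, mp = NULL) {
  p <- ggplot2::ggplot(as_tibble(trajectory),
                       ggplot2::aes(x = .data$day, y = .data$af,
                                    colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "Days from diagnosis", y = "Allele frequency",
                  colour = "Variant") +
    ggplot2::theme_minimal()
  if (!is.null(recist) && nrow(recist) > 0) {
    pd <- filter(as_tibble(recist), .data$response == "PD")
    if (nrow(pd) > 0) {
      p <- p + ggplot2::geom_vline(xintercept = min(pd$day),
                                   colour = "red3", linetype = "solid")
    }
  }
  if (!is.null(mp) && isTRUE(mp$called)) {
    p <- p + ggplot2::geom_vline(xintercept = mp$call_day,
                                 colour = "grey30", linetype = "dashed")
  }
  p
}

#' @describeIn km_estimate Kaplan-Meier step curves, one per group, with
#'   censoring marks.
#' @param object A `km_fit`.
#' @param ... Unused.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  start <- d |>
    group_by(.data$group) |>
    summarise(time = 0, survival = 1, .groups = "drop")
  cens <- filter(d, .data$n_censor > 0)
  ggplot2::ggplot(bind_rows(start,
                            select(d, "group", "time", "survival")),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days from diagnosis",
                  y = "Progression-free survival", colour = NULL) +
    ggplot2::theme_minimal()
}
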