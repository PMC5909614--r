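#' Phenotype-space plot for a two-site-year subset
#'
#' Achievable simulated date pairs as tiles with observed lines overlaid,
#' coloured by expressibility — the phenotype-space view in which the
#' expressivity frontier appears as the edge of the achievable region.
#'
#' @param object An [achievable_tuples()] result over two site-years.
#' @param reports Optional [classify_lines()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.achievable_set <- function(object, reports = NULL, ...) {
  if (length(object$subset) != 2) {
    abort("phenotype-space plotting needs a two-site-year subset")
  }
  ach <- tibble::tibble(x = object$tuples[, 1], y = object$tuples[, 2])
  p <- ggplot2::ggplot(ach, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = paste("anthesis day,", object$subset[1]),
                  y = paste("anthesis day,", object$subset[2]),
                  title = "Achievable phenotype space")
  if (!is.null(reports)) {
    obs <- tibble::tibble(
      x = reports[[paste0("obs_", object$subset[1])]],
      y = reports[[paste0("obs_", object$subset[2])]],
      expressible = reports$expressible)
    p <- p + ggplot2::geom_point(
      data = obs, ggplot2::aes(colour = .data$expressible), size = 1) +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "goldenrod", `FALSE` = "firebrick"),
        name = "expressible")
  }
  p + ggplot2::theme_minimal()
}

#' Equifinality (tie-count) distribution across lines
#'
#' @param estimates An [invert_lines()] result.
#' @return A ggplot object: tie counts on a log10(1 + ties) axis.
#' @export
plot_tie_distribution <- function(estimates) {
  dat <- dplyr::filter(estimates, !is.na(.data$n_ties))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n_ties + 1)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "1 + number of ties (log scale)", y = "lines",
                  title = "Extent of equifinality") +
    ggplot2::theme_minimal()
}

#' Variance decomposition of the stability analysis
#'
#' @param object A [stability_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object: per-GSP stacked variance shares.
#' @export
autoplot.gsp_stability <- function(object, ...) {
  long <- tibble::as_tibble(object)[c("gsp", "var_line", "var_subset",
                                      "var_resid")] |>
    tidyr::pivot_longer(-"gsp", names_to = "component",
                        values_to = "variance") |>
    dplyr::mutate(component = sub("^var_", "", .data$component))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gsp, y = .data$variance,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "share of total variance",
                  title = "GSP variance decomposition") +
    ggplot2::theme_minimal()
}
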