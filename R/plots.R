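# ggplot2 displays for the main result types.

#' Plot posterior functional-response curves
#'
#' One panel per species: posterior mean diet proportion against the
#' focal availability index, with credible ribbons, coloured by the level
#' at which alternative prey are held.
#'
#' @param curves Output of [response_curves()].
#' @return A ggplot object.
#' @export
plot_response_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$availability, y = .data$mean,
                               colour = .data$alt_level,
                               fill = .data$alt_level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Prey availability index (max = 100)",
                  y = "Diet proportion",
                  colour = "Alternative prey", fill = "Alternative prey") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_response_curves Trace and density plot of attack-rate
#'   chains for a fitted response.
#' @param object An `msfr_fit`.
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @export
autoplot.msfr_fit <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  free <- setdiff(object$species, object$ref_species)
  d <- imap(object$chains, function(ch, i) {
    as_tibble(ch$a[, free, drop = FALSE]) |>
      mutate(chain = factor(i), iteration = dplyr::row_number()) |>
      pivot_longer(dplyr::all_of(free), names_to = "species",
                   values_to = "a")
  }) |> list_rbind()
  p <- ggplot2::ggplot(d)
  if (type == "trace") {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(x = .data$iteration, y = .data$a,
                   colour = .data$chain), alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_density(
      ggplot2::aes(x = .data$a, colour = .data$chain))
  }
  p + ggplot2::facet_wrap(~species, scales = "free") +
    ggplot2::labs(y = "attack rate", colour = "chain") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_response_curves Map of a fitted prey-density field
#'   for one year.
#' @param year Year to display (default: first).
#' @export
autoplot.prey_field <- function(object, year = NULL, ...) {
  d <- object$grid_pred
  year <- year %||% min(d$year)
  ggplot2::ggplot(filter(d, .data$year == !!year),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$bpue)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("%s, %s, %d", object$species,
                                  object$quarter, year),
                  x = "easting (km)", y = "northing (km)",
                  fill = "BPUE (g)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_response_curves Diet composition with bootstrap error
#'   bars.
#' @export
autoplot.diet_composition <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$species,
                                                  -.data$mean),
                               y = 100 * .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * pmax(.data$mean - .data$sd, 0),
                   ymax = 100 * (.data$mean + .data$sd)), width = 0.3) +
    ggplot2::labs(x = NULL, y = "% of total prey mass") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
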