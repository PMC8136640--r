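# ggplot2 views of ranges and chorotypes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

poly_fortify <- function(geom, id) {
  polys <- poly_assemble(geom)
  purrr::imap_dfr(polys, function(rings, pi) {
    purrr::imap_dfr(rings, function(r, ri) {
      tibble::tibble(species_id = id,
                     piece = paste(id, pi, ri, sep = "."),
                     x = r$x, y = r$y)
    })
  })
}

#' Plot species ranges
#'
#' Draws every range polygon, coloured by species.  With many species,
#' suppress the legend.
#'
#' @param object A `species_ranges` tibble.
#' @param alpha Fill transparency.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_ranges <- function(object, alpha = 0.3, ...) {
  df <- purrr::map2_dfr(object$geometry, object$species_id, poly_fortify)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   group = .data$piece,
                                   fill = .data$species_id)) +
    ggplot2::geom_polygon(alpha = alpha, colour = "grey30",
                          linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "species") +
    ggplot2::theme_minimal()
}

#' Congruence diagram of a chorotype
#'
#' Depicts every partial chorotype of one reference species in the
#' congruence-threshold (y) versus closure-depth (x) plane: a segment
#' spans the threshold interval over which the composition is stable,
#' labelled with its species richness.
#'
#' @param object A `chorotype`.
#' @param ... Unused.
#' @return A ggplot object, or `NULL` (with a warning) for a
#'   non-informative chorotype.
#' @export
autoplot.chorotype <- function(object, ...) {
  if (!object$informative) {
    warning("chorotype of ", object$reference,
            " is non-informative; nothing to plot")
    return(invisible(NULL))
  }
  df <- dplyr::select(object$partials, "partial", "richness", "depth",
                      "ct_max", "ct_min")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$ct_min,
                                         ymax = .data$ct_max,
                                         colour = factor(.data$partial)),
                            linewidth = 2, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(y = (.data$ct_max + .data$ct_min) / 2,
                                    label = .data$richness),
                       nudge_x = 0.15, size = 3) +
    ggplot2::scale_x_continuous(breaks = function(l) {
      seq(floor(l[1]), ceiling(l[2]))
    }) +
    ggplot2::labs(title = paste("Chorotype of", object$reference),
                  x = "closure depth",
                  y = "congruence threshold") +
    ggplot2::theme_minimal()
}

#' Plot the threshold profile of a scan
#'
#' Richness of the closed group per visited threshold for each
#' reference; failed rounds are omitted.
#'
#' @param result A `scan_result`.
#' @return A ggplot object.
#' @export
plot_scan_profile <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  df <- purrr::map_dfr(result$chorotypes, function(ch) {
    dplyr::mutate(dplyr::filter(ch$log, .data$closed),
                  reference = ch$reference)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$ct, .data$n_members,
                                   colour = .data$reference)) +
    ggplot2::geom_step(show.legend = length(result$references) <= 12) +
    ggplot2::labs(x = "congruence threshold", y = "closed group size",
                  colour = "reference") +
    ggplot2::theme_minimal()
}
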