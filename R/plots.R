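# ggplot2 displays for the main result types.

#' Plot a barrel similarity network
#'
#' Fruchterman-Reingold layout (seeded, deterministic), nodes coloured by
#' strand number.
#'
#' @param object A `barrel_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barrel_network <- function(object, seed = 1L, ...) {
  g <- object$graph
  xy <- with_local_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  ed <- tidy(object)
  ed$x <- nodes$x[match(ed$from, nodes$protein_id)]
  ed$y <- nodes$y[match(ed$from, nodes$protein_id)]
  ed$xend <- nodes$x[match(ed$to, nodes$protein_id)]
  ed$yend <- nodes$y[match(ed$to, nodes$protein_id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   colour = factor(.data$n_strands)),
      size = 2
    ) +
    ggplot2::labs(colour = "strands",
                  title = sprintf("Barrel network, E ≤ %g",
                                  object$threshold)) +
    ggplot2::theme_void()
}

#' Plot strand-position conservation profiles
#'
#' One panel per barrel size; bar height is the number of alignments in
#' which that strand position takes part.
#'
#' @param profile Tibble from [conservation_profile()].
#' @return A ggplot object.
#' @export
plot_conservation_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~n_strands, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "strand position (N to C)",
                  y = "alignments containing the strand") +
    ggplot2::theme_minimal()
}

#' Plot an idealized barrel
#'
#' Side view of the CA trace (azimuthal unrolling), coloured by strand and
#' loop regions.
#'
#' @param object A `synthetic_barrel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthetic_barrel <- function(object, ...) {
  res <- object$residues
  dat <- tibble(
    theta = atan2(res$ca_y, res$ca_x),
    z = res$ca_z,
    region = ifelse(grepl("^strand", res$region), "strand", "loop"),
    strand = res$region
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$theta, y = .data$z,
                                    colour = .data$region)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "azimuth (rad)", y = "z along barrel axis (Å)") +
    ggplot2::theme_minimal()
}
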