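# ggplot2 displays for the main result types.

#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = log10(.data$degree), y = log10(.data$frequency))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "log10 degree", y = "log10 frequency",
      title = sprintf("Degree distribution (slope %.2f, R² = %.2f)",
                      object$slope, object$r_squared)
    )
}

#' @export
autoplot.apl_null <- function(object, ...) {
  ggplot2::ggplot(tibble(apl = object$apl_random), ggplot2::aes(x = .data$apl)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = object$apl_real, colour = "red") +
    ggplot2::labs(
      x = "average path length (rewired replicates)", y = "count",
      title = sprintf("APL null: observed %.3f, empirical p = %.3g",
                      object$apl_real, object$empirical_p)
    )
}

#' @export
autoplot.stratified_cohort <- function(object, ...) {
  ggplot2::ggplot(object$km,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability", colour = "risk group",
      title = sprintf("Kaplan–Meier by risk group (log-rank p = %.3g)",
                      object$logrank$p)
    )
}

#' Plot a ceRNA network
#'
#' Simple force-directed layout; node colour encodes kind, edge linetype
#' encodes edge type.
#'
#' @param net A [cerna_network()].
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(net, seed = 1L) {
  stopifnot(inherits(net, "cerna_network"))
  g <- as_igraph(net)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  lay <- tibble(id = igraph::V(g)$name, kind = igraph::V(g)$kind,
                x = xy[, 1], y = xy[, 2])
  ed <- net$edges |>
    left_join(select(lay, "id", xf = "x", yf = "y"), by = c(from = "id")) |>
    left_join(select(lay, "id", xt = "x", yt = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$xf, y = .data$yf,
                                       xend = .data$xt, yend = .data$yt,
                                       linetype = .data$type),
                          colour = "grey60") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$kind), size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "node kind", linetype = "edge type")
}
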