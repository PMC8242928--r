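# ggplot2 views of the package's result objects.

.tern_xy <- function(f1, f2, f3) {
  # barycentric -> 2D: vertex 1 at origin, vertex 2 at (1,0), vertex 3 on top
  list(x = f2 + 0.5 * f3, y = sqrt(3) / 2 * f3)
}

#' Plot a prior-simplex region map
#'
#' Ternary scatter of the barycentric grid, coloured by the best-looking
#' response at each prior; located region boundaries are overlaid in black.
#'
#' @param object a [simplex_region()] object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.simplex_region <- function(object, ...) {
  g <- object$grid
  xy <- .tern_xy(g$f1, g$f2, g$f3)
  g$x <- xy$x; g$y <- xy$y
  g$winner_lab <- factor(paste0("d", g$winner))
  labs <- paste0("d", object$support,
                 ifelse(is.na(strategy_name(object$support)), "",
                        paste0(" (", strategy_name(object$support), ")")))
  corners <- data.frame(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2), lab = labs)
  p <- ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$winner_lab), size = 1.2) +
    ggplot2::geom_text(data = corners,
                       ggplot2::aes(label = .data$lab),
                       vjust = c(1.6, 1.6, -0.8), size = 3.2) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::labs(colour = "best-looking\nresponse",
                  title = paste0("Observer's choice by prior, c = ", object$cost)) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.margin = ggplot2::margin(16, 16, 16, 16))
  if (nrow(object$boundary) > 0) {
    b <- object$boundary
    bxy <- .tern_xy(b$f1, b$f2, b$f3)
    p <- p + ggplot2::geom_point(data = data.frame(x = bxy$x, y = bxy$y),
                                 size = 0.4, colour = "black")
  }
  p
}

#' Plot the best-response graph
#'
#' Nodes are the sixteen strategies on a circle; arrows point from each
#' resident to its best response. Self-loops (symmetric Nash equilibria) are
#' highlighted.
#'
#' @param edges an edge tibble from [response_graph()].
#' @return A ggplot.
#' @export
plot_response_graph <- function(edges) {
  th <- (0:15) / 16 * 2 * pi
  nodes <- data.frame(index = 0:15, x = cos(th), y = sin(th),
                      lab = ifelse(is.na(strategy_name(0:15)), paste0("d", 0:15),
                                   paste0("d", 0:15, "\n", strategy_name(0:15))),
                      self = 0:15 %in% edges$from[edges$self_loop])
  e <- edges[!edges$self_loop, ]
  seg <- data.frame(x = nodes$x[e$from + 1L], y = nodes$y[e$from + 1L],
                    xend = nodes$x[e$to + 1L], yend = nodes$y[e$to + 1L])
  shrink <- 0.12
  dx <- seg$xend - seg$x; dy <- seg$yend - seg$y
  len <- sqrt(dx^2 + dy^2)
  seg$x <- seg$x + shrink * dx / len; seg$y <- seg$y + shrink * dy / len
  seg$xend <- seg$xend - shrink * dx / len; seg$yend <- seg$yend - shrink * dy / len
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          arrow = ggplot2::arrow(length = ggplot2::unit(5, "pt")),
                          colour = "grey40") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$self),
                        size = 9) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$lab),
                       size = 2.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey85", `TRUE` = "lightblue"),
                                 guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Best-response relations (self-loops = symmetric NE)")
}

#' Plot a posterior-concentration sweep
#'
#' @param sweep a tibble from [regime_sweep()].
#' @param epsilon optionally mark `M = 1/epsilon`, the crossover scale.
#' @return A ggplot of the mean posterior weight on the resident against `M`.
#' @export
plot_regime_sweep <- function(sweep, epsilon = NULL) {
  agg <- dplyr::summarise(dplyr::group_by(sweep, .data$M),
                          mean_weight = mean(.data$weight_on_resident),
                          .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$M, y = .data$mean_weight)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "observed pairs M",
                  y = "mean posterior weight on resident",
                  title = "Identification crossover with observation budget") +
    ggplot2::theme_minimal()
  if (!is.null(epsilon)) {
    p <- p + ggplot2::geom_vline(xintercept = 1 / epsilon, linetype = 2)
  }
  p
}

#' Tidy a simplex region map
#' @param x a `simplex_region` object.
#' @param ... unused.
#' @return The grid tibble with a `winner_name` column.
#' @export
tidy.simplex_region <- function(x, ...) {
  dplyr::mutate(x$grid, winner_name = strategy_name(.data$winner))
}

#' @rdname tidy.simplex_region
#' @return For `glance()`: a one-row tibble with the support, cost, step and
#'   each support member's share of the simplex won by WSLS and by the modal
#'   winner.
#' @export
glance.simplex_region <- function(x, ...) {
  w <- x$grid$winner
  tibble::tibble(
    support = paste0("d", x$support, collapse = ","),
    cost = x$cost, step = x$step, n_grid = length(w),
    wsls_share = mean(w == 9L),
    modal_winner = as.integer(names(which.max(table(w)))),
    n_regions = length(unique(w))
  )
}

#' Tidy an equilibrium report
#' @param x an `equilibrium_report` from [classify_equilibrium()].
#' @param ... unused.
#' @return A one-row tibble of the classification flags.
#' @export
tidy.equilibrium_report <- function(x, ...) {
  tibble::tibble(
    strategy = x$strategy, name = strategy_name(x$strategy),
    regime = x$regime, category = x$category,
    candidates = paste0("d", x$candidates, collapse = ","),
    best_looking = paste0("d", x$best_looking, collapse = ","),
    NE = x$NE, SCE = x$SCE, SCENE = x$SCENE
  )
}
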