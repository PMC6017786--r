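#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a topology ranking
#'
#' One row per ranked assignment: the `path` list column is unnested so
#' every (segment, stick, direction) triple is a row, keeping rank and
#' total score.
#'
#' @param x a `topology_ranking`
#' @param ... unused
#' @return a tibble with columns `rank`, `total_score`, `i`, `j`, `t`
#' @export
tidy.topology_ranking <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(rank = integer(), total_score = double(),
                  i = integer(), j = integer(), t = integer()))
  }
  tibble(rank = x$rank, total_score = x$total_score, path = x$path) |>
    tidyr::unnest("path")
}

#' One-row summary of a topology ranking
#'
#' @param x a `topology_ranking`
#' @param ... unused
#' @return a tibble: `n_topologies`, `best_score`, `worst_score`,
#'   `n_assignments`, `scheme`
#' @export
glance.topology_ranking <- function(x, ...) {
  tibble(
    n_topologies = nrow(x),
    best_score = if (nrow(x)) min(x$total_score) else NA_real_,
    worst_score = if (nrow(x)) max(x$total_score) else NA_real_,
    n_assignments = attr(x, "N") %||% NA_integer_,
    scheme = attr(x, "scheme") %||% NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a topology ranking
#'
#' Rank against total score; the true topology, when supplied, is
#' highlighted.
#'
#' @param object a `topology_ranking`
#' @param truth optional truth tibble (`i`, `j`, `t`)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.topology_ranking <- function(object, truth = NULL, ...) {
  df <- tibble(rank = object$rank, total_score = object$total_score,
               is_truth = FALSE)
  if (!is.null(truth)) {
    r <- rank_of_truth(object, truth, cap = max(object$rank, 1L))
    if (!is.na(r)) df$is_truth[df$rank == r] <- TRUE
  }
  ggplot2::ggplot(df, ggplot2::aes(x = rank, y = total_score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_truth), show.legend = any(df$is_truth)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                                 name = "true topology") +
    ggplot2::labs(x = "rank", y = "total score",
                  title = paste0("ranked topologies (scheme ",
                                 attr(object, "scheme"), ")")) +
    ggplot2::theme_minimal()
}

#' Contour plot of the packing-geometry score
#'
#' The scaled bivariate-normal score over the (phi, eta) plane, optionally
#' overlaid with angle samples.
#'
#' @param params a [geometry_params()]
#' @param samples optional tibble with `phi`, `eta`
#' @param n grid resolution per axis
#' @return a ggplot
#' @export
plot_geometry_score <- function(params = geometry_params(), samples = NULL,
                                n = 101) {
  grid <- tidyr::expand_grid(
    phi = seq(-180, 180, length.out = n),
    eta = seq(0, 360, length.out = n))
  grid$f <- geometry_score(grid$phi, grid$eta, params)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$eta)) +
    ggplot2::geom_contour_filled(ggplot2::aes(z = .data$f)) +
    ggplot2::labs(x = "dihedral phi (deg)", y = "packing-angle sum eta (deg)",
                  fill = "f(phi, eta)") +
    ggplot2::theme_minimal()
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_point(data = as_tibble(samples), alpha = 0.2,
                                 size = 0.4, colour = "white")
  }
  p
}

#' Bar chart of scheme summary fractions
#'
#' @param table a rank table such as [benchmark_ranks()]
#' @param top_k one or more rank thresholds
#' @return a ggplot
#' @export
plot_rank_summary <- function(table, top_k = c(15, 35, 100)) {
  df <- summarize_schemes(table, top_k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$fraction,
                                   fill = factor(.data$top_k))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "scoring scheme", y = "fraction of proteins",
                  fill = "top-k") +
    ggplot2::theme_minimal()
}
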