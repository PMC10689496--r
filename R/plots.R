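#' Trace plot of a posterior sample
#'
#' @param object a [run_mcmc()] result
#' @param parameters trace columns to show
#' @param ... unused
#' @return a ggplot of parameter traces over MCMC generations.
#' @export
autoplot.posterior_sample <- function(object,
                                      parameters = c("posterior",
                                                     "tree_height",
                                                     "clock_rate"), ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$trace, "state", dplyr::all_of(parameters)),
    -"state", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$state, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "generation", y = NULL) +
    ggplot2::theme_minimal()
}

#' Likelihood ladder of a nested-sampling run
#'
#' @param object a [nested_sampling()] result
#' @param ... unused
#' @return a ggplot of the log-likelihood floor per iteration.
#' @export
autoplot.nested_sampling_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$ladder),
                       log_likelihood = object$ladder)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_likelihood)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "log-likelihood floor") +
    ggplot2::theme_minimal()
}

#' Plot a raster layer (suitability, binary or biome map)
#'
#' @param m numeric or integer matrix (optionally with a `classes`
#'   attribute, as returned by [project_biome_map()])
#' @param title plot title
#' @return a ggplot tile map.
#' @export
plot_raster <- function(m, title = NULL) {
  classes <- attr(m, "classes")
  df <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    value = as.vector(m)
  )
  df <- df[!is.na(df$value), ]
  if (!is.null(classes)) df$value <- factor(classes[df$value], classes)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL, title = title) +
    ggplot2::theme_void()
  if (is.null(classes)) {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Dated tree with node ages
#'
#' @param x an `mcc_summary` from [mcc_tree()]
#' @param ... passed to [ape::plot.phylo()]
#' @return invisibly, the plotted tree.
#' @export
plot.mcc_summary <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  ape::axisPhylo()
  invisible(x$tree)
}
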