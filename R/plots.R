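#' Structure-style stacked ancestry bars
#'
#' @param object An `admixture_run` (or a consensus Q matrix with a roster
#'   via [plot_structure()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.admixture_run <- function(object, ...) {
  plot_structure(object$Q, object$roster)
}

#' @rdname autoplot.admixture_run
#' @param Q Individuals x K ancestry matrix.
#' @param roster Tibble with `id`, `pop` matching the rows of `Q`.
#' @export
plot_structure <- function(Q, roster) {
  df <- dplyr::bind_cols(
    roster,
    tibble::as_tibble(Q, .name_repair = ~ paste0("cluster", seq_along(.x)))) |>
    dplyr::arrange(.data$pop) |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    tidyr::pivot_longer(dplyr::starts_with("cluster"),
                        names_to = "cluster", values_to = "q")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$q,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~pop, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "ancestry proportion", fill = NULL) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.05, "lines"))
}

#' Delta-K chart
#'
#' @param object A `delta_k_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_k_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$delta_k), ],
                  ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "K", y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' DAPC scatter plot
#'
#' First two discriminant functions (or a one-dimensional density when a
#' single function is retained), coloured by group.
#'
#' @param object A `dapc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dapc_fit <- function(object, ...) {
  df <- tibble::as_tibble(object$ind_coord)
  if (object$n_da >= 2) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                     colour = .data$group)) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::stat_ellipse(level = 0.67, linewidth = 0.3) +
      ggplot2::labs(colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$LD1, fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::labs(fill = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Pairwise-Fst heatmap
#'
#' @param object A `pairwise_fst`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pairwise_fst <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$pop1, y = .data$pop2,
                               fill = .data$fst)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$fst)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fst") +
    ggplot2::theme_minimal()
}
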