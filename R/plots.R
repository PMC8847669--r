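## ggplot2 front-ends for the main result types.

#' Plot a simulated trajectory
#'
#' Faceted time courses; by default the four organ DC counts, the key
#' NF-kB-pathway species and the four T-cell pools.
#'
#' @param object A `dcvax_trajectory`.
#' @param variables Character vector of state/observable names to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcvax_trajectory <- function(object,
                                      variables = c("dc_count_blood",
                                                    "dc_count_lung",
                                                    "dc_count_liver",
                                                    "dc_count_spleen",
                                                    "ikkb", "nfkb",
                                                    "naive",
                                                    "early_effector",
                                                    "short_lived_effector",
                                                    "memory"),
                                      ...) {
  df <- tidy.dcvax_trajectory(object)
  df <- df[df$variable %in% variables, ]
  df$variable <- factor(df$variable, levels = variables)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = paste("scenario:", object$scenario$name)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic calibration dataset over the reference trajectory
#'
#' @param object A `dcvax_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcvax_dataset <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time, .data$value,
                               colour = .data$arm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$sd,
                                          ymax = .data$value + .data$sd),
                             size = 0.2) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL,
                  title = paste("synthetic dataset:",
                                attr(object, "kind"))) +
    ggplot2::theme_minimal()
}

#' Plot Sobol indices
#'
#' Bar chart of first- and total-order indices for one output (default: the
#' integral output), restricted to the `k` most influential parameters.
#'
#' @param object A `dcvax_sobol`.
#' @param output Output name (default last / integral).
#' @param k Number of parameters shown (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcvax_sobol <- function(object, output = NULL, k = 15, ...) {
  if (is.null(output)) output <- object$outputs[length(object$outputs)]
  rk <- rank_parameters(object, k = min(k, nrow(object$ST)))
  df <- tidy.dcvax_sobol(object)
  df <- df[df$output == output & df$parameter %in% rk$parameter, ]
  df <- tidyr::pivot_longer(df, c("S1", "ST"), names_to = "index",
                            values_to = "value")
  df$parameter <- factor(df$parameter, levels = rev(rk$parameter))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$value,
                                   fill = .data$index)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Sobol index", title = output) +
    ggplot2::theme_minimal()
}

#' Plot a single-parameter perturbation scan
#'
#' @param object A `dcvax_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcvax_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fold, .data$fold_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste("fold factor on", attr(object, "param")),
                  y = "steady-state memory fold-change") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise perturbation scan as a heat map
#'
#' @param object A `dcvax_scan2`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcvax_scan2 <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$fold1, .data$fold2,
                               fill = .data$fold_change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste("fold on", object$param1),
                  y = paste("fold on", object$param2),
                  fill = "M* fold") +
    ggplot2::theme_minimal()
}

#' Plot a correlation matrix of parameter estimates
#'
#' @param report A `dcvax_identifiability`.
#' @return A ggplot object.
#' @export
plot_estimate_correlations <- function(report) {
  stopifnot(inherits(report, "dcvax_identifiability"))
  df <- tibble::as_tibble(report$correlations, rownames = "p1")
  df <- tidyr::pivot_longer(df, -"p1", names_to = "p2", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$p1, .data$p2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
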