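#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_line
#'   geom_ribbon facet_wrap labs scale_color_viridis_c theme_minimal
NULL

#' Plot a per-landmark scalar field on the template
#'
#' Frontal (x, y) projection of the template landmarks colored by the
#' field value — the plotting analog of a facial heritability map.
#'
#' @param object a [scalar_field()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot scalar_field
#' @export
autoplot.scalar_field <- function(object, ...) {
  df <- tibble::tibble(x = object$template$vertices[, 1L],
                       y = object$template$vertices[, 2L],
                       value = object$values)
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$value)) +
    geom_point(size = 2) +
    scale_color_viridis_c(name = object$name) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot one level of a segmentation hierarchy on the template
#'
#' @param object a `segmentation_hierarchy`.
#' @param template the matching [template_mesh()].
#' @param level hierarchy level to display (default: deepest).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot segmentation_hierarchy
#' @export
autoplot.segmentation_hierarchy <- function(object, template,
                                            level = object$levels, ...) {
  df <- tibble::tibble(x = template$vertices[, 1L],
                       y = template$vertices[, 2L],
                       segment = factor(level_labels(object, level)))
  ggplot(df, aes(x = .data$x, y = .data$y, color = .data$segment)) +
    geom_point(size = 2) +
    labs(x = NULL, y = NULL,
         title = paste0("Segmentation, level ", level)) +
    theme_minimal()
}

#' Heatmap of a co-heritability matrix
#'
#' @param object a `coherit_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coherit_matrix
#' @export
autoplot.coherit_matrix <- function(object, ...) {
  V <- object$values
  df <- tibble::tibble(i = rep(seq_len(nrow(V)), times = ncol(V)),
                       j = rep(seq_len(ncol(V)), each = nrow(V)),
                       h2 = as.vector(V))
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$h2)) +
    geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "co-h2") +
    ggplot2::scale_y_reverse() +
    labs(x = "offspring landmark", y = "father landmark") +
    theme_minimal()
}

#' Modular heritability estimates by level and cohort
#'
#' Dot plot of per-module `h2` faceted by hierarchy level, with filled
#' points marking modules that pass the supplied significance threshold.
#'
#' @param modular tibble from [modular_heritability()].
#' @param alpha significance threshold (e.g. `multiple_testing$alpha_adj`).
#' @return a ggplot.
#' @export
plot_modular_h2 <- function(modular, alpha = 0.05) {
  modular$significant <- modular$p_value <= alpha
  ggplot(modular, aes(x = factor(.data$module_id), y = .data$h2,
                      color = .data$cohort, shape = .data$significant)) +
    geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    facet_wrap(~level, scales = "free_x") +
    labs(x = "module", y = expression(h^2)) +
    theme_minimal()
}

#' Subsample stability curve
#'
#' Mean and +/- 1 SD band of the heritability estimate as a function of
#' subsample size; convergence of the band shows the sample size at
#' which the estimate stabilizes.
#'
#' @param curve tibble from [subsample_stability()].
#' @return a ggplot.
#' @export
plot_stability <- function(curve) {
  s <- summarize_stability(curve)
  s$sd_h2[is.na(s$sd_h2)] <- 0
  ggplot(s, aes(x = .data$size, y = .data$mean_h2)) +
    geom_ribbon(aes(ymin = .data$mean_h2 - .data$sd_h2,
                    ymax = .data$mean_h2 + .data$sd_h2), alpha = 0.25) +
    geom_line() +
    labs(x = "pairs", y = expression(h^2)) +
    theme_minimal()
}
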