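matrix_to_long <- function(m, value_name) {
  tibble(row = rep(seq_len(nrow(m)), ncol(m)),
         col = rep(seq_len(ncol(m)), each = nrow(m)),
         "{value_name}" := as.vector(m))
}

#' @importFrom rlang :=
NULL

#' Plot a T2 map
#'
#' Raster of the accepted T2 values (rejected/outside voxels blank).
#'
#' @param object A `"t2_map"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2_map
#' @export
autoplot.t2_map <- function(object, ...) {
  df <- matrix_to_long(object$t2_ms, "t2_ms") |> tidyr::drop_na()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$t2_ms)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "T2 (ms)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "Quantitative T2 map") +
    ggplot2::theme_minimal()
}

#' Plot a plaque segmentation
#'
#' Raster of the segmented tissue labels inside the wall.
#'
#' @param object A `"plaque_segmentation"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot plaque_segmentation
#' @export
autoplot.plaque_segmentation <- function(object, ...) {
  df <- matrix_to_long(object$label_map, "label") |>
    dplyr::filter(.data$label != "outside")
  levels <- c(object$model$classes, "calcification", "rejected")
  df$label <- factor(df$label, levels = levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "class",
                  title = "Plaque segmentation") +
    ggplot2::theme_minimal()
}

#' Plot a voxel decay fit
#'
#' Measured intensities over TE with the fitted mono-exponential curve and
#' its 95% confidence band (curve CI from the Gauss-Newton covariance by
#' the delta method). The discarded first echo, if present in the data, is
#' shown hollow.
#'
#' @param object A `"t2_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2_fit
#' @export
autoplot.t2_fit <- function(object, ...) {
  d <- object$data
  d$used <- seq_len(nrow(d)) > 1
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$te_ms, y = .data$si)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$used), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "TE (ms)", y = "SI",
                  title = "Mono-exponential T2 decay fit") +
    ggplot2::theme_minimal()
  if (is.finite(object$t2_ms)) {
    te <- seq(min(d$te_ms), max(d$te_ms), length.out = 120)
    e <- exp(-te / object$t2_ms)
    fitcurve <- object$beta * e
    # delta-method SE of the curve from the parameter covariance
    g_beta <- e
    g_t2 <- object$beta * te * e / object$t2_ms^2
    var_c <- g_beta^2 * object$se_beta^2 + g_t2^2 * object$se_t2^2
    tq <- qt(0.975, max(1, object$n_points_used - 2))
    band <- tibble(te_ms = te, fit = fitcurve,
                   lo = fitcurve - tq * sqrt(var_c),
                   hi = fitcurve + tq * sqrt(var_c))
    p <- p +
      ggplot2::geom_ribbon(data = band,
                           ggplot2::aes(x = .data$te_ms, ymin = .data$lo,
                                        ymax = .data$hi),
                           inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(data = band,
                         ggplot2::aes(x = .data$te_ms, y = .data$fit),
                         inherit.aes = FALSE, colour = "red")
  }
  p
}

#' Plot the class likelihoods of a model
#'
#' Prior-weighted Gaussian class densities over T2, with the MAP decision
#' boundaries as vertical lines.
#'
#' @param object A `"class_model"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot class_model
#' @export
autoplot.class_model <- function(object, ...) {
  p <- object$params
  lo <- max(0.5, min(p$mu_ms - 4 * p$sd_ms))
  hi <- max(p$mu_ms + 4 * p$sd_ms)
  grid <- seq(lo, hi, length.out = 500)
  df <- purrr::map_dfr(seq_len(nrow(p)), function(i) {
    tibble(t2_ms = grid, class = p$class[i],
           density = p$prior[i] * dnorm(grid, p$mu_ms[i], p$sd_ms[i]))
  })
  df$class <- factor(df$class, levels = object$classes)
  b <- decision_boundaries(object, c(lo, hi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t2_ms, y = .data$density,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = b$t2_ms, linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = "T2 (ms)", y = "prior-weighted density",
                  title = "Bayes class model and MAP boundaries") +
    ggplot2::theme_minimal()
}
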