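# ggplot2 views of the core result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_abline geom_hline scale_fill_viridis_c scale_y_reverse labs
#'   theme_minimal geom_step facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot an elastogram
#'
#' Depth x slow-time axial-velocity map; the shear wavefront appears as a
#' tilted ridge whose slope (mm/ms) is the shear-wave speed.
#'
#' @param object a [track_displacement()] elastogram.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pocte_elastogram
#' @export
autoplot.pocte_elastogram <- function(object, ...) {
  df <- tidyr::expand_grid(depth_mm = object$depth_axis_mm,
                           time_ms = object$time_axis_ms)
  df$velocity <- as.vector(t(object$m))
  ggplot(df, aes(x = .data$time_ms, y = .data$depth_mm,
                 fill = .data$velocity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "v (um/ms)") +
    scale_y_reverse() +
    labs(x = "slow time (ms)", y = "depth (mm)",
         title = "Elastogram (axial velocity)") +
    theme_minimal()
}

#' Plot a B-mode image
#'
#' @param object a [form_bmode()] image.
#' @param dynamic_range_db displayed dynamic range below the maximum.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pocte_bmode
#' @export
autoplot.pocte_bmode <- function(object, dynamic_range_db = 50, ...) {
  img <- object$image_db
  top <- max(img)
  df <- tidyr::expand_grid(depth_mm = object$depth_axis_mm,
                           lateral_mm = object$lateral_axis_mm)
  df$db <- pmax(as.vector(img), top - dynamic_range_db)
  ggplot(df, aes(x = .data$lateral_mm, y = .data$depth_mm, fill = .data$db)) +
    geom_raster() +
    scale_fill_viridis_c(option = "magma", name = "dB") +
    scale_y_reverse() +
    labs(x = "lateral (mm)", y = "depth (mm)", title = "B-mode") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object a [roc_auc()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pocte_roc
#' @export
autoplot.pocte_roc <- function(object, ...) {
  cv <- object$curve
  df <- tibble::tibble(fpr = c(1, rev(1 - cv$spec), 0),
                       tpr = c(1, rev(cv$sens), 0))
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUROC %.3f, 95%% CI %.2f-%.2f)",
                         object$auroc, object$ci95[1], object$ci95[2])) +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Scatter of differences (`y - x`) against pair means with the bias and
#' 95% limits of agreement.
#'
#' @param x benchmark measurements.
#' @param y comparison measurements.
#' @param xlab,ylab axis labels.
#' @return A ggplot.
#' @export
plot_bland_altman <- function(x, y, xlab = "mean of methods",
                              ylab = "difference (y - x)") {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(avg = (x + y) / 2, diff = y - x)
  ggplot(df, aes(x = .data$avg, y = .data$diff)) +
    geom_point(alpha = 0.4) +
    geom_hline(yintercept = ba$bias, colour = "steelblue") +
    geom_hline(yintercept = c(ba$loa_lo, ba$loa_hi), linetype = "dashed",
               colour = "steelblue") +
    labs(x = xlab, y = ylab,
         title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                         ba$bias, ba$loa_lo, ba$loa_hi)) +
    theme_minimal()
}

#' Plot a measurement-count sufficiency table
#'
#' AUROC against subset size per endpoint and method, mirroring the layout
#' of repeated-measurement sufficiency reporting.
#'
#' @param object a [sufficiency_table()] tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pocte_sufficiency
#' @export
autoplot.pocte_sufficiency <- function(object, ...) {
  ggplot(object, aes(x = .data$k, y = .data$auroc,
                     colour = .data$method)) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$endpoint) +
    labs(x = "number of repetitions in median", y = "AUROC",
         title = "Diagnostic accuracy vs number of measurements") +
    theme_minimal()
}
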