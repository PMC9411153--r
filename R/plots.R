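#' Plot Kaplan-Meier curves
#'
#' @param object A `milsurv_km` tibble from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot object (step curves per group, with censoring
#'   implicit in the flat segments).
#' @method autoplot milsurv_km
#' @export
autoplot.milsurv_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the training log of a MIL fit
#'
#' @param object A `mil_fit` from [mil_train()].
#' @param ... Unused.
#' @return A ggplot object with the training loss and validation
#'   c-index per epoch (free y scales).
#' @method autoplot mil_fit
#' @export
autoplot.mil_fit <- function(object, ...) {
  long <- object$log |>
    tidyr::pivot_longer(c("train_npll", "val_cindex"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attention map as a patch-grid heat tile
#'
#' @param object An [attention_map()].
#' @param ... Unused.
#' @return A ggplot object (one tile per patch, filled by the scaled
#'   attention weight; y is flipped to image orientation).
#' @method autoplot attention_map
#' @export
autoplot.attention_map <- function(object, ...) {
  size <- object$patch_size_px[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$col + size / 2,
                               y = .data$row + size / 2,
                               fill = .data$scaled_weight)) +
    ggplot2::geom_tile(width = size, height = size) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "navy", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "Attention") +
    ggplot2::theme_minimal()
}

#' Bar summary of per-phenotype attention (clustered variant)
#'
#' The clustered model attends over phenotypes rather than image
#' positions, so its interpretability view is a per-phenotype bar chart
#' instead of a spatial heatmap.
#'
#' @param prediction A `risk_prediction` from [forward_risk()] on the
#'   clustered path.
#' @return A ggplot object.
#' @export
plot_phenotype_attention <- function(prediction) {
  df <- tibble::tibble(phenotype = factor(seq_along(prediction$attention)),
                       attention = prediction$attention)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype,
                                   y = .data$attention)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Phenotype cluster", y = "Attention weight",
                  title = prediction$patient_id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
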