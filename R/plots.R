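#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a delta-AFD curve
#'
#' Mean control-minus-mTBI AFD difference per strain bin, with its
#' confidence interval; a flat curve near zero means no strain-dependent
#' group difference, a rising curve means greater AFD loss where normative
#' strain is higher.
#'
#' @param object A [delta_afd_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_afd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center,
                                       y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.08, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normative OSS (z-score bin center)",
                  y = expression(Delta * "AFD (control - mTBI)")) +
    ggplot2::theme_minimal()
}

#' Strip plot of high/low-strain AFD ratios by group
#'
#' @param object A [roi_afd_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roi_summary <- function(object, ...) {
  d <- object[!is.na(object$ratio), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$ratio,
                                  colour = .data$sex)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 2, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = expression(AFD[HS] / AFD[LS])) +
    ggplot2::theme_minimal()
}

#' Paired fold plot for leave-one-out cross-validation
#'
#' One line per held-out subject connecting its mean OSS z in the fold's
#' low-strain and high-strain regions.
#'
#' @param object A [loo_cross_validation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.loo_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$folds, c("ls_mean", "hs_mean"),
                           names_to = "region", values_to = "oss_z")
  d$region <- factor(d$region, levels = c("ls_mean", "hs_mean"),
                     labels = c("low strain", "high strain"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$oss_z,
                                  group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.5, colour = "grey40") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = NULL, y = "held-out subject mean OSS (z)") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a scalar map or ROI mask
#'
#' @param x A [scalar_map()] or [strain_roi_mask()].
#' @param slice Axial (third-axis) slice index; defaults to the middle.
#' @return A ggplot raster of the slice (masked voxels only).
#' @export
plot_slice <- function(x, slice = NULL) {
  if (inherits(x, "strain_roi_mask")) {
    vals <- array(0, dim = dim(x$brain_mask))
    vals[x$ls] <- 1
    vals[x$hs] <- 2
    mask <- x$brain_mask
    lab <- "region (0 out, 1 LS, 2 HS)"
  } else {
    stopifnot(inherits(x, "scalar_map"))
    vals <- x$values
    mask <- x$mask
    lab <- x$kind
  }
  if (is.null(slice)) slice <- ceiling(dim(vals)[3] / 2)
  d <- expand.grid(i = seq_len(dim(vals)[1]), j = seq_len(dim(vals)[2]))
  d$value <- as.vector(vals[, , slice])
  d <- d[as.vector(mask[, , slice]), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$i, y = .data$j,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::theme_void()
}
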