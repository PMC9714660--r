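#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the coefficients of a fitted classifier
#'
#' @param x An `rja_logit` fit.
#' @param exponentiate Return odds ratios instead of log-odds
#'   coefficients.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.rja_logit <- function(x, exponentiate = FALSE, ...) {
  est <- x$coefficients
  z <- est / x$se
  out <- tibble::tibble(
    term = names(est),
    estimate = if (exponentiate) exp(unname(est)) else unname(est),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(unname(z)))
  )
  out
}

#' One-row summary of a fitted classifier
#' @param x An `rja_logit` fit.
#' @param ... Unused.
#' @return A tibble with `n`, `deviance`, `n_iterations`, `status`,
#'   `converged`.
#' @export
glance.rja_logit <- function(x, ...) {
  tibble::tibble(n = x$n, deviance = x$deviance,
                 n_iterations = x$n_iterations, status = x$status,
                 converged = x$converged)
}

#' Tidy a classifier evaluation
#' @param x An `rja_eval` object.
#' @param ... Unused.
#' @return The per-fold cross-validation accuracies.
#' @export
tidy.rja_eval <- function(x, ...) x$cv_per_fold

#' One-row summary of a classifier evaluation
#' @param x An `rja_eval` object.
#' @param ... Unused.
#' @export
glance.rja_eval <- function(x, ...) {
  tibble::tibble(
    train_accuracy = x$train_accuracy, test_accuracy = x$test_accuracy,
    cv_mean = x$cv_mean, cv_sd = x$cv_sd, auc = x$auc,
    max_cooks = x$diagnostics$max_cooks,
    max_abs_std_residual = x$diagnostics$max_abs_std_residual,
    vif_rate = x$diagnostics$vif[["rate"]],
    vif_events = x$diagnostics$vif[["events"]],
    n_train = x$n_train, n_test = x$n_test, seed = x$seed
  )
}

#' Plot a ROC curve
#' @param object An `rja_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rja_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a clip's scanpath over its AOI layout
#'
#' Fixations as points sized by duration and joined in order; the AOI
#' polygons and their detection circles (1.2 x radius around the face
#' and target centres) drawn underneath.
#'
#' @param fixations Fixation tibble for one clip.
#' @param aoi_set The clip's AOI set.
#' @param config A [detector_config()] (for the circle multiplier).
#' @return A ggplot in screen coordinates (y flipped, origin top-left).
#' @export
plot_scanpath <- function(fixations, aoi_set, config = detector_config()) {
  geom <- aoi_geometry(aoi_set)
  poly <- dplyr::bind_rows(lapply(c("face", "target", "nontarget"), function(r) {
    v <- aoi_set[[r]]
    tibble::tibble(region = r, x = v[, 1], y = v[, 2])
  }))
  circ <- dplyr::bind_rows(lapply(list(
    c(geom$F, config$radius_multiplier * geom$R_F),
    c(geom$T, config$radius_multiplier * geom$R_T)
  ), function(cc) {
    th <- seq(0, 2 * pi, length.out = 120)
    tibble::tibble(x = cc[1] + cc[3] * cos(th), y = cc[2] + cc[3] * sin(th),
                   id = paste(cc[1], cc[2]))
  }))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = poly,
                          ggplot2::aes(.data$x, .data$y, fill = .data$region),
                          alpha = 0.3) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(.data$x, .data$y, group = .data$id),
                       colour = "red", linetype = "dotted") +
    ggplot2::geom_path(data = fixations, ggplot2::aes(.data$x, .data$y),
                       colour = "blue") +
    ggplot2::geom_point(data = fixations,
                        ggplot2::aes(.data$x, .data$y,
                                     size = .data$duration_ms),
                        colour = "blue", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", size = "duration (ms)") +
    ggplot2::theme_minimal()
}

#' Plot calibration bins of a classifier evaluation
#' @param object An `rja_eval` object.
#' @param ... Unused.
#' @return A ggplot of observed ASD fraction against predicted
#'   probability decile.
#' @export
autoplot.rja_eval <- function(object, ...) {
  ggplot2::ggplot(object$calibration,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted P(ASD)", y = "Observed ASD fraction",
                  size = "n") +
    ggplot2::theme_minimal()
}
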