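#' Plot a psychometric or neurometric fit
#'
#' Observed per-slant proportions with the fitted cumulative Gaussian.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  d <- object$data
  d$prop <- d$k / d$n
  xs <- seq(min(d$slant_deg), max(d$slant_deg), length.out = 200)
  curve <- tibble::tibble(
    slant_deg = xs,
    prop = object$gamma + (1 - object$gamma - object$lambda) *
      pnorm((xs - object$pse_deg) / object$threshold_deg))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slant_deg, y = .data$prop)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "slant (deg)", y = "proportion top-far",
                  subtitle = sprintf("P.S.E. %.2f deg, threshold %.2f deg",
                                     object$pse_deg, object$threshold_deg)) +
    ggplot2::theme_minimal()
}

#' Plot a neurometric curve
#'
#' @param object A `neurometric_result`.
#' @param ... Unused.
#' @return A ggplot of oriented ROC values vs slant with the fitted curve.
#' @method autoplot neurometric_result
#' @export
autoplot.neurometric_result <- function(object, ...) {
  d <- object$per_slant
  fit <- object$fit
  xs <- seq(min(d$slant_deg), max(d$slant_deg), length.out = 200)
  curve <- tibble::tibble(
    slant_deg = xs,
    p = fit$gamma + (1 - fit$gamma - fit$lambda) *
      pnorm((xs - fit$pse_deg) / fit$threshold_deg))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slant_deg,
                                  y = .data$p_ideal_top_far)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(shape = 8) +
    ggplot2::labs(x = "slant (deg)", y = "ideal observer P(top-far)",
                  subtitle = sprintf("neuronal threshold %.2f deg (x2 = %.2f)",
                                     object$neuronal_threshold_deg,
                                     object$comparison_threshold_deg)) +
    ggplot2::theme_minimal()
}

#' Plot a population time course
#'
#' @param object A `timecourse_result`.
#' @param stim_offset_ms Vertical reference line (default 1000).
#' @param ... Unused.
#' @return A ggplot of the per-bin mean with SEM ribbon.
#' @method autoplot timecourse_result
#' @export
autoplot.timecourse_result <- function(object, stim_offset_ms = 1000, ...) {
  d <- object$per_bin
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$center_ms, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = stim_offset_ms, linetype = "dashed") +
    ggplot2::labs(x = "time from stimulus onset (ms)", y = object$metric) +
    ggplot2::theme_minimal()
  if (object$metric == "cp") {
    gg <- gg + ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted")
  }
  gg
}

#' Equal-area map of preferred directions
#'
#' Scatter of tuned neurons' preferred slant-tilt directions in the Lambert
#' equal-area projection, with slant rings at 20, 40, 60, and 90 degrees.
#'
#' @param prefs Data frame with `slant_deg`, `tilt_deg`, and optionally
#'   `area` for coloring.
#' @return A ggplot.
#' @export
plot_preference_map <- function(prefs) {
  prefs <- tibble::as_tibble(prefs)
  xy <- project_equal_area(prefs$slant_deg, prefs$tilt_deg)
  d <- dplyr::bind_cols(prefs, xy)
  rings <- dplyr::bind_rows(lapply(c(20, 40, 60, 90), function(s) {
    t <- seq(0, 360, length.out = 181)
    out <- project_equal_area(rep(s, length(t)), t)
    out$ring <- s
    out
  }))
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = rings,
                       ggplot2::aes(group = .data$ring), color = "grey70") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if ("area" %in% names(d)) {
    gg + ggplot2::geom_point(ggplot2::aes(color = .data$area), alpha = 0.8)
  } else {
    gg + ggplot2::geom_point(alpha = 0.8)
  }
}

#' Choice-conditioned slant tuning plot
#'
#' @param curves Output of [choice_conditioned_tuning()].
#' @return A ggplot with the overall and per-choice tuning curves.
#' @export
plot_choice_tuning <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$slant_deg,
                                       y = .data$mean_count,
                                       color = .data$curve)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_count - .data$sem,
                                        ymax = .data$mean_count + .data$sem),
                           width = 0.5) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(all = "black",
                                           top_far = "darkorange",
                                           top_near = "purple")) +
    ggplot2::labs(x = "slant (deg)", y = "mean spike count") +
    ggplot2::theme_minimal()
}

#' Partial-correlation quadrant scatter with confidence ellipses
#'
#' @param population Data frame with `r_FS_C`, `r_FC_S`, `grand_cp`.
#' @param ellipses Optional output of [fit_cp_ellipses()].
#' @return A ggplot of the choice vs slant partial-correlation plane.
#' @export
plot_cp_scatter <- function(population, ellipses = NULL) {
  pop <- tibble::as_tibble(population)
  gg <- ggplot2::ggplot(pop, ggplot2::aes(x = .data$r_FS_C, y = .data$r_FC_S,
                                          color = .data$grand_cp)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_color_gradient2(midpoint = 0.5, low = "blue",
                                   high = "darkgreen", mid = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "slant partial correlation",
                  y = "choice partial correlation", color = "grand CP") +
    ggplot2::theme_minimal()
  if (!is.null(ellipses)) {
    for (e in ellipses) {
      if (is.null(e)) next
      t <- seq(0, 2 * pi, length.out = 181)
      a <- e$angle_deg * pi / 180
      xy <- tibble::tibble(
        r_FS_C = e$center[1] + e$semi_major * cos(t) * cos(a) -
          e$semi_minor * sin(t) * sin(a),
        r_FC_S = e$center[2] + e$semi_major * cos(t) * sin(a) +
          e$semi_minor * sin(t) * cos(a))
      gg <- gg + ggplot2::geom_path(data = xy, color = "black",
                                    linetype = if (identical(e$group, "cp_above_half"))
                                      "dashed" else "solid")
    }
  }
  gg
}
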