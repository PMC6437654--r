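#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return One-row tibble of fitted parameters.
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(pse_deg = x$pse_deg, threshold_deg = x$threshold_deg,
                 gamma = x$gamma, lambda = x$lambda)
}

#' @rdname tidy.psychometric_fit
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(pse_deg = x$pse_deg, threshold_deg = x$threshold_deg,
                 logLik = x$loglik, n_trials = x$n_trials,
                 converged = x$converged)
}

#' Tidy a neurometric result
#'
#' @param x A `neurometric_result`.
#' @param ... Unused.
#' @return The per-slant tibble of oriented ROC values.
#' @method tidy neurometric_result
#' @export
tidy.neurometric_result <- function(x, ...) x$per_slant

#' @rdname tidy.neurometric_result
#' @method glance neurometric_result
#' @export
glance.neurometric_result <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, area = x$area,
                 neuronal_threshold_deg = x$neuronal_threshold_deg,
                 comparison_threshold_deg = x$comparison_threshold_deg,
                 converged = x$fit$converged)
}

#' Tidy a choice-probability result
#'
#' @param x A `cp_result`.
#' @param ... Unused.
#' @return The per-slant inclusion bookkeeping tibble.
#' @method tidy cp_result
#' @export
tidy.cp_result <- function(x, ...) x$included_slants

#' @rdname tidy.cp_result
#' @method glance cp_result
#' @export
glance.cp_result <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, area = x$area,
                 cp_zero = x$cp_zero, grand_cp = x$grand_cp,
                 p_perm = x$p_perm, n_permutations = x$n_permutations,
                 n_trials_used = x$n_trials_used)
}

#' Tidy a partial-correlation result
#'
#' @param x A `partialcorr_result`.
#' @param ... Unused.
#' @return One-row tibble with pairwise and partial correlations.
#' @method tidy partialcorr_result
#' @export
tidy.partialcorr_result <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, area = x$area,
                 r_FS = x$r_FS, r_FC = x$r_FC, r_SC = x$r_SC,
                 r_FS_C = x$r_FS_C, p_FS_C = x$p_FS_C,
                 r_FC_S = x$r_FC_S, p_FC_S = x$p_FC_S,
                 spc2 = x$spc2, cpc2 = x$cpc2, quadrant = x$quadrant)
}

#' Tidy a tuning result
#'
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @return One-row tibble of tuning statistics and classification.
#' @method tidy tuning_result
#' @export
tidy.tuning_result <- function(x, ...) {
  tibble::tibble(neuron_id = x$neuron_id, area = x$area, sodi = x$sodi,
                 anova_p = x$anova_p, bingham_r = x$bingham_r,
                 classification = x$classification,
                 preferred_slant_deg = x$preferred_slant_deg,
                 preferred_tilt_deg = x$preferred_tilt_deg,
                 slant_axis_anova_p = x$slant_axis_anova_p,
                 preferred_sign_axis = x$preferred_sign_axis)
}

#' Tidy a time-course result
#'
#' @param x A `timecourse_result`.
#' @param ... Unused.
#' @return The per-bin tibble (center, mean, SEM, n).
#' @method tidy timecourse_result
#' @export
tidy.timecourse_result <- function(x, ...) {
  out <- x$per_bin
  out$metric <- x$metric
  out
}

#' @rdname tidy.timecourse_result
#' @method glance timecourse_result
#' @export
glance.timecourse_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, n_bins = nrow(x$per_bin),
                 n_neurons = nrow(x$per_neuron), anova_p = x$anova_p,
                 first_significant_bin_ms = x$first_significant_bin_ms)
}

#' Tidy an ellipse fit
#'
#' @param x An `ellipse_fit`.
#' @param ... Unused.
#' @return One-row tibble with center, axes, and angle CI.
#' @method tidy ellipse_fit
#' @export
tidy.ellipse_fit <- function(x, ...) {
  tibble::tibble(group = x$group %||% NA_character_,
                 center_x = x$center[1], center_y = x$center[2],
                 semi_major = x$semi_major, semi_minor = x$semi_minor,
                 angle_deg = x$angle_deg,
                 angle_lo_deg = x$angle_ci_deg[1],
                 angle_hi_deg = x$angle_ci_deg[2],
                 n_points = x$n_points)
}
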