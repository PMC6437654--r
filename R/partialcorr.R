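#' Slant and choice partial correlations of a session
#'
#' Pearson correlations are computed among spike count `F`, signed slant
#' `S`, and choice `C` (top-near coded -1, top-far +1) over all
#' discrimination trials, and combined into the slant partial correlation
#' `r_FS.C = (r_FS - r_FC r_SC) / sqrt((1 - r_FC^2)(1 - r_SC^2))`
#' (count vs slant controlling for choice) and the choice partial
#' correlation
#' `r_FC.S = (r_FC - r_FS r_SC) / sqrt((1 - r_FS^2)(1 - r_SC^2))`
#' (count vs choice controlling for slant). Positive `r_FS.C` means larger
#' counts for positive slants; positive `r_FC.S` means larger counts for
#' top-far choices. Significance uses the t-transform with `n - 3` degrees
#' of freedom. The `(r_FS.C, r_FC.S)` sign pattern assigns the neuron to a
#' quadrant: I `(+,+)`, II `(-,+)`, III `(-,-)`, IV `(+,-)` -- quadrants I
#' and III hold congruent stimulus and choice effects.
#'
#' @param x A `slant_session` with >= 2 distinct slants and both choices, or
#'   a data frame with columns `spike_count`, `slant_deg`, `choice`.
#' @param slant_transform Optional monotone function applied to slant before
#'   correlating (a sensitivity recoding; default identity).
#' @return A list of class `partialcorr_result` with the three pairwise
#'   correlations, both partials with p-values, their squares, and the
#'   quadrant.
#' @export
partial_correlations <- function(x, slant_transform = identity) {
  tr <- if (inherits(x, "slant_session")) {
    session_trials(x, task = "discrimination")
  } else tibble::as_tibble(x)
  if (nrow(tr) < 4) abort("need at least 4 trials")
  if (length(unique(tr$slant_deg)) < 2) abort("need >= 2 distinct slants")
  if (!all(c("top_far", "top_near") %in% tr$choice)) {
    abort("both choices must be present")
  }
  f <- as.numeric(tr$spike_count)
  s <- slant_transform(tr$slant_deg)
  c_ <- ifelse(tr$choice == "top_far", 1, -1)
  if (sd(f) == 0) abort("constant spike counts: correlations undefined")
  r_fs <- cor(f, s); r_fc <- cor(f, c_); r_sc <- cor(s, c_)
  if (abs(r_sc) >= 1 - 1e-12) {
    abort("collinearity: choice is perfectly determined by slant (|r_SC| = 1)")
  }
  # guard the degenerate case of a perfect pairwise correlation: the partial
  # of the remaining variable carries no information beyond it
  partial_of <- function(num, den2) {
    if (den2 < 1e-24) {
      if (abs(num) < 1e-8) 0 else sign(num)
    } else num / sqrt(den2)
  }
  r_fs_c <- partial_of(r_fs - r_fc * r_sc, (1 - r_fc^2) * (1 - r_sc^2))
  r_fc_s <- partial_of(r_fc - r_fs * r_sc, (1 - r_fs^2) * (1 - r_sc^2))
  n <- length(f)
  p_of <- function(r) {
    r <- max(-1 + 1e-15, min(1 - 1e-15, r))
    t <- r * sqrt((n - 3) / (1 - r^2))
    2 * pt(-abs(t), df = n - 3)
  }
  quadrant <- if (r_fs_c >= 0 && r_fc_s >= 0) "I"
              else if (r_fs_c < 0 && r_fc_s >= 0) "II"
              else if (r_fs_c < 0 && r_fc_s < 0) "III" else "IV"
  structure(list(
    neuron_id = if (inherits(x, "slant_session")) x$neuron_id else NA_character_,
    area = if (inherits(x, "slant_session")) x$area else NA_character_,
    n_trials = n,
    r_FS = r_fs, r_FC = r_fc, r_SC = r_sc,
    r_FS_C = r_fs_c, r_FC_S = r_fc_s,
    p_FS_C = p_of(r_fs_c), p_FC_S = p_of(r_fc_s),
    spc2 = r_fs_c^2, cpc2 = r_fc_s^2,
    quadrant = quadrant
  ), class = "partialcorr_result")
}

#' @export
print.partialcorr_result <- function(x, ...) {
  cat(sprintf("<partialcorr_result> r_FS.C = %.3f (p = %.3g), r_FC.S = %.3f (p = %.3g), quadrant %s\n",
              x$r_FS_C, x$p_FS_C, x$r_FC_S, x$p_FC_S, x$quadrant))
  invisible(x)
}

#' Choice-conditioned slant tuning curves
#'
#' Mean spike count as a function of signed slant: overall, and separately
#' for top-far and top-near choice trials. A slant contributes to a
#' choice-conditioned curve only when the animal made at least `min_choices`
#' choices in that direction at that slant.
#'
#' @param x A `slant_session` with discrimination trials.
#' @param min_choices Minimum choices per slant per direction (default 3).
#' @return A tibble with columns `curve` (`all`, `top_far`, `top_near`),
#'   `slant_deg`, `mean_count`, `sem`, `n`.
#' @export
choice_conditioned_tuning <- function(x, min_choices = 3L) {
  tr <- session_trials(x, task = "discrimination")
  if (nrow(tr) == 0) abort("session has no discrimination trials")
  curve_of <- function(d, label) {
    out <- dplyr::summarise(dplyr::group_by(d, .data$slant_deg),
                            mean_count = mean(.data$spike_count),
                            sem = sd(.data$spike_count) / sqrt(dplyr::n()),
                            n = dplyr::n(), .groups = "drop")
    out$curve <- label
    out
  }
  all_c <- curve_of(tr, "all")
  far <- curve_of(tr[tr$choice == "top_far", , drop = FALSE], "top_far")
  near <- curve_of(tr[tr$choice == "top_near", , drop = FALSE], "top_near")
  far <- far[far$n >= min_choices, , drop = FALSE]
  near <- near[near$n >= min_choices, , drop = FALSE]
  dplyr::bind_rows(all_c, far, near)[, c("curve", "slant_deg", "mean_count",
                                         "sem", "n")]
}

#' 95% confidence ellipse of partial-correlation points
#'
#' Fits the bivariate-normal 95% coverage ellipse to `(r_FS.C, r_FC.S)`
#' points: axes from the eigendecomposition of the 2x2 covariance scaled by
#' the chi-square(2) 0.95 quantile, major-axis angle from the principal
#' eigenvector (reported in `[0, 180)` degrees), and a percentile bootstrap
#' CI for the angle over resamples of the points (bootstrap angles are
#' aligned to the point estimate modulo 180 degrees before taking
#' percentiles, since the axis is orientation- but not direction-valued).
#'
#' @param points Data frame with columns `r_FS_C` and `r_FC_S` (>= 5 rows).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Coverage level (default 0.95).
#' @return A list of class `ellipse_fit` with `center`, `semi_major`,
#'   `semi_minor`, `angle_deg`, `angle_ci_deg`, `n_points`.
#' @export
confidence_ellipse <- function(points, n_boot = 1000L, seed = 1L,
                               level = 0.95) {
  pts <- tibble::as_tibble(points)
  stopifnot(all(c("r_FS_C", "r_FC_S") %in% names(pts)))
  m <- as.matrix(pts[, c("r_FS_C", "r_FC_S")])
  if (nrow(m) < 5) abort("need at least 5 points")
  ellipse_of <- function(m) {
    cv <- stats::cov(m)
    if (any(!is.finite(cv)) || det(cv) <= 1e-16) {
      abort("degenerate covariance: ellipse undefined")
    }
    eg <- eigen(cv, symmetric = TRUE)
    k <- qchisq(level, df = 2)
    ang <- (atan2(eg$vectors[2, 1], eg$vectors[1, 1]) * 180 / pi) %% 180
    list(center = colMeans(m), semi_major = sqrt(eg$values[1] * k),
         semi_minor = sqrt(eg$values[2] * k), angle_deg = ang)
  }
  est <- ellipse_of(m)
  set.seed(seed)
  boot_ang <- vapply(seq_len(n_boot), function(b) {
    mb <- m[sample.int(nrow(m), replace = TRUE), , drop = FALSE]
    tryCatch(ellipse_of(mb)$angle_deg, error = function(e) NA_real_)
  }, numeric(1))
  # align to the estimate modulo 180 so the CI does not straddle the seam
  d <- (boot_ang - est$angle_deg + 90) %% 180 - 90
  ci <- est$angle_deg + quantile(d, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(center = est$center, semi_major = est$semi_major,
                 semi_minor = est$semi_minor, angle_deg = est$angle_deg,
                 angle_ci_deg = ci, n_points = nrow(m)),
            class = "ellipse_fit")
}

#' Confidence ellipses for CP-above- and CP-below-chance groups
#'
#' Splits a population of neurons by grand CP above or below 0.5 and fits a
#' [confidence_ellipse()] to each group's partial-correlation points.
#'
#' @param population Data frame with columns `r_FS_C`, `r_FC_S`, `grand_cp`.
#' @param n_boot,seed Passed to [confidence_ellipse()].
#' @return Named list with entries `cp_above_half` and `cp_below_half`
#'   (either may be `NULL` with fewer than 5 neurons in the group).
#' @export
fit_cp_ellipses <- function(population, n_boot = 1000L, seed = 1L) {
  pop <- tibble::as_tibble(population)
  out <- list()
  for (grp in c("cp_above_half", "cp_below_half")) {
    sel <- if (grp == "cp_above_half") pop$grand_cp > 0.5 else pop$grand_cp < 0.5
    d <- pop[sel, , drop = FALSE]
    out[[grp]] <- if (nrow(d) >= 5) {
      e <- confidence_ellipse(d, n_boot = n_boot, seed = seed)
      e$group <- grp
      e
    } else NULL
  }
  out
}
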