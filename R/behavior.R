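#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `P(top_far | s) = gamma + (1 - gamma - lambda) * Phi((s - mu) / sigma)`
#' to per-slant counts of top-far choices. The point of subjective equality
#' (P.S.E.) is the mean `mu` and the threshold is the SD `sigma` of the
#' fitted cumulative Gaussian. Lapse parameters `gamma` (lower asymptote) and
#' `lambda` (upper) are fitted but bounded in `[0, lapse_max]`; unbounded
#' lapses destabilize the threshold.
#'
#' @param slants Signed slants, degrees.
#' @param k_top_far Number of top-far choices at each slant.
#' @param n Number of trials at each slant; zero-trial rows are dropped with
#'   a warning.
#' @param lapse_max Upper bound on each lapse parameter (default 0.1).
#' @return A list of class `psychometric_fit` with `pse_deg`,
#'   `threshold_deg` (`Inf` when the data show no slant modulation and the
#'   fit cannot converge), `gamma`, `lambda`, `loglik`, `n_trials`, the
#'   per-slant data, and a `converged` flag.
#' @export
fit_cumulative_gaussian <- function(slants, k_top_far, n, lapse_max = 0.1) {
  stopifnot(length(slants) == length(k_top_far), length(slants) == length(n))
  keep <- n > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d slant(s) with zero trials", sum(!keep)))
    slants <- slants[keep]; k_top_far <- k_top_far[keep]; n <- n[keep]
  }
  if (length(unique(slants)) < 4 || min(slants) >= 0 || max(slants) <= 0) {
    abort("need >= 4 distinct slants spanning both signs")
  }
  if (any(k_top_far < 0 | k_top_far > n)) abort("k_top_far must lie in [0, n]")
  prop <- k_top_far / n
  data <- tibble::tibble(slant_deg = slants, k = k_top_far, n = n, prop = prop)

  sig_lo <- 1e-3; sig_hi <- 1e6
  nll <- function(par) {
    p <- par[3] + (1 - par[3] - par[4]) * pnorm((slants - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(k_top_far * log(p) + (n - k_top_far) * log(1 - p))
  }
  span <- max(slants) - min(slants)
  mu0 <- sum(slants * n * (prop * (1 - prop) + 1e-6)) /
    sum(n * (prop * (1 - prop) + 1e-6))
  starts <- list(c(mu0, log(span / 4), 0.01, 0.01),
                 c(0, log(span / 8), 0.01, 0.01),
                 c(mu0, log(span), 0.01, 0.01),
                 c(0, log(sig_lo * 2), 0.001, 0.001))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B",
            lower = c(min(slants) - span, log(sig_lo), 0, 0),
            upper = c(max(slants) + span, log(sig_hi), lapse_max, lapse_max)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  flat <- length(unique(prop)) == 1
  if (is.null(best) || flat) {
    return(structure(list(pse_deg = if (flat) NA_real_ else NA_real_,
                          threshold_deg = Inf, gamma = NA_real_,
                          lambda = NA_real_, loglik = NA_real_,
                          n_trials = sum(n), data = data, converged = FALSE),
                     class = "psychometric_fit"))
  }
  sigma <- exp(best$par[2])
  converged <- best$convergence == 0 && sigma < sig_hi / 10
  structure(list(pse_deg = best$par[1],
                 threshold_deg = if (converged) sigma else Inf,
                 gamma = best$par[3], lambda = best$par[4],
                 loglik = -best$value, n_trials = sum(n), data = data,
                 converged = converged),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> P.S.E. %.3f deg, threshold %.3f deg (%d trials%s)\n",
              x$pse_deg, x$threshold_deg, x$n_trials,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Psychometric fit of a discrimination session
#'
#' Aggregates the proportion of top-far choices per signed slant and fits the
#' cumulative Gaussian of [fit_cumulative_gaussian()].
#'
#' @param x A `slant_session` with discrimination trials.
#' @param depths Depths (cm) to include; default all.
#' @param ... Passed to [fit_cumulative_gaussian()].
#' @return A `psychometric_fit`.
#' @export
fit_psychometric <- function(x, depths = NULL, ...) {
  tr <- session_trials(x, task = "discrimination")
  if (!is.null(depths)) tr <- tr[tr$depth_cm %in% depths, , drop = FALSE]
  if (nrow(tr) == 0) abort("no discrimination trials at the requested depths")
  agg <- dplyr::summarise(dplyr::group_by(tr, .data$slant_deg),
                          k = sum(.data$choice == "top_far"),
                          n = dplyr::n(), .groups = "drop")
  fit_cumulative_gaussian(agg$slant_deg, agg$k, agg$n, ...)
}

#' Depth-control ANOVA of psychometric parameters
#'
#' Tests whether the P.S.E. or the threshold depends on the mean stimulus
#' depth (near / screen / far), one fit per session and depth. A slant-based
#' observer is depth-invariant; an observer relying on local absolute
#' disparity would show P.S.E. biases of at least the screen-crossing slant
#' (about 14 deg for a 31-deg stimulus at +/- 2.25 cm and 32.5 cm viewing
#' distance), which is reported alongside for comparison.
#'
#' @param fits Data frame with one row per (session, depth): columns
#'   `session`, `depth_cm`, `pse_deg`, `threshold_deg`.
#' @param stim_angle_deg,view_dist_cm Stimulus angular size and viewing
#'   distance used for the local-disparity prediction bound.
#' @return A list with `pse_p`, `threshold_p` (one-way ANOVA p-values across
#'   depth levels), the per-depth means, and
#'   `disparity_prediction_deg` (the screen-crossing bound).
#' @export
depth_control_anova <- function(fits, stim_angle_deg = 31,
                                view_dist_cm = 32.5) {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c("session", "depth_cm", "pse_deg", "threshold_deg") %in% names(fits)))
  bad <- !is.finite(fits$pse_deg) | !is.finite(fits$threshold_deg)
  if (any(bad)) {
    warn(sprintf("dropping %d non-converged fit(s)", sum(bad)))
    fits <- fits[!bad, , drop = FALSE]
  }
  depths <- unique(fits$depth_cm)
  if (length(depths) < 2) abort("need at least 2 depth levels")
  if (any(table(fits$depth_cm) < 2)) abort("need >= 2 sessions per depth")
  p_of <- function(v) {
    fit <- aov(v ~ factor(fits$depth_cm))
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(p)) 1 else p   # zero between-group variance: no depth effect
  }
  means <- dplyr::summarise(dplyr::group_by(fits, .data$depth_cm),
                            mean_pse = mean(.data$pse_deg),
                            mean_threshold = mean(.data$threshold_deg),
                            n = dplyr::n(), .groups = "drop")
  list(pse_p = p_of(fits$pse_deg),
       threshold_p = p_of(fits$threshold_deg),
       per_depth = means,
       disparity_prediction_deg =
         screen_crossing_slant(stim_angle_deg, view_dist_cm, 2.25))
}

#' Slant at which a slanted plane crosses the display screen
#'
#' For a stimulus of angular size `stim_angle_deg` centered `depth_offset_cm`
#' in front of or behind the screen at viewing distance `view_dist_cm`, the
#' smallest slant at which the plane's edge reaches the display plane is
#' `atan(|depth_offset| / (view_dist * tan(stim_angle / 2)))`. An observer
#' judging whether part of the stimulus lies in front of the screen (local
#' absolute disparity) rather than judging slant would show P.S.E. biases of
#' at least this magnitude at the offset depths.
#'
#' @param stim_angle_deg Angular size of the stimulus, degrees (> 0).
#' @param view_dist_cm Viewing distance, cm (> 0).
#' @param depth_offset_cm Depth offset of the plane's center from the screen,
#'   cm (sign ignored).
#' @return Slant in degrees.
#' @export
screen_crossing_slant <- function(stim_angle_deg, view_dist_cm,
                                  depth_offset_cm) {
  if (any(stim_angle_deg <= 0)) abort("stim_angle_deg must be > 0")
  if (any(view_dist_cm <= 0)) abort("view_dist_cm must be > 0")
  half_extent <- view_dist_cm * tan(stim_angle_deg * pi / 360)
  atan(abs(depth_offset_cm) / half_extent) * 180 / pi
}
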