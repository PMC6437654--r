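#' @keywords internal
# one row per fixation trial with a collapsed condition label (slant 0 pools
# all tilts into the single frontoparallel condition)
fixation_condition_table <- function(x) {
  if (inherits(x, "slant_session")) {
    tr <- session_trials(x, task = "fixation")
    if (nrow(tr) == 0) abort("session has no fixation trials")
    tibble::tibble(
      slant_deg = tr$slant_deg,
      tilt_deg = ifelse(tr$slant_deg == 0, NA_real_, tr$tilt_deg),
      condition = ifelse(tr$slant_deg == 0, "s0",
                         sprintf("s%g_t%g", tr$slant_deg, tr$tilt_deg)),
      response = tr$spike_count
    )
  } else {
    x <- tibble::as_tibble(x)
    if (!all(c("condition", "response") %in% names(x))) {
      abort("need a slant_session or a data frame with columns condition, response")
    }
    x
  }
}

#' Surface orientation discrimination index (SODI)
#'
#' Quantifies response modulation across stimulus conditions relative to
#' within-condition variability:
#' `SODI = (Rmax - Rmin) / (Rmax - Rmin + 2 * sqrt(SSE / (N - M)))`,
#' where `Rmax`/`Rmin` are the largest and smallest condition-mean responses,
#' `SSE` is the summed squared error of trials around their condition means,
#' `N` the total trial count and `M` the number of conditions. The index lies
#' in `[0, 1]`: 1 when responses are perfectly repeatable (`SSE = 0`) but
#' modulated, 0 when all condition means are equal.
#'
#' @param x A `slant_session` (its fixation trials, grouped into the 25
#'   slant-tilt conditions) or a data frame with columns `condition` and
#'   `response`.
#' @return A list of class `sodi_result` with `sodi`, `R_max`, `R_min`,
#'   `SSE`, `N_trials`, `M_conditions`, and the condition means.
#' @export
compute_sodi <- function(x) {
  tab <- fixation_condition_table(x)
  if (nrow(tab) == 0) abort("no trials supplied")
  means <- dplyr::summarise(dplyr::group_by(tab, .data$condition),
                            mean_response = mean(.data$response),
                            n = dplyr::n(), .groups = "drop")
  if (nrow(means) < 2) abort("need responses in at least 2 conditions")
  sse <- sum((tab$response -
                means$mean_response[match(tab$condition, means$condition)])^2)
  n <- nrow(tab); m <- nrow(means)
  rmax <- max(means$mean_response); rmin <- min(means$mean_response)
  if (sse > 0 && n <= m) {
    abort("SODI undefined: N <= M with nonzero within-condition variance")
  }
  noise <- if (sse == 0) 0 else 2 * sqrt(sse / (n - m))
  num <- rmax - rmin
  sodi <- if (num == 0 && noise == 0) 0 else num / (num + noise)
  structure(list(sodi = sodi, R_max = rmax, R_min = rmin, SSE = sse,
                 N_trials = n, M_conditions = m, condition_means = means),
            class = "sodi_result")
}

#' One-way ANOVA across stimulus conditions
#'
#' Fixed-effects one-way ANOVA of trial responses across the slant-tilt
#' conditions; the resulting p-value is the first gate of the two-step
#' tuned/untuned classification.
#'
#' @inheritParams compute_sodi
#' @return The ANOVA p-value.
#' @export
condition_anova <- function(x) {
  tab <- fixation_condition_table(x)
  counts <- table(tab$condition)
  if (length(counts) < 2) abort("need at least 2 conditions")
  if (any(counts < 2)) {
    abort(paste0("every condition needs >= 2 trials; too few in: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  fit <- aov(response ~ factor(condition), data = tab)
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' Fit a Bingham tuning function to 25 condition means
#'
#' Maps each slant-tilt condition to its unit surface normal
#' `n = (sin s cos t, sin s sin t, cos s)` and fits
#' `R(n) = A * exp(lambda1 (v1.n)^2 + lambda2 (v2.n)^2) + B`
#' by multi-start Levenberg-Marquardt least squares (starts placed at the
#' conditions with the largest observed means). The quality of fit is the
#' Pearson correlation between fitted and observed condition means; the
#' preferred direction is the argmax of the fitted surface over a dense
#' hemisphere grid.
#'
#' @param condition_means Data frame with columns `slant_deg`, `tilt_deg`
#'   (NA allowed at slant 0), and `mean_response`, one row per condition.
#' @param n_starts Number of multi-start initializations (default 8).
#' @param grid_step_deg Resolution of the hemisphere grid used to locate the
#'   fitted peak, degrees.
#' @return A list of class `bingham_fit` with elements `params`
#'   ([bingham_params()]), `r` (Pearson correlation, `-Inf` if no start
#'   converged or the fit is degenerate), `fitted`, `preferred_slant_deg`,
#'   `preferred_tilt_deg`, and `converged`.
#' @export
fit_bingham_tuning <- function(condition_means, n_starts = 8L,
                               grid_step_deg = 1) {
  cm <- tibble::as_tibble(condition_means)
  stopifnot(all(c("slant_deg", "tilt_deg", "mean_response") %in% names(cm)))
  if (all(cm$slant_deg == 0)) abort("need at least one non-frontoparallel condition")
  normals <- slant_tilt_to_normal(cm$slant_deg,
                                  ifelse(is.na(cm$tilt_deg), 0, cm$tilt_deg))
  y <- cm$mean_response
  # model: y = exp(a + q(n)) + B with q = n' M n, m33 fixed at 0 (the shift
  # degeneracy q -> q + c is absorbed by a)
  qform <- function(p, N) {
    M <- matrix(c(p[3], p[5], p[6],
                  p[5], p[4], p[7],
                  p[6], p[7], 0), 3, 3)
    rowSums((N %*% M) * N)
  }
  predict_p <- function(p, N) exp(pmin(p[1] + qform(p, N), 50)) + p[2]
  resid_fun <- function(p) predict_p(p, normals) - y

  ord <- order(y, decreasing = TRUE)
  rmin <- min(y); rmax <- max(y)
  best <- NULL; best_sse <- Inf
  for (k in seq_len(min(n_starts, nrow(cm)))) {
    n0 <- normals[ord[k], ]
    Mfull <- -3 * (diag(3) - tcrossprod(n0))
    Madj <- Mfull - Mfull[3, 3] * diag(3)
    q0 <- as.numeric(n0 %*% Madj %*% n0)
    a0 <- log(max(rmax - rmin, 1e-3)) - q0
    p0 <- c(a0, max(rmin, 0), Madj[1, 1], Madj[2, 2],
            Madj[1, 2], Madj[1, 3], Madj[2, 3])
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fun,
                         lower = c(-50, 0, rep(-100, 5)),
                         upper = c(50, max(y) + 1, rep(100, 5)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$deviance) && fit$deviance < best_sse) {
      best <- fit; best_sse <- fit$deviance
    }
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, r = -Inf, fitted = rep(NA_real_, nrow(cm)),
                          preferred_slant_deg = NA_real_,
                          preferred_tilt_deg = NA_real_, converged = FALSE),
                     class = "bingham_fit"))
  }
  p <- best$par
  fitted <- predict_p(p, normals)
  r <- if (sd(fitted) < 1e-12 || sd(y) < 1e-12) -Inf else cor(fitted, y)
  # canonical Bingham parameters from the symmetric form
  M <- matrix(c(p[3], p[5], p[6], p[5], p[4], p[7], p[6], p[7], 0), 3, 3)
  eg <- eigen(M, symmetric = TRUE)
  shift <- eg$values[1]                      # largest eigenvalue
  lam <- eg$values[2:3] - shift              # lambda2 >= lambda1 after sort
  params <- tryCatch(
    bingham_params(amplitude = exp(min(p[1] + shift, 50)), baseline = p[2],
                   lambda1 = min(lam), lambda2 = min(max(lam), 0),
                   v1 = eg$vectors[, 3], v2 = eg$vectors[, 2]),
    error = function(e) NULL)
  # fitted peak on a dense hemisphere grid
  grid <- expand.grid(slant_deg = seq(0, 90, by = grid_step_deg),
                      tilt_deg = seq(0, 360 - grid_step_deg, by = grid_step_deg))
  gn <- slant_tilt_to_normal(grid$slant_deg, grid$tilt_deg)
  gfit <- predict_p(p, gn)
  i <- which.max(gfit)
  structure(list(params = params, r = r, fitted = fitted,
                 preferred_slant_deg = grid$slant_deg[i],
                 preferred_tilt_deg = if (grid$slant_deg[i] == 0) NA_real_
                                      else grid$tilt_deg[i],
                 converged = TRUE),
            class = "bingham_fit")
}

#' Two-step tuned/untuned classification
#'
#' A neuron is *tuned* when the condition ANOVA rejects (`p < 0.05`) and the
#' Bingham fit correlates with the observed means at `r >= 0.8`; a neuron
#' that passes the ANOVA but fails the correlation gate is
#' *untuned_multipeak* (the unimodal fit underfits multi-peaked profiles that
#' can still pass an ANOVA); all others are *untuned*.
#'
#' @param anova_p ANOVA p-value(s).
#' @param bingham_r Pearson correlation(s) of the Bingham fit (`-Inf`/`NA`
#'   for failed or degenerate fits).
#' @param p_cut,r_cut Classification thresholds (defaults 0.05 and 0.8).
#' @return Factor with levels `tuned`, `untuned_multipeak`, `untuned`.
#' @export
classify_tuning <- function(anova_p, bingham_r, p_cut = 0.05, r_cut = 0.8) {
  r <- ifelse(is.na(bingham_r), -Inf, bingham_r)
  out <- ifelse(anova_p < p_cut & r >= r_cut, "tuned",
                ifelse(anova_p < p_cut, "untuned_multipeak", "untuned"))
  factor(out, levels = c("tuned", "untuned_multipeak", "untuned"))
}

#' Full tuning analysis of a fixation session
#'
#' Runs the SODI, the 25-condition ANOVA, the Bingham fit, the tuned/untuned
#' classification, and the slant ANOVA restricted to the 90/270-deg tilt axis
#' (the axis used in the discrimination task; signed slants -60..60 deg).
#'
#' @param x A `slant_session` with fixation trials.
#' @return A list of class `tuning_result`.
#' @export
analyze_tuning <- function(x) {
  stopifnot(inherits(x, "slant_session"))
  tab <- fixation_condition_table(x)
  sodi <- compute_sodi(tab)
  anova_p <- condition_anova(tab)
  cm <- dplyr::summarise(
    dplyr::group_by(tab, .data$slant_deg, .data$tilt_deg),
    mean_response = mean(.data$response), .groups = "drop")
  bfit <- fit_bingham_tuning(cm)
  cls <- classify_tuning(anova_p, bfit$r)
  # slant tuning along the 90/270 axis, signed (tilt 90 -> negative)
  axis <- tab[tab$slant_deg == 0 | tab$tilt_deg %in% c(90, 270), , drop = FALSE]
  axis$signed_slant <- ifelse(axis$slant_deg == 0, 0,
                              ifelse(axis$tilt_deg == 90, -1, 1) * axis$slant_deg)
  slant_axis_p <- if (length(unique(axis$signed_slant)) >= 2 &&
                      all(table(axis$signed_slant) >= 2)) {
    summary(aov(response ~ factor(signed_slant), data = axis))[[1]][["Pr(>F)"]][1]
  } else NA_real_
  # preference sign along the axis from the fixation means
  ax_means <- tapply(axis$response, axis$signed_slant, mean)
  pos <- ax_means[as.numeric(names(ax_means)) > 0]
  neg <- ax_means[as.numeric(names(ax_means)) < 0]
  pref_sign <- if (length(pos) == 0 || length(neg) == 0) "unknown"
               else if (max(pos) >= max(neg)) "positive" else "negative"
  structure(list(
    neuron_id = x$neuron_id, area = x$area,
    condition_means = cm,
    R_max = sodi$R_max, R_min = sodi$R_min, SSE = sodi$SSE,
    N_trials = sodi$N_trials, M_conditions = sodi$M_conditions,
    sodi = sodi$sodi, anova_p = anova_p,
    bingham = bfit, bingham_r = bfit$r,
    tuned = cls == "tuned",
    multi_peak_rejected = cls == "untuned_multipeak",
    classification = as.character(cls),
    preferred_slant_deg = bfit$preferred_slant_deg,
    preferred_tilt_deg = bfit$preferred_tilt_deg,
    slant_axis_anova_p = slant_axis_p,
    preferred_sign_axis = pref_sign
  ), class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> neuron %s (%s): SODI %.3f, ANOVA p %.3g, Bingham r %.3f -> %s\n",
              x$neuron_id, x$area, x$sodi, x$anova_p, x$bingham_r,
              x$classification))
  if (isTRUE(x$tuned)) {
    cat(sprintf("  preferred slant %.1f deg, tilt %s deg\n",
                x$preferred_slant_deg,
                ifelse(is.na(x$preferred_tilt_deg), "-", x$preferred_tilt_deg)))
  }
  invisible(x)
}

#' Lambert azimuthal equal-area projection of a slant-tilt direction
#'
#' Projects a direction on the viewing hemisphere to the plane about the
#' frontoparallel pole: radius `rho = 2 sin(slant / 2)`, azimuth = tilt, so
#' the map preserves area (equal solid angles on the hemisphere cover equal
#' planar area).
#'
#' @param slant_deg Slant(s) in `[0, 90]` degrees.
#' @param tilt_deg Tilt(s), degrees; ignored (taken as 0) where slant is 0.
#' @return A tibble with columns `x`, `y`.
#' @export
project_equal_area <- function(slant_deg, tilt_deg) {
  if (any(slant_deg < 0 | slant_deg > 90)) {
    abort("slant_deg must lie in [0, 90]")
  }
  tilt_deg <- ifelse(slant_deg == 0 & is.na(tilt_deg), 0, tilt_deg)
  rho <- 2 * sin(slant_deg * pi / 360)
  t <- tilt_deg * pi / 180
  tibble::tibble(x = rho * cos(t), y = rho * sin(t))
}

#' Inverse of the equal-area projection
#'
#' @param x,y Planar coordinates from [project_equal_area()].
#' @return A tibble with `slant_deg`, `tilt_deg`.
#' @export
equal_area_inverse <- function(x, y) {
  rho <- sqrt(x^2 + y^2)
  slant <- 2 * asin(pmin(1, rho / 2)) * 180 / pi
  tilt <- (atan2(y, x) * 180 / pi) %% 360
  tibble::tibble(slant_deg = slant, tilt_deg = tilt)
}

#' Chi-square test of preference uniformity on the hemisphere
#'
#' Bins preferred directions into equal-area cells (tilt sectors crossed with
#' slant rings at equal-area radii, pooled until every cell expects at least
#' `min_expected` counts under uniformity) and tests the counts against the
#' uniform expectation with a chi-square goodness-of-fit test. Under a
#' uniform distribution of preferences each equal-area cell is equally
#' likely, so the test is calibrated by construction.
#'
#' @param prefs Data frame with columns `slant_deg` (in `[0, 90]`) and
#'   `tilt_deg`, one row per neuron.
#' @param max_slant_deg Outer edge of the represented hemisphere cap
#'   (default 90).
#' @param min_expected Minimum expected count per cell (default 5).
#' @return A list with `statistic`, `p_value`, `df`, `n_sectors`, `n_rings`,
#'   and the observed `counts`.
#' @export
preference_uniformity_test <- function(prefs, max_slant_deg = 90,
                                       min_expected = 5) {
  prefs <- tibble::as_tibble(prefs)
  n <- nrow(prefs)
  if (n < 20) {
    abort("need >= 20 preferred directions; use coarser binning or more neurons")
  }
  # choose the finest sector x ring grid with expected counts >= min_expected
  grids <- expand.grid(sectors = c(8, 4, 2), rings = c(3, 2, 1))
  grids <- grids[order(-(grids$sectors * grids$rings)), ]
  pick <- grids[n / (grids$sectors * grids$rings) >= min_expected, , drop = FALSE]
  if (nrow(pick) == 0) pick <- grids[nrow(grids), , drop = FALSE]
  ns <- pick$sectors[1]; nr <- pick$rings[1]
  rho <- 2 * sin(prefs$slant_deg * pi / 360)
  rho_max <- 2 * sin(max_slant_deg * pi / 360)
  ring <- pmin(nr, floor(nr * (rho / rho_max)^2) + 1)   # equal-area rings
  tilt <- ifelse(is.na(prefs$tilt_deg), 0, prefs$tilt_deg) %% 360
  sector <- floor(tilt / (360 / ns)) + 1
  cell <- factor(paste(ring, sector), levels = as.vector(outer(
    seq_len(nr), seq_len(ns), function(r, s) paste(r, s))))
  counts <- table(cell)
  ct <- suppressWarnings(chisq.test(as.vector(counts),
                                    p = rep(1 / length(counts), length(counts))))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), n_sectors = ns, n_rings = nr,
       counts = as.vector(counts))
}
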