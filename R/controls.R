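#' Eye-movement confound control: ANCOVA and linear-trend removal
#'
#' For each session, an analysis of covariance tests whether firing rate
#' depends on the chosen eye covariate (trial-mean vertical eye position,
#' vertical eye velocity, or vergence) while accounting for choice; the
#' per-neuron covariate p-values are corrected family-wise across neurons by
#' the Bonferroni-Holm step-down. Responses are then detrended by removing
#' the marginal linear trend of spike count on the covariate (so the
#' corrected responses have exactly zero linear trend on it, and detrending
#' twice equals detrending once), and the grand CP and comparison neuronal
#' threshold are recomputed on the corrected responses. Paired before/after
#' comparisons summarize how much the confound contributed. Sessions lacking
#' the covariate (or with a constant covariate) are skipped and logged.
#'
#' @param sessions List of `slant_session` objects with discrimination
#'   trials and the covariate column.
#' @param covariate One of `"eye_vpos_deg"`, `"eye_vvel_deg_s"`,
#'   `"vergence_deg"`.
#' @param min_choices Grand-CP inclusion rule.
#' @return A list of class `eye_control_result` with `per_neuron` (tibble of
#'   ancova p, Holm-adjusted p, CP and threshold before/after, residual
#'   covariate slope), `significant_fraction`, paired-test p-values and
#'   before/after correlations, and the ids of skipped sessions.
#' @export
eye_ancova_and_detrend <- function(sessions,
                                   covariate = c("eye_vpos_deg",
                                                 "eye_vvel_deg_s",
                                                 "vergence_deg"),
                                   min_choices = 3L) {
  covariate <- match.arg(covariate)
  if (inherits(sessions, "slant_session")) sessions <- list(sessions)
  skipped <- character()
  rows <- list()
  for (s in sessions) {
    tr <- session_trials(s, task = "discrimination")
    if (!covariate %in% names(tr) || anyNA(tr[[covariate]])) {
      skipped <- c(skipped, s$neuron_id)
      next
    }
    v <- tr[[covariate]]
    if (sd(v) == 0) {
      warn(sprintf("neuron %s: constant covariate, skipped", s$neuron_id))
      skipped <- c(skipped, s$neuron_id)
      next
    }
    f <- as.numeric(tr$spike_count)
    cc <- factor(tr$choice, levels = c("top_near", "top_far"))
    anc <- lm(f ~ cc + v)
    p_cov <- summary(anc)$coefficients["v", "Pr(>|t|)"]
    # marginal linear trend removal
    slope <- cov(f, v) / var(v)
    f_corr <- f - slope * (v - mean(v))
    pref_choice <- preferred_choice_label(s$preferred_sign_fixation)
    is_pref <- tr$choice == pref_choice
    cp_of <- function(resp) tryCatch(
      grand_cp_core(resp, tr$slant_deg, is_pref, min_choices,
                    warn_zero_scale = FALSE)$cp,
      error = function(e) NA_real_)
    thr_of <- function(resp) {
      at0 <- tr$depth_cm == 0
      out <- tryCatch(suppressWarnings(
        neurometric_core(resp[at0], tr$slant_deg[at0],
                         s$preferred_sign_fixation,
                         warn_excluded = FALSE)$fit$threshold_deg),
        error = function(e) NA_real_)
      if (is.finite(out)) 2 * out else NA_real_
    }
    resid_slope <- cov(f_corr, v) / var(v)
    rows[[length(rows) + 1]] <- tibble::tibble(
      neuron_id = s$neuron_id, area = s$area,
      ancova_p = p_cov, trend_slope = slope, residual_slope = resid_slope,
      cp_before = cp_of(f), cp_after = cp_of(f_corr),
      threshold_before = thr_of(f), threshold_after = thr_of(f_corr)
    )
  }
  if (length(rows) == 0) abort("no session carries the requested covariate")
  per <- dplyr::bind_rows(rows)
  per$holm_p <- p.adjust(per$ancova_p, method = "holm")
  per$significant <- per$holm_p < 0.05
  paired_p <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok] - b[ok]) == 0) return(NA_real_)
    t.test(a[ok], b[ok], paired = TRUE)$p.value
  }
  corr_of <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(NA_real_)
    cor(a[ok], b[ok])
  }
  structure(list(
    covariate = covariate,
    per_neuron = per,
    significant_fraction = mean(per$significant),
    cp_paired_p = paired_p(per$cp_before, per$cp_after),
    threshold_paired_p = paired_p(per$threshold_before, per$threshold_after),
    cp_correlation = corr_of(per$cp_before, per$cp_after),
    threshold_correlation = corr_of(per$threshold_before,
                                    per$threshold_after),
    skipped = skipped
  ), class = "eye_control_result")
}

#' @export
print.eye_control_result <- function(x, ...) {
  cat(sprintf("<eye_control_result> %s: %d neurons (%d skipped), %.0f%% significant after Holm\n",
              x$covariate, nrow(x$per_neuron), length(x$skipped),
              100 * x$significant_fraction))
  cat(sprintf("  CP before/after r = %.3f (paired p = %.3g)\n",
              x$cp_correlation, x$cp_paired_p))
  invisible(x)
}
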