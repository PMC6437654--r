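#' Sliding analysis-window specification
#'
#' Windows of `width_ms` centered at `first_center_ms`, `first_center_ms +
#' step_ms`, ..., `last_center_ms`. The defaults (200-ms windows stepped by
#' 50 ms, centers 100 to 1150 ms) give 22 bins: the first window is
#' `[0, 200)` and the last, centered 150 ms after stimulus offset, is
#' `[1050, 1250)` -- reaching approximately the median choice time (271 ms
#' after offset, i.e. 1271 ms after onset).
#'
#' @param width_ms Window width, ms.
#' @param step_ms Center-to-center step, ms (> 0).
#' @param first_center_ms,last_center_ms First and last window centers, ms.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(width_ms = 200, step_ms = 50,
                        first_center_ms = 100, last_center_ms = 1150) {
  if (step_ms <= 0) abort("step_ms must be > 0")
  if (last_center_ms < first_center_ms) abort("last center before first center")
  structure(list(width_ms = width_ms, step_ms = step_ms,
                 first_center_ms = first_center_ms,
                 last_center_ms = last_center_ms),
            class = "window_spec")
}

#' Materialize the analysis windows
#'
#' @param spec A [window_spec()].
#' @return A tibble with one row per window: `center_ms`, `start_ms`,
#'   `end_ms` (half-open `[start, end)`); windows may extend past stimulus
#'   offset.
#' @export
make_windows <- function(spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  centers <- seq(spec$first_center_ms, spec$last_center_ms, by = spec$step_ms)
  tibble::tibble(center_ms = centers,
                 start_ms = centers - spec$width_ms / 2,
                 end_ms = centers + spec$width_ms / 2)
}

# trials x windows matrix of spike counts from per-trial spike times
window_count_matrix <- function(trials, windows) {
  if (!"spike_times_ms" %in% names(trials)) {
    abort("time-course analyses need spike_times_ms on every trial")
  }
  st <- trials$spike_times_ms
  out <- matrix(0L, nrow(trials), nrow(windows))
  for (j in seq_len(nrow(windows))) {
    out[, j] <- vapply(st, function(t) {
      sum(t >= windows$start_ms[j] & t < windows$end_ms[j])
    }, integer(1))
  }
  out
}

# per-bin statistic of one session; returns numeric vector over windows
session_window_metric <- function(x, metric, windows, min_choices = 3L) {
  tr <- session_trials(x, task = "discrimination")
  counts <- window_count_matrix(tr, windows)
  pref_choice <- if (metric %in% c("cp", "cpc2", "spc2")) {
    preferred_choice_label(x$preferred_sign_fixation)
  } else NULL
  vapply(seq_len(nrow(windows)), function(j) {
    resp <- as.numeric(counts[, j])
    switch(metric,
      cp = tryCatch(
        grand_cp_core(resp, tr$slant_deg, tr$choice == pref_choice,
                      min_choices, warn_zero_scale = FALSE)$cp,
        error = function(e) NA_real_),
      threshold = {
        at0 <- tr$depth_cm == 0
        out <- tryCatch(suppressWarnings(
          neurometric_core(resp[at0], tr$slant_deg[at0],
                           x$preferred_sign_fixation,
                           warn_excluded = FALSE)$fit$threshold_deg),
          error = function(e) NA_real_)
        if (!is.finite(out)) NA_real_ else 2 * out
      },
      spc2 = tryCatch(
        partial_correlations(tibble::tibble(
          spike_count = resp, slant_deg = tr$slant_deg,
          choice = tr$choice))$spc2,
        error = function(e) NA_real_),
      cpc2 = tryCatch(
        partial_correlations(tibble::tibble(
          spike_count = resp, slant_deg = tr$slant_deg,
          choice = tr$choice))$cpc2,
        error = function(e) NA_real_),
      abort(paste0("unknown metric: ", metric)))
  }, numeric(1))
}

#' Population time course of a per-neuron statistic
#'
#' Recomputes a per-neuron statistic -- grand CP, comparison neuronal
#' threshold (twice the fitted SD), or squared slant/choice partial
#' correlation -- on spike counts restricted to each sliding window, then
#' summarizes across neurons (mean and SEM per bin). A one-way ANOVA across
#' bins with Tukey-corrected comparisons against the first bin locates the
#' first bin whose population value departs from the initial one.
#'
#' @param sessions List of `slant_session` objects with spike times.
#' @param metric One of `"cp"`, `"threshold"`, `"spc2"`, `"cpc2"`.
#' @param spec A [window_spec()].
#' @param min_choices Grand-CP inclusion rule (CP metric only).
#' @return A list of class `timecourse_result` with `per_bin` (tibble:
#'   center, mean, sem, n), the per-neuron matrix, `anova_p`, and
#'   `first_significant_bin_ms` (`NA` if no bin differs).
#' @export
metric_timecourse <- function(sessions, metric = c("cp", "threshold", "spc2", "cpc2"),
                              spec = window_spec(), min_choices = 3L) {
  metric <- match.arg(metric)
  if (inherits(sessions, "slant_session")) sessions <- list(sessions)
  if (any(vapply(sessions, function(s)
    nrow(session_trials(s, "discrimination")) == 0, logical(1)))) {
    abort(paste0("metric '", metric, "' needs discrimination sessions with choices"))
  }
  windows <- make_windows(spec)
  vals <- t(vapply(sessions, session_window_metric, numeric(nrow(windows)),
                   metric = metric, windows = windows,
                   min_choices = min_choices))
  summarize_timecourse(vals, windows, metric)
}

summarize_timecourse <- function(vals, windows, metric) {
  per_bin <- tibble::tibble(
    center_ms = windows$center_ms,
    mean = apply(vals, 2, mean, na.rm = TRUE),
    sem = apply(vals, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
    n = apply(vals, 2, function(v) sum(!is.na(v)))
  )
  long <- tibble::tibble(
    value = as.vector(vals),
    bin = factor(rep(windows$center_ms, each = nrow(vals)),
                 levels = windows$center_ms)
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  anova_p <- NA_real_; first_sig <- NA_real_
  if (nrow(windows) > 1 && length(unique(long$bin)) > 1) {
    fit <- aov(value ~ bin, data = long)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- tryCatch(suppressWarnings(TukeyHSD(fit)$bin), error = function(e) NULL)
    if (!is.null(tk)) {
      base <- as.character(windows$center_ms[1])
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      vs_base <- vapply(pairs, function(p) base %in% p, logical(1))
      other <- vapply(pairs[vs_base], function(p) p[p != base][1], character(1))
      padj <- tk[vs_base, "p adj"]
      sig <- as.numeric(other)[!is.na(padj) & padj < 0.05]
      if (length(sig) > 0) first_sig <- min(sig)
    }
  }
  structure(list(metric = metric, per_bin = per_bin, per_neuron = vals,
                 anova_p = anova_p, first_significant_bin_ms = first_sig),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf("<timecourse_result> %s over %d bins (%d neurons): ANOVA p = %.3g, first bin differing from the initial bin: %s ms\n",
              x$metric, nrow(x$per_bin), nrow(x$per_neuron), x$anova_p,
              ifelse(is.na(x$first_significant_bin_ms), "none",
                     x$first_significant_bin_ms)))
  invisible(x)
}

#' Population spike density function
#'
#' Mean firing rate (Hz) in each sliding window, averaged over trials within
#' a neuron and then over neurons -- the same binning as the other time
#' courses so the SDF can be correlated with, e.g., the squared slant
#' partial correlation time course.
#'
#' @param sessions List of `slant_session` objects with spike times.
#' @param spec A [window_spec()].
#' @return A `timecourse_result` with metric `"sdf"` (no across-bin test).
#' @export
compute_sdf <- function(sessions, spec = window_spec()) {
  if (inherits(sessions, "slant_session")) sessions <- list(sessions)
  windows <- make_windows(spec)
  vals <- t(vapply(sessions, function(s) {
    tr <- session_trials(s)
    counts <- window_count_matrix(tr, windows)
    colMeans(counts) * 1000 / spec$width_ms
  }, numeric(nrow(windows))))
  out <- summarize_timecourse(vals, windows, "sdf")
  out$anova_p <- NA_real_
  out$first_significant_bin_ms <- NA_real_
  out
}
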