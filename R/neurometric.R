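#' ROC area between two response distributions
#'
#' The probability that a random draw from `responses_b` exceeds one from
#' `responses_a`, with ties counted 1/2 (the Mann-Whitney rank-sum
#' formulation, identical to the trapezoidal area under the ROC curve traced
#' by sweeping a decision threshold).
#'
#' @param responses_a,responses_b Numeric response vectors (non-empty).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(responses_a, responses_b) {
  na <- length(responses_a); nb <- length(responses_b)
  if (na == 0 || nb == 0) abort("both response groups must be non-empty")
  r <- rank(c(responses_a, responses_b))
  (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

# per-slant ideal-observer "report positive" probabilities and the fitted
# cumulative Gaussian; responses/slant are parallel vectors of 0-depth trials
neurometric_core <- function(responses, slant, pref_sign, min_reps = 10L,
                             warn_excluded = TRUE) {
  if (!any(slant == 0)) abort("neurometric curve needs 0-degree slant trials")
  resp0 <- responses[slant == 0]
  tab <- table(slant)
  nz <- sort(as.numeric(names(tab)[as.numeric(names(tab)) != 0]))
  enough <- nz[tab[as.character(nz)] >= min_reps]
  if (length(tab["0"]) == 0 || tab["0"] < min_reps) {
    abort(sprintf("need >= %d repetitions of the 0-degree slant", min_reps))
  }
  excluded <- setdiff(nz, enough)
  if (length(excluded) > 0 && warn_excluded) {
    warn(paste0("excluding slants with < ", min_reps, " repetitions: ",
                paste(excluded, collapse = ", ")))
  }
  if (length(enough) < 4) abort("too few slants with enough repetitions")
  auc <- vapply(enough, function(s) roc_auc(resp0, responses[slant == s]),
                numeric(1))
  p_pos <- if (pref_sign == "positive") auc else 1 - auc
  n_s <- as.integer(tab[as.character(enough)])
  fit <- tryCatch(
    fit_cumulative_gaussian(enough, p_pos * n_s, n_s),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- structure(list(pse_deg = NA_real_, threshold_deg = Inf,
                          gamma = NA_real_, lambda = NA_real_,
                          loglik = NA_real_, n_trials = sum(n_s),
                          data = NULL, converged = FALSE),
                     class = "psychometric_fit")
  }
  list(per_slant = tibble::tibble(slant_deg = enough, p_ideal_top_far = p_pos,
                                  auc_vs_zero = auc, n = n_s),
       fit = fit)
}

#' Build the neurometric function of a discrimination session
#'
#' For each nonzero slant (with at least `min_reps` repetitions at screen
#' depth), computes the ROC area between the 0-degree response distribution
#' and that slant's distribution -- the ability of an ideal observer to tell
#' the slant from frontoparallel. Each area is oriented as the probability
#' that the ideal observer reports *positive* slant, using the neuron's
#' slant-preference sign from the fixation task (areas flip for
#' negative-preferring neurons). A cumulative Gaussian fitted to the
#' resulting function of signed slant gives the neuronal threshold (its SD).
#' Only screen-depth (0 cm) trials enter.
#'
#' @param x A `slant_session` with discrimination trials and a known
#'   fixation slant-preference sign.
#' @param min_reps Minimum repetitions per slant (default 10).
#' @return A list of class `neurometric_result` with `per_slant` (tibble of
#'   oriented ROC values), `fit`, `neuronal_threshold_deg` (the fitted SD;
#'   `Inf` for an uninformative neuron), and `comparison_threshold_deg`
#'   (exactly twice the neuronal threshold; the behavioral task has a single
#'   stimulus interval whereas the ROC compares two response distributions).
#' @export
build_neurometric_curve <- function(x, min_reps = 10L) {
  stopifnot(inherits(x, "slant_session"))
  tr <- session_trials(x, task = "discrimination")
  tr <- tr[tr$depth_cm == 0, , drop = FALSE]
  if (nrow(tr) == 0) abort("no screen-depth discrimination trials")
  core <- neurometric_core(tr$spike_count, tr$slant_deg,
                           pref_sign = x$preferred_sign_fixation,
                           min_reps = min_reps)
  structure(list(
    neuron_id = x$neuron_id, area = x$area,
    per_slant = core$per_slant, fit = core$fit,
    neuronal_threshold_deg = core$fit$threshold_deg,
    comparison_threshold_deg = 2 * core$fit$threshold_deg
  ), class = "neurometric_result")
}

#' @export
print.neurometric_result <- function(x, ...) {
  cat(sprintf("<neurometric_result> neuron %s (%s): threshold %.3f deg (x2 = %.3f deg)\n",
              x$neuron_id, x$area, x$neuronal_threshold_deg,
              x$comparison_threshold_deg))
  invisible(x)
}

#' Neuronal vs behavioral threshold comparison
#'
#' Applies the one-interval correction (neuronal threshold times 2) and
#' forms the neuronal-to-behavioral threshold ratio. Ratios below 1 -- a
#' neuron apparently more sensitive than the animal -- are flagged for
#' review; an infinite neuronal threshold yields an infinite, flagged ratio.
#'
#' @param neurometric A `neurometric_result`.
#' @param behavioral A `psychometric_fit` from the same session.
#' @return A tibble with `neuronal_threshold_deg`,
#'   `comparison_threshold_deg`, `behavioral_threshold_deg`,
#'   `threshold_ratio`, and `flagged`.
#' @export
neuronal_threshold <- function(neurometric, behavioral) {
  stopifnot(inherits(neurometric, "neurometric_result"),
            inherits(behavioral, "psychometric_fit"))
  sig_n <- neurometric$neuronal_threshold_deg
  sig_b <- behavioral$threshold_deg
  ratio <- 2 * sig_n / sig_b
  tibble::tibble(
    neuron_id = neurometric$neuron_id,
    neuronal_threshold_deg = sig_n,
    comparison_threshold_deg = 2 * sig_n,
    behavioral_threshold_deg = sig_b,
    threshold_ratio = ratio,
    flagged = !is.finite(ratio) | ratio < 1
  )
}
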