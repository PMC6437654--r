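#' Balanced z-score normalization of one slant's responses
#'
#' Standardizes responses so that choice imbalance within the slant does not
#' bias the pooled distributions: the center is the mean of the two
#' choice-conditional means and the scale is the SD of the equal-weight
#' mixture of the two choice distributions,
#' `scale^2 = (v_pref + v_nonpref) / 2 + (m_pref - m_nonpref)^2 / 4`
#' (population-denominator variances). When the two choices are equally
#' frequent this reduces exactly to the ordinary (population-SD) z-score.
#'
#' @param responses Numeric responses of one slant's trials.
#' @param is_pref Logical, TRUE where the choice favored the neuron's
#'   preferred slant sign; both values must be represented.
#' @return Normalized responses, or all-`NA` (with a warning) when the
#'   balanced scale is zero.
#' @export
balanced_zscore <- function(responses, is_pref) {
  stopifnot(length(responses) == length(is_pref))
  if (!any(is_pref) || !any(!is_pref)) {
    abort("both choice directions must be represented within the slant")
  }
  pvar <- function(v) mean((v - mean(v))^2)
  m1 <- mean(responses[is_pref]); m2 <- mean(responses[!is_pref])
  v1 <- pvar(responses[is_pref]); v2 <- pvar(responses[!is_pref])
  center <- (m1 + m2) / 2
  scale <- sqrt((v1 + v2) / 2 + (m1 - m2)^2 / 4)
  if (scale == 0) {
    warn("zero balanced SD within slant; responses set to NA")
    return(rep(NA_real_, length(responses)))
  }
  (responses - center) / scale
}

# grand CP on raw vectors: balanced z-score per slant, pool, ROC area
# between nonpreferred- and preferred-choice composites
grand_cp_core <- function(responses, slant, is_pref, min_choices = 3L,
                          warn_zero_scale = TRUE) {
  groups <- split(seq_along(responses), slant)
  book <- tibble::tibble(
    slant_deg = as.numeric(names(groups)),
    n_pref_choices = vapply(groups, function(i) sum(is_pref[i]), integer(1)),
    n_nonpref_choices = vapply(groups, function(i) sum(!is_pref[i]), integer(1))
  )
  book$included <- book$n_pref_choices >= min_choices &
    book$n_nonpref_choices >= min_choices
  z <- c(); zp <- c()
  for (j in which(book$included)) {
    i <- groups[[j]]
    zi <- withCallingHandlers(
      balanced_zscore(responses[i], is_pref[i]),
      warning = function(w) if (!warn_zero_scale) invokeRestart("muffleWarning"))
    if (all(is.na(zi))) {
      book$included[j] <- FALSE
      next
    }
    z <- c(z, zi); zp <- c(zp, is_pref[i])
  }
  if (!any(book$included)) {
    abort(paste0("no slant passes the inclusion rule (>= ", min_choices,
                 " choices in each direction)"))
  }
  list(cp = roc_auc(z[!zp], z[zp]), included = book, n_trials_used = length(z))
}

# map session choices to preferred/nonpreferred given the fixation sign
session_choice_frame <- function(x) {
  tr <- session_trials(x, task = "discrimination")
  if (nrow(tr) == 0) abort("session has no discrimination trials")
  pref_choice <- preferred_choice_label(x$preferred_sign_fixation)
  tibble::tibble(slant_deg = tr$slant_deg,
                 response = as.numeric(tr$spike_count),
                 is_pref = tr$choice == pref_choice,
                 choice = tr$choice)
}

#' Choice probability at the ambiguous (0-degree) slant
#'
#' ROC area between the response distributions for nonpreferred- and
#' preferred-sign choices on 0-degree-slant trials. Values above 0.5 mean
#' the neuron fired more when the animal chose its preferred slant sign. The
#' preferred sign always comes from the fixation task.
#'
#' @param x A `slant_session`.
#' @return CP in `[0, 1]`, or `NA` (with a warning) when either choice group
#'   at 0 degrees is empty -- an undefined CP is reported as missing, not as
#'   chance.
#' @export
cp_zero_slant <- function(x) {
  cf <- session_choice_frame(x)
  cf <- cf[cf$slant_deg == 0, , drop = FALSE]
  if (nrow(cf) == 0 || !any(cf$is_pref) || !any(!cf$is_pref)) {
    warn("0-degree CP undefined: a choice group is empty")
    return(NA_real_)
  }
  roc_auc(cf$response[!cf$is_pref], cf$response[cf$is_pref])
}

#' Grand choice probability of a session
#'
#' Pools balanced-z-scored responses across every slant for which the animal
#' made at least `min_choices` choices in each direction, then computes the
#' ROC area between the preferred- and nonpreferred-choice composite
#' distributions. Also records the 0-degree CP when defined and the
#' inclusion bookkeeping.
#'
#' @param x A `slant_session` with a known fixation slant-preference sign.
#' @param min_choices Per-slant minimum number of choices in each direction
#'   (default 3).
#' @return A list of class `cp_result`.
#' @export
grand_cp <- function(x, min_choices = 3L) {
  cf <- session_choice_frame(x)
  core <- grand_cp_core(cf$response, cf$slant_deg, cf$is_pref, min_choices)
  cp0 <- tryCatch(suppressWarnings(cp_zero_slant(x)), error = function(e) NA_real_)
  structure(list(
    neuron_id = x$neuron_id, area = x$area,
    cp_zero = cp0, grand_cp = core$cp,
    p_perm = NA_real_, n_permutations = 0L,
    included_slants = core$included,
    preferred_sign_source = "fixation_task",
    preferred_sign = x$preferred_sign_fixation,
    n_trials_used = core$n_trials_used
  ), class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("<cp_result> neuron %s (%s): grand CP %.3f (0-deg CP %s), %d trials over %d slants",
              x$neuron_id, x$area, x$grand_cp,
              ifelse(is.na(x$cp_zero), "NA", sprintf("%.3f", x$cp_zero)),
              x$n_trials_used, sum(x$included_slants$included)))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g (%d perms)",
                                    x$p_perm, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Permutation test of the grand choice probability
#'
#' Shuffles choice labels within each slant (preserving every slant's choice
#' counts, hence the inclusion set), recomputes the grand CP for each
#' permutation, and reports the two-sided p-value for a departure from
#' chance: the fraction of permutations with `|CP - 0.5|` at least as large
#' as observed, with add-one smoothing in numerator and denominator (so the
#' smallest attainable p is `1 / (n_perm + 1)`).
#'
#' @param x A `slant_session`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param min_choices Inclusion rule passed to the grand CP.
#' @return A `cp_result` with `p_perm`, `n_permutations`, and the permuted
#'   CPs in attribute `"perm_cps"`.
#' @export
permutation_test_cp <- function(x, n_perm = 1000L, seed = 1L,
                                min_choices = 3L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  res <- grand_cp(x, min_choices)
  cf <- session_choice_frame(x)
  keep_slants <- res$included_slants$slant_deg[res$included_slants$included]
  cf <- cf[cf$slant_deg %in% keep_slants, , drop = FALSE]
  groups <- split(seq_len(nrow(cf)), cf$slant_deg)
  obs <- abs(res$grand_cp - 0.5)
  set.seed(seed)
  perm_cps <- vapply(seq_len(n_perm), function(k) {
    lab <- cf$is_pref
    for (i in groups) lab[i] <- lab[i][sample.int(length(i))]
    out <- tryCatch(
      grand_cp_core(cf$response, cf$slant_deg, lab, min_choices,
                    warn_zero_scale = FALSE)$cp,
      error = function(e) NA_real_)
    out
  }, numeric(1))
  ok <- !is.na(perm_cps)
  res$p_perm <- (1 + sum(abs(perm_cps[ok] - 0.5) >= obs - 1e-12)) / (sum(ok) + 1)
  res$n_permutations <- as.integer(n_perm)
  res$seed <- seed
  attr(res, "perm_cps") <- perm_cps
  res
}

#' Population relationship between choice probability and neuronal threshold
#'
#' Per brain area, the Pearson correlation between the comparison threshold
#' (twice the neurometric SD) and the grand CP, with the linear-fit slope and
#' its 95% CI; across areas, an analysis of covariance with CP as the
#' dependent variable, threshold as a continuous covariate, and area as a
#' factor, reporting the threshold-by-area interaction p (a test of whether
#' the CP-threshold relationship differs between areas).
#'
#' @param population Data frame with columns `neuron_id`, `area`,
#'   `grand_cp`, `comparison_threshold_deg` (non-finite thresholds are
#'   dropped with a warning).
#' @param min_per_area Minimum neurons per area (default 5).
#' @return A list with `per_area` (tibble: area, n, r, p, slope and CI) and
#'   `ancova_interaction_p`.
#' @export
cp_vs_threshold <- function(population, min_per_area = 5L) {
  pop <- tibble::as_tibble(population)
  stopifnot(all(c("area", "grand_cp", "comparison_threshold_deg") %in% names(pop)))
  bad <- !is.finite(pop$comparison_threshold_deg)
  if (any(bad)) {
    warn(sprintf("dropping %d neuron(s) with non-finite thresholds", sum(bad)))
    pop <- pop[!bad, , drop = FALSE]
  }
  if (any(table(pop$area) < min_per_area)) {
    abort(sprintf("need >= %d neurons per area", min_per_area))
  }
  per_area <- dplyr::group_modify(dplyr::group_by(pop, .data$area), function(d, g) {
    if (sd(d$comparison_threshold_deg) == 0) {
      abort("degenerate (constant) thresholds within an area")
    }
    ct <- suppressWarnings(stats::cor.test(d$comparison_threshold_deg, d$grand_cp))
    fit <- lm(grand_cp ~ comparison_threshold_deg, data = d)
    ci <- stats::confint(fit)["comparison_threshold_deg", ]
    tibble::tibble(n = nrow(d), r = unname(ct$estimate), p = ct$p.value,
                   slope = unname(coef(fit)[2]),
                   slope_lo = ci[1], slope_hi = ci[2])
  })
  ancova_p <- NA_real_
  if (length(unique(pop$area)) >= 2) {
    fit <- lm(grand_cp ~ comparison_threshold_deg * factor(area), data = pop)
    tab <- anova(fit)
    ancova_p <- tab[grepl(":", rownames(tab)), "Pr(>F)"][1]
  }
  list(per_area = dplyr::ungroup(per_area), ancova_interaction_p = ancova_p)
}
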