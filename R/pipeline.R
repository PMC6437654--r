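#' Pipeline configuration
#'
#' @param n_permutations Permutations for the grand-CP null (>= 1).
#' @param n_bootstrap Bootstrap resamples for ellipse-angle CIs.
#' @param window A [window_spec()] for time-course analyses.
#' @param seed Base random seed; per-neuron permutation seeds are derived
#'   from it and recorded in every output.
#' @param min_reps Per-slant repetition gate for discrimination eligibility.
#' @param min_choices Per-slant choice gate for the grand CP.
#' @param run_timecourse Compute sliding-window time courses (needs spike
#'   times on every trial)?
#' @param run_controls Run eye-covariate controls where covariates exist?
#' @param output_dir Optional directory for JSON/TSV outputs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_permutations = 1000L, n_bootstrap = 1000L,
                            window = window_spec(), seed = 1L,
                            min_reps = 10L, min_choices = 3L,
                            run_timecourse = FALSE, run_controls = TRUE,
                            output_dir = NULL) {
  if (n_permutations < 1) abort("config error: n_permutations must be >= 1")
  if (n_bootstrap < 1) abort("config error: n_bootstrap must be >= 1")
  structure(list(n_permutations = as.integer(n_permutations),
                 n_bootstrap = as.integer(n_bootstrap),
                 window = window, seed = as.integer(seed),
                 min_reps = as.integer(min_reps),
                 min_choices = as.integer(min_choices),
                 run_timecourse = run_timecourse,
                 run_controls = run_controls,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full per-neuron and population analysis pipeline
#'
#' For every session: the discrimination eligibility gate (repetitions per
#' slant), the psychometric fit, the neurometric curve and threshold, the
#' grand CP with its permutation test, and the partial-correlation
#' decomposition. Population summaries follow: mean grand CP per area, the
#' CP-vs-threshold regression and area ANCOVA (when each area has enough
#' neurons), confidence ellipses over the partial-correlation plane, and,
#' optionally, sliding-window time courses and eye-covariate controls.
#' Every gate decision is logged in the report.
#'
#' @param sessions A list of `slant_session` objects, or a character vector
#'   of trial-table paths read with [read_session()].
#' @param config A [pipeline_config()].
#' @return A list of class `slantchoice_report` with `per_neuron` (tibble),
#'   `population`, `gates` (tibble of gate decisions), `config`, and
#'   `exit_status` (nonzero when no session passed the gates).
#' @export
run_pipeline <- function(sessions, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(sessions)) sessions <- lapply(sessions, read_session)
  if (inherits(sessions, "slant_session")) sessions <- list(sessions)
  gates <- list(); rows <- list(); kept <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    elig <- session_is_eligible(s, config$min_reps)
    reps <- attr(elig, "reps")
    sign_known <- s$preferred_sign_fixation %in% c("positive", "negative")
    gates[[i]] <- tibble::tibble(
      neuron_id = s$neuron_id, area = s$area,
      n_trials = nrow(s$trials),
      min_reps_per_slant = if (nrow(reps) > 0) min(reps$n) else 0L,
      eligible = as.logical(elig), preferred_sign_known = sign_known
    )
    if (!elig || !sign_known) next
    psy <- tryCatch(fit_psychometric(s), error = function(e) NULL)
    neu <- tryCatch(suppressWarnings(build_neurometric_curve(s, config$min_reps)),
                    error = function(e) NULL)
    cp <- tryCatch(suppressWarnings(
      permutation_test_cp(s, config$n_permutations,
                          seed = config$seed + i,
                          min_choices = config$min_choices)),
      error = function(e) NULL)
    pc <- tryCatch(partial_correlations(s), error = function(e) NULL)
    if (is.null(cp)) next
    kept[[length(kept) + 1]] <- s
    rows[[length(rows) + 1]] <- tibble::tibble(
      neuron_id = s$neuron_id, area = s$area, monkey_id = s$monkey_id,
      preferred_sign = s$preferred_sign_fixation,
      pse_deg = if (is.null(psy)) NA_real_ else psy$pse_deg,
      behavioral_threshold_deg = if (is.null(psy)) NA_real_ else psy$threshold_deg,
      neuronal_threshold_deg = if (is.null(neu)) NA_real_ else neu$neuronal_threshold_deg,
      comparison_threshold_deg = if (is.null(neu)) NA_real_ else neu$comparison_threshold_deg,
      threshold_ratio = if (is.null(neu) || is.null(psy)) NA_real_ else
        neu$comparison_threshold_deg / psy$threshold_deg,
      cp_zero = cp$cp_zero, grand_cp = cp$grand_cp, p_perm = cp$p_perm,
      r_FS_C = if (is.null(pc)) NA_real_ else pc$r_FS_C,
      r_FC_S = if (is.null(pc)) NA_real_ else pc$r_FC_S,
      quadrant = if (is.null(pc)) NA_character_ else pc$quadrant,
      seed = config$seed + i
    )
  }
  gates <- dplyr::bind_rows(gates)
  per_neuron <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  population <- list()
  exit_status <- 0L
  if (nrow(per_neuron) == 0) {
    warn("zero eligible neurons: population section is empty")
    exit_status <- 1L
  } else {
    population$mean_grand_cp <- dplyr::summarise(
      dplyr::group_by(per_neuron, .data$area),
      n = dplyr::n(), mean_grand_cp = mean(.data$grand_cp),
      sem = sd(.data$grand_cp) / sqrt(dplyr::n()),
      frac_significant = mean(.data$p_perm < 0.05), .groups = "drop")
    population$cp_vs_threshold <- tryCatch(
      suppressWarnings(cp_vs_threshold(per_neuron)), error = function(e) NULL)
    population$ellipses <- tryCatch(
      fit_cp_ellipses(per_neuron, n_boot = config$n_bootstrap,
                      seed = config$seed),
      error = function(e) NULL)
    if (config$run_timecourse) {
      population$timecourse <- tryCatch(list(
        cp = metric_timecourse(kept, "cp", config$window, config$min_choices),
        spc2 = metric_timecourse(kept, "spc2", config$window),
        cpc2 = metric_timecourse(kept, "cpc2", config$window),
        sdf = compute_sdf(kept, config$window)
      ), error = function(e) NULL)
    }
    if (config$run_controls) {
      has_cov <- vapply(kept, function(s)
        all(c("eye_vpos_deg", "eye_vvel_deg_s", "vergence_deg") %in%
              names(s$trials)), logical(1))
      if (any(has_cov)) {
        population$eye_controls <- lapply(
          c("eye_vpos_deg", "eye_vvel_deg_s", "vergence_deg"),
          function(v) tryCatch(
            suppressWarnings(eye_ancova_and_detrend(kept[has_cov], v,
                                                    config$min_choices)),
            error = function(e) NULL))
        names(population$eye_controls) <-
          c("eye_vpos_deg", "eye_vvel_deg_s", "vergence_deg")
      }
    }
  }
  report <- structure(list(per_neuron = per_neuron, population = population,
                           gates = gates, config = config,
                           exit_status = exit_status),
                      class = "slantchoice_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(per_neuron) > 0) {
      write_results(per_neuron, file.path(config$output_dir, "per_neuron.tsv"))
    }
    write_results(gates, file.path(config$output_dir, "gates.tsv"))
    if (!is.null(population$mean_grand_cp)) {
      write_results(population$mean_grand_cp,
                    file.path(config$output_dir, "population_cp.tsv"))
    }
    summary_json <- list(
      seed = config$seed, n_permutations = config$n_permutations,
      n_sessions = length(sessions), n_analyzed = nrow(per_neuron),
      exit_status = exit_status)
    write_results(summary_json, file.path(config$output_dir, "summary.json"))
  }
  report
}

#' @export
print.slantchoice_report <- function(x, ...) {
  cat(sprintf("<slantchoice_report> %d sessions, %d analyzed (seed %d)\n",
              nrow(x$gates), nrow(x$per_neuron), x$config$seed))
  if (!is.null(x$population$mean_grand_cp)) {
    print(x$population$mean_grand_cp)
  } else cat("  population section empty\n")
  invisible(x)
}
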