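#' Session and trial data model
#'
#' A *session* holds every trial recorded from one neuron together with its
#' metadata. Trials live in a tibble with one row per stimulus presentation;
#' the remaining fields describe the neuron and the timing of the task.
#'
#' Two task types exist. In the *fixation* task a planar checkerboard is shown
#' at one of 25 slant-tilt combinations (slants 0-60 deg in 20 deg steps,
#' tilts 0-315 deg in 45 deg steps; slant 0 collapses all tilts into a single
#' frontoparallel condition) while the animal only fixates, so `choice` is
#' always `"none"`. In the *discrimination* task a random-dot plane is slanted
#' about the 90/270 deg tilt axis and the animal reports the slant sign.
#' Signed slants follow the convention that tilt 90 deg (top of the plane
#' nearer) is negative and tilt 270 deg (top further) is positive, so
#' `choice = "top_far"` is the correct report for positive slants.
#'
#' @param trials Data frame of trials, one row per presentation. Required
#'   columns: `trial_id`, `task`, `slant_deg`, `tilt_deg`, `depth_cm`,
#'   `choice`, `spike_count`. Optional: `spike_times_ms` (list column of
#'   numeric vectors, ms from stimulus onset), `eye_vpos_deg`,
#'   `eye_vvel_deg_s`, `vergence_deg` (trial-mean eye covariates).
#' @param neuron_id,monkey_id Identifier strings.
#' @param area Brain area label, `"CIP"` or `"V3A"`.
#' @param stim_dur_ms Stimulus duration in ms (default 1000). Spike counts are
#'   taken over the half-open window `[0, stim_dur_ms)`.
#' @param preferred_sign_fixation Slant-preference sign along the 90/270 deg
#'   tilt axis measured during fixation: `"positive"`, `"negative"`, or
#'   `"unknown"`. Choice-probability analyses require a known sign.
#' @param slant_ladder_deg Optional numeric vector of signed slants used in
#'   the discrimination task; defaults to the slants present in the data.
#'
#' @return An object of class `slant_session`.
#' @export
#' @examples
#' gt <- make_ground_truth(seed = 1)
#' s <- simulate_discrimination_session(gt, n_reps_per_slant = 12, seed = 2)
#' s
session <- function(trials,
                    neuron_id = "n001",
                    area = c("CIP", "V3A"),
                    monkey_id = "m1",
                    stim_dur_ms = 1000L,
                    preferred_sign_fixation = c("unknown", "positive", "negative"),
                    slant_ladder_deg = NULL) {
  area <- match.arg(area)
  preferred_sign_fixation <- match.arg(preferred_sign_fixation)
  trials <- tibble::as_tibble(trials)
  x <- structure(
    list(
      neuron_id = as.character(neuron_id),
      area = area,
      monkey_id = as.character(monkey_id),
      stim_dur_ms = as.integer(stim_dur_ms),
      preferred_sign_fixation = preferred_sign_fixation,
      slant_ladder_deg = slant_ladder_deg,
      trials = trials
    ),
    class = "slant_session"
  )
  validate_session(x)
}

.choice_levels <- c("top_near", "top_far", "none")
.task_levels <- c("fixation", "discrimination")
.depth_levels <- c(-2.25, 0, 2.25)
.fix_slants <- c(0, 20, 40, 60)
.fix_tilts <- seq(0, 315, by = 45)

#' Validate a session
#'
#' Checks the structural invariants of the trial table: required columns,
#' enum values, unique trial ids, the choice/task pairing (`choice == "none"`
#' iff the trial is a fixation trial), depth levels, ladder membership of
#' discrimination slants, and agreement between `spike_count` and the number
#' of entries of `spike_times_ms` inside `[0, stim_dur_ms)`. Problems are
#' reported with the offending row numbers.
#'
#' @param x A `slant_session`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error is thrown.
#' @export
validate_session <- function(x) {
  stopifnot(inherits(x, "slant_session"))
  tr <- x$trials
  required <- c("trial_id", "task", "slant_deg", "tilt_deg", "depth_cm",
                "choice", "spike_count")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols) > 0) {
    abort(paste0("schema error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "slantchoice_schema_error")
  }
  if (x$stim_dur_ms <= 0) abort("stim_dur_ms must be positive")
  bad_rows <- function(idx, what) {
    if (any(idx)) {
      abort(paste0("validation error: ", what, " (rows ",
                   paste(head(which(idx), 5), collapse = ", "),
                   if (sum(idx) > 5) ", ..." else "", ")"),
            class = "slantchoice_validation_error")
    }
  }
  if (!all(tr$task %in% .task_levels)) {
    abort(paste0("schema error: task must be one of {",
                 paste(.task_levels, collapse = ", "), "}; found: ",
                 paste(unique(setdiff(tr$task, .task_levels)), collapse = ", ")),
          class = "slantchoice_schema_error")
  }
  if (!all(tr$choice %in% .choice_levels)) {
    abort(paste0("schema error: choice must be one of {",
                 paste(.choice_levels, collapse = ", "), "}; found: ",
                 paste(unique(setdiff(tr$choice, .choice_levels)), collapse = ", ")),
          class = "slantchoice_schema_error")
  }
  bad_rows(duplicated(tr$trial_id), "duplicate trial_id")
  bad_rows(tr$task == "fixation" & tr$choice != "none",
           "choice present on fixation trial")
  bad_rows(tr$task == "discrimination" & tr$choice == "none",
           "discrimination trial without a choice")
  bad_rows(!is.na(tr$depth_cm) & !tr$depth_cm %in% .depth_levels,
           "depth_cm outside {-2.25, 0, 2.25}")
  bad_rows(tr$spike_count < 0 | tr$spike_count != round(tr$spike_count),
           "spike_count must be a non-negative integer")
  is_fix <- tr$task == "fixation"
  bad_rows(is_fix & !tr$slant_deg %in% .fix_slants,
           "fixation slant_deg outside {0, 20, 40, 60}")
  bad_rows(is_fix & tr$slant_deg > 0 & !tr$tilt_deg %in% .fix_tilts,
           "fixation tilt_deg outside the 45-degree grid")
  ladder <- x$slant_ladder_deg %||%
    sort(unique(tr$slant_deg[tr$task == "discrimination"]))
  bad_rows(tr$task == "discrimination" & !tr$slant_deg %in% ladder,
           "discrimination slant_deg outside the session's slant ladder")
  if ("spike_times_ms" %in% names(tr)) {
    n_in_win <- vapply(tr$spike_times_ms, function(st) {
      if (is.null(st) || all(is.na(st))) return(NA_integer_)
      sum(st >= 0 & st < x$stim_dur_ms)
    }, integer(1))
    bad_rows(!is.na(n_in_win) & n_in_win != tr$spike_count,
             "spike_count does not match spike_times_ms within [0, stim_dur_ms)")
  }
  invisible(x)
}

#' @export
print.slant_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("<slant_session> neuron %s (%s, monkey %s)\n",
              x$neuron_id, x$area, x$monkey_id))
  cat(sprintf("  %d trials (%d fixation, %d discrimination), stim %d ms\n",
              nrow(tr), sum(tr$task == "fixation"),
              sum(tr$task == "discrimination"), x$stim_dur_ms))
  cat(sprintf("  fixation slant preference: %s\n", x$preferred_sign_fixation))
  invisible(x)
}

#' Trial table of a session as a tibble
#'
#' @param x A `slant_session`.
#' @param task Optionally restrict to `"fixation"` or `"discrimination"` trials.
#' @return A tibble of trials.
#' @export
session_trials <- function(x, task = NULL) {
  stopifnot(inherits(x, "slant_session"))
  tr <- x$trials
  if (!is.null(task)) tr <- tr[tr$task == task, , drop = FALSE]
  tibble::as_tibble(tr)
}

#' Discrimination-task eligibility of a session
#'
#' A session enters the discrimination analyses only if every slant of its
#' ladder was presented at least `min_reps` times (default 10).
#'
#' @param x A `slant_session`.
#' @param min_reps Minimum repetitions per slant.
#' @return Logical scalar with attribute `"reps"` (a tibble of per-slant counts).
#' @export
session_is_eligible <- function(x, min_reps = 10L) {
  tr <- session_trials(x, task = "discrimination")
  if (nrow(tr) == 0) {
    out <- FALSE
    attr(out, "reps") <- tibble::tibble(slant_deg = numeric(), n = integer())
    return(out)
  }
  reps <- dplyr::count(tr, .data$slant_deg)
  ladder <- x$slant_ladder_deg %||% sort(unique(tr$slant_deg))
  ok <- all(ladder %in% reps$slant_deg) && all(reps$n >= min_reps)
  out <- ok
  attr(out, "reps") <- reps
  out
}

# signed slant -> (slant, tilt) unit surface normal; frontoparallel is (0,0,1)
signed_slant_to_normal <- function(signed_slant_deg) {
  tilt <- ifelse(signed_slant_deg < 0, 90, 270)
  slant_tilt_to_normal(abs(signed_slant_deg), tilt)
}

slant_tilt_to_normal <- function(slant_deg, tilt_deg) {
  s <- slant_deg * pi / 180
  t <- tilt_deg * pi / 180
  cbind(sin(s) * cos(t), sin(s) * sin(t), cos(s))
}

# preferred/nonpreferred choice label for a session's fixation sign
preferred_choice_label <- function(preferred_sign) {
  switch(preferred_sign,
         positive = "top_far",
         negative = "top_near",
         abort("preferred_sign_fixation must be known (positive or negative) for choice analyses"))
}
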