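#' Observer model configuration
#'
#' The behavioral model is a noisy sign-discriminator: on a trial with signed
#' slant `s` the observer forms a decision variable
#' `d = (s - bias_deg) / sensory_sigma_deg + rho * eta + sqrt(1 - rho^2) * nu`
#' with independent standard-normal `eta` and `nu`, and reports "top-far" when
#' `d > 0`; a lapse flips the report with probability `lapse_rate`. `eta` is
#' the component of decision noise shared with the simulated neuron's count
#' fluctuation, so `coupling_rho` sets the trial-level correlation between the
#' neuron's standardized stimulus-window count noise and the decision noise --
#' the generative knob behind choice probability. The shared component is
#' injected congruently with the neuron's slant-preference sign, so positive
#' `coupling_rho` always pushes choice probability above 0.5.
#'
#' This construction yields `P(top_far | s) = Phi((s - bias_deg) / sigma)` (up
#' to lapses), i.e. a cumulative-Gaussian psychometric function whose mean is
#' `bias_deg` (the point of subjective equality) and whose SD is
#' `sensory_sigma_deg` (the behavioral threshold).
#'
#' @param sensory_sigma_deg Behavioral threshold scale, degrees (> 0).
#' @param bias_deg Point-of-subjective-equality offset, degrees.
#' @param lapse_rate Probability of flipping the report, in `[0, 0.5)`.
#' @param coupling_rho Neuron-choice coupling in `[-1, 1]`.
#' @param coupling_onset_ms Time after stimulus onset at which the shared
#'   component enters the neuron's spiking (0 = throughout the trial).
#' @param slant_ladder_deg Symmetric signed-slant ladder including 0. The
#'   default is the ladder used for monkeys N and Z; `preset = "P"` selects
#'   the monkey-P ladder (20, 9, 4.05, 1.83, 0.82, 0 and their negatives).
#' @param depth_mixture Named proportions over depths -2.25, 0, +2.25 cm;
#'   default 15/70/15 (screen distance on 70% of trials).
#' @param preset Ladder preset, `"NZ"` or `"P"`.
#' @return A list of class `observer_config`.
#' @export
observer_config <- function(sensory_sigma_deg = 3.6,
                            bias_deg = 0,
                            lapse_rate = 0,
                            coupling_rho = 0,
                            coupling_onset_ms = 0,
                            slant_ladder_deg = NULL,
                            depth_mixture = c(`-2.25` = 0.15, `0` = 0.70, `2.25` = 0.15),
                            preset = c("NZ", "P")) {
  preset <- match.arg(preset)
  if (is.null(slant_ladder_deg)) {
    half <- if (preset == "NZ") c(1.25, 2.5, 5, 10, 20) else c(0.82, 1.83, 4.05, 9, 20)
    slant_ladder_deg <- sort(c(-half, 0, half))
  }
  stopifnot(sensory_sigma_deg > 0, lapse_rate >= 0, lapse_rate < 0.5,
            abs(coupling_rho) <= 1)
  if (abs(sum(depth_mixture) - 1) > 1e-9) abort("depth_mixture must sum to 1")
  if (max(abs(sort(slant_ladder_deg) + rev(sort(slant_ladder_deg)))) > 1e-9) {
    abort("slant_ladder_deg must be symmetric about 0")
  }
  structure(list(
    sensory_sigma_deg = sensory_sigma_deg, bias_deg = bias_deg,
    lapse_rate = lapse_rate, coupling_rho = coupling_rho,
    coupling_onset_ms = coupling_onset_ms,
    slant_ladder_deg = sort(slant_ladder_deg),
    depth_mixture = depth_mixture
  ), class = "observer_config")
}

#' Bingham tuning parameters
#'
#' Unimodal tuning over unit surface normals:
#' `R(n) = A * exp(lambda1 * (v1 . n)^2 + lambda2 * (v2 . n)^2) + B`
#' with concentrations `lambda1 <= lambda2 <= 0` and orthonormal axes
#' `v1`, `v2`. The peak direction is `v3 = v1 x v2`, where the exponent is 0.
#'
#' @param amplitude Peak-minus-baseline response `A >= 0` (Hz).
#' @param baseline Baseline response `B >= 0` (Hz).
#' @param lambda1,lambda2 Concentrations, `lambda1 <= lambda2 <= 0`.
#' @param v1,v2 Orthonormal unit 3-vectors.
#' @return A list of class `bingham_params` with derived `peak` direction and
#'   `preferred_slant_deg` / `preferred_tilt_deg`.
#' @export
bingham_params <- function(amplitude, baseline, lambda1, lambda2, v1, v2) {
  stopifnot(amplitude >= 0, baseline >= 0, lambda1 <= lambda2 + 1e-12,
            lambda2 <= 1e-12)
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  if (abs(sum(v1 * v2)) > 1e-8) abort("v1 and v2 must be orthogonal")
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (v3[3] < 0) v3 <- -v3  # report the peak on the viewing hemisphere
  slant <- acos(pmin(1, pmax(-1, v3[3]))) * 180 / pi
  tilt <- (atan2(v3[2], v3[1]) * 180 / pi) %% 360
  structure(list(amplitude = amplitude, baseline = baseline,
                 lambda1 = lambda1, lambda2 = lambda2, v1 = v1, v2 = v2,
                 peak = v3, preferred_slant_deg = slant,
                 preferred_tilt_deg = tilt),
            class = "bingham_params")
}

# evaluate a bingham_params tuning profile at unit normals (rows)
bingham_rate <- function(bp, normals) {
  q1 <- as.vector(normals %*% bp$v1)
  q2 <- as.vector(normals %*% bp$v2)
  bp$amplitude * exp(bp$lambda1 * q1^2 + bp$lambda2 * q2^2) + bp$baseline
}

#' Sample a reproducible ground truth for a synthetic neuron
#'
#' Draws tuning, rate, noise-model, and observer parameters from the ranges in
#' `spec`. Preferred directions are sampled uniformly on the hemisphere by
#' default; `slant_bias > 0` concentrates preferences at small slants (the
#' preferred-slant cosine is the maximum of `slant_bias + 1` uniforms).
#'
#' @param spec Named list overriding any of: `baseline_hz` (range),
#'   `gain_hz` (range), `lambda_range` (range, negative), `slant_bias`
#'   (integer >= 0), `noise_model` (`"poisson"` or `"gaussian"`),
#'   `fano_factor` (> 0, Gaussian model only), `observer` (an
#'   [observer_config()] or a list of overrides for one).
#' @param seed Integer seed; the same seed always yields the same ground truth.
#' @return A list of class `ground_truth`.
#' @export
make_ground_truth <- function(spec = list(), seed = 1L) {
  defaults <- list(
    baseline_hz = c(5, 15), gain_hz = c(20, 60), lambda_range = c(-6, -1.5),
    slant_bias = 0L, noise_model = "poisson", fano_factor = 1,
    observer = observer_config()
  )
  bad <- setdiff(names(spec), names(defaults))
  if (length(bad) > 0) abort(paste0("unknown ground-truth spec field(s): ",
                                    paste(bad, collapse = ", ")))
  spec <- modifyList(defaults, spec)
  rng_ok <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] <= r[2]
  if (!rng_ok(spec$baseline_hz) || !rng_ok(spec$gain_hz) ||
      !rng_ok(spec$lambda_range)) {
    abort("config error: parameter ranges must be finite length-2 [lo, hi]")
  }
  if (!spec$noise_model %in% c("poisson", "gaussian")) {
    abort("noise_model must be 'poisson' or 'gaussian'")
  }
  if (spec$fano_factor <= 0) abort("fano_factor must be > 0")
  if (!inherits(spec$observer, "observer_config")) {
    spec$observer <- do.call(observer_config, spec$observer)
  }
  set.seed(seed)
  # preferred direction: tilt uniform; cos(slant) = max of (slant_bias+1) uniforms
  u <- max(runif(spec$slant_bias + 1))
  slant <- acos(u) * 180 / pi
  tilt <- runif(1, 0, 360)
  v3 <- as.vector(slant_tilt_to_normal(slant, tilt))
  # orthonormal complement with a random roll about the peak
  ref <- if (abs(v3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a <- ref - sum(ref * v3) * v3; a <- a / sqrt(sum(a^2))
  b <- c(v3[2] * a[3] - v3[3] * a[2], v3[3] * a[1] - v3[1] * a[3],
         v3[1] * a[2] - v3[2] * a[1])
  roll <- runif(1, 0, 2 * pi)
  v1 <- cos(roll) * a + sin(roll) * b
  v2 <- -sin(roll) * a + cos(roll) * b
  lam <- sort(runif(2, spec$lambda_range[1], spec$lambda_range[2]))
  baseline <- runif(1, spec$baseline_hz[1], spec$baseline_hz[2])
  gain <- runif(1, spec$gain_hz[1], spec$gain_hz[2])
  tuning <- bingham_params(gain, baseline, lam[1], lam[2], v1, v2)
  structure(list(
    tuning = tuning, baseline_hz = baseline, gain_hz = gain,
    noise_model = spec$noise_model, fano_factor = spec$fano_factor,
    observer = spec$observer, seed = seed
  ), class = "ground_truth")
}

# slant-preference sign along the 90/270 tilt axis implied by the tuning
ground_truth_pref_sign <- function(gt, probe_deg = 20) {
  r <- bingham_rate(gt$tuning, signed_slant_to_normal(c(-probe_deg, probe_deg)))
  if (r[2] >= r[1]) "positive" else "negative"
}

# draw integer counts around mean mu given the noise model, via the latent
# standard-normal z (gaussian copula for poisson counts)
draw_counts <- function(mu, z, noise_model, fano_factor) {
  if (noise_model == "poisson") {
    qpois(pnorm(z), mu)
  } else {
    pmax(0L, as.integer(round(mu + sqrt(fano_factor * mu) * z)))
  }
}

#' Simulate a fixation (tuning-measurement) session
#'
#' One trial per repetition of each of the 25 unique slant-tilt conditions
#' (slants 0-60 deg in 20 deg steps crossed with tilts 0-315 deg in 45 deg
#' steps; slant 0 collapses to a single frontoparallel condition), presented
#' in pseudo-random order. Counts over the 1000-ms window are drawn from the
#' ground truth's noise model around the Bingham tuning rate.
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_reps Repetitions per condition (>= 1).
#' @param seed Integer seed.
#' @return A `slant_session` with `25 * n_reps` fixation trials.
#' @export
simulate_fixation_session <- function(gt, n_reps = 3L, seed = 1L) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_reps < 1) abort("n_reps must be >= 1")
  set.seed(seed)
  conds <- rbind(
    data.frame(slant_deg = 0, tilt_deg = NA_real_),
    expand.grid(slant_deg = c(20, 40, 60), tilt_deg = seq(0, 315, by = 45))
  )
  tr <- conds[rep(seq_len(nrow(conds)), each = n_reps), ]
  tr <- tr[sample.int(nrow(tr)), ]
  normals <- slant_tilt_to_normal(tr$slant_deg,
                                  ifelse(is.na(tr$tilt_deg), 0, tr$tilt_deg))
  mu <- bingham_rate(gt$tuning, normals)  # 1000 ms window -> rate in Hz = count
  z <- rnorm(nrow(tr))
  counts <- draw_counts(mu, z, gt$noise_model, gt$fano_factor)
  trials <- tibble::tibble(
    trial_id = seq_len(nrow(tr)),
    task = "fixation",
    slant_deg = tr$slant_deg,
    tilt_deg = tr$tilt_deg,
    depth_cm = 0,
    choice = "none",
    spike_count = as.integer(counts)
  )
  session(trials, neuron_id = sprintf("sim%05d", seed), area = "CIP",
          monkey_id = "sim", stim_dur_ms = 1000L,
          preferred_sign_fixation = ground_truth_pref_sign(gt))
}

#' Simulate a discrimination session
#'
#' Each slant of the observer's ladder is presented `n_reps_per_slant` times
#' in shuffled order, with mean depth drawn per trial from the 15/70/15
#' near/screen/far mixture. Choices come from the noisy observer of
#' [observer_config()]; the correct sign is rewarded, and 0-deg slants are
#' rewarded with probability 0.5. Spiking is generated in 50-ms bins over
#' `[0, 1250)` ms (extending 250 ms past stimulus offset so sliding-window
#' analyses have post-offset data): each bin's count is drawn around the
#' tuning-defined rate, and on bins at or after `coupling_onset_ms` the latent
#' noise contains the observer's shared component, weighted so the trial-level
#' correlation between the standardized stimulus-window count and the shared
#' decision noise equals `coupling_rho`. `spike_count` is the count in
#' `[0, 1000)` ms; spike times are placed uniformly within their bins.
#'
#' @param gt A [make_ground_truth()] object.
#' @param n_reps_per_slant Trials per ladder slant (>= 1).
#' @param seed Integer seed.
#' @param include_spike_times Keep per-trial spike times (needed for
#'   time-course analyses)? Counts are drawn before spike times, so turning
#'   this off does not change them.
#' @param rate_profile Optional function of time (ms, vectorized) returning a
#'   non-negative multiplicative rate gain; default is a flat profile.
#' @return A `slant_session` of discrimination trials with a `rewarded` column.
#' @export
simulate_discrimination_session <- function(gt, n_reps_per_slant = 40L,
                                            seed = 1L,
                                            include_spike_times = TRUE,
                                            rate_profile = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_reps_per_slant < 1) abort("n_reps_per_slant must be >= 1")
  ob <- gt$observer
  set.seed(seed)
  slants <- rep(ob$slant_ladder_deg, each = n_reps_per_slant)
  slants <- slants[sample.int(length(slants))]
  n <- length(slants)
  depths <- sample(as.numeric(names(ob$depth_mixture)), n, replace = TRUE,
                   prob = ob$depth_mixture)

  # observer
  eta <- rnorm(n)
  nu <- rnorm(n)
  rho <- ob$coupling_rho
  d <- (slants - ob$bias_deg) / ob$sensory_sigma_deg +
    rho * eta + sqrt(1 - rho^2) * nu
  choice_far <- d > 0
  if (ob$lapse_rate > 0) {
    flip <- runif(n) < ob$lapse_rate
    choice_far <- xor(choice_far, flip)
  }
  rewarded <- ifelse(slants == 0, runif(n) < 0.5,
                     choice_far == (slants > 0))

  # neuron: 50-ms bins over [0, 1250)
  bin_w <- 50
  bin_starts <- seq(0, 1200, by = bin_w)
  n_bins <- length(bin_starts)
  centers <- bin_starts + bin_w / 2
  stim_dur <- 1000
  in_stim <- bin_starts < stim_dur
  shared_bin <- centers >= ob$coupling_onset_ms
  Kc <- sum(in_stim)
  Ks <- sum(in_stim & shared_bin)
  # per-bin shared weight chosen so the stimulus-window count's standardized
  # fluctuation correlates with eta at rho (gaussian approximation)
  w <- if (rho == 0 || Ks == 0) 0 else {
    min(1, abs(rho) * sqrt(Kc) / (sqrt(Ks) * sqrt(Ks * (1 - rho^2) + rho^2)))
  }
  g <- if (ground_truth_pref_sign(gt) == "positive") 1 else -1
  rate_hz <- bingham_rate(gt$tuning, signed_slant_to_normal(slants))
  prof <- if (is.null(rate_profile)) rep(1, n_bins) else rate_profile(centers)
  mu_bin <- outer(rate_hz * bin_w / 1000, prof)          # n x n_bins
  xi <- matrix(rnorm(n * n_bins), n, n_bins)
  zsh <- w * g * sign(rho) * eta
  z <- xi
  if (w > 0) {
    z[, shared_bin] <- zsh + sqrt(1 - w^2) * xi[, shared_bin]
  }
  counts_bin <- matrix(draw_counts(as.vector(mu_bin), as.vector(z),
                                   gt$noise_model, gt$fano_factor),
                       n, n_bins)
  spike_count <- as.integer(rowSums(counts_bin[, in_stim, drop = FALSE]))

  trials <- tibble::tibble(
    trial_id = seq_len(n),
    task = "discrimination",
    slant_deg = slants,
    tilt_deg = NA_real_,
    depth_cm = depths,
    choice = ifelse(choice_far, "top_far", "top_near"),
    spike_count = spike_count,
    rewarded = rewarded
  )
  if (include_spike_times) {
    total <- rowSums(counts_bin)
    u <- runif(sum(total))
    starts_rep <- rep(rep(bin_starts, n), times = as.vector(t(counts_bin)))
    times <- starts_rep + u * bin_w
    idx <- rep(seq_len(n), times = total)
    trials$spike_times_ms <- unname(lapply(split(times, factor(idx, levels = seq_len(n))), sort))
  }
  session(trials, neuron_id = sprintf("sim%05d", seed), area = "CIP",
          monkey_id = "sim", stim_dur_ms = 1000L,
          preferred_sign_fixation = ground_truth_pref_sign(gt),
          slant_ladder_deg = ob$slant_ladder_deg)
}

#' Add simulated eye-movement covariates to a session
#'
#' Attaches trial-mean vertical eye position, vertical eye velocity, and
#' vergence to every trial. Each covariate is Gaussian noise plus an optional
#' shift with the choice (`choice_shift`, native units times the choice sign)
#' and can be injected linearly into the spike counts (`count_beta`, spikes
#' per unit covariate). Injected spikes are added to (or removed from) the
#' spike-time lists at uniform times so counts and times stay consistent. The
#' generating coefficients are recorded in the returned session's
#' `eye_ground_truth` field.
#'
#' @param x A `slant_session` with discrimination trials.
#' @param effect_sizes Named list with optional entries `choice_shift` and
#'   `count_beta`, each a named vector over
#'   `c("eye_vpos_deg", "eye_vvel_deg_s", "vergence_deg")`.
#' @param seed Integer seed.
#' @param sds Baseline SDs of the three covariates, native units.
#' @return The session with covariate columns added.
#' @export
simulate_eye_covariates <- function(x, effect_sizes = list(), seed = 1L,
                                    sds = c(eye_vpos_deg = 0.2,
                                            eye_vvel_deg_s = 2,
                                            vergence_deg = 0.2)) {
  stopifnot(inherits(x, "slant_session"))
  tr <- x$trials
  if (nrow(tr) == 0) abort("session has no trials")
  set.seed(seed)
  covs <- names(sds)
  shift <- effect_sizes$choice_shift %||% setNames(numeric(3), covs)
  beta <- effect_sizes$count_beta %||% setNames(numeric(3), covs)
  cc <- ifelse(tr$choice == "top_far", 1, ifelse(tr$choice == "top_near", -1, 0))
  n <- nrow(tr)
  for (v in covs) {
    tr[[v]] <- rnorm(n, 0, sds[[v]]) + (shift[v] %||% 0) * cc
  }
  delta <- rep(0, n)
  for (v in covs) {
    b <- beta[v] %||% 0
    if (!is.na(b) && b != 0) delta <- delta + b * tr[[v]]
  }
  if (any(delta != 0)) {
    new_count <- pmax(0L, as.integer(round(tr$spike_count + delta)))
    if ("spike_times_ms" %in% names(tr)) {
      tr$spike_times_ms <- lapply(seq_len(n), function(i) {
        st <- tr$spike_times_ms[[i]]
        in_win <- st >= 0 & st < x$stim_dur_ms
        cur <- sum(in_win)
        want <- new_count[i]
        if (want > cur) {
          sort(c(st, runif(want - cur, 0, x$stim_dur_ms)))
        } else if (want < cur) {
          drop <- sample(which(in_win), cur - want)
          sort(st[-drop])
        } else st
      })
    }
    tr$spike_count <- new_count
  }
  x$trials <- tr
  x$eye_ground_truth <- list(choice_shift = shift, count_beta = beta,
                             sds = sds, seed = seed)
  validate_session(x)
}

#' Simulate a population of discrimination sessions
#'
#' Convenience wrapper drawing one ground truth and one discrimination
#' session per neuron, with per-neuron seeds `seed_base + 1:n_neurons`.
#'
#' @param n_neurons Number of neurons.
#' @param spec Ground-truth spec passed to [make_ground_truth()].
#' @param n_reps_per_slant Trials per slant per neuron.
#' @param seed_base Base seed; neuron `i` uses `seed_base + i`.
#' @param include_spike_times Passed through to
#'   [simulate_discrimination_session()].
#' @param area Area label stamped on the sessions.
#' @return A list of `slant_session` objects.
#' @export
simulate_population <- function(n_neurons = 20L, spec = list(),
                                n_reps_per_slant = 40L, seed_base = 0L,
                                include_spike_times = FALSE, area = "CIP") {
  lapply(seq_len(n_neurons), function(i) {
    gt <- make_ground_truth(spec, seed = seed_base + i)
    s <- simulate_discrimination_session(gt, n_reps_per_slant,
                                         seed = seed_base + i,
                                         include_spike_times = include_spike_times)
    s$area <- area
    s
  })
}
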