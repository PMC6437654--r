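test_that("ground truth sampling is reproducible and respects fixed fields", {
  gt1 <- make_ground_truth(list(observer = list(coupling_rho = 0)), seed = 42)
  gt2 <- make_ground_truth(list(observer = list(coupling_rho = 0)), seed = 42)
  expect_equal(gt1$observer$coupling_rho, 0)
  expect_identical(gt1$tuning$peak, gt2$tuning$peak)
  expect_identical(gt1$baseline_hz, gt2$baseline_hz)
  expect_error(make_ground_truth(list(baseline_hz = c(5, NA))), "config error")
  expect_error(make_ground_truth(list(nonsense = 1)), "unknown")
})

test_that("slant-biased spec concentrates preferred slants at low slant", {
  pref_uniform <- vapply(1:250, function(i)
    make_ground_truth(seed = i)$tuning$preferred_slant_deg, numeric(1))
  pref_biased <- vapply(1:250, function(i)
    make_ground_truth(list(slant_bias = 6L), seed = i)$tuning$preferred_slant_deg,
    numeric(1))
  # uniform on the hemisphere: median preferred slant = 60 deg (cos = 0.5)
  expect_gt(median(pref_uniform), 45)
  expect_lt(median(pref_biased), median(pref_uniform) - 15)
})

test_that("fixation sessions have 25 conditions and the stated noise structure", {
  gt <- make_ground_truth(seed = 8)
  s <- simulate_fixation_session(gt, n_reps = 3, seed = 8)
  expect_equal(nrow(s$trials), 75)

  # poisson counts: per-condition Fano factor near 1 over many reps
  s_many <- simulate_fixation_session(gt, n_reps = 200, seed = 9)
  tab <- s_many$trials
  key <- paste(tab$slant_deg, tab$tilt_deg)
  fano <- tapply(tab$spike_count, key, var) / tapply(tab$spike_count, key, mean)
  expect_equal(unname(mean(fano)), 1, tolerance = 0.1)

  # gaussian noise with vanishing variance: zero within-condition SD
  gt0 <- make_ground_truth(list(noise_model = "gaussian", fano_factor = 1e-12),
                           seed = 8)
  s0 <- simulate_fixation_session(gt0, n_reps = 4, seed = 8)
  sds <- tapply(s0$trials$spike_count,
                paste(s0$trials$slant_deg, s0$trials$tilt_deg), sd)
  expect_true(all(sds == 0))

  expect_error(simulate_fixation_session(gt, n_reps = 0), ">= 1")
})

test_that("observer behavior matches its generating parameters", {
  # symmetric observer at the ambiguous slant
  gt <- make_ground_truth(seed = 21)
  s <- simulate_discrimination_session(gt, 400, seed = 21,
                                       include_spike_times = FALSE)
  tr0 <- s$trials[s$trials$slant_deg == 0, ]
  expect_equal(mean(tr0$choice == "top_far"), 0.5, tolerance = 0.06)

  # noiseless observer: every nonzero-slant choice matches the slant sign
  gt_hard <- make_ground_truth(
    list(observer = list(sensory_sigma_deg = 1e-6)), seed = 22)
  s_hard <- simulate_discrimination_session(gt_hard, 20, seed = 22,
                                            include_spike_times = FALSE)
  nz <- s_hard$trials[s_hard$trials$slant_deg != 0, ]
  expect_true(all((nz$choice == "top_far") == (nz$slant_deg > 0)))

  # 0-deg trials are rewarded about half the time, correct signs always
  expect_true(all(nz$rewarded))
  p0 <- mean(s$trials$rewarded[s$trials$slant_deg == 0])
  expect_lt(abs(p0 - 0.5), 3.5 * sqrt(0.25 / 400))  # binomial sampling band
})

test_that("psychometric recovery: fitted SD approaches the generating sigma", {
  gt <- make_ground_truth(seed = 7)
  s <- simulate_discrimination_session(gt, 909, seed = 7,
                                       include_spike_times = FALSE)
  f <- fit_psychometric(s)
  expect_equal(f$threshold_deg, 3.6, tolerance = 0.05 * 3.6)
  expect_equal(f$pse_deg, 0, tolerance = 0.3)
})

test_that("depth frequencies follow the 15/70/15 near/screen/far mixture", {
  gt <- make_ground_truth(seed = 30)
  s <- simulate_discrimination_session(gt, 200, seed = 30,
                                       include_spike_times = FALSE)
  n <- nrow(s$trials)
  p_hat <- table(factor(s$trials$depth_cm, levels = c(-2.25, 0, 2.25))) / n
  for (i in seq_along(p_hat)) {
    p0 <- c(0.15, 0.70, 0.15)[i]
    ci <- p0 + c(-1, 1) * 3.3 * sqrt(p0 * (1 - p0) / n)
    expect_gt(p_hat[i], ci[1]); expect_lt(p_hat[i], ci[2])
  }
})

test_that("same seed reproduces sessions and covariates exactly", {
  gt <- make_ground_truth(seed = 31)
  s1 <- simulate_discrimination_session(gt, 15, seed = 31)
  s2 <- simulate_discrimination_session(gt, 15, seed = 31)
  expect_identical(s1$trials$spike_count, s2$trials$spike_count)
  expect_identical(s1$trials$choice, s2$trials$choice)
  e1 <- simulate_eye_covariates(s1, seed = 5)
  e2 <- simulate_eye_covariates(s2, seed = 5)
  expect_identical(e1$trials$eye_vpos_deg, e2$trials$eye_vpos_deg)
})

test_that("eye covariates are independent of counts when effects are zero", {
  gt <- make_ground_truth(seed = 32)
  s <- simulate_discrimination_session(gt, 182, seed = 32,
                                       include_spike_times = FALSE)
  s <- simulate_eye_covariates(s, seed = 6)
  for (v in c("eye_vpos_deg", "eye_vvel_deg_s", "vergence_deg")) {
    expect_lt(abs(cor(s$trials$spike_count, s$trials[[v]])), 0.05)
  }
})

test_that("injected covariate effects move counts and stay spike-time consistent", {
  gt <- make_ground_truth(seed = 33)
  s <- simulate_discrimination_session(gt, 30, seed = 33)
  s2 <- simulate_eye_covariates(
    s, effect_sizes = list(count_beta = c(eye_vpos_deg = 25)), seed = 7)
  expect_gt(cor(s2$trials$spike_count, s2$trials$eye_vpos_deg), 0.3)
  expect_silent(validate_session(s2))  # spike times were adjusted to match
})

test_that("mean grand CP is chance at zero coupling and increases with coupling", {
  rhos <- c(0, 0.2, 0.4, 0.6)
  means <- vapply(rhos, function(r) {
    n <- if (r == 0) 200 else 100
    mean(vapply(quick_population(n, rho = r, seed_base = round(1000 * r)),
                function(s) grand_cp(s)$grand_cp, numeric(1)))
  }, numeric(1))
  expect_lt(abs(means[1] - 0.5), 0.01)
  expect_true(all(diff(means) > 0))
})
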