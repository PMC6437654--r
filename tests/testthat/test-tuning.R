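test_that("modulation index hits its limits and matches the direct formula", {
  # zero within-condition variance, modulated means -> exactly 1
  d <- tibble::tibble(condition = rep(letters[1:25], each = 3),
                      response = rep(seq(2, 50, by = 2), each = 3))
  expect_identical(compute_sodi(d)$sodi, 1)

  # all condition means equal -> exactly 0
  d0 <- tibble::tibble(condition = rep(letters[1:5], each = 4),
                       response = rep(c(1, 2, 3, 4), times = 5))
  expect_identical(compute_sodi(d0)$sodi, 0)

  # hand-listed 3 conditions x 4 reps vs independent brute-force evaluation
  dh <- tibble::tibble(condition = rep(c("a", "b", "c"), each = 4),
                       response = c(3, 5, 4, 6, 10, 12, 9, 13, 1, 2, 2, 1))
  expect_equal(compute_sodi(dh)$sodi,
               sodi_brute(dh$condition, dh$response), tolerance = 1e-14)

  # exact invariance under a common shift of every response
  dh2 <- dh; dh2$response <- dh2$response + 7.3
  expect_equal(compute_sodi(dh2)$sodi, compute_sodi(dh)$sodi,
               tolerance = 1e-12)
})

test_that("modulation index rejects undefined variance cases", {
  d <- tibble::tibble(condition = c("a", "b"), response = c(1, 2.5))
  # N = M with zero SSE is fine (noise term 0)
  expect_equal(compute_sodi(d)$sodi, 1)
  # a single condition cannot define modulation
  expect_error(compute_sodi(tibble::tibble(condition = "a", response = 1:3)),
               "2 conditions")
})

test_that("condition ANOVA is calibrated under the null and powered under separation", {
  p_null <- vapply(1:600, function(i) {
    set.seed(5000 + i)
    d <- tibble::tibble(condition = rep(sprintf("c%02d", 1:25), each = 3),
                        response = rnorm(75, 20, 4))
    condition_anova(d)
  }, numeric(1))
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.03)  # 3.3 binomial SEs

  set.seed(1)
  d_sep <- tibble::tibble(condition = rep(sprintf("c%02d", 1:25), each = 3),
                          response = rep(1:25 * 10, each = 3) + rnorm(75, 0, 0.01))
  expect_lt(condition_anova(d_sep), 1e-6)

  expect_error(condition_anova(tibble::tibble(condition = c("a", "a", "b"),
                                              response = c(1, 2, 3))),
               ">= 2 trials")
})

test_that("label permutation preserves the ANOVA null distribution", {
  set.seed(99)
  base <- tibble::tibble(condition = rep(sprintf("c%02d", 1:25), each = 4),
                         response = rnorm(100, 15, 3))
  p <- vapply(1:200, function(i) {
    d <- base
    d$condition <- sample(d$condition)
    condition_anova(d)
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Bingham fit recovers a noiseless generating profile", {
  gt <- make_ground_truth(seed = 17)
  conds <- rbind(data.frame(slant_deg = 0, tilt_deg = NA_real_),
                 expand.grid(slant_deg = c(20, 40, 60),
                             tilt_deg = seq(0, 315, by = 45)))
  normals <- slantchoice:::slant_tilt_to_normal(
    conds$slant_deg, ifelse(is.na(conds$tilt_deg), 0, conds$tilt_deg))
  conds$mean_response <- slantchoice:::bingham_rate(gt$tuning, normals)
  fit <- fit_bingham_tuning(conds)
  expect_gt(fit$r, 1 - 1e-6)
  # recovered peak within a degree on the evaluation grid
  pk <- slantchoice:::slant_tilt_to_normal(fit$preferred_slant_deg,
                                           fit$preferred_tilt_deg)
  ang <- acos(pmin(1, sum(pk * gt$tuning$peak))) * 180 / pi
  expect_lt(ang, 1.5)
})

test_that("flat and two-peaked profiles fail the unimodal-fit gate", {
  conds <- rbind(data.frame(slant_deg = 0, tilt_deg = NA_real_),
                 expand.grid(slant_deg = c(20, 40, 60),
                             tilt_deg = seq(0, 315, by = 45)))
  flat <- conds; flat$mean_response <- 12
  ff <- fit_bingham_tuning(flat)
  expect_true(ff$r < 0.8)  # degenerate fit cannot certify tuning
  expect_equal(as.character(classify_tuning(0.01, ff$r)), "untuned_multipeak")

  # separated bumps underfit the (antipodally symmetric, unimodal) family
  nm <- slantchoice:::slant_tilt_to_normal(
    conds$slant_deg, ifelse(is.na(conds$tilt_deg), 0, conds$tilt_deg))
  bump <- function(s, t, k = 12) {
    n0 <- slantchoice:::slant_tilt_to_normal(s, t)
    40 * exp(-k * (1 - (nm %*% n0[1, ])^2))
  }
  multi <- conds
  multi$mean_response <- as.vector(bump(40, 0) + bump(40, 90) +
                                     bump(40, 225)) + 5
  expect_lt(fit_bingham_tuning(multi)$r, 0.8)
  two <- conds
  two$mean_response <- as.vector(bump(0, 0, 10) + bump(60, 90, 10)) + 5
  expect_lt(fit_bingham_tuning(two)$r, 0.8)
})

test_that("the two-step classification rule is a pure function of its gates", {
  grid <- expand.grid(p = c(0.01, 0.5), r = c(0.95, 0.6))
  got <- as.character(classify_tuning(grid$p, grid$r))
  expect_equal(got, c("tuned", "untuned", "untuned_multipeak", "untuned"))
})

test_that("equal-area projection has closed-form values, an inverse, and unit Jacobian", {
  expect_equal(as.numeric(project_equal_area(0, 123)), c(0, 0))
  expect_equal(as.numeric(project_equal_area(60, 90)), c(0, 1),
               tolerance = 1e-12)
  expect_error(project_equal_area(95, 0), "\\[0, 90\\]")

  s <- c(5, 15, 25, 40, 55, 70, 85); t <- c(10, 80, 150, 200, 260, 300, 350)
  xy <- project_equal_area(s, t)
  inv <- equal_area_inverse(xy$x, xy$y)
  expect_equal(inv$slant_deg, s, tolerance = 1e-9)
  expect_equal(inv$tilt_deg, t, tolerance = 1e-9)

  # area preservation: |J| = (rho * drho/ds) / sin(s) = 1 everywhere
  h <- 1e-4
  for (si in c(10, 30, 50, 70, 89)) {
    r1 <- sqrt(rowSums(project_equal_area(si - h, 0)^2))
    r2 <- sqrt(rowSums(project_equal_area(si + h, 0)^2))
    rho <- sqrt(rowSums(project_equal_area(si, 0)^2))
    jac <- rho * (r2 - r1) / (2 * h * pi / 180) / sin(si * pi / 180)
    expect_equal(unname(jac), 1, tolerance = 0.005)
  }
})

test_that("uniformity test is calibrated, powered, and detects concentration", {
  # calibration: uniform hemisphere samples give uniform p-values
  p <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    prefs <- tibble::tibble(slant_deg = acos(runif(120)) * 180 / pi,
                            tilt_deg = runif(120, 0, 360))
    preference_uniformity_test(prefs)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)

  # maximal concentration
  same <- tibble::tibble(slant_deg = rep(33, 60), tilt_deg = rep(120, 60))
  expect_lt(preference_uniformity_test(same)$p_value, 1e-10)

  # power against the low-slant-biased generator at n = 200
  set.seed(12)
  biased <- tibble::tibble(
    slant_deg = acos(apply(matrix(runif(200 * 7), 200), 1, max)) * 180 / pi,
    tilt_deg = runif(200, 0, 360))
  expect_lt(preference_uniformity_test(biased)$p_value, 0.05)

  expect_error(preference_uniformity_test(same[1:10, ]), "coarser")
})

test_that("full tuning analysis classifies a strongly tuned synthetic neuron", {
  gt <- make_ground_truth(seed = 40)
  s <- simulate_fixation_session(gt, n_reps = 5, seed = 40)
  res <- analyze_tuning(s)
  expect_true(res$tuned)
  expect_gt(res$sodi, 0.3)
  expect_lt(res$anova_p, 0.05)
  expect_gte(res$bingham_r, 0.8)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$classification, "tuned")
})
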