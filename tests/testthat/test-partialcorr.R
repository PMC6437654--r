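test_that("partial-correlation formulas reduce correctly in special cases", {
  # F tracks S exactly while C is independent of both
  s <- rep(c(-2, -1, 1, 2), each = 4)
  c_ <- rep(c("top_far", "top_near"), 8)
  f <- s * 3 + 10
  res <- partial_correlations(tibble::tibble(spike_count = f, slant_deg = s,
                                             choice = c_))
  expect_equal(res$r_FS_C, 1, tolerance = 1e-9)
  expect_equal(res$r_FC_S, 0, tolerance = 1e-9)
  expect_equal(res$quadrant, "I")

  # with r_FC = r_SC = 0 the slant partial equals the raw correlation
  set.seed(4)
  s2 <- rep(c(-2, -1, 1, 2), 10)
  f2 <- 2 * s2 + rnorm(40)
  # construct choices orthogonal to both by balancing within slant
  c2 <- unlist(lapply(split(seq_along(s2), s2),
                      function(i) rep(c("top_far", "top_near"), length(i) / 2)))
  d2 <- tibble::tibble(spike_count = f2[order(s2)], slant_deg = sort(s2),
                       choice = c2)
  r_sc <- cor(sort(s2), ifelse(c2 == "top_far", 1, -1))
  expect_equal(r_sc, 0, tolerance = 1e-12)
  res2 <- partial_correlations(d2)
  if (abs(res2$r_FC) < 1e-9) {
    expect_equal(res2$r_FS_C, res2$r_FS, tolerance = 1e-9)
  }
})

test_that("partials agree with the residual-regression oracle on random data", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(10:40, 1)
    s <- sample(c(-5, -2, 2, 5), n, replace = TRUE)
    c_num <- ifelse(runif(n) < pnorm(s / 4), 1, -1)
    if (length(unique(c_num)) < 2) next
    f <- round(10 + s + 2 * c_num + rnorm(n, 0, 3))
    d <- tibble::tibble(spike_count = f, slant_deg = s,
                        choice = ifelse(c_num > 0, "top_far", "top_near"))
    res <- tryCatch(partial_correlations(d), error = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$r_FS_C, partial_cor_residual(f, s, c_num),
                 tolerance = 1e-12)
    expect_equal(res$r_FC_S, partial_cor_residual(f, c_num, s),
                 tolerance = 1e-12)
  }
})

test_that("any monotone two-level choice coding yields identical partials", {
  set.seed(77)
  s <- rep(c(-5, -2, 2, 5), each = 8)
  f <- round(10 + 0.8 * s + rnorm(32, 0, 2))
  choice <- ifelse(runif(32) < pnorm(s / 4), "top_far", "top_near")
  d <- tibble::tibble(spike_count = f, slant_deg = s, choice = choice)
  res <- partial_correlations(d)
  # recode choice numerically as 0/7 instead of -1/+1: correlations with a
  # two-level variable are invariant to positive affine recodings
  c01 <- ifelse(choice == "top_far", 7, 0)
  expect_equal(res$r_FC_S, partial_cor_residual(f, c01, s), tolerance = 1e-12)
})

test_that("collinear or constant inputs are rejected with a clear message", {
  s <- rep(c(-5, 5), each = 6)
  d_coll <- tibble::tibble(spike_count = rpois(12, 10), slant_deg = s,
                           choice = ifelse(s > 0, "top_far", "top_near"))
  expect_error(partial_correlations(d_coll), "collinear")
  d_const <- tibble::tibble(spike_count = rep(4, 12), slant_deg = s,
                            choice = rep(c("top_far", "top_near"), 6))
  expect_error(partial_correlations(d_const), "constant")
})

test_that("choice-conditioned tuning separates under coupling and not without", {
  gt0 <- make_ground_truth(seed = 301)
  s0 <- simulate_discrimination_session(gt0, 90, seed = 301,
                                        include_spike_times = FALSE)
  cur0 <- choice_conditioned_tuning(s0)
  shared <- intersect(cur0$slant_deg[cur0$curve == "top_far"],
                      cur0$slant_deg[cur0$curve == "top_near"])
  gap0 <- vapply(shared, function(sl) {
    cur0$mean_count[cur0$curve == "top_far" & cur0$slant_deg == sl] -
      cur0$mean_count[cur0$curve == "top_near" & cur0$slant_deg == sl]
  }, numeric(1))
  sems <- vapply(shared, function(sl) {
    sum(cur0$sem[cur0$slant_deg == sl & cur0$curve != "all"])
  }, numeric(1))
  expect_gt(mean(abs(gap0) < 2 * sems), 0.7)   # curves coincide within error

  gt1 <- make_ground_truth(list(observer = list(coupling_rho = 0.6)),
                           seed = 302)
  s1 <- simulate_discrimination_session(gt1, 90, seed = 302,
                                        include_spike_times = FALSE)
  pref_far <- s1$preferred_sign_fixation == "positive"
  cur1 <- choice_conditioned_tuning(s1)
  shared1 <- intersect(cur1$slant_deg[cur1$curve == "top_far"],
                       cur1$slant_deg[cur1$curve == "top_near"])
  gap1 <- vapply(shared1, function(sl) {
    cur1$mean_count[cur1$curve == "top_far" & cur1$slant_deg == sl] -
      cur1$mean_count[cur1$curve == "top_near" & cur1$slant_deg == sl]
  }, numeric(1))
  if (!pref_far) gap1 <- -gap1
  # preferred-choice curve lies above at most shared slants (sign test)
  expect_gt(mean(gap1 > 0), 0.75)
})

test_that("slants without three choices in a direction are excluded per curve", {
  slant <- c(rep(0, 8), rep(10, 8))
  choice <- c(rep(c("top_far", "top_near"), 4),
              rep("top_far", 6), rep("top_near", 2))
  s <- hand_discrim_session(slant, choice, seq_along(slant))
  cur <- choice_conditioned_tuning(s)
  expect_true(10 %in% cur$slant_deg[cur$curve == "top_far"])
  expect_false(10 %in% cur$slant_deg[cur$curve == "top_near"])
  expect_true(all(c(0, 10) %in% cur$slant_deg[cur$curve == "all"]))
})

test_that("confidence ellipse orients along a constructed diagonal", {
  set.seed(41)
  u <- rnorm(60, 0, 0.2)
  pts <- tibble::tibble(r_FS_C = u + rnorm(60, 0, 0.03),
                        r_FC_S = u + rnorm(60, 0, 0.03))
  e <- confidence_ellipse(pts, n_boot = 400, seed = 2)
  expect_equal(e$angle_deg, 45, tolerance = 5)
  expect_gt(e$angle_ci_deg[1], 20)
  expect_lt(e$angle_ci_deg[2], 70)
  expect_gte(e$semi_major, e$semi_minor)
  # CI contains the point estimate; fixed seed reproduces it
  expect_true(e$angle_ci_deg[1] <= e$angle_deg &&
                e$angle_deg <= e$angle_ci_deg[2])
  e2 <- confidence_ellipse(pts, n_boot = 400, seed = 2)
  expect_identical(e$angle_ci_deg, e2$angle_ci_deg)
})

test_that("an isotropic cloud has near-equal axes and an uninformative angle", {
  set.seed(42)
  pts <- tibble::tibble(r_FS_C = rnorm(400, 0, 0.1),
                        r_FC_S = rnorm(400, 0, 0.1))
  e <- confidence_ellipse(pts, n_boot = 300, seed = 3)
  expect_lt(e$semi_major / e$semi_minor, 1.15)
  expect_gt(diff(e$angle_ci_deg), 60)   # angle badly constrained
})

test_that("congruent coupling lands most neurons in quadrants I and III", {
  pop <- quick_population(30, rho = 0.6, n_reps = 40, seed_base = 900)
  # mirror the study's inclusion gate: only neurons with significant slant
  # tuning along the task axis enter the discrimination analyses
  rows <- lapply(seq_along(pop), function(i) {
    s <- pop[[i]]
    tr <- s$trials
    slant_p <- summary(aov(spike_count ~ factor(slant_deg),
                           data = tr))[[1]][["Pr(>F)"]][1]
    pc <- partial_correlations(s)
    cp <- permutation_test_cp(s, n_perm = 200, seed = i)
    tibble::tibble(quadrant = pc$quadrant, grand_cp = cp$grand_cp,
                   p_perm = cp$p_perm, slant_p = slant_p)
  })
  d <- dplyr::bind_rows(rows)
  sig <- d[d$p_perm < 0.05 & d$slant_p < 0.05, , drop = FALSE]
  expect_gt(nrow(sig), 5)
  congruent <- sig$quadrant %in% c("I", "III")
  expect_gte(mean(congruent), 0.8)
  expect_gt(mean(sig$grand_cp[congruent]), 0.5)
})
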