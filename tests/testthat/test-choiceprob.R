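test_that("0-degree CP matches the exhaustive pair-count oracle", {
  pref <- c(3, 5, 4, 6); nonpref <- c(2, 4, 3, 5)
  s <- hand_discrim_session(
    slant = rep(0, 8),
    choice = c(rep("top_far", 4), rep("top_near", 4)),
    count = c(pref, nonpref), pref = "positive")
  expect_equal(cp_zero_slant(s), auc_brute(nonpref, pref), tolerance = 1e-12)

  # identical distributions -> 0.5; complete separation -> 1
  s_eq <- hand_discrim_session(rep(0, 8),
                               rep(c("top_far", "top_near"), 4),
                               rep(c(4, 7), each = 4))
  expect_equal(cp_zero_slant(s_eq), 0.5)
  s_sep <- hand_discrim_session(rep(0, 8),
                                c(rep("top_far", 4), rep("top_near", 4)),
                                c(rep(10, 4), rep(0, 4)))
  expect_equal(cp_zero_slant(s_sep), 1)

  # one empty choice group: missing, not chance
  s_one <- hand_discrim_session(rep(0, 4), rep("top_far", 4), 1:4)
  expect_warning(out <- cp_zero_slant(s_one), "undefined")
  expect_true(is.na(out))
})

test_that("balanced z-score matches its symbolic evaluation and invariances", {
  # hand-computed 6-trial group: 4 pref (2,4,6,8), 2 nonpref (1,3)
  x <- c(2, 4, 6, 8, 1, 3)
  is_pref <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  # center (5 + 2)/2 = 3.5; scale^2 = (5 + 1)/2 + (5 - 2)^2/4 = 5.25
  expect_equal(balanced_zscore(x, is_pref), (x - 3.5) / sqrt(5.25),
               tolerance = 1e-14)

  # balanced choices: identical to the ordinary population z-score
  xb <- c(2, 4, 6, 8, 1, 3, 5, 9)
  pb <- rep(c(TRUE, FALSE), each = 4)
  pop_sd <- sqrt(mean((xb - mean(xb))^2))
  expect_equal(balanced_zscore(xb, pb), (xb - mean(xb)) / pop_sd,
               tolerance = 1e-12)

  # positive affine invariance within the slant
  expect_equal(balanced_zscore(3 * x + 11, is_pref), balanced_zscore(x, is_pref),
               tolerance = 1e-12)
})

test_that("grand CP equals the brute-force area on pooled z-scored hand data", {
  slant <- rep(c(-2, 2), each = 6)
  choice <- rep(c("top_far", "top_far", "top_far", "top_near", "top_near",
                  "top_near"), 2)
  count <- c(8, 9, 7, 4, 5, 3, 12, 15, 13, 9, 10, 8)
  s <- hand_discrim_session(slant, choice, count, pref = "positive")
  res <- grand_cp(s)
  z <- unlist(lapply(c(-2, 2), function(sl) {
    i <- slant == sl
    balanced_zscore(count[i], choice[i] == "top_far")
  }))
  pref <- unlist(lapply(c(-2, 2), function(sl) choice[slant == sl] == "top_far"))
  expect_equal(res$grand_cp, auc_brute(z[!pref], z[pref]), tolerance = 1e-12)
  expect_equal(res$n_trials_used, 12)
})

test_that("a single balanced slant reduces the grand CP to the raw-response CP", {
  s <- hand_discrim_session(rep(0, 10),
                            rep(c("top_far", "top_near"), 5),
                            c(5, 3, 8, 2, 6, 4, 9, 1, 7, 5))
  res <- grand_cp(s)
  expect_equal(res$grand_cp, cp_zero_slant(s), tolerance = 1e-12)
})

test_that("grand CP is invariant to per-slant positive affine transforms", {
  pop <- quick_population(5, rho = 0.4, n_reps = 20, seed_base = 40)
  for (s in pop) {
    base <- grand_cp(s)$grand_cp
    s2 <- s
    for (sl in unique(s2$trials$slant_deg)) {
      i <- s2$trials$slant_deg == sl
      a <- runif(1, 0.5, 4); b <- runif(1, -5, 5)
      s2$trials$spike_count[i] <- s2$trials$spike_count[i] * a + b
    }
    # bypass integer-count validation: transform acts on the response column
    cf <- tibble::tibble(slant_deg = s2$trials$slant_deg,
                         response = s2$trials$spike_count,
                         is_pref = s2$trials$choice ==
                           slantchoice:::preferred_choice_label(s2$preferred_sign_fixation))
    core <- slantchoice:::grand_cp_core(cf$response, cf$slant_deg, cf$is_pref)
    expect_equal(core$cp, base, tolerance = 1e-12)
  }
})

test_that("flipping the preferred sign maps CP to its complement", {
  pop <- quick_population(4, rho = 0.5, n_reps = 25, seed_base = 70)
  for (s in pop) {
    base <- grand_cp(s)
    s$preferred_sign_fixation <- if (s$preferred_sign_fixation == "positive")
      "negative" else "positive"
    flipped <- grand_cp(s)
    expect_equal(flipped$grand_cp, 1 - base$grand_cp, tolerance = 1e-12)
    expect_equal(flipped$cp_zero, 1 - base$cp_zero, tolerance = 1e-12)
  }
})

test_that("inclusion rule drops slants without three choices in each direction", {
  slant <- c(rep(0, 8), rep(10, 8))
  choice <- c(rep(c("top_far", "top_near"), 4),
              rep("top_far", 6), rep("top_near", 2))   # only 2 near at 10 deg
  s <- hand_discrim_session(slant, choice, seq_along(slant))
  res <- grand_cp(s)
  inc <- res$included_slants
  expect_true(inc$included[inc$slant_deg == 0])
  expect_false(inc$included[inc$slant_deg == 10])
  expect_equal(res$n_trials_used, 8)

  s_none <- hand_discrim_session(rep(5, 6), c(rep("top_far", 5), "top_near"),
                                 1:6)
  expect_error(grand_cp(s_none), "inclusion rule")
})

test_that("permutation test is deterministic, floored, and centered on chance", {
  s_lock <- hand_discrim_session(
    rep(c(0, 2), each = 20),
    rep(rep(c("top_far", "top_near"), each = 10), 2),
    c(rep(c(30, 5), each = 10), rep(c(40, 8), each = 10)))
  res <- permutation_test_cp(s_lock, n_perm = 1000, seed = 3)
  expect_equal(res$grand_cp, 1)
  expect_lte(res$p_perm, 0.002)
  expect_gte(res$p_perm, 1 / 1001)

  res2 <- permutation_test_cp(s_lock, n_perm = 1000, seed = 3)
  expect_identical(res$p_perm, res2$p_perm)

  # permuted CPs scatter around chance
  perms <- attr(permutation_test_cp(s_lock, n_perm = 400, seed = 5),
                "perm_cps")
  expect_equal(mean(perms, na.rm = TRUE), 0.5, tolerance = 0.02)
  expect_error(permutation_test_cp(s_lock, n_perm = 0), ">= 1")
})

test_that("CP-threshold regression recovers a constructed sensitivity link", {
  set.seed(201)
  n <- 40
  thr <- runif(n, 10, 120)
  cp <- 0.75 - 0.002 * thr + rnorm(n, 0, 0.03)   # coupling in sensitive neurons
  cip <- tibble::tibble(neuron_id = as.character(1:n), area = "CIP",
                        grand_cp = cp, comparison_threshold_deg = thr)
  v3a <- tibble::tibble(neuron_id = as.character(1:n), area = "V3A",
                        grand_cp = 0.5 + rnorm(n, 0, 0.03),
                        comparison_threshold_deg = runif(n, 10, 120))
  res <- cp_vs_threshold(dplyr::bind_rows(cip, v3a))
  r_cip <- res$per_area$r[res$per_area$area == "CIP"]
  r_v3a <- res$per_area$r[res$per_area$area == "V3A"]
  expect_lt(r_cip, -0.5)
  expect_lt(abs(r_v3a), 0.35)
  expect_lt(res$ancova_interaction_p, 0.05)

  # identical populations as two areas: no slope difference
  dup <- dplyr::bind_rows(cip, dplyr::mutate(cip, area = "V3A"))
  res_dup <- cp_vs_threshold(dup)
  expect_gt(res_dup$ancova_interaction_p, 0.95)

  cip_const <- dplyr::mutate(cip, comparison_threshold_deg = 50)
  expect_error(cp_vs_threshold(dplyr::bind_rows(cip_const, v3a)), "degenerate")
})
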