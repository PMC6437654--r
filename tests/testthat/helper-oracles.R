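# Independent oracles used to pin expected values.

# exhaustive pair-count AUC: P(b > a) with ties counted 1/2
auc_brute <- function(a, b) {
  cmp <- outer(b, a, ">") + 0.5 * outer(b, a, "==")
  mean(cmp)
}

# explicit threshold-sweep trapezoidal ROC area
auc_trapezoid <- function(a, b) {
  cuts <- c(sort(unique(c(a, b))), Inf)
  fpr <- vapply(cuts, function(t) mean(a >= t), numeric(1))
  tpr <- vapply(cuts, function(t) mean(b >= t), numeric(1))
  fpr <- c(1, fpr); tpr <- c(1, tpr)
  sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# partial correlation via residual regression: correlate residuals of y ~ z
# with residuals of x ~ z
partial_cor_residual <- function(y, x, z) {
  ry <- residuals(lm(y ~ z))
  rx <- residuals(lm(x ~ z))
  cor(ry, rx)
}

# direct evaluation of the modulation-vs-variability index from a long table
sodi_brute <- function(condition, response) {
  means <- tapply(response, condition, mean)
  sse <- sum((response - means[as.character(condition)])^2)
  n <- length(response); m <- length(means)
  num <- max(means) - min(means)
  num / (num + 2 * sqrt(sse / (n - m)))
}

# minimal hand-built discrimination session
hand_discrim_session <- function(slant, choice, count, depth = 0,
                                 pref = "positive", spike_times = NULL) {
  n <- length(slant)
  tr <- tibble::tibble(
    trial_id = seq_len(n), task = "discrimination",
    slant_deg = slant, tilt_deg = NA_real_,
    depth_cm = rep(depth, length.out = n),
    choice = choice, spike_count = as.integer(count))
  if (!is.null(spike_times)) tr$spike_times_ms <- spike_times
  session(tr, preferred_sign_fixation = pref)
}

# discrimination population under configurable coupling, counts only
quick_population <- function(n_neurons, rho = 0, n_reps = 40L, seed_base = 0L,
                             onset = 0, spike_times = FALSE) {
  lapply(seq_len(n_neurons), function(i) {
    gt <- make_ground_truth(
      list(observer = list(coupling_rho = rho, coupling_onset_ms = onset)),
      seed = seed_base + i)
    simulate_discrimination_session(gt, n_reps, seed = seed_base + i,
                                    include_spike_times = spike_times)
  })
}
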