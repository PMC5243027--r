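make_times <- function(n = 300, dt = 0.01) (seq_len(n) - 0.5) * dt

test_that("decision detection applies the first-crossing rule", {
  t <- make_times()
  flat <- rep(5, length(t))
  right <- ifelse(t >= 1.35, 25, 5)
  dec <- detect_decision(flat, right, t, threshold = 20, window = c(1, 3))
  expect_equal(dec$choice, "right")
  expect_equal(dec$time, 0.355)  # first grid sample at/after the crossing

  none <- detect_decision(flat, flat, t, threshold = 20, window = c(1, 3))
  expect_equal(none$choice, "none")
  expect_true(is.na(none$time))

  left <- ifelse(t >= 1.2, 30, 5)
  later <- ifelse(t >= 1.4, 30, 5)
  dec2 <- detect_decision(left, later, t, threshold = 20, window = c(1, 3))
  expect_equal(dec2$choice, "left")
  expect_equal(dec2$time, 0.205)

  # crossings before the window are ignored
  early <- ifelse(t >= 0.5 & t < 0.9, 30, 5)
  dec3 <- detect_decision(early, flat, t, threshold = 20, window = c(1, 3))
  expect_equal(dec3$choice, "none")
  expect_error(detect_decision(flat, flat, t, threshold = 0, window = c(1, 3)),
               "threshold")
})

test_that("simultaneous crossings break by rate then by a seeded coin", {
  t <- make_times()
  a <- ifelse(t >= 1.5, 25, 5)
  b <- ifelse(t >= 1.5, 22, 5)
  expect_equal(detect_decision(a, b, t, 20, c(1, 3))$choice, "left")
  expect_equal(detect_decision(b, a, t, 20, c(1, 3))$choice, "right")
  # exact tie: deterministic under the same seed
  c1 <- detect_decision(a, a, t, 20, c(1, 3), tie_seed = 5)
  c2 <- detect_decision(a, a, t, 20, c(1, 3), tie_seed = 5)
  expect_identical(c1$choice, c2$choice)
  flips <- vapply(1:40, function(s)
    detect_decision(a, a, t, 20, c(1, 3), tie_seed = s)$choice, character(1))
  expect_setequal(unique(flips), c("left", "right"))
})

test_that("outlier filtering removes deviant decision times but never the
          bulk of a group", {
  rec <- data.frame(subject_id = 1, condition = "none",
                    responded = c(1, 1, 1, 1, 1, 0),
                    decision_time_s = c(0.30, 0.31, 0.32, 0.29, 3.0, NA))
  out <- filter_trials(rec)
  expect_identical(out$valid, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))

  same <- data.frame(subject_id = 1, condition = "none",
                     responded = 1, decision_time_s = rep(0.4, 8))
  expect_true(all(filter_trials(same)$valid))

  # guard property: never more than half of a group removed
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    grp <- data.frame(subject_id = 1, condition = "x", responded = 1,
                      decision_time_s = rexp(n, rate = 2) + 0.05)
    flt <- filter_trials(grp)
    expect_gte(sum(flt$valid), ceiling(n / 2))
  }
})

test_that("Weibull threshold inversion recovers noiseless generating
          parameters", {
  cs <- c(0.032, 0.064, 0.128, 0.256, 0.512)
  gen <- function(alpha, beta) 1 - 0.5 * exp(-(cs / alpha)^beta)
  acc <- data.frame(coherence = cs, p_correct = gen(0.1, 2), n = 20)
  fit <- weibull_accuracy_threshold(acc, target = 0.8)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0.1, tolerance = 1e-4)
  expect_equal(fit$beta, 2, tolerance = 1e-3)
  # closed-form inverse: alpha * (-log(2 (1 - 0.8)))^(1/beta)
  expect_equal(fit$accuracy_threshold, 0.1 * 0.9163^(1 / 2), tolerance = 1e-3)
  # recovery within 5% across generating parameters (noiseless)
  for (alpha in c(0.05, 0.15, 0.3)) {
    for (beta in c(1, 1.5, 3)) {
      acc2 <- data.frame(coherence = cs, p_correct = gen(alpha, beta))
      fit2 <- weibull_accuracy_threshold(acc2, target = 0.8)
      truth <- alpha * (-log(0.4))^(1 / beta)
      expect_lt(abs(fit2$accuracy_threshold - truth) / truth, 0.05)
    }
  }
  # near the 2AFC floor the threshold collapses toward zero
  low <- weibull_accuracy_threshold(acc, target = 0.501)
  expect_lt(low$accuracy_threshold, 0.05 * 0.1 / 0.0957 + 0.01)
  # degenerate: perfect accuracy everywhere
  sat <- data.frame(coherence = cs, p_correct = rep(1, 5))
  fit_sat <- weibull_accuracy_threshold(sat)
  expect_false(fit_sat$converged)
  expect_gte(fit_sat$accuracy_threshold, min(cs))
  expect_lte(fit_sat$accuracy_threshold, max(cs))
  expect_error(weibull_accuracy_threshold(acc[1:2, ]), "3 coherence")
  expect_error(weibull_accuracy_threshold(acc, target = 0.4), "target")
})

test_that("decision-time difference regression is exact on constructed
          lines", {
  cs <- c(0.032, 0.064, 0.128, 0.256, 0.512)
  ctrl <- data.frame(coherence = cs, dt_mean = 0.5 - 0.2 * cs)
  same <- dt_difference_regression(ctrl, ctrl)
  expect_equal(same$beta0, 0, tolerance = 1e-12)
  expect_equal(same$beta1, 0, tolerance = 1e-12)

  stim <- transform(ctrl, dt_mean = dt_mean + 0.05 - 0.1 * coherence)
  fit <- dt_difference_regression(stim, ctrl)
  expect_equal(fit$beta0, 0.05, tolerance = 1e-10)
  expect_equal(fit$beta1, -0.1, tolerance = 1e-10)

  const <- transform(ctrl, dt_mean = dt_mean + 0.01)
  fit2 <- dt_difference_regression(const, ctrl)
  expect_equal(fit2$beta0, 0.01, tolerance = 1e-10)
  expect_equal(fit2$beta1, 0, tolerance = 1e-10)

  expect_error(dt_difference_regression(ctrl[1, ], ctrl[1, ]), "coherence")
})

test_that("hysteresis logistic recovers generating coefficients", {
  # null previous-choice effect
  rec0 <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = 0,
                                          reps = 500, p_nonresponse = 0,
                                          p_outlier = 0, seed = 8))
  fit0 <- hysteresis_logistic(rec0)
  expect_lt(abs(fit0$a2), 0.1)
  # strong recovery at n = 10,000
  rec1 <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = 0.5,
                                          reps = 1000, p_nonresponse = 0,
                                          p_outlier = 0, seed = 9))
  fit1 <- hysteresis_logistic(rec1)
  expect_lt(abs(fit1$a1 - 10) / 10, 0.1)
  expect_lt(abs(fit1$a2 - 0.5) / 0.5, 0.1)
  expect_equal(fit1$ratio, fit1$a2 / fit1$a1)
  expect_true(fit1$converged)
  # degenerate: all choices to one side
  rec_all <- rec1
  rec_all$choice <- "right"
  rec_all$previous_choice <- c("none", rec_all$choice[-nrow(rec_all)])
  expect_error(hysteresis_logistic(rec_all), "separable")
  expect_error(hysteresis_logistic(rec1[1:10, ]), "at least")
})

test_that("perfect separation falls back to a weak ridge penalty", {
  # deterministic choices from the coherence sign: separable design
  set.seed(33)
  trials <- make_trial_list(reps_per_direction = 20)
  signed <- ifelse(trials$direction == "left", -trials$coherence,
                   trials$coherence)
  rec <- data.frame(
    subject_id = 1, condition = "synthetic",
    coherence_signed = signed,
    choice = ifelse(signed > 0, "right", "left"),
    responded = 1, decision_time_s = 0.4)
  rec$previous_choice <- c("none", rec$choice[-nrow(rec)])
  fit <- hysteresis_logistic(rec)
  expect_true(fit$regularized)
  expect_true(fit$converged)
  expect_gt(fit$a1, 0)
  expect_true(is.finite(fit$a2))
})

test_that("fitted coefficients maximize the likelihood (grid-search
          oracle)", {
  rec <- generate_session(synthetic_spec(a0 = 0.2, a1 = 8, a2 = 0.6,
                                         reps = 50, p_nonresponse = 0,
                                         p_outlier = 0, seed = 10))
  fit <- hysteresis_logistic(rec)
  grid <- hysteresis_grid_fit(rec,
                              a0_grid = seq(-1, 1, by = 0.1),
                              a1_grid = seq(4, 14, by = 0.5),
                              a2_grid = seq(-0.2, 1.4, by = 0.1))
  expect_lt(abs(fit$a0 - grid$a0), 0.1 + 1e-9)
  expect_lt(abs(fit$a1 - grid$a1), 0.5 + 1e-9)
  expect_lt(abs(fit$a2 - grid$a2), 0.1 + 1e-9)
  # the MLE's likelihood is at least the grid's best
  expect_gte(hysteresis_loglik(rec, fit$a0, fit$a1, fit$a2),
             grid$loglik - 1e-6)
})

test_that("indecision points shift positively under generated hysteresis", {
  # no history dependence: shift statistically near zero
  rec0 <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = 0,
                                          reps = 400, p_nonresponse = 0,
                                          p_outlier = 0, seed = 12))
  ip0 <- indecision_points(rec0)
  expect_lt(abs(ip0$shift), 0.02)
  # strong hysteresis: positive shift
  rec1 <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = 0.8,
                                          reps = 400, p_nonresponse = 0,
                                          p_outlier = 0, seed = 13))
  ip1 <- indecision_points(rec1)
  expect_gt(ip1$shift, 0.02)
  # known indecision point c0 = 0.05 recovered: P(right) = logistic(k (c - c0))
  rec2 <- generate_session(synthetic_spec(a0 = -10 * 0.05, a1 = 10, a2 = 0,
                                          reps = 600, p_nonresponse = 0,
                                          p_outlier = 0, seed = 14))
  ip2 <- indecision_points(rec2)
  expect_lt(abs(mean(c(ip2$ip_after_left, ip2$ip_after_right)) - 0.05), 0.02)
})
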