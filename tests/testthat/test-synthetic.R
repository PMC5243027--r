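test_that("generator is deterministic and balanced before non-response
          injection", {
  spec <- synthetic_spec(reps = 5, seed = 77)
  rec1 <- generate_session(spec)
  rec2 <- generate_session(spec)
  expect_identical(rec1, rec2)
  spec0 <- synthetic_spec(reps = 5, p_nonresponse = 0, seed = 78)
  rec <- generate_session(spec0)
  tab <- table(abs(rec$coherence_signed), rec$direction)
  expect_true(all(tab == 5))
  expect_equal(nrow(rec), 5 * 2 * 5)
  expect_true(all(rec$responded == 1))
  expect_equal(rec$previous_choice[1], "none")
  expect_identical(rec$previous_choice[-1], rec$choice[-nrow(rec)])
})

test_that("deterministic limits of the generating model hold", {
  # enormous coherence weight: choice always follows the evidence sign
  rec <- generate_session(synthetic_spec(a1 = 1000, a2 = 0, reps = 20,
                                         p_nonresponse = 0, p_outlier = 0,
                                         seed = 3))
  expect_true(all(rec$choice == ifelse(rec$coherence_signed > 0,
                                       "right", "left")))
  # enormous history weight: every trial repeats the first choice
  rec2 <- generate_session(synthetic_spec(a0 = 0, a1 = 0, a2 = 1000,
                                          reps = 20, p_nonresponse = 0,
                                          p_outlier = 0, seed = 4))
  expect_true(all(rec2$choice == rec2$choice[1]))
})

test_that("empirical choice probabilities match the generating logistic", {
  spec <- synthetic_spec(a0 = 0, a1 = 10, a2 = 0.5, reps = 2000,
                         p_nonresponse = 0, p_outlier = 0, seed = 55)
  rec <- generate_session(spec)
  use <- rec$previous_choice %in% c("left", "right")
  rec <- rec[use, ]
  prev <- ifelse(rec$previous_choice == "right", 1, -1)
  for (co in unique(rec$coherence_signed)) {
    for (pv in c(-1, 1)) {
      sel <- rec$coherence_signed == co & prev == pv
      n <- sum(sel)
      if (n < 200) next
      p_hat <- mean(rec$choice[sel] == "right")
      p_true <- 1 / (1 + exp(-(10 * co + 0.5 * pv)))
      # binomial 99% bound
      expect_lt(abs(p_hat - p_true), 2.58 * sqrt(p_true * (1 - p_true) / n))
    }
  }
})

test_that("response times decrease with coherence and respect the floor", {
  rec <- generate_session(synthetic_spec(reps = 300, p_nonresponse = 0,
                                         p_outlier = 0, rt_noise_sd = 0.01,
                                         seed = 6))
  m <- aggregate(decision_time_s ~ abs(coherence_signed), data = rec,
                 FUN = mean)
  expect_true(all(diff(m$decision_time_s) < 0))
  expect_true(all(rec$decision_time_s >= 0.05))
})

test_that("non-response and outlier trials are injected at the stated
          rates", {
  spec <- synthetic_spec(reps = 2000, p_nonresponse = 0.1, p_outlier = 0.05,
                         seed = 91)
  rec <- generate_session(spec)
  n <- nrow(rec)
  expect_lt(abs(mean(rec$responded == 0) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_true(all(is.na(rec$decision_time_s[rec$responded == 0])))
  # outliers show up as a heavy upper tail and get flagged downstream
  flt <- filter_trials(rec)
  expect_gt(sum(!flt$valid & flt$responded == 1), 0)
})

test_that("recovery experiment reports one row per replicate with small
          bias", {
  spec <- synthetic_spec(a0 = 0, a1 = 10, a2 = 0.5, reps = 120, seed = 100)
  res <- recovery_experiment(spec, n_replicates = 3)
  expect_equal(nrow(res$estimates), 3)
  expect_equal(res$n_failures, 0)
  expect_setequal(res$summary$coefficient, c("a0", "a1", "a2"))
  # a2 = 0 truth: mean estimate consistent with zero
  spec0 <- synthetic_spec(a0 = 0, a1 = 10, a2 = 0, reps = 400, seed = 101)
  res0 <- recovery_experiment(spec0, n_replicates = 5)
  se <- sd(res0$estimates$a2) / sqrt(nrow(res0$estimates))
  expect_lt(abs(mean(res0$estimates$a2)), max(4 * se, 0.05))
})

test_that("indecision-point shift is positive in nearly all replicates when
          the generating hysteresis is substantial", {
  shifts <- vapply(1:12, function(r) {
    rec <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = 0.4,
                                           reps = 200, p_nonresponse = 0,
                                           p_outlier = 0, seed = 200 + r))
    indecision_points(rec)$shift
  }, numeric(1))
  expect_gte(mean(shifts > 0), 11 / 12)
})

test_that("indecision-point sign agrees with the logistic coefficient sign", {
  agree <- vapply(1:10, function(r) {
    a2 <- sample(c(-0.5, 0.5), 1)
    rec <- generate_session(synthetic_spec(a0 = 0, a1 = 10, a2 = a2,
                                           reps = 150, p_nonresponse = 0,
                                           p_outlier = 0, seed = 300 + r))
    fit <- hysteresis_logistic(rec)
    ip <- indecision_points(rec)
    sign(ip$shift) == sign(fit$a2)
  }, logical(1))
  expect_gte(mean(agree), 0.9)
})
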