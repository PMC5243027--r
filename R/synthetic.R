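#' Specification for the synthetic behavioral generator
#'
#' Defines a generating model with exactly the statistical structure the
#' analysis pipeline assumes: sequential logistic choices with a
#' previous-choice term, response times that shorten linearly with absolute
#' coherence, and injected non-response and outlier trials. Lets every
#' analysis stage be validated without running the network.
#'
#' @param a0,a1,a2 generating logistic coefficients (intercept, coherence,
#'   previous-choice).
#' @param coherences coherence levels (proportions).
#' @param reps trials per coherence x direction cell.
#' @param rt_base baseline response time (s).
#' @param rt_slope response-time decrease per unit `|coherence|` (s).
#' @param rt_noise_sd Gaussian response-time noise SD (s).
#' @param p_nonresponse probability a trial is a non-response.
#' @param p_outlier probability a responded trial's RT is inflated.
#' @param outlier_scale RT multiplier for outlier trials.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(a0 = 0, a1 = 10, a2 = 0.5,
                           coherences = c(0.032, 0.064, 0.128, 0.256, 0.512),
                           reps = 10, rt_base = 0.6, rt_slope = 0.4,
                           rt_noise_sd = 0.05, p_nonresponse = 0.02,
                           p_outlier = 0.02, outlier_scale = 5, seed = 1L) {
  probs <- c(p_nonresponse, p_outlier)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (rt_base <= 0) stop("rt_base must be positive", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  structure(list(a0 = a0, a1 = a1, a2 = a2, coherences = coherences,
                 reps = reps, rt_base = rt_base, rt_slope = rt_slope,
                 rt_noise_sd = rt_noise_sd, p_nonresponse = p_nonresponse,
                 p_outlier = p_outlier, outlier_scale = outlier_scale,
                 seed = as.integer(seed)),
            class = c("synthetic_spec", "list"))
}

#' Generate one synthetic behavioral session
#'
#' Trials are the randomized balanced design of the spec. The choice on
#' trial n is Bernoulli with
#' `P(right) = 1 / (1 + exp(-(a0 + a1 c_n + a2 (prev_R - prev_L))))`; the
#' first trial (and trials after a non-response) uses no history term.
#' Response times are `rt_base - rt_slope |c| + noise`, floored at 50 ms;
#' outlier trials are multiplied by `outlier_scale`; non-response trials
#' carry no choice or time.
#'
#' @param spec a [synthetic_spec()].
#' @param subject_id,condition,block labels copied into the records.
#' @return Trial records in the package dialect (see [run_session()]).
#' @examples
#' rec <- generate_session(synthetic_spec(reps = 2, seed = 42))
#' table(rec$choice)
#' @export
generate_session <- function(spec, subject_id = 1L, condition = "synthetic",
                             block = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    trials <- make_trial_list(spec$coherences, spec$reps)
    n <- nrow(trials)
    signed <- ifelse(trials$direction == "left", -trials$coherence, trials$coherence)
    choice <- character(n)
    rt <- numeric(n)
    prev <- 0  # previous-choice regressor: +1 right, -1 left, 0 undefined
    prev_label <- "none"
    prev_col <- character(n)
    for (k in seq_len(n)) {
      prev_col[k] <- prev_label
      if (runif(1) < spec$p_nonresponse) {
        choice[k] <- "none"
        rt[k] <- NA_real_
        prev <- 0
        prev_label <- "none"
        next
      }
      eta <- spec$a0 + spec$a1 * signed[k] + spec$a2 * prev
      p_right <- 1 / (1 + exp(-eta))
      choice[k] <- if (runif(1) < p_right) "right" else "left"
      base_rt <- spec$rt_base - spec$rt_slope * abs(signed[k]) +
        rnorm(1, 0, spec$rt_noise_sd)
      if (runif(1) < spec$p_outlier) base_rt <- base_rt * spec$outlier_scale
      rt[k] <- max(base_rt, 0.05)
      prev <- if (choice[k] == "right") 1 else -1
      prev_label <- choice[k]
    }
    data.frame(
      subject_id = as.integer(subject_id),
      block = block,
      condition = condition,
      trial_index = seq_len(n),
      coherence_signed = signed,
      direction = trials$direction,
      choice = choice,
      responded = as.integer(choice != "none"),
      decision_time_s = rt,
      prestim_rate_chosen_hz = NA_real_,
      prestim_rate_unchosen_hz = NA_real_,
      previous_choice = prev_col,
      correct = ifelse(choice == "none", NA,
                       (signed > 0 & choice == "right") |
                         (signed < 0 & choice == "left")),
      stringsAsFactors = FALSE
    )
  })
}

#' Coefficient-recovery experiment for the hysteresis model
#'
#' Repeatedly generates synthetic sessions, fits [hysteresis_logistic()] to
#' each, and summarizes per-coefficient bias and root-mean-square error
#' against the generating values.
#'
#' @param spec a [synthetic_spec()]; each replicate uses `spec$seed + r`.
#' @param n_replicates number of generated sessions.
#' @return List with `estimates` (one row per successful replicate),
#'   `summary` (bias and RMSE per coefficient) and `n_failures`.
#' @export
recovery_experiment <- function(spec, n_replicates) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1)
  rows <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    rep_spec <- spec
    rep_spec$seed <- spec$seed + r
    rec <- generate_session(rep_spec)
    fit <- tryCatch(hysteresis_logistic(rec), error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      replicate = r, a0 = fit$a0, a1 = fit$a1, a2 = fit$a2,
      regularized = fit$regularized)
  }
  estimates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicate = integer(0), a0 = numeric(0), a1 = numeric(0),
               a2 = numeric(0), regularized = logical(0))
  truth <- c(a0 = spec$a0, a1 = spec$a1, a2 = spec$a2)
  summ <- do.call(rbind, lapply(names(truth), function(nm) {
    est <- estimates[[nm]]
    data.frame(coefficient = nm, truth = truth[[nm]],
               bias = mean(est) - truth[[nm]],
               rmse = sqrt(mean((est - truth[[nm]])^2)))
  }))
  rownames(summ) <- NULL
  list(estimates = estimates, summary = summ, n_failures = failures)
}
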