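#' Detect the decision from two population rate traces
#'
#' The first selective population whose smoothed rate reaches the response
#' threshold inside the response window determines the choice; the crossing
#' time minus the window start (task-input onset) is the decision time.
#' A simultaneous first crossing is broken by the higher rate at that
#' sample, then by a seeded coin flip. No crossing means no response.
#'
#' @param trace_left,trace_right smoothed rates (Hz) on a common time grid.
#' @param times sample times (s) of the traces.
#' @param threshold response threshold (Hz).
#' @param window `c(start, end)` of the response window (s); `start` is the
#'   task-input onset from which the decision time is measured.
#' @param tie_seed integer seed for the tie-breaking coin flip.
#' @return List with `choice` (`"left"`, `"right"` or `"none"`) and `time`
#'   (decision time in s from window start, `NA` if none).
#' @examples
#' t <- seq(0, 3, by = 0.01)
#' right <- ifelse(t >= 1.35, 25, 5)
#' detect_decision(rep(5, length(t)), right, t, threshold = 20,
#'                 window = c(1, 3))
#' @export
detect_decision <- function(trace_left, trace_right, times, threshold,
                            window, tie_seed = 1L) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (length(trace_left) != length(times) || length(trace_right) != length(times))
    stop("traces and times must have equal length", call. = FALSE)
  in_win <- times >= window[1] & times <= window[2]
  if (!any(in_win)) stop("response window not covered by the traces", call. = FALSE)
  idx <- which(in_win)
  l_cross <- idx[trace_left[idx] >= threshold][1]
  r_cross <- idx[trace_right[idx] >= threshold][1]
  if (is.na(l_cross) && is.na(r_cross))
    return(list(choice = "none", time = NA_real_))
  if (is.na(r_cross) || (!is.na(l_cross) && l_cross < r_cross))
    return(list(choice = "left", time = times[l_cross] - window[1]))
  if (is.na(l_cross) || r_cross < l_cross)
    return(list(choice = "right", time = times[r_cross] - window[1]))
  # simultaneous first crossing
  if (trace_left[l_cross] > trace_right[r_cross])
    return(list(choice = "left", time = times[l_cross] - window[1]))
  if (trace_right[r_cross] > trace_left[l_cross])
    return(list(choice = "right", time = times[r_cross] - window[1]))
  choice <- with_local_seed(tie_seed, sample(c("left", "right"), 1))
  list(choice = choice, time = times[l_cross] - window[1])
}

#' Flag non-response and outlier trials
#'
#' Within each subject-by-condition group, non-response trials are invalid,
#' and responded trials whose decision time deviates from the group median
#' by more than `k_mad` scaled median absolute deviations are flagged as
#' outliers. A floor on the MAD protects degenerate groups with identical
#' times from spurious removals. This is the package's rendering of
#' median-of-deviations outlier screening.
#'
#' @param records trial records (the [run_session()] dialect: needs
#'   `subject_id`, `condition`, `responded`, `decision_time_s`).
#' @param k_mad cutoff in units of `1.4826 * MAD`.
#' @return `records` with a logical `valid` column added.
#' @export
filter_trials <- function(records, k_mad = 3) {
  stopifnot(all(c("subject_id", "condition", "responded", "decision_time_s")
                %in% names(records)))
  records$valid <- records$responded == 1
  groups <- interaction(records$subject_id, records$condition, drop = TRUE)
  for (g in levels(groups)) {
    sel <- which(groups == g & records$valid)
    if (!length(sel)) {
      warning("empty response group ", g, "; left unchanged", call. = FALSE)
      next
    }
    dts <- records$decision_time_s[sel]
    med <- median(dts)
    scaled_mad <- max(1.4826 * median(abs(dts - med)), 1e-9)
    records$valid[sel] <- abs(dts - med) <= k_mad * scaled_mad
  }
  records
}

#' Coherence needed to reach a target accuracy (Weibull fit)
#'
#' Fits per-coherence accuracy to the two-alternative Weibull psychometric
#' curve `P(correct | c) = 1 - 0.5 exp(-(c / alpha)^beta)` by least squares
#' and inverts it at the target:
#' `threshold = alpha * (-log(2 (1 - target)))^(1 / beta)`.
#'
#' @param accuracy data frame with columns `coherence`, `p_correct` and
#'   optionally `n` (trials per level, used as weights).
#' @param target target accuracy in (0.5, 1); default 0.8.
#' @return List with `alpha`, `beta`, `accuracy_threshold` and `converged`.
#'   Degenerate inputs (accuracy at or above target everywhere, or nowhere
#'   increasing) return `converged = FALSE` with the threshold clamped to
#'   the tested coherence range.
#' @examples
#' cs <- c(0.032, 0.064, 0.128, 0.256, 0.512)
#' acc <- data.frame(coherence = cs, p_correct = 1 - 0.5 * exp(-(cs / 0.1)^2))
#' weibull_accuracy_threshold(acc)$accuracy_threshold
#' @export
weibull_accuracy_threshold <- function(accuracy, target = 0.8) {
  stopifnot(all(c("coherence", "p_correct") %in% names(accuracy)))
  if (nrow(accuracy) < 3) stop("need at least 3 coherence levels", call. = FALSE)
  if (target <= 0.5 || target >= 1) stop("target must lie in (0.5, 1)", call. = FALSE)
  w <- if ("n" %in% names(accuracy)) accuracy$n else rep(1, nrow(accuracy))
  cs <- accuracy$coherence
  pc <- accuracy$p_correct
  invert <- function(alpha, beta) alpha * (-log(2 * (1 - target)))^(1 / beta)
  degenerate <- all(pc >= target) || all(diff(pc[order(cs)]) <= 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(pc ~ 1 - 0.5 * exp(-(cs / alpha)^beta),
                      start = list(alpha = median(cs), beta = 1.5),
                      weights = w,
                      lower = c(1e-6, 0.05), upper = c(10, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    thr <- if (all(pc >= target)) min(cs) else max(cs)
    return(list(alpha = NA_real_, beta = NA_real_,
                accuracy_threshold = thr, converged = FALSE))
  }
  est <- coef(fit)
  thr <- invert(est[["alpha"]], est[["beta"]])
  converged <- !degenerate && thr >= 0
  if (degenerate || thr < min(cs) / 10 || thr > max(cs) * 10)
    thr <- min(max(thr, min(cs)), max(cs))
  list(alpha = unname(est[["alpha"]]), beta = unname(est[["beta"]]),
       accuracy_threshold = unname(thr), converged = converged)
}

#' Decision-time difference regression on coherence
#'
#' Ordinary least squares fit of the per-coherence decision-time difference
#' between a stimulation condition and its control,
#' `DT_stim - DT_control = beta0 + beta1 c`. Differences are formed within
#' matching coherence (and subject, when a `subject_id` column is present)
#' cells and pooled.
#'
#' @param stim_means,control_means data frames with columns `coherence`,
#'   `dt_mean` (s) and optionally `subject_id`.
#' @return List with `beta0` (s), `beta1` (s per unit coherence), `p_slope`
#'   (two-sided), and the fitted `model`.
#' @export
dt_difference_regression <- function(stim_means, control_means) {
  keys <- intersect(c("subject_id", "coherence"), names(stim_means))
  merged <- merge(stim_means, control_means, by = keys,
                  suffixes = c("_stim", "_control"))
  if (length(unique(merged$coherence)) < 2)
    stop("need at least 2 distinct coherence levels", call. = FALSE)
  merged$diff <- merged$dt_mean_stim - merged$dt_mean_control
  fit <- lm(diff ~ coherence, data = merged)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  p_slope <- if (nrow(merged) > 2) sm["coherence", "Pr(>|t|)"] else NA_real_
  list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
       p_slope = unname(p_slope), model = fit)
}

# logistic MLE with optional ridge penalty on the non-intercept terms
logistic_irls <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X + pen, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(list(beta = beta, converged = FALSE))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) return(list(beta = beta, converged = TRUE))
  }
  list(beta = beta, converged = FALSE)
}

#' Sequential logistic model of choice hysteresis
#'
#' Maximum-likelihood logistic regression of the rightward-choice indicator
#' on signed coherence and the previous-choice regressor
#' (`+1` after a rightward, `-1` after a leftward choice):
#' `P(right) = 1 / (1 + exp(-(a0 + a1 c + a2 (prev_R - prev_L))))`.
#' Choice hysteresis is indicated by `a2 > 0`; the normalized effect is the
#' ratio `a2 / a1`. Trials without a defined previous choice (the first of
#' each block) and invalid trials are excluded. Under perfect separation the
#' fit is retried with a weak L2 penalty (`lambda = 1e-3`) on the slope
#' terms and flagged `regularized`.
#'
#' @param records trial records with `coherence_signed`, `choice`,
#'   `previous_choice`, and optionally `valid`.
#' @param min_trials minimum number of usable trials.
#' @return List with `a0`, `a1`, `a2`, `ratio` (`a2 / a1`, `NA` unless
#'   `a1 > 0`), `converged`, `regularized`, and `n`.
#' @export
hysteresis_logistic <- function(records, min_trials = 20) {
  use <- records$choice %in% c("left", "right") &
    records$previous_choice %in% c("left", "right")
  if ("valid" %in% names(records)) use <- use & records$valid
  rec <- records[use, ]
  if (nrow(rec) < min_trials)
    stop("need at least ", min_trials, " valid trials with a defined previous choice",
         call. = FALSE)
  y <- as.numeric(rec$choice == "right")
  prev <- ifelse(rec$previous_choice == "right", 1, -1)
  if (length(unique(y)) < 2)
    stop("all choices identical: logistic model is separable", call. = FALSE)
  X <- cbind(1, rec$coherence_signed, prev)
  fit <- NULL
  separated <- FALSE
  withCallingHandlers(
    fit <- glm.fit(X, y, family = binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  regularized <- FALSE
  if (separated || !fit$converged || any(!is.finite(beta)) || max(abs(beta)) > 1e3) {
    ridge <- logistic_irls(X, y, lambda = 1e-3)
    beta <- ridge$beta
    regularized <- TRUE
  }
  a0 <- beta[1]; a1 <- beta[2]; a2 <- beta[3]
  list(a0 = unname(a0), a1 = unname(a1), a2 = unname(a2),
       ratio = if (is.finite(a1) && a1 > 0) unname(a2 / a1) else NA_real_,
       converged = regularized || fit$converged,
       regularized = regularized,
       n = nrow(rec))
}

# 2-parameter logistic psychometric fit: P(right | c) = 1/(1+exp(-k (c - c0)))
fit_psychometric <- function(coherence_signed, chose_right) {
  y <- as.numeric(chose_right)
  if (length(unique(y)) < 2)
    return(list(slope = NA_real_, indecision_point = NA_real_, converged = FALSE))
  X <- cbind(1, coherence_signed)
  fit <- NULL
  warned <- FALSE
  withCallingHandlers(
    fit <- glm.fit(X, y, family = binomial()),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  beta <- fit$coefficients
  if (warned || !fit$converged || any(!is.finite(beta)) || max(abs(beta)) > 1e3) {
    beta <- logistic_irls(X, y, lambda = 1e-3)$beta
  }
  k <- beta[2]
  c0 <- if (is.finite(k) && k != 0) -beta[1] / k else NA_real_
  list(slope = unname(k), indecision_point = unname(c0),
       converged = is.finite(c0))
}

#' Indecision points split by the previous choice
#'
#' Splits trials by the choice made on the previous trial, fits a logistic
#' psychometric curve `P(right | c)` to each group, and reports the signed
#' coherence at which rightward choices occur 50% of the time (the
#' indecision point). The shift, indecision point after a left choice minus
#' after a right choice, is positive under repetition bias.
#'
#' @param records trial records (see [hysteresis_logistic()]); invalid
#'   trials and trials without a defined previous choice are excluded.
#' @return List with `ip_after_left`, `ip_after_right`, `shift`, and the two
#'   group fits.
#' @export
indecision_points <- function(records) {
  use <- records$choice %in% c("left", "right") &
    records$previous_choice %in% c("left", "right")
  if ("valid" %in% names(records)) use <- use & records$valid
  rec <- records[use, ]
  for (side in c("left", "right")) {
    grp <- rec[rec$previous_choice == side, ]
    if (nrow(grp) < 4 || length(unique(grp$coherence_signed)) < 2)
      stop("previous-", side, " group too small for a psychometric fit",
           call. = FALSE)
  }
  fit_l <- fit_psychometric(rec$coherence_signed[rec$previous_choice == "left"],
                            rec$choice[rec$previous_choice == "left"] == "right")
  fit_r <- fit_psychometric(rec$coherence_signed[rec$previous_choice == "right"],
                            rec$choice[rec$previous_choice == "right"] == "right")
  shift <- if (fit_l$converged && fit_r$converged)
    fit_l$indecision_point - fit_r$indecision_point else NA_real_
  list(ip_after_left = fit_l$indecision_point,
       ip_after_right = fit_r$indecision_point,
       shift = shift,
       fit_after_left = fit_l, fit_after_right = fit_r)
}
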