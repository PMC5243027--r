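#' Gaussian smoothing kernel for population rates
#'
#' Unit-area Gaussian truncated at `+/- halfwidth` ms. The default reading of
#' a filter "5 ms wide at the tails" is a cutoff at 5 ms with
#' `sigma = halfwidth / 3`, which puts the kernel at about 1% of its peak at
#' the cutoff.
#'
#' @param dt sample step (ms).
#' @param halfwidth truncation half-width (ms).
#' @param sigma Gaussian SD (ms); default `halfwidth / 3`.
#' @return Numeric kernel summing to 1.
#' @export
rate_kernel <- function(dt, halfwidth = 5, sigma = halfwidth / 3) {
  n <- floor(halfwidth / dt)
  x <- (-n:n) * dt
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# centred convolution with edge renormalization so flat traces stay flat
smooth_rate <- function(rate, dt, halfwidth = 5, sigma = halfwidth / 3) {
  k <- rate_kernel(dt, halfwidth, sigma)
  n <- length(rate)
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(0, half), rate, rep(0, half))
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + n)])
  # renormalize near the edges where the kernel is clipped
  w <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                     method = "convolution", sides = 2)
  sm / as.numeric(w[(half + 1):(half + n)])
}

#' Smoothed population firing-rate trace from spike events
#'
#' The instantaneous population rate (spike count per bin divided by
#' `n_neurons * dt`) convolved with the truncated Gaussian kernel of
#' [rate_kernel()].
#'
#' @param spike_times spike times (ms), pooled over the population.
#' @param n_neurons population size.
#' @param duration_ms trace duration (ms).
#' @param dt bin width (ms).
#' @param kernel_halfwidth kernel truncation half-width (ms).
#' @param population optional label attached to the result.
#' @return A data frame with columns `time_ms` (bin centers), `rate_hz`, and
#'   `population`.
#' @examples
#' tr <- population_rate_trace(c(10, 10.2, 15), n_neurons = 100,
#'                             duration_ms = 50, dt = 0.5)
#' sum(tr$rate_hz) * 0.5 / 1000 * 100  # area returns the spike count
#' @export
population_rate_trace <- function(spike_times, n_neurons, duration_ms,
                                  dt = 0.5, kernel_halfwidth = 5,
                                  population = "population") {
  if (n_neurons <= 0) stop("n_neurons must be positive", call. = FALSE)
  n_bins <- as.integer(ceiling(duration_ms / dt))
  counts <- tabulate(pmin(n_bins, pmax(1L, as.integer(ceiling(spike_times / dt)))),
                     nbins = n_bins)
  if (!length(spike_times)) counts <- integer(n_bins)
  inst <- counts / (n_neurons * dt / 1000)  # Hz
  k <- rate_kernel(dt, kernel_halfwidth)
  half <- (length(k) - 1L) / 2L
  padded <- c(rep(0, half), inst, rep(0, half))
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  data.frame(time_ms = (seq_len(n_bins) - 0.5) * dt,
             rate_hz = as.numeric(sm[(half + 1):(half + n_bins)]),
             population = population, stringsAsFactors = FALSE)
}

#' Prestimulus activity bias per trial
#'
#' For every responded trial, the mean difference between the eventually
#' chosen and the unchosen selective population's smoothed rate over the
#' window (default 500 ms) ending at task-input onset. A positive bias on a
#' repeated-choice trial is the signature of decaying tail activity from the
#' previous trial carrying into the current one.
#'
#' @param result a [run_session()] result with traces retained, or a list
#'   with `traces`, `onset_step`, `trial_steps`, `dt` and `records`.
#' @param window prestimulus window length (ms).
#' @return Data frame with columns `trial_index`, `bias_hz` and `repeated`
#'   (choice equals previous choice); trials without a response or without a
#'   defined previous choice are dropped.
#' @export
prestimulus_bias <- function(result, window = 500) {
  if (is.null(result$traces))
    stop("session result does not retain traces; rerun with return_traces = TRUE",
         call. = FALSE)
  rec <- result$records
  dt <- result$dt
  win_steps <- round(window / dt)
  if (win_steps > result$onset_step)
    stop("prestimulus window does not fit before input onset", call. = FALSE)
  rows <- list()
  for (k in seq_len(nrow(rec))) {
    if (rec$choice[k] == "none" || rec$previous_choice[k] == "none") next
    i0 <- (k - 1) * result$trial_steps
    idx <- (i0 + result$onset_step - win_steps + 1):(i0 + result$onset_step)
    pre_l <- mean(result$traces$left[idx])
    pre_r <- mean(result$traces$right[idx])
    bias <- if (rec$choice[k] == "left") pre_l - pre_r else pre_r - pre_l
    rows[[length(rows) + 1]] <- data.frame(
      trial_index = rec$trial_index[k], bias_hz = bias,
      repeated = rec$choice[k] == rec$previous_choice[k])
  }
  if (!length(rows))
    return(data.frame(trial_index = integer(0), bias_hz = numeric(0),
                      repeated = logical(0)))
  do.call(rbind, rows)
}

#' Compare prestimulus bias across stimulation conditions
#'
#' Collapses per-trial biases to one mean per subject and condition, then
#' compares every condition against a baseline with the paired Wilcoxon
#' signed-rank test.
#'
#' @param biases data frame with columns `subject_id`, `condition` and
#'   `bias_hz` (e.g. row-bound [prestimulus_bias()] outputs with the two id
#'   columns added).
#' @param baseline name of the reference condition.
#' @return List with `means` (subject x condition mean biases) and
#'   `comparisons` (one [wilcoxon_signed_rank()] result per non-baseline
#'   condition).
#' @export
bias_condition_summary <- function(biases, baseline = "none") {
  stopifnot(all(c("subject_id", "condition", "bias_hz") %in% names(biases)))
  means <- aggregate(bias_hz ~ subject_id + condition, data = biases, FUN = mean)
  conds <- setdiff(unique(means$condition), baseline)
  if (!baseline %in% means$condition)
    stop("baseline condition '", baseline, "' not present", call. = FALSE)
  base <- means[means$condition == baseline, ]
  comparisons <- list()
  for (cond in conds) {
    cur <- means[means$condition == cond, ]
    shared <- intersect(base$subject_id, cur$subject_id)
    comparisons[[cond]] <- wilcoxon_signed_rank(
      cur$bias_hz[match(shared, cur$subject_id)],
      base$bias_hz[match(shared, base$subject_id)])
  }
  list(means = means, comparisons = comparisons)
}
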