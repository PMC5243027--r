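# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force or fine-grained integration, separately from the
# package's own implementation paths.

# Forward-Euler integration of a single isolated neuron in plain R, using
# the package's membrane_derivative as the right-hand side. `I_inj` is an
# injected (positive = depolarizing) current in pA.
reference_single_neuron <- function(params, I_inj, duration_ms, dt,
                                    V0 = params$E_L) {
  n_steps <- round(duration_ms / dt)
  v <- V0
  spikes <- numeric(0)
  trace <- numeric(n_steps)
  ref_left <- 0L
  ref_steps <- round(params$tau_r / dt)
  for (s in seq_len(n_steps)) {
    if (ref_left > 0) {
      ref_left <- ref_left - 1L
      v <- params$V_r
    } else {
      v <- v + membrane_derivative(v, -I_inj, params) * dt
      if (v >= params$V_s) {
        spikes <- c(spikes, s * dt)
        v <- params$V_r
        ref_left <- ref_steps
      }
    }
    trace[s] <- v
  }
  list(V = v, spikes = spikes, trace = trace)
}

# Exact two-sided signed-rank p value by enumeration over all 2^n sign
# patterns: p = min(1, 2 P(W+ <= min(W+, W-))).
wilcoxon_enumeration_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 16)
  ranks <- rank(abs(d))
  w_plus <- sum(ranks[d > 0])
  w_obs <- min(w_plus, n * (n + 1) / 2 - w_plus)
  count <- 0L
  for (m in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(m, 0:(n - 1)), 1L)
    if (sum(ranks[signs == 1L]) <= w_obs) count <- count + 1L
  }
  min(1, 2 * count / 2^n)
}

# Binomial log-likelihood of the sequential logistic model on trial records.
hysteresis_loglik <- function(records, a0, a1, a2) {
  use <- records$choice %in% c("left", "right") &
    records$previous_choice %in% c("left", "right")
  rec <- records[use, ]
  y <- as.numeric(rec$choice == "right")
  prev <- ifelse(rec$previous_choice == "right", 1, -1)
  eta <- a0 + a1 * rec$coherence_signed + a2 * prev
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Coarse grid maximization of the same likelihood: an independent check of
# the fitting routine.
hysteresis_grid_fit <- function(records, a0_grid, a1_grid, a2_grid) {
  best <- c(NA, NA, NA)
  best_ll <- -Inf
  for (a0 in a0_grid) for (a1 in a1_grid) for (a2 in a2_grid) {
    ll <- hysteresis_loglik(records, a0, a1, a2)
    if (ll > best_ll) {
      best_ll <- ll
      best <- c(a0, a1, a2)
    }
  }
  list(a0 = best[1], a1 = best[2], a2 = best[3], loglik = best_ll)
}

# A minimal fake session_result for neural-analysis unit tests.
fake_session_result <- function(rate_left, rate_right, records,
                                dt = 0.5, onset_step = 2000L,
                                trial_steps = 6000L) {
  structure(list(records = records,
                 traces = list(time_ms = (seq_along(rate_left) - 0.5) * dt,
                               left = rate_left, right = rate_right),
                 onset_step = onset_step, trial_steps = trial_steps,
                 dt = dt),
            class = c("session_result", "list"))
}
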