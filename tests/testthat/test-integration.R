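# Single-neuron and small-network contracts of the Euler integrator.

single_neuron_net <- function(update = "additive") {
  build_network(network_config(n_pyramidal = 1, n_selective = 0,
                               n_interneurons = 0, wiring_seed = 1,
                               synapse_update = update))
}

small_net <- function(seed = 4) {
  build_network(network_config(n_pyramidal = 100, n_selective = 20,
                               n_interneurons = 24, wiring_seed = seed))
}

test_that("a quiet neuron settles at the subthreshold fixed point", {
  net <- single_neuron_net()
  sim <- simulate_network(net, n_steps = 200)  # 100 ms
  v_star <- membrane_fixed_point(0, neuron_params("pyramidal"))
  expect_lt(abs(sim$state$V[1] - v_star), 1)
  expect_equal(sum(sim$counts), 0)
})

test_that("the compiled integrator matches the plain-R reference step for
          step", {
  net <- single_neuron_net()
  pyr <- neuron_params("pyramidal")
  for (I_inj in c(0, 100, 250)) {  # subthreshold currents
    sim <- simulate_network(net, n_steps = 400, stim = c(I_inj, 0))
    ref <- reference_single_neuron(pyr, I_inj, 200, 0.5)
    expect_lt(abs(sim$state$V[1] - ref$V), 1e-4)
  }
})

test_that("suprathreshold current gives periodic firing matching a
          fine-step reference", {
  net <- single_neuron_net()
  sim <- simulate_network(net, n_steps = 2000, stim = c(310, 0),
                          return_spikes = TRUE)
  expect_gt(length(sim$spike_time_ms), 5)
  period_sim <- mean(diff(sim$spike_time_ms))
  ref <- reference_single_neuron(neuron_params("pyramidal"), 310, 1000, 0.01)
  period_ref <- mean(diff(ref$spikes))
  expect_lt(abs(period_sim - period_ref) / period_ref, 0.1)
})

test_that("halving the step changes a subthreshold trace by well under
          0.1 mV", {
  pyr <- neuron_params("pyramidal")
  coarse <- reference_single_neuron(pyr, 200, 1000, 0.5)
  fine <- reference_single_neuron(pyr, 200, 1000, 0.25)
  # compare on the common grid (every second fine sample)
  expect_lt(max(abs(coarse$trace - fine$trace[seq(2, 4000, by = 2)])), 0.1)
})

test_that("a neuron at or above the spike threshold fires exactly once and
          resets", {
  net <- single_neuron_net()
  st <- simulate_network(net, n_steps = 1)$state
  st$V[1] <- -15  # above V_s = -20
  sim <- simulate_network(net, n_steps = 1, init_state = st)
  expect_equal(sum(sim$counts), 1)
  expect_equal(sim$state$V[1], -53)  # reset to V_r
  expect_equal(sim$state$refractory_steps[1], 4L)  # 2 ms at dt = 0.5
})

test_that("numerical instability is reported with the neuron identity", {
  net <- single_neuron_net()
  st <- simulate_network(net, n_steps = 1)$state
  st$V[1] <- 1e308
  expect_error(simulate_network(net, n_steps = 1, init_state = st),
               "instability.*neuron 1")
})

test_that("externally scheduled events set and decay the input
          conductance", {
  net <- single_neuron_net()
  ev <- data.frame(neuron = 1, step = 0)
  sim1 <- simulate_network(net, n_steps = 1, ext_events = ev)
  expect_equal(sim1$state$g_ext[1], 1.6)  # delivered, not yet decayed
  sim2 <- simulate_network(net, n_steps = 2, ext_events = ev)
  expect_equal(sim2$state$g_ext[1], 1.6 * exp(-0.5 / 2), tolerance = 1e-7)
})

test_that("additive aggregation sums quanta; saturating mode caps at G", {
  ev2 <- data.frame(neuron = c(1, 1), step = c(0, 0))
  add <- simulate_network(single_neuron_net("additive"), n_steps = 1,
                          ext_events = ev2)
  expect_equal(add$state$g_ext[1], 3.2)
  sat <- simulate_network(single_neuron_net("saturating"), n_steps = 1,
                          ext_events = ev2)
  expect_equal(sat$state$g_ext[1], 1.6)
})

test_that("simulation state carries across calls bit-identically
          (continuity contract)", {
  net <- small_net()
  whole <- simulate_network(net, n_steps = 400, background_rate = 1200,
                            seed = 31)
  first <- simulate_network(net, n_steps = 200, background_rate = 1200,
                            seed = 31)
  second <- simulate_network(net, n_steps = 200, background_rate = 1200,
                             init_state = first$state)
  expect_identical(rbind(first$counts, second$counts), whole$counts)
  expect_identical(second$state$V, whole$state$V)
  expect_identical(second$state$g_bg, whole$state$g_bg)
  expect_identical(second$state$x_nmda_slow, whole$state$x_nmda_slow)
  expect_identical(second$state$rng_state, whole$state$rng_state)
  expect_identical(second$state$pending_spikes, whole$state$pending_spikes)
})

test_that("reinitialization resets the trajectory at trial starts", {
  net <- small_net()
  cont <- simulate_network(net, n_steps = 300, background_rate = 1200,
                           seed = 77, trial_start_steps = c(0L, 150L),
                           reinitialize = FALSE)
  reinit <- simulate_network(net, n_steps = 300, background_rate = 1200,
                             seed = 77, trial_start_steps = c(0L, 150L),
                             reinitialize = TRUE)
  # identical before the second trial starts, different after the reset
  expect_identical(cont$counts[1:150, ], reinit$counts[1:150, ])
  expect_false(identical(cont$counts[151:300, ], reinit$counts[151:300, ]))
})

test_that("identical seeds reproduce the simulation exactly", {
  net <- small_net()
  a <- simulate_network(net, n_steps = 300, background_rate = 1200, seed = 9)
  b <- simulate_network(net, n_steps = 300, background_rate = 1200, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$state$V, b$state$V)
  c <- simulate_network(net, n_steps = 300, background_rate = 1200, seed = 10)
  expect_false(identical(a$counts, c$counts))
})
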