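test_that("alpha-function synaptic kernel has the documented shape", {
  expect_error(synaptic_kernel(1, 0), "positive")
  expect_identical(synaptic_kernel(0, 5, 3), 0)
  expect_identical(synaptic_kernel(-2, 5, 3), 0)
  # peak value equals the amplitude, at exactly t = tau_S
  expect_equal(synaptic_kernel(5, 5, 3), 3)
  tt <- seq(0, 50, 0.01)
  expect_equal(tt[which.max(synaptic_kernel(tt, 5))], 5, tolerance = 1e-3)
  # analytic value at 2*tau: x e^(1-x) with x = 2
  expect_equal(synaptic_kernel(2 * 7, 7, 1), 2 * exp(-1))
})

test_that("synaptic depression depletes at spikes and recovers toward 1", {
  expect_error(update_depression(0, FALSE, 1), "\\(0, 1\\]")
  expect_error(update_depression(1.2, FALSE, 1), "\\(0, 1\\]")
  expect_equal(update_depression(1, TRUE, 0.1, alpha = 0.8), 0.8)
  # two spikes in immediate succession compose multiplicatively
  expect_equal(update_depression(update_depression(1, TRUE, 0.1),
                                 TRUE, 0.1), 0.64)
  # long quiescence relaxes to the fixed point
  expect_equal(update_depression(0.5, FALSE, 1e5, tau_D = 1000), 1,
               tolerance = 1e-8)
  # exact exponential relaxation over a finite step
  expect_equal(update_depression(0.5, FALSE, 250, tau_D = 1000),
               1 - 0.5 * exp(-0.25))
})

test_that("an unstimulated noise-free network is exactly silent at rest", {
  topo <- network_topology(10, 0.3, 0.2, topology_seed = 1, label_seed = 2)
  sp <- run_simulation(topo, neuron_params(g_xi = 0),
                       synapse_params(lambda_ext = 0),
                       duration = 2000, seed = 1, record_v = 1:3,
                       record_every = 100L)
  expect_identical(nrow(sp$spikes), 0L)
  # v decays from its jittered start toward rest and stays subthreshold;
  # by the end it is back at v_r
  expect_true(all(sp$v_trace < -45))
  expect_equal(unname(sp$v_trace[nrow(sp$v_trace), ]), rep(-60, 3),
               tolerance = 1e-3)
})

test_that("driven single-neuron spike count matches an adaptive reference integration", {
  skip_if_not_installed("deSolve")
  np <- neuron_params(g_xi = 0)
  i_ext <- 60   # above the quadratic barrier max of K_v*((v_t-v_r)/2)^2
  sp <- run_simulation(single_neuron_topology(), np,
                       synapse_params(lambda_ext = 0),
                       duration = 10000, dt = 0.1, seed = 1, i_ext = i_ext)
  # independent oracle: dense integration with root-triggered reset
  f <- function(t, y, parms) {
    list(c((np$K_v * (y[1] - np$v_r) * (y[1] - np$v_t) - y[2] + i_ext) /
             np$tau_v,
           (np$K_w * (y[1] - np$v_r) - y[2]) / np$tau_w))
  }
  root <- function(t, y, parms) y[1] - np$v_p
  evf <- function(t, y, parms) c(np$v_c, y[2] + np$delta_w)
  out <- deSolve::lsodar(c(v = np$v_r, w = 0), seq(0, 10000, 1), f,
                         rootfunc = root,
                         events = list(func = evf, root = TRUE,
                                       maxroot = 1000),
                         rtol = 1e-8, atol = 1e-8)
  n_ref <- length(attributes(out)$troot)
  expect_lte(abs(nrow(sp$spikes) - n_ref), 1)
  # initial jitter is off only in expectation; spike times should be regular
  isi <- diff(sp$spikes$time)
  expect_lt(diff(range(isi[-1])), 1)
})

test_that("halving the time step barely moves deterministic spike times", {
  np <- neuron_params(g_xi = 0)
  sy <- synapse_params(lambda_ext = 0)
  sp1 <- run_simulation(single_neuron_topology(), np, sy, duration = 5000,
                        dt = 0.1, seed = 4, i_ext = 60)
  sp2 <- run_simulation(single_neuron_topology(), np, sy, duration = 5000,
                        dt = 0.05, seed = 4, i_ext = 60)
  # same jittered start is not guaranteed across dt (different RNG use),
  # so compare inter-spike intervals rather than absolute times
  n <- min(nrow(sp1$spikes), nrow(sp2$spikes)) - 1
  expect_gt(n, 5)
  expect_true(all(abs(diff(sp1$spikes$time)[2:n] -
                      diff(sp2$spikes$time)[2:n]) < 0.1))
})

test_that("recorded membrane potential never exceeds the spike peak", {
  sml <- small_sim()
  sp <- run_simulation(sml$topology, duration = 5000, seed = 77,
                       record_v = 1:5, record_every = 1L)
  expect_true(all(sp$v_trace <= neuron_params()$v_p))
})

test_that("simulations are reproducible given a seed and the drive is Poisson", {
  topo <- network_topology(12, 0.3, 0.25, topology_seed = 5, label_seed = 6)
  a <- run_simulation(topo, duration = 3000, seed = 42)
  b <- run_simulation(topo, duration = 3000, seed = 42)
  expect_identical(a$spikes, b$spikes)
  d <- run_simulation(topo, duration = 3000, seed = 43)
  expect_false(identical(a$spikes, d$spikes))

  # external event counts across many isolated neurons ~ Poisson(lambda*T)
  big <- list(n_neurons = 2000L, adjacency = matrix(0L, 2000, 2000),
              labels = rep("excitatory", 2000))
  sp <- run_simulation(big, neuron_params(g_xi = 0),
                       synapse_params(lambda_ext = 20, g_E = 0),
                       duration = 500, seed = 8)
  k <- sp$n_ext_events
  mu <- 20 * 0.5   # lambda * T in seconds
  expect_lt(abs(mean(k) - mu), 3 * sqrt(mu / 2000))
  # chi-square goodness of fit against the Poisson pmf
  breaks <- c(-0.5, seq(4.5, 15.5, 1), Inf)
  obs <- table(cut(k, breaks))
  pr <- diff(ppois(c(-1, 4:15, Inf), mu))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})
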