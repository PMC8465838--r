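# Shared fixtures built in code. The small control simulation is cached per
# test run because several files probe different stages of the same pipeline.

.cache <- new.env(parent = emptyenv())

# 30-neuron, 30-second control network: small enough for unit tests, busy
# enough to contain bursts and quiet epochs
small_sim <- function() {
  if (is.null(.cache$small)) {
    topo <- network_topology(30, 0.3, 0.2, topology_seed = 301,
                             label_seed = 302)
    spikes <- run_simulation(topo, duration = 30000, seed = 303)
    .cache$small <- list(topology = topo, spikes = spikes)
  }
  .cache$small
}

# a lone neuron wrapped in the minimal topology the simulator needs
single_neuron_topology <- function() {
  list(n_neurons = 1L, adjacency = matrix(0L, 1, 1), labels = "excitatory")
}

# analytic calcium kernel, for oracle computations in tests
calcium_kernel_fun <- function(t, A = 1, tau1 = 10, tau2 = 700) {
  ifelse(t >= 0, A * exp(-t / tau2) * (1 - exp(-t / tau1)), 0)
}
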