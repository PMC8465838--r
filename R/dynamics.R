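#' Alpha-function synaptic kernel
#'
#' Post-synaptic input waveform
#' \eqn{I(t) = A \, (t/\tau_S) e^{1 - t/\tau_S} \theta(t)}, which rises from
#' zero, peaks at exactly `amplitude` when `t_since = tau_S`, and decays.
#'
#' @param t_since time since delivery (ms); negative values return 0
#' @param tau_S synaptic time constant (ms)
#' @param amplitude peak value (mV)
#' @return kernel value(s), vectorized over `t_since`
#' @export
synaptic_kernel <- function(t_since, tau_S, amplitude = 1) {
  if (tau_S <= 0) stop("tau_S must be positive")
  ifelse(t_since >= 0,
         amplitude * (t_since / tau_S) * exp(1 - t_since / tau_S),
         0)
}

#' Advance the synaptic depression variable
#'
#' Between spikes the presynaptic resource recovers toward 1 with time
#' constant `tau_D` (integrated exactly over `dt`); at a spike it is
#' depleted multiplicatively to `alpha * D` after the event amplitude has
#' been read.
#'
#' @param D current depression state in `(0, 1]`
#' @param event logical; did the presynaptic neuron spike in this step?
#' @param dt step length (ms), used only when `event` is `FALSE`
#' @param alpha depression factor in `[0, 1]`
#' @param tau_D recovery time constant (ms)
#' @return updated depression state
#' @export
update_depression <- function(D, event, dt, alpha = 0.8, tau_D = 1000) {
  if (any(D <= 0) || any(D > 1)) stop("D must lie in (0, 1]")
  if (event) alpha * D else 1 + (D - 1) * exp(-dt / tau_D)
}

#' Simulate the spiking network
#'
#' Integrates the quadratic integrate-and-fire network defined by a
#' [network_topology()] with classical RK4 at fixed step `dt`; the membrane
#' white-noise term is added once per step (Euler-Maruyama splitting).
#' Each spike of presynaptic neuron `j` schedules an alpha-function input on
#' every postsynaptic target, delivered after `synapse$delay_syn` ms with
#' amplitude `g_S * D_j` (read before depletion) and sign set by `j`'s
#' label. Independent Poisson events at rate `synapse$lambda_ext` per
#' neuron are injected as immediate excitatory events.
#'
#' @param topology a `network_topology`
#' @param neuron a [neuron_params()] list
#' @param synapse a [synapse_params()] list
#' @param duration total simulated time (ms)
#' @param dt integration step (ms)
#' @param seed RNG seed (controls initial jitter, membrane noise and the
#'   Poisson drive)
#' @param i_ext constant injected current (mV, inside the `1/tau_v`
#'   bracket); useful for single-neuron validation runs
#' @param record_v neuron indices whose membrane voltage to record
#' @param record_every record every this many steps
#' @return an object of class `spike_train_set`: list with `spikes`
#'   (data.frame `neuron`, `time` in ms), `spike_times` (per-neuron sorted
#'   lists), `n_neurons`, `duration`, `dt`, `n_ext_events` (external
#'   Poisson events delivered per neuron), and optionally `v_trace`
#' @export
run_simulation <- function(topology, neuron = neuron_params(),
                           synapse = synapse_params(), duration = 300000,
                           dt = 0.1, seed = 1, i_ext = 0,
                           record_v = integer(0), record_every = 10L) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  set.seed(seed)
  res <- sim_qif_cpp(topology$adjacency,
                     as.integer(topology$labels == "inhibitory"),
                     neuron, synapse, duration, dt, i_ext,
                     as.integer(record_v), as.integer(record_every))
  n <- topology$n_neurons
  spikes <- data.frame(neuron = res$neuron, time = res$time)
  out <- structure(list(spikes = spikes,
                        spike_times = split(spikes$time,
                                            factor(spikes$neuron, 1:n)),
                        n_neurons = n, duration = duration, dt = dt,
                        seed = seed,
                        n_ext_events = res$n_ext_events),
                   class = "spike_train_set")
  if (length(record_v)) {
    out$v_trace <- res$v_trace
    out$v_time <- seq(0, by = dt * record_every,
                      length.out = nrow(res$v_trace))
  }
  out
}

#' @export
print.spike_train_set <- function(x, ...) {
  rate <- nrow(x$spikes) / x$n_neurons / (x$duration / 1000)
  cat("spike_train_set:", x$n_neurons, "neurons,",
      sprintf("%.1f s, %d spikes (%.2f Hz/neuron)\n", x$duration / 1000,
              nrow(x$spikes), rate))
  invisible(x)
}
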