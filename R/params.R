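#' Neuron model parameters
#'
#' Parameters of the quadratic integrate-and-fire neuron with
#' spike-frequency adaptation. Membrane voltage `v` obeys
#' \deqn{\tau_v \dot v = K_v (v - v_r)(v - v_t) - w + I_S + g_\xi \xi(t)}
#' and spikes when `v >= v_p`, after which `v` is reset to `v_c` and the
#' adaptation current `w` is incremented by `delta_w`. The adaptation
#' current relaxes as \eqn{\tau_w \dot w = K_w (v - v_r) - w}.
#'
#' Defaults reproduce spiking/bursting dynamics typical of dissociated
#' cortical cultures.
#'
#' @param v_r resting potential (mV)
#' @param v_t threshold potential (mV)
#' @param v_p peak (spike) potential (mV)
#' @param v_c post-spike reset potential (mV)
#' @param tau_v membrane time constant (ms)
#' @param K_v quadratic gain (1/mV)
#' @param g_xi membrane noise amplitude (mV sqrt(ms)); the integrator adds
#'   `g_xi * sqrt(dt) * N(0,1) / tau_v` to `v` once per step. The default
#'   gives subthreshold fluctuations of about 2 mV sd, calibrated so that
#'   the 100-neuron control network exhibits the spiking/bursting
#'   population oscillations at 0.5-1 Hz typical of cultured networks (see
#'   the methods vignette for the calibration rationale)
#' @param tau_w adaptation time constant (ms)
#' @param K_w adaptation sensitivity to subthreshold voltage (dimensionless)
#' @param delta_w adaptation increment at each spike (mV)
#' @return a named list of class `neuron_params`
#' @export
neuron_params <- function(v_r = -60, v_t = -45, v_p = 35, v_c = -50,
                          tau_v = 50, K_v = 0.5, g_xi = 55,
                          tau_w = 50, K_w = 0.5, delta_w = 50) {
  stopifnot(v_r < v_t, v_t < v_p, tau_v > 0, tau_w > 0)
  structure(list(v_r = v_r, v_t = v_t, v_p = v_p, v_c = v_c, tau_v = tau_v,
                 K_v = K_v, g_xi = g_xi, tau_w = tau_w, K_w = K_w,
                 delta_w = delta_w),
            class = "neuron_params")
}

#' Synapse and external-drive parameters
#'
#' Synaptic events evoke alpha-function inputs
#' \eqn{I(t) = g_S D \, (t/\tau_S) e^{1 - t/\tau_S}} delivered
#' `delay_syn` ms after the presynaptic spike. `g_E` and `g_I` are
#' magnitudes; inputs from inhibitory sources enter the voltage equation
#' with negative sign. The presynaptic resource `D` is depleted to
#' `alpha * D` at each spike and recovers toward 1 with time constant
#' `tau_D`. Each neuron additionally receives an independent excitatory
#' Poisson drive of rate `lambda_ext` (Hz) with amplitude `g_E`, no
#' depression and no delay.
#'
#' The default excitatory/inhibitory balance is `g_E:g_I = 1:2`; vary `g_I`
#' to explore other balances.
#'
#' @param g_E excitatory synaptic strength (mV)
#' @param g_I inhibitory synaptic strength (mV, magnitude)
#' @param tau_E excitatory synaptic time constant (ms)
#' @param tau_I inhibitory synaptic time constant (ms)
#' @param delay_syn synaptic delay (ms)
#' @param alpha multiplicative depression factor in `[0, 1]`
#' @param tau_D depression recovery time constant (ms)
#' @param lambda_ext external Poisson rate per neuron (Hz)
#' @return a named list of class `synapse_params`
#' @export
synapse_params <- function(g_E = 200, g_I = 400, tau_E = 1, tau_I = 5,
                           delay_syn = 1, alpha = 0.8, tau_D = 1000,
                           lambda_ext = 0.5) {
  stopifnot(g_E >= 0, g_I >= 0, tau_E > 0, tau_I > 0, delay_syn >= 0,
            alpha >= 0, alpha <= 1, tau_D > 0, lambda_ext >= 0)
  structure(list(g_E = g_E, g_I = g_I, tau_E = tau_E, tau_I = tau_I,
                 delay_syn = delay_syn, alpha = alpha, tau_D = tau_D,
                 lambda_ext = lambda_ext),
            class = "synapse_params")
}

#' Calcium response kernel parameters
#'
#' Each spike adds a fluorescence transient
#' \eqn{A e^{-t/\tau_{decay}} (1 - e^{-t/\tau_{rise}})} to the neuron's
#' trace. Optical acquisition noise is white Gaussian with standard
#' deviation `noise_sd_fraction * A` per sample.
#'
#' @param A transient amplitude (arbitrary fluorescence units)
#' @param tau_rise rise time constant (ms)
#' @param tau_decay decay time constant (ms); must exceed `tau_rise`
#' @param noise_sd_fraction acquisition noise sd as a fraction of `A`
#' @return a named list of class `calcium_kernel_params`
#' @export
calcium_kernel_params <- function(A = 1, tau_rise = 10, tau_decay = 700,
                                  noise_sd_fraction = 0.1) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise, noise_sd_fraction >= 0)
  structure(list(A = A, tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd_fraction = noise_sd_fraction),
            class = "calcium_kernel_params")
}

#' Transfer-entropy estimator configuration
#'
#' @param k_x Markov order (number of past bins) of the target series
#' @param k_y Markov order of the source series
#' @param delay_bins offset `d` (in bins) applied to the source embedding;
#'   `d = 0` includes the same-bin source value, capturing interactions
#'   faster than the acquisition bin
#' @param roi_threshold fluorescence level on the network-average trace:
#'   only bins where the average is strictly below the threshold enter the
#'   estimate; `"all"` disables the restriction
#' @return a named list of class `te_config`
#' @export
te_config <- function(k_x = 1, k_y = 2, delay_bins = 0,
                      roi_threshold = "all") {
  stopifnot(k_x >= 1, k_y >= 1, delay_bins >= 0)
  structure(list(k_x = as.integer(k_x), k_y = as.integer(k_y),
                 delay_bins = as.integer(delay_bins),
                 roi_threshold = roi_threshold),
            class = "te_config")
}
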