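#' Simulate several model realizations of the benchmark network
#'
#' All realizations share one spatial layout and one structural adjacency
#' (drawn from `seed`); each realization redraws only the sorting of
#' excitatory and inhibitory neurons and the dynamical noise. Set
#' `resample_adjacency = TRUE` to redraw the structural network per
#' realization instead.
#'
#' @param n_realizations number of realizations
#' @param n_neurons,sigma_r,fraction_inhibitory passed to
#'   [network_topology()]
#' @param neuron,synapse model parameter lists
#' @param duration simulated time per realization (ms)
#' @param dt integration step (ms)
#' @param seed master seed; all per-realization seeds derive from it
#' @param resample_adjacency redraw positions/adjacency per realization?
#' @return list of realizations, each with `topology` and `spikes`
#' @export
simulate_realizations <- function(n_realizations = 3, n_neurons = 100,
                                  sigma_r = 0.3, fraction_inhibitory = 0.2,
                                  neuron = neuron_params(),
                                  synapse = synapse_params(),
                                  duration = 180000, dt = 0.1, seed = 1,
                                  resample_adjacency = FALSE) {
  seed <- as.integer(seed) %% 100000L
  base <- network_topology(n_neurons, sigma_r, fraction_inhibitory,
                           topology_seed = seed * 10L + 1L,
                           label_seed = seed * 10L + 2L)
  lapply(seq_len(n_realizations), function(r) {
    topo <- if (resample_adjacency && r > 1) {
      network_topology(n_neurons, sigma_r, fraction_inhibitory,
                       topology_seed = seed * 10L + 1L + 1000L * r,
                       label_seed = seed * 10L + 2L + 1000L * r)
    } else {
      relabel(base, seed * 10L + 2L + 1000L * r)
    }
    spikes <- run_simulation(topo, neuron, synapse, duration, dt,
                             seed = seed * 10L + 3L + 1000L * r)
    list(topology = topo, spikes = spikes)
  })
}

#' Calcium forward model, spike re-detection and TE inference for one
#' realization
#'
#' @param spikes a `spike_train_set`
#' @param bin_size acquisition bin (ms)
#' @param noisy add acquisition noise before re-detection?
#' @param kernel calcium kernel parameters
#' @param delays bin delays `d` at which to compute the TE sweep
#' @param k_x,k_y Markov orders
#' @param n_roi_levels ROI thresholds swept per delay
#' @param noise_seed RNG seed for the acquisition noise
#' @param raster_source `"detected"` re-extracts activity from the calcium
#'   trace (the benchmark's default); `"true"` uses the binned simulated
#'   spikes directly
#' @return list with `calcium` (`calcium_raster`), `raster`
#'   (`binary_raster`), `detection_accuracy` (vs. the binned true spikes),
#'   and `te`, a list of `local_te_result` sweeps named by delay
#' @export
infer_realization <- function(spikes, bin_size = 10, noisy = FALSE,
                              kernel = calcium_kernel_params(),
                              delays = 0:2, k_x = 1, k_y = 2,
                              n_roi_levels = 20, noise_seed = 1,
                              raster_source = c("detected", "true")) {
  raster_source <- match.arg(raster_source)
  cal <- calcium_raster(spikes, kernel, bin_size, noisy, noise_seed)
  truth_raster <- bin_spikes(spikes, bin_size)
  raster <- if (raster_source == "true") truth_raster
            else detect_spikes(cal, kernel)
  acc <- if (raster_source == "true") 1
         else detection_accuracy(raster, truth_raster)
  te <- lapply(delays, function(d)
    te_matrix(raster, te_config(k_x, k_y, delay_bins = d),
              average_trace = cal$network_average,
              n_roi_levels = n_roi_levels))
  names(te) <- paste0("d", delays)
  list(calcium = cal, raster = raster, detection_accuracy = acc, te = te)
}

#' Run the full signed-connectivity benchmark
#'
#' Simulates `n_realizations` of the spatial network, forward-models
#' calcium at each requested bin size (deterministic and, optionally,
#' noisy), re-extracts binary activity, computes local excitatory and
#' inhibitory TE at each delay with an ROI sweep, and scores both
#' components against the ground-truth signed adjacency by ROC analysis.
#'
#' @inheritParams simulate_realizations
#' @param bin_sizes acquisition bins to analyze (ms)
#' @param noise logical vector: which noise settings to analyze
#' @param delays bin delays
#' @param kernel calcium kernel parameters
#' @param k_x,k_y Markov orders of the TE estimator
#' @param n_roi_levels ROI thresholds swept
#' @param realizations optionally, pre-simulated output of
#'   [simulate_realizations()] to reuse
#' @return object of class `te_benchmark`: `summary` data.frame (one row
#'   per condition, component and delay with mean/sd of AUC, J,
#'   sensitivity, specificity), `detail` (per realization),
#'   `detection` (spike-recovery accuracy per condition/realization)
#' @export
run_benchmark <- function(n_realizations = 3, duration = 180000, seed = 1,
                          n_neurons = 100, sigma_r = 0.3,
                          fraction_inhibitory = 0.2,
                          neuron = neuron_params(),
                          synapse = synapse_params(),
                          bin_sizes = 10, noise = FALSE, delays = 0:2,
                          kernel = calcium_kernel_params(),
                          k_x = 1, k_y = 2, n_roi_levels = 20, dt = 0.1,
                          realizations = NULL) {
  if (is.null(realizations))
    realizations <- simulate_realizations(n_realizations, n_neurons,
                                          sigma_r, fraction_inhibitory,
                                          neuron, synapse, duration, dt,
                                          seed)
  seed <- as.integer(seed) %% 100000L
  summary_rows <- list()
  detail_rows <- list()
  detect_rows <- list()
  for (bin in bin_sizes) {
    for (noisy in noise) {
      tes <- vector("list", length(realizations))
      for (r in seq_along(realizations)) {
        inf <- infer_realization(realizations[[r]]$spikes, bin, noisy,
                                 kernel, delays, k_x, k_y, n_roi_levels,
                                 noise_seed = seed * 10L + 4L + 1000L * r)
        tes[[r]] <- inf$te
        detect_rows[[length(detect_rows) + 1L]] <-
          data.frame(bin_size = bin, noisy = noisy, realization = r,
                     accuracy = inf$detection_accuracy)
      }
      truths_E <- lapply(realizations, function(z) truth_matrix(z$topology, "E"))
      truths_I <- lapply(realizations, function(z) truth_matrix(z$topology, "I"))
      for (d in seq_along(delays)) {
        for (comp in c("E", "I")) {
          cond <- evaluate_condition(lapply(tes, `[[`, d),
                                     if (comp == "E") truths_E else truths_I,
                                     comp)
          summary_rows[[length(summary_rows) + 1L]] <-
            data.frame(bin_size = bin, noisy = noisy, component = comp,
                       delay = delays[d],
                       auc = cond$mean[["auc"]], auc_sd = cond$sd[["auc"]],
                       j = cond$mean[["j"]], j_sd = cond$sd[["j"]],
                       sensitivity = cond$mean[["sensitivity"]],
                       specificity = cond$mean[["specificity"]])
          detail_rows[[length(detail_rows) + 1L]] <-
            cbind(bin_size = bin, noisy = noisy, component = comp,
                  delay = delays[d], cond$per_realization)
        }
      }
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 detail = do.call(rbind, detail_rows),
                 detection = do.call(rbind, detect_rows),
                 n_realizations = length(realizations),
                 duration = realizations[[1]]$spikes$duration,
                 seed = seed),
            class = "te_benchmark")
}

#' @export
print.te_benchmark <- function(x, ...) {
  cat("te_benchmark:", x$n_realizations, "realization(s),",
      sprintf("%.0f s each\n", x$duration / 1000))
  print(transform(x$summary,
                  auc = round(auc, 3), auc_sd = round(auc_sd, 3),
                  j = round(j, 3), j_sd = round(j_sd, 3),
                  sensitivity = round(sensitivity, 3),
                  specificity = round(specificity, 3)))
  invisible(x)
}

#' Reproduce the benchmark condition tables
#'
#' Emits machine-readable analogues of the three headline tables: rows
#' AUC, J, sensitivity and specificity; columns the excitatory and
#' inhibitory components at delays 0, 1, 2.
#' * `table = 1`: 10 ms bins, `g_E:g_I = 1:2`, deterministic and noisy.
#' * `table = 2`: 10 ms bins, deterministic, `g_E:g_I = 1:1` and `1:3`.
#' * `table = 3`: deterministic, `g_E:g_I = 1:2`, 5 and 20 ms bins.
#'
#' @param table which table to reproduce (1, 2 or 3)
#' @param n_realizations realizations per condition
#' @param duration simulated time per realization (ms)
#' @param seed master seed
#' @param ... further arguments passed to [run_benchmark()]
#' @return a data.frame in long format with columns `condition`,
#'   `component`, `delay`, `metric`, `mean`, `sd`
#' @export
reproduce_table <- function(table = 1, n_realizations = 3,
                            duration = 180000, seed = 1, ...) {
  stopifnot(table %in% 1:3)
  runs <- switch(as.character(table),
    "1" = list(list(label = "deterministic bin10 1:2", g_I = 400,
                    bin = 10, noise = FALSE),
               list(label = "noise bin10 1:2", g_I = 400, bin = 10,
                    noise = TRUE)),
    "2" = list(list(label = "deterministic bin10 1:1", g_I = 200,
                    bin = 10, noise = FALSE),
               list(label = "deterministic bin10 1:3", g_I = 600,
                    bin = 10, noise = FALSE)),
    "3" = list(list(label = "deterministic bin5 1:2", g_I = 400,
                    bin = 5, noise = FALSE),
               list(label = "deterministic bin20 1:2", g_I = 400,
                    bin = 20, noise = FALSE)))
  out <- list()
  for (run in runs) {
    bm <- run_benchmark(n_realizations = n_realizations,
                        duration = duration, seed = seed,
                        synapse = synapse_params(g_I = run$g_I),
                        bin_sizes = run$bin, noise = run$noise, ...)
    s <- bm$summary
    for (metric in c("auc", "j", "sensitivity", "specificity")) {
      sdcol <- if (metric %in% c("auc", "j")) paste0(metric, "_sd") else NA
      out[[length(out) + 1L]] <-
        data.frame(condition = run$label, component = s$component,
                   delay = s$delay, metric = metric, mean = s[[metric]],
                   sd = if (!is.na(sdcol)) s[[sdcol]] else NA_real_)
    }
  }
  do.call(rbind, out)
}
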