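#' Write / read a binary raster as delimited text
#'
#' Rasters are stored as tab-separated `neurons x bins` matrices with a
#' header comment carrying the bin size and provenance, so externally
#' produced rasters (any delimited 0/1 matrix) can also be read and fed to
#' [te_matrix()].
#'
#' @param raster a `binary_raster`
#' @param path output file
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# binary_raster bin_size=%g provenance=%s",
                     raster$bin_size, raster$provenance), con)
  write.table(raster$states, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @param bin_size bin size to assume when the file has no header comment
#' @return `read_raster()` returns a `binary_raster`
#' @export
read_raster <- function(path, bin_size = 1) {
  first <- readLines(path, n = 1)
  provenance <- "user"
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("bin_size=([0-9.]+)", first))[[1]]
    if (length(m) == 2) bin_size <- as.numeric(m[2])
    m <- regmatches(first, regexec("provenance=(\\S+)", first))[[1]]
    if (length(m) == 2) provenance <- m[2]
  }
  states <- as.matrix(read.table(path, skip = skip, sep = "\t"))
  dimnames(states) <- NULL
  binary_raster(states, bin_size, provenance)
}

#' Serialize a network topology to a directory of delimited-text tables
#'
#' Writes `positions.tsv` (neuron_id, x, y), `labels.tsv` (neuron_id,
#' type), `adjacency.tsv` (dense 0/1, rows = targets) and
#' `adjacency_signed.tsv` (+1 excitatory source, -1 inhibitory source).
#'
#' @param topology a `network_topology`
#' @param dir output directory (created if missing)
#' @export
write_topology <- function(topology, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- topology$n_neurons
  write.table(data.frame(neuron_id = 1:n, x = topology$positions[, 1],
                         y = topology$positions[, 2]),
              file.path(dir, "positions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(neuron_id = 1:n, type = topology$labels),
              file.path(dir, "labels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(topology$adjacency, file.path(dir, "adjacency.tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(signed_adjacency(topology),
              file.path(dir, "adjacency_signed.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write spike trains as two-column delimited text
#'
#' @param spikes a `spike_train_set`
#' @param path output file (columns `neuron_id`, `spike_time_ms`)
#' @export
write_spikes <- function(spikes, path) {
  write.table(setNames(spikes$spikes, c("neuron_id", "spike_time_ms")),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the whole pipeline from a config list and write all stage outputs
#'
#' Thin orchestration over [simulate_realizations()],
#' [infer_realization()] and [evaluate_condition()]: writes topology
#' tables, spike trains, rasters, TE matrices at the best ROI level, the
#' benchmark summary and a run manifest (all parameters and seeds) into
#' `out_dir`.
#'
#' @param config named list; recognized keys (with defaults):
#'   `n_realizations` (1), `n_neurons` (100), `sigma_r` (0.3),
#'   `fraction_inhibitory` (0.2), `duration` (180000), `dt` (0.1),
#'   `g_E` (200), `g_I` (400), `bin_size` (10), `noisy` (FALSE),
#'   `delays` (0:2), `k_x` (1), `k_y` (2), `n_roi_levels` (20)
#' @param out_dir output directory
#' @param seed master seed
#' @return the `te_benchmark` object, invisibly
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  defaults <- list(n_realizations = 1, n_neurons = 100, sigma_r = 0.3,
                   fraction_inhibitory = 0.2, duration = 180000, dt = 0.1,
                   g_E = 200, g_I = 400, bin_size = 10, noisy = FALSE,
                   delays = 0:2, k_x = 1, k_y = 2, n_roi_levels = 20)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reals <- simulate_realizations(cfg$n_realizations, cfg$n_neurons,
                                 cfg$sigma_r, cfg$fraction_inhibitory,
                                 neuron_params(),
                                 synapse_params(g_E = cfg$g_E,
                                                g_I = cfg$g_I),
                                 cfg$duration, cfg$dt, seed)
  write_topology(reals[[1]]$topology, file.path(out_dir, "topology"))
  for (r in seq_along(reals)) {
    rdir <- file.path(out_dir, sprintf("realization_%02d", r))
    dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(neuron_id = 1:cfg$n_neurons,
                           type = reals[[r]]$topology$labels),
                file.path(rdir, "labels.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write_spikes(reals[[r]]$spikes, file.path(rdir, "spikes.tsv"))
    inf <- infer_realization(reals[[r]]$spikes, cfg$bin_size, cfg$noisy,
                             delays = cfg$delays, k_x = cfg$k_x,
                             k_y = cfg$k_y,
                             n_roi_levels = cfg$n_roi_levels,
                             noise_seed = seed + 7L * r)
    write_raster(inf$raster, file.path(rdir, "raster.tsv"))
    for (dn in names(inf$te)) {
      te <- inf$te[[dn]]
      best <- score_component(te, truth_matrix(reals[[r]]$topology, "I"),
                              "I")$roi_level
      for (comp in c("te_total", "te_E", "te_I"))
        write.table(te[[comp]][, , best],
                    file.path(rdir, sprintf("%s_%s.tsv", comp, dn)),
                    sep = "\t", row.names = FALSE, col.names = FALSE)
    }
  }
  bm <- run_benchmark(realizations = reals, bin_sizes = cfg$bin_size,
                      noise = cfg$noisy, delays = cfg$delays,
                      k_x = cfg$k_x, k_y = cfg$k_y,
                      n_roi_levels = cfg$n_roi_levels, seed = seed,
                      synapse = synapse_params(g_E = cfg$g_E,
                                               g_I = cfg$g_I))
  write.table(bm$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest <- c(sprintf("package_version: %s",
                        as.character(utils::packageVersion("neuroTE"))),
               sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               sprintf("seed: %d", seed),
               paste0(names(cfg), ": ",
                      vapply(cfg, function(v) paste(v, collapse = ","),
                             character(1))))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(bm)
}
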