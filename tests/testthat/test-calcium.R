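make_spikes <- function(times, neuron = 1L, n_neurons = 1L,
                        duration = 2000, dt = 0.1) {
  structure(list(spikes = data.frame(neuron = rep(neuron,
                                                  length.out = length(times)),
                                     time = times),
                 n_neurons = n_neurons, duration = duration, dt = dt),
            class = "spike_train_set")
}

test_that("calcium transients superpose the analytic kernel per spike", {
  empty <- make_spikes(numeric(0))
  expect_true(all(convolve_calcium(empty) == 0))

  # single spike: compare the whole trace against the closed-form kernel
  sp <- make_spikes(100)
  tr <- convolve_calcium(sp, dt = 0.1)
  tt <- seq(0.1, 2000, 0.1)
  expect_equal(tr[1, ], calcium_kernel_fun(tt - 100), tolerance = 1e-10)

  # analytic argmax t* = tau1 * log((tau1 + tau2)/tau1) and peak value
  t_star <- 10 * log(71)
  expect_equal(tt[which.max(tr[1, ])] - 100, t_star, tolerance = 0.1)
  expect_equal(max(tr[1, ]), calcium_kernel_fun(t_star), tolerance = 1e-6)
  expect_equal(max(tr[1, ]), 0.927, tolerance = 1e-3)

  # linearity: merged spike trains give the summed trace, exactly
  a <- make_spikes(c(50, 300))
  b <- make_spikes(c(120, 800, 801))
  ab <- make_spikes(sort(c(50, 300, 120, 800, 801)))
  expect_equal(convolve_calcium(ab), convolve_calcium(a) + convolve_calcium(b),
               tolerance = 1e-12)
})

test_that("acquisition noise is seeded additive white Gaussian of the stated sd", {
  tr <- matrix(0, 2, 50000)
  expect_identical(add_noise(tr, 0), tr)
  n1 <- add_noise(tr, 0.1, A = 1, seed = 1)
  expect_equal(sd(n1 - tr), 0.1, tolerance = 0.005)
  n2 <- add_noise(tr, 0.1, A = 1, seed = 2)
  expect_false(identical(n1, n2))
  # clean component unchanged: same seeds on a different clean trace
  tr2 <- matrix(5, 2, 50000)
  expect_equal(add_noise(tr2, 0.1, A = 1, seed = 1) - tr2, n1 - tr,
               tolerance = 1e-12)
})

test_that("down-sampling decimates traces and ORs spikes within bins", {
  m <- matrix(seq_len(40), 2, 20, byrow = TRUE)
  expect_identical(downsample(m, bin_size = 1, dt = 1), m)
  expect_error(downsample(m, bin_size = 0.3, dt = 0.2), "integer multiple")
  d <- downsample(m, bin_size = 5, dt = 1)
  expect_identical(d, m[, c(5, 10, 15, 20)])

  # spike at 12 ms with 10 ms bins lands in the second bin: [10, 20)
  sp <- make_spikes(12, duration = 50)
  r <- downsample(sp, 10)
  expect_s3_class(r, "binary_raster")
  expect_identical(r$states[1, ], c(0L, 1L, 0L, 0L, 0L))

  # a 3-second train at dt = 0.1 ms binned at 10 ms has 300 bins
  sp <- make_spikes(c(1, 2999.95), duration = 3000)
  expect_identical(ncol(bin_spikes(sp, 10)$states), 300L)

  # binning commutes with OR-decimation of the fine binary raster
  set.seed(2)
  times <- sort(runif(40, 0, 499))
  times <- round(times / 0.1) * 0.1 + 0.1          # snap to the dt grid
  sp <- make_spikes(times, duration = 500)
  coarse <- bin_spikes(sp, 10)$states[1, ]
  fine <- bin_spikes(sp, 0.1)$states[1, ]
  ored <- tapply(fine, rep(1:50, each = 100), max)
  expect_identical(unname(coarse), as.integer(ored))
})

test_that("raster objects validate entries and recompute the network average", {
  expect_error(binary_raster(matrix(c(0, 2), 1, 2), 1), "0/1")
  sml <- small_sim()
  cal <- calcium_raster(sml$spikes, bin_size = 10)
  expect_equal(cal$network_average, colMeans(cal$traces))
  expect_identical(ncol(cal$traces), 3000L)
})

test_that("derivative detection recovers the binned spike train", {
  # constant trace: no onsets
  flat <- structure(list(traces = matrix(1, 3, 100), bin_size = 10,
                         noisy = FALSE), class = "calcium_raster")
  expect_true(all(detect_spikes(flat)$states == 0L))

  sml <- small_sim()
  truth <- bin_spikes(sml$spikes, 10)

  cal <- calcium_raster(sml$spikes, bin_size = 10, noisy = FALSE)
  det <- detect_spikes(cal)
  expect_identical(det$provenance, "detected_from_deterministic")
  expect_gt(detection_accuracy(det, truth), 0.95)
  # strict same-bin recovery is lower but still high
  expect_gt(detection_accuracy(det, truth, tolerance_bins = 0), 0.7)
  # false-active load stays small
  expect_lt(mean(det$states[truth$states == 0L]), 0.05)

  caln <- calcium_raster(sml$spikes, bin_size = 10, noisy = TRUE, seed = 5)
  detn <- detect_spikes(caln)
  expect_identical(detn$provenance, "detected_from_noisy")
  expect_gt(detection_accuracy(detn, truth), 0.8)

  # accuracy is monotonically non-increasing in the noise level
  accs <- vapply(c(0, 0.1, 0.25, 0.5), function(ns) {
    kern <- calcium_kernel_params(noise_sd_fraction = ns)
    cal <- calcium_raster(sml$spikes, kern, bin_size = 10,
                          noisy = ns > 0, seed = 5)
    detection_accuracy(detect_spikes(cal, kern), truth)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.01))
})
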