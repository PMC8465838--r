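# Naive oracle: explicit probability tables straight from the defining sum,
# independent of both the R reference and the C++ production code.
naive_te <- function(x, y, kx, ky, d, roi = NULL) {
  T_ <- length(x)
  n0 <- max(kx, d + ky - 1L)
  rows <- list()
  for (n in (n0 + 1L):T_) {
    if (!is.null(roi) && !roi[n]) next
    rows[[length(rows) + 1L]] <-
      c(x[n], x[n - seq_len(kx)], y[n - d - seq_len(ky) + 1L])
  }
  tup <- do.call(rbind, rows)
  key_all <- apply(tup, 1, paste, collapse = ",")
  key_xyp <- apply(tup[, -1, drop = FALSE], 1, paste, collapse = ",")
  key_xxp <- apply(tup[, 1:(1 + kx), drop = FALSE], 1, paste, collapse = ",")
  key_xp <- apply(tup[, 2:(1 + kx), drop = FALSE], 1, paste, collapse = ",")
  N <- nrow(tup)
  te_e <- te_i <- 0
  for (s in unique(key_all)) {
    idx <- which(key_all == s)[1]
    p_s <- sum(key_all == s) / N
    p_cond_joint <- sum(key_all == s) / sum(key_xyp == key_xyp[idx])
    p_cond_self <- sum(key_xxp == key_xxp[idx]) / sum(key_xp == key_xp[idx])
    term <- p_s * log2(p_cond_joint / p_cond_self)
    y_active <- any(tup[idx, (2 + kx):(1 + kx + ky)] == 1)
    if (y_active == (tup[idx, 1] == 1)) te_e <- te_e + term
    else te_i <- te_i + term
  }
  list(te_E = te_e, te_I = te_i, te_total = te_e + te_i)
}

te_pair_cpp <- function(x, y, cfg, average = NULL) {
  r <- te_matrix(rbind(y, x), cfg, average_trace = average, n_roi_levels = 1)
  list(te_total = r$te_total[2, 1, 1], te_E = r$te_E[2, 1, 1],
       te_I = r$te_I[2, 1, 1])
}

test_that("state embedding indexes target past and delayed source correctly", {
  x <- c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  y <- c(1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L)
  expect_error(embed_states(x, y[1:5], te_config()), "equal length")
  expect_error(embed_states(x[1:3], y[1:3], te_config(1, 2, 2)), "too short")

  # d = 0 includes the same-bin source value
  emb <- embed_states(x, y, te_config(k_x = 1, k_y = 2, delay_bins = 0))
  n6 <- emb[attr(emb, "n_index") == 6, ]
  expect_identical(unname(n6), c(x[6], x[5], y[6], y[5]))

  emb <- embed_states(x, y, te_config(k_x = 1, k_y = 2, delay_bins = 2))
  expect_identical(nrow(emb), 7L)
  expect_identical(attr(emb, "n_index"), 4:10)
  n6 <- emb[attr(emb, "n_index") == 6, ]
  expect_identical(unname(n6), c(x[6], x[5], y[4], y[3]))
})

test_that("TE vanishes for uninformative sources and is non-negative", {
  set.seed(1)
  x <- as.integer(runif(500) < 0.4)
  # constant source: single source state, conditionals coincide
  expect_equal(transfer_entropy(x, rep(0L, 500), te_config(1, 2, 1)), 0)
  # exactly factorized counts: x_n alternates independently of y
  x2 <- rep(c(0L, 1L), 50)
  y2 <- rep(c(0L, 0L, 1L, 1L), 25)
  expect_equal(transfer_entropy(x2, y2, te_config(1, 1, 1)), 0,
               tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(s)
    xx <- as.integer(runif(300) < 0.3)
    yy <- as.integer(runif(300) < 0.3)
    expect_gte(transfer_entropy(xx, yy, te_config(1, 2, 1)), 0)
  }
})

test_that("a perfect copier carries H(x_n | x_past) bits, all excitatory", {
  set.seed(7)
  y <- as.integer(runif(400) < 0.35)
  x <- c(0L, y[-400])
  cfg <- te_config(k_x = 1, k_y = 1, delay_bins = 1)
  sp <- local_te_split(x, y, cfg)
  # by-hand conditional entropy of x_n given x_{n-1} on the same tuples
  # (valid n runs from 2 to 400 for this embedding)
  xn <- x[2:400]; xp <- x[1:399]
  h <- 0
  for (a in 0:1) for (b in 0:1) {
    p_ab <- mean(xn == a & xp == b)
    p_cond <- p_ab / mean(xp == b)
    if (p_ab > 0) h <- h - p_ab * log2(p_cond)
  }
  expect_equal(sp$te_total, h, tolerance = 1e-12)
  expect_equal(sp$te_I, 0, tolerance = 1e-12)

  # perfect inverter: all mass in opposite-event states
  xi <- c(0L, 1L - y[-400])
  spi <- local_te_split(xi, y, cfg)
  expect_equal(spi$te_E, 0, tolerance = 1e-12)
  expect_equal(spi$te_total, spi$te_I, tolerance = 1e-12)
})

test_that("production estimator matches the naive oracle exhaustively", {
  # every 0/1 series pair of length 6 at k_x = k_y = 1, d = 1
  cfg <- te_config(1, 1, 1)
  grid <- as.matrix(expand.grid(rep(list(0:1), 6)))
  for (i in seq_len(nrow(grid))) {
    x <- as.integer(grid[i, ])
    for (j in c(1, 17, 33, 64)) {
      y <- as.integer(grid[j, ])
      ref <- naive_te(x, y, 1, 1, 1)
      got <- local_te_split(x, y, cfg)
      expect_equal(got$te_total, ref$te_total, tolerance = 1e-12)
      expect_equal(got$te_E, ref$te_E, tolerance = 1e-12)
      expect_equal(got$te_I, ref$te_I, tolerance = 1e-12)
      gotc <- te_pair_cpp(x, y, cfg)
      expect_equal(gotc$te_total, ref$te_total, tolerance = 1e-12)
      expect_equal(gotc$te_E, ref$te_E, tolerance = 1e-12)
    }
  }
  # longer random series at the production orders kx=1, ky=2, several delays
  for (s in 1:6) {
    set.seed(s)
    x <- as.integer(runif(200) < 0.3)
    y <- as.integer(runif(200) < 0.3)
    d <- s %% 3
    ref <- naive_te(x, y, 1, 2, d)
    got <- local_te_split(x, y, te_config(1, 2, d))
    gotc <- te_pair_cpp(x, y, te_config(1, 2, d))
    expect_equal(got$te_total, ref$te_total, tolerance = 1e-12)
    expect_equal(got$te_E, ref$te_E, tolerance = 1e-12)
    expect_equal(gotc$te_total, ref$te_total, tolerance = 1e-12)
    expect_equal(gotc$te_I, ref$te_I, tolerance = 1e-12)
  }
})

test_that("partition identity and 0/1 relabeling invariance hold", {
  for (s in 1:8) {
    set.seed(s)
    x <- as.integer(runif(300) < runif(1, 0.2, 0.6))
    y <- as.integer(runif(300) < runif(1, 0.2, 0.6))
    cfg <- te_config(1, 2, s %% 3)
    sp <- local_te_split(x, y, cfg)
    expect_equal(sp$te_E + sp$te_I, sp$te_total, tolerance = 1e-12)
    expect_gte(sp$te_total, -1e-14)
    # relabeling both series leaves the total invariant
    flip <- local_te_split(1L - x, 1L - y, cfg)
    expect_equal(flip$te_total, sp$te_total, tolerance = 1e-12)
  }
})

test_that("ROI selection masks bins by the network-average level", {
  avg <- c(0.1, 0.9, 0.2, 0.8)
  expect_identical(select_roi(avg, 0.5), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(select_roi(avg, "all"), rep(TRUE, 4))
  expect_identical(select_roi(avg, max(avg) + 0.01), rep(TRUE, 4))
  expect_identical(select_roi(avg, min(avg)), rep(FALSE, 4))

  # estimators agree under an ROI mask; embeddings may leave the mask
  set.seed(3)
  x <- as.integer(runif(400) < 0.3)
  y <- as.integer(c(0, x[-400]) | (runif(400) < 0.1))
  avg <- runif(400)
  mask <- select_roi(avg, 0.6)
  cfg <- te_config(1, 2, 1)
  ref <- naive_te(x, y, 1, 2, 1, roi = mask)
  got <- local_te_split(x, y, cfg, roi_mask = mask)
  expect_equal(got$te_total, ref$te_total, tolerance = 1e-12)
  expect_equal(got$te_E, ref$te_E, tolerance = 1e-12)
  expect_error(local_te_split(x, y, cfg, roi_mask = rep(FALSE, 400)),
               "insufficient")
})

test_that("pairwise TE matrices are oriented source->target with NA diagonal", {
  set.seed(11)
  y <- as.integer(runif(2000) < 0.3)
  x <- c(0L, y[-2000])                    # neuron 2 copies neuron 1
  z <- as.integer(runif(2000) < 0.3)      # independent bystander
  ras <- binary_raster(rbind(y, x, z), 1, "user")
  res <- te_matrix(ras, te_config(1, 1, 1))
  m <- res$te_total[, , 1]
  expect_true(all(is.na(diag(m))))
  # tight coupling 1 -> 2: entry [target=2, source=1] dominates
  expect_gt(m[2, 1], 10 * m[1, 2])
  expect_gt(m[2, 1], 10 * max(m[3, 1], m[2, 3], na.rm = TRUE))
  # partition identity across the whole matrix
  expect_equal(res$te_E + res$te_I, res$te_total, tolerance = 1e-12)

  # per-pair agreement with the single-pair reference implementation
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    ref <- transfer_entropy(ras$states[i, ], ras$states[j, ],
                            te_config(1, 1, 1))
    expect_equal(m[i, j], ref, tolerance = 1e-12)
  }
})

test_that("time-shuffling the source collapses TE toward the bias floor", {
  set.seed(21)
  y <- as.integer(runif(3000) < 0.3)
  x <- as.integer(c(0L, y[-3000]) | (runif(3000) < 0.05))
  cfg <- te_config(1, 2, 1)
  coupled <- transfer_entropy(x, y, cfg)
  shuffled <- vapply(1:11, function(s) {
    set.seed(100 + s)
    transfer_entropy(x, sample(y), cfg)
  }, numeric(1))
  expect_lt(median(shuffled), coupled / 5)
})

test_that("the ROI sweep nests masks and matches per-threshold recomputation", {
  sml <- small_sim()
  cal <- calcium_raster(sml$spikes, bin_size = 10)
  ras <- detect_spikes(cal)
  cfg <- te_config(1, 2, 1)
  sweep <- te_matrix(ras, cfg, average_trace = cal$network_average,
                     n_roi_levels = 10)
  expect_identical(dim(sweep$te_total), c(30L, 30L, 10L))
  expect_true(all(diff(sweep$n_samples) >= 0))
  expect_equal(sweep$te_E + sweep$te_I, sweep$te_total, tolerance = 1e-12)

  # spot-check one interior level against the single-pair reference
  lev <- 6
  mask <- select_roi(cal$network_average, sweep$roi_thresholds[lev])
  ref <- local_te_split(ras$states[4, ], ras$states[9, ], cfg,
                        roi_mask = mask)
  expect_equal(sweep$te_total[4, 9, lev], ref$te_total, tolerance = 1e-12)
  expect_equal(sweep$te_I[4, 9, lev], ref$te_I, tolerance = 1e-12)
})
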