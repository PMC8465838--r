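#' Embed a pair of binary series into TE state tuples
#'
#' For each valid time index `n` (1-based), emits the target's current bin
#' `x_n`, its past `x_past = (x_{n-1}, ..., x_{n-k_x})` and the delayed
#' source embedding `y_past = (y_{n-d}, ..., y_{n-d-k_y+1})`. With
#' `delay_bins = 0` the same-bin source value `y_n` is the first entry of
#' `y_past`.
#'
#' @param x target binary series
#' @param y source binary series, same length
#' @param cfg a [te_config()]
#' @return integer matrix with columns `x_n`, `x_past_1..k_x`,
#'   `y_past_1..k_y`; attribute `n_index` holds the time index of each row
#' @export
embed_states <- function(x, y, cfg = te_config()) {
  T_ <- length(x)
  if (length(y) != T_) stop("series must have equal length")
  kx <- cfg$k_x; ky <- cfg$k_y; d <- cfg$delay_bins
  n0 <- max(kx, d + ky - 1L)
  if (T_ <= n0) stop("series too short for the requested embedding")
  n <- (n0 + 1L):T_
  xp <- vapply(seq_len(kx), function(q) x[n - q], integer(length(n)))
  yp <- vapply(seq_len(ky), function(q) y[n - d - q + 1L],
               integer(length(n)))
  out <- cbind(x_n = x[n], matrix(xp, ncol = kx,
                                  dimnames = list(NULL, paste0("x_past_", seq_len(kx)))),
               matrix(yp, ncol = ky,
                      dimnames = list(NULL, paste0("y_past_", seq_len(ky)))))
  attr(out, "n_index") <- n
  out
}

#' ROI mask from the network-average trace
#'
#' Selects the time bins whose network-average fluorescence lies strictly
#' below `threshold`, excluding globally synchronous (bursting) epochs from
#' the TE estimate. `"all"` selects every bin.
#'
#' @param average_trace per-bin mean fluorescence over neurons
#' @param threshold fluorescence level, or `"all"`
#' @return logical mask over bins
#' @export
select_roi <- function(average_trace, threshold = "all") {
  if (identical(threshold, "all")) return(rep(TRUE, length(average_trace)))
  average_trace < threshold
}

te_from_table <- function(emb, kx, ky) {
  key <- apply(emb, 1, paste, collapse = "")
  cnt <- table(key)
  tot <- sum(cnt)
  states <- names(cnt)
  xn <- substr(states, 1, 1)
  xp <- substr(states, 2, 1 + kx)
  yp <- substr(states, kx + 2, kx + 1 + ky)
  n_xyp <- tapply(as.numeric(cnt), paste(xp, yp), sum)
  n_xxp <- tapply(as.numeric(cnt), paste(xn, xp), sum)
  n_xp <- tapply(as.numeric(cnt), xp, sum)
  te_e <- 0; te_i <- 0
  for (s in seq_along(cnt)) {
    c_s <- as.numeric(cnt[s])
    p_joint <- c_s / n_xyp[[paste(xp[s], yp[s])]]
    p_self <- n_xxp[[paste(xn[s], xp[s])]] / n_xp[[xp[s]]]
    term <- (c_s / tot) * log2(p_joint / p_self)
    y_active <- grepl("1", yp[s], fixed = TRUE)
    if ((xn[s] == "1") == y_active) te_e <- te_e + term
    else te_i <- te_i + term
  }
  list(te_E = unname(te_e), te_I = unname(te_i),
       te_total = unname(te_e + te_i), n = tot)
}

#' Plug-in Transfer Entropy between two binary series
#'
#' Empirical-frequency estimator of
#' \deqn{TE_{Y \to X} = \sum P(x_n, x^{(k_x)}_{n-1}, y^{(k_y)}_{n-d})
#'   \log_2 \frac{P(x_n | x^{(k_x)}_{n-1}, y^{(k_y)}_{n-d})}
#'               {P(x_n | x^{(k_x)}_{n-1})}}
#' over the state tuples of [embed_states()] whose time index survives
#' `roi_mask`. Summands with zero joint probability contribute 0.
#'
#' This is the transparent single-pair reference implementation; use
#' [te_matrix()] for all-pairs computation.
#'
#' @param x target binary series
#' @param y source binary series
#' @param cfg a [te_config()]
#' @param roi_mask logical mask over time bins (`NULL` = all)
#' @return TE in bits (non-negative)
#' @export
transfer_entropy <- function(x, y, cfg = te_config(), roi_mask = NULL) {
  local_te_split(x, y, cfg, roi_mask)$te_total
}

#' Local excitatory/inhibitory decomposition of Transfer Entropy
#'
#' Routes each summand of the plug-in TE to the excitatory component when
#' the source embedding and the target's current bin carry the same event
#' (both active or both inactive) and to the inhibitory component when they
#' carry opposite events. The source embedding `y_past` counts as active
#' when at least one of its entries is 1; the full vector still enters all
#' probability estimates. The two components partition the total:
#' `te_E + te_I = te_total` exactly.
#'
#' @inheritParams transfer_entropy
#' @return list with `te_E`, `te_I`, `te_total` (bits) and `n` tuples used
#' @export
local_te_split <- function(x, y, cfg = te_config(), roi_mask = NULL) {
  emb <- embed_states(x, y, cfg)
  n_index <- attr(emb, "n_index")
  if (!is.null(roi_mask)) {
    keep <- roi_mask[n_index]
    if (!any(keep)) stop("insufficient data: ROI mask selects no tuples")
    emb <- emb[keep, , drop = FALSE]
  }
  te_from_table(emb, cfg$k_x, cfg$k_y)
}

roi_level_index <- function(average_trace, n_levels) {
  lo <- min(average_trace); hi <- max(average_trace)
  if (hi <= lo) return(rep(1L, length(average_trace)))
  step <- (hi - lo) / n_levels
  pmin(as.integer(floor((average_trace - lo) / step)) + 1L,
       n_levels + 1L)
}

#' ROI threshold grid for a network-average trace
#'
#' @param average_trace per-bin network mean
#' @param n_levels number of evenly spaced levels between min and max
#' @return numeric vector of thresholds (level `l` at
#'   `min + l * (max - min) / n_levels`)
#' @export
roi_thresholds <- function(average_trace, n_levels = 20) {
  lo <- min(average_trace); hi <- max(average_trace)
  lo + seq_len(n_levels) * (hi - lo) / n_levels
}

#' Pairwise local TE matrices for a binary raster
#'
#' Computes total, excitatory and inhibitory TE for every ordered pair
#' (source -> target) of the raster, for a whole nested family of ROI
#' selections in one pass. Entry `[i, j]` of each matrix is the TE from
#' source `j` to target `i`, matching the orientation of the structural
#' adjacency. The diagonal is `NA`.
#'
#' When `average_trace` is supplied, `n_roi_levels` thresholds evenly
#' spaced between its minimum and maximum are swept (level `L` retains
#' nearly all bins, low levels only the quietest epochs); otherwise a
#' single all-bins estimate is returned. The ROI gates only the current
#' time index of each tuple; embedding vectors may reach outside it.
#'
#' @param raster a `binary_raster` (or plain 0/1 matrix, neurons x bins)
#' @param cfg a [te_config()] (its `roi_threshold` is ignored here)
#' @param average_trace network-average fluorescence per bin, or `NULL`
#' @param n_roi_levels number of ROI levels when sweeping
#' @return object of class `local_te_result`: list with `te_total`, `te_E`,
#'   `te_I` (each `n x n x n_levels`), `roi_thresholds`, `n_samples` per
#'   level, and `config`
#' @export
te_matrix <- function(raster, cfg = te_config(), average_trace = NULL,
                      n_roi_levels = 20) {
  states <- if (inherits(raster, "binary_raster")) raster$states
            else {
              storage.mode(raster) <- "integer"
              raster
            }
  if (nrow(states) < 2) stop("need at least 2 neurons")
  T_ <- ncol(states)
  if (is.null(average_trace)) {
    lev <- rep(1L, T_)
    L <- 1L
    thr <- NA_real_
  } else if (is.numeric(cfg$roi_threshold)) {
    # single fixed ROI threshold taken from the config
    if (length(average_trace) != T_)
      stop("average_trace length must match raster bins")
    lev <- ifelse(average_trace < cfg$roi_threshold, 1L, 2L)
    L <- 1L
    thr <- cfg$roi_threshold
  } else {
    if (length(average_trace) != T_)
      stop("average_trace length must match raster bins")
    L <- as.integer(n_roi_levels)
    lev <- roi_level_index(average_trace, L)
    thr <- roi_thresholds(average_trace, L)
  }
  res <- te_local_pairs_cpp(states, cfg$k_x, cfg$k_y, cfg$delay_bins,
                            lev, L)
  structure(list(te_total = res$te_total, te_E = res$te_E,
                 te_I = res$te_I, roi_thresholds = thr,
                 n_samples = res$n_samples, config = cfg),
            class = "local_te_result")
}

#' @export
print.local_te_result <- function(x, ...) {
  dm <- dim(x$te_total)
  cat("local_te_result:", dm[1], "neurons,", dm[3], "ROI level(s),",
      sprintf("kx=%d ky=%d d=%d\n", x$config$k_x, x$config$k_y,
              x$config$delay_bins))
  invisible(x)
}
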