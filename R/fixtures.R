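#' Analytically characterized test rasters
#'
#' Generates small binary rasters with known TE signatures, used to
#' validate the estimator and the ROC scorer:
#' * `"copier"` — neuron 2 copies neuron 1 with a 1-bin lag: a pure
#'   excitatory signature (all empirical mass in same-event states, so the
#'   inhibitory TE component vanishes at the matching delay).
#' * `"inverter"` — neuron 2 outputs the negation of neuron 1's previous
#'   bin: a pure inhibitory signature.
#' * `"independent"` — two independent Bernoulli series (null).
#' * `"tiny-net"` — a 5-neuron network with known signed adjacency, driven
#'   by a logistic spiking rule on the previous bin (excitatory sources
#'   raise, inhibitory sources lower, the firing probability).
#'
#' @param kind fixture type
#' @param T_ number of bins (>= 10)
#' @param seed RNG seed
#' @param p firing probability of the driving series
#' @return list with `raster` (a `binary_raster`) and `truth_signed`
#'   (signed adjacency, `[target, source]`)
#' @export
make_fixtures <- function(kind = c("copier", "inverter", "independent",
                                   "tiny-net"),
                          T_ = 1000, seed = 1, p = 0.3) {
  kind <- match.arg(kind)
  if (T_ < 10) stop("T_ must be at least 10")
  set.seed(seed)
  if (kind %in% c("copier", "inverter", "independent")) {
    y <- as.integer(runif(T_) < p)
    x <- switch(kind,
                copier = c(0L, y[-T_]),
                inverter = c(0L, 1L - y[-T_]),
                independent = as.integer(runif(T_) < p))
    truth <- matrix(0L, 2, 2)
    if (kind == "copier") truth[2, 1] <- 1L
    if (kind == "inverter") truth[2, 1] <- -1L
    return(list(raster = binary_raster(rbind(y, x), 1, "user"),
                truth_signed = truth))
  }
  # tiny-net: 5 neurons, fixed signed adjacency [target, source]
  truth <- matrix(0L, 5, 5)
  truth[2, 1] <- 1L   # 1 -> 2 excitatory
  truth[3, 1] <- 1L   # 1 -> 3 excitatory
  truth[4, 3] <- -1L  # 3 -> 4 inhibitory
  truth[5, 4] <- 1L   # 4 -> 5 excitatory
  truth[1, 5] <- -1L  # 5 -> 1 inhibitory
  states <- matrix(0L, 5, T_)
  states[, 1] <- as.integer(runif(5) < p)
  b0 <- stats::qlogis(p)
  for (n in 2:T_) {
    drive <- truth %*% states[, n - 1]
    states[, n] <- as.integer(runif(5) < stats::plogis(b0 + 2.5 * drive))
  }
  list(raster = binary_raster(states, 1, "user"), truth_signed = truth)
}
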