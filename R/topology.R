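#' Place neurons uniformly on the unit square
#'
#' @param n number of neurons (>= 2)
#' @param seed RNG seed
#' @return an `n x 2` matrix of coordinates in `[0, 1]^2`
#' @export
place_neurons <- function(n, seed) {
  if (n < 2) stop("need at least 2 neurons")
  set.seed(seed)
  cbind(x = runif(n), y = runif(n))
}

#' Draw distance-dependent directed connectivity
#'
#' Every ordered pair `j -> i` (`i != j`) is connected by an independent
#' Bernoulli draw with probability `exp(-d_ij^2 / sigma_r^2)`, the Gaussian
#' kernel of the pairwise Euclidean distance. Self-connections are excluded.
#'
#' @param positions `n x 2` coordinate matrix
#' @param sigma_r kernel width (> 0), same units as the coordinates
#' @param seed RNG seed
#' @return an `n x n` 0/1 integer matrix; entry `[i, j]` is 1 when neuron
#'   `j` projects to neuron `i` (rows index targets, columns sources)
#' @export
build_connectivity <- function(positions, sigma_r, seed) {
  if (sigma_r <= 0) stop("sigma_r must be positive")
  n <- nrow(positions)
  d2 <- as.matrix(stats::dist(positions))^2
  p <- exp(-d2 / sigma_r^2)
  set.seed(seed)
  u <- matrix(runif(n * n), n, n)
  adj <- (u < p) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- NULL
  storage.mode(adj) <- "integer"
  adj
}

#' Assign excitatory/inhibitory labels
#'
#' Exactly `round(n * fraction_inhibitory)` neurons are labeled inhibitory,
#' chosen uniformly at random without replacement.
#'
#' @param n number of neurons
#' @param fraction_inhibitory fraction in `[0, 1]`
#' @param seed RNG seed
#' @return a character vector of `"excitatory"` / `"inhibitory"` labels
#' @export
assign_types <- function(n, fraction_inhibitory, seed) {
  if (fraction_inhibitory < 0 || fraction_inhibitory > 1)
    stop("fraction_inhibitory must be in [0, 1]")
  n_inh <- round(n * fraction_inhibitory)
  set.seed(seed)
  labels <- rep("excitatory", n)
  labels[sample.int(n, n_inh)] <- "inhibitory"
  labels
}

#' Build a spatial excitatory/inhibitory network
#'
#' Combines [place_neurons()], [build_connectivity()] and [assign_types()]
#' into the ground-truth structural network used throughout the benchmark.
#' Positions and adjacency depend only on `topology_seed`; labels only on
#' `label_seed`, so model realizations that share the spatial layout but
#' re-sort excitatory and inhibitory neurons are obtained by varying
#' `label_seed` alone (see [relabel()]).
#'
#' @param n_neurons number of neurons
#' @param sigma_r Gaussian connectivity kernel width (non-dimensional);
#'   0.3 yields a mean connection probability of about 0.2 at `n = 100`
#' @param fraction_inhibitory fraction of inhibitory neurons
#' @param topology_seed seed for positions and connectivity
#' @param label_seed seed for the excitatory/inhibitory sorting
#' @return an object of class `network_topology`: list with `n_neurons`,
#'   `positions`, `adjacency` (`[target, source]` 0/1), `labels`,
#'   `sigma_r` and the two seeds
#' @export
network_topology <- function(n_neurons = 100, sigma_r = 0.3,
                             fraction_inhibitory = 0.2,
                             topology_seed = 1, label_seed = 2) {
  pos <- place_neurons(n_neurons, topology_seed)
  adj <- build_connectivity(pos, sigma_r, topology_seed + 1L)
  lab <- assign_types(n_neurons, fraction_inhibitory, label_seed)
  structure(list(n_neurons = n_neurons, positions = pos, adjacency = adj,
                 labels = lab, sigma_r = sigma_r,
                 fraction_inhibitory = fraction_inhibitory,
                 topology_seed = topology_seed, label_seed = label_seed),
            class = "network_topology")
}

#' Redraw the excitatory/inhibitory sorting of an existing network
#'
#' Positions and adjacency are kept; only the labels are resampled.
#'
#' @param topology a `network_topology`
#' @param label_seed new label seed
#' @return a `network_topology` with new labels
#' @export
relabel <- function(topology, label_seed) {
  topology$labels <- assign_types(topology$n_neurons,
                                  topology$fraction_inhibitory, label_seed)
  topology$label_seed <- label_seed
  topology
}

#' Signed adjacency matrix
#'
#' @param topology a `network_topology`
#' @return integer matrix: `+1` where the source is excitatory and
#'   projects, `-1` where the source is inhibitory and projects, else 0
#' @export
signed_adjacency <- function(topology) {
  sgn <- ifelse(topology$labels == "inhibitory", -1L, 1L)
  sweep(topology$adjacency, 2, sgn, `*`)
}

#' Ground-truth adjacency for one synapse class
#'
#' Entry `[i, j]` is `TRUE` when a structural link of the requested class
#' runs from `j` to `i`. Links of the other class and absent links are both
#' negatives; the diagonal is `FALSE`.
#'
#' @param topology a `network_topology`
#' @param component `"E"` or `"I"`
#' @return logical matrix `[target, source]`
#' @export
truth_matrix <- function(topology, component = c("E", "I")) {
  component <- match.arg(component)
  want <- if (component == "E") "excitatory" else "inhibitory"
  tr <- sweep(topology$adjacency == 1L, 2, topology$labels == want, `&`)
  diag(tr) <- FALSE
  tr
}

#' @export
print.network_topology <- function(x, ...) {
  cat("network_topology:", x$n_neurons, "neurons, sigma_r =", x$sigma_r,
      "\n  inhibitory:", sum(x$labels == "inhibitory"),
      "\n  connections:", sum(x$adjacency),
      sprintf("(mean in-degree %.1f)\n", mean(rowSums(x$adjacency))))
  invisible(x)
}
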