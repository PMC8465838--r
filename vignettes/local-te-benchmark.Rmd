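---
title: "Inferring signed synaptic connectivity with local Transfer Entropy: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signed synaptic connectivity with local Transfer Entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Calcium imaging of two-dimensional neuronal cultures records the activity of
every cell in a network at modest temporal resolution (frames every 5–20 ms).
A long-standing analysis goal is to recover the *structural* synaptic wiring
from such recordings — and, beyond the mere existence of links, their *sign*:
whether a connection is excitatory or inhibitory. Plain Transfer Entropy (TE)
detects directed statistical dependence but is blind to sign. `neuroTE`
implements a benchmark for a signed variant: TE split into local excitatory
and inhibitory components, evaluated at a configurable bin delay, and scored
against a known ground-truth network generated by the package itself.

The pipeline has five stages, each usable on its own:

1. **topology** — a spatial network on the unit square with
   distance-dependent connectivity and an 80/20 excitatory/inhibitory split;
2. **dynamics** — a quadratic integrate-and-fire (QIF) network with
   adaptation, depressing alpha-function synapses and Poisson drive;
3. **calcium** — a fluorescence forward model, acquisition noise,
   down-sampling, and derivative-based spike re-detection;
4. **te_core** — the plug-in TE estimator with the local E/I decomposition,
   bin delays and dynamical-state (ROI) conditioning;
5. **evaluation** — ROC/AUC/Youden scoring against the ground truth,
   aggregated over model realizations.

# Network model

## Topology

`n` neurons (default 100) are placed uniformly at random on $[0,1]^2$. Each
ordered pair $j \to i$ is connected independently with probability
$\exp(-d_{ij}^2 / \sigma_r^2)$, the Gaussian kernel of the Euclidean
distance. With $\sigma_r = 0.3$ the mean connection probability is close to
0.2, i.e. about 20 inward connections per neuron — a mildly sparse,
spatially structured graph resembling cultures grown on plates.
Self-connections are excluded: autapses are outside the model's scope and
would contaminate the pairwise TE evaluation. Distances are plain Euclidean
(no periodic wrap-around; a plated culture has edges). Reciprocal links are
drawn independently.

A "realization" of the model keeps the positions and the adjacency fixed and
redraws only the assignment of excitatory/inhibitory labels
(`relabel()`). This isolates the effect of where inhibition sits in a fixed
wiring. `simulate_realizations(resample_adjacency = TRUE)` redraws the whole
network instead, for users who prefer fully independent replicates.

## Single-neuron dynamics

Each neuron follows a QIF model with adaptation,

$$\tau_v \dot v = K_v (v - v_r)(v - v_t) - w + I_S + g_\xi \xi(t), \qquad
  \tau_w \dot w = K_w (v - v_r) - w,$$

with a spike recorded when $v \ge v_p$, followed by $v \leftarrow v_c$ and
$w \leftarrow w + \Delta w$. Parameters (mV, ms):
$v_r = -60$, $v_t = -45$, $v_p = 35$, $v_c = -50$, $\tau_v = 50$,
$K_v = 0.5\,\mathrm{mV}^{-1}$, $\tau_w = 50$, $K_w = 0.5$,
$\Delta w = 50$. The quadratic nonlinearity gives an effective subthreshold
relaxation time $\tau_v / (K_v (v_t - v_r)) \approx 6.7$ ms and reproduces
both regular spiking and bursting.

Synapses deliver alpha-function inputs
$g_S D\,(t/\tau_S) e^{1 - t/\tau_S}$ after a 1 ms axonal delay, with
$g_E = 200$, $g_I = 400$ (the control 1:2 balance), $\tau_E = 1$ ms,
$\tau_I = 5$ ms. Inhibitory inputs enter with negative sign. A single
excitatory event depolarizes a resting cell by about 8 mV and a single
inhibitory event hyperpolarizes it by about 20 mV (the 1:2.5 peak ratio
reflects the slower inhibitory time constant integrating longer). The
presynaptic resource $D$ is depleted multiplicatively ($D \to \alpha D$,
$\alpha = 0.8$) at each spike and recovers with $\tau_D = 1000$ ms
($\dot D = (1 - D)/\tau_D$); this short-term depression terminates bursts
and sets the slow inter-burst rhythm. Each neuron also receives an
independent excitatory Poisson drive at $\lambda = 0.5$ Hz (amplitude
$g_E$, no depression, no delay), modeling extrinsic input and minis.

**Noise amplitude.** The membrane noise enters the voltage equation inside
the $1/\tau_v$ bracket and is integrated as
$g_\xi \sqrt{\Delta t}\, \mathcal{N}(0,1) / \tau_v$ per step. Under this
contract the default $g_\xi = 55$ (units mV·ms$^{1/2}$) produces
subthreshold fluctuations of ≈ 2 mV sd, and — together with the Poisson
drive — spontaneous population bursts at 0.5–1 Hz with per-neuron rates
near 1 Hz, i.e. the spiking/bursting regime of cultured cortical networks
that the benchmark is designed around. This value was fixed by calibrating
the *emergent dynamics* (burst rate) once, before any inference was run,
because the noise amplitude is the one model constant whose published units
do not determine its magnitude under a stochastic integration scheme;
substantially smaller values leave the network silent and substantially
larger ones abolish the burst structure.

**Integration.** The deterministic part (including the synaptic filter
states) advances with classical RK4 at $\Delta t = 0.1$ ms; the noise
increment is added once per step (Euler–Maruyama splitting). Alpha-function
synapses are realized as per-neuron pairs of linear filter ODEs — the exact
impulse response is $A (t/\tau) e^{1 - t/\tau}$ — rather than by summing
kernels over past spikes, which keeps the cost at $O(N)$ per step; tests
assert the filter reproduces the closed-form kernel. Spike times are
recorded on the step grid (no sub-step interpolation): $\Delta t$ is two
orders of magnitude below the smallest analysis bin. Initial conditions are
$v(0) = v_r + U(-5, 5)$ mV (jitter avoids artificial initial synchrony),
$w(0) = 0$, $D(0) = 1$. Filter states are flushed to zero below $10^{-12}$
to avoid denormal-arithmetic slowdowns; at mV scale this is far below any
observable effect. Halving $\Delta t$ moves deterministic spike times by
less than one step (tested), and a driven single neuron matches an adaptive
reference integrator to ±1 spike over 10 s.

# Calcium forward model and spike re-detection

Each spike adds a transient
$A e^{-t/\tau_{decay}} (1 - e^{-t/\tau_{rise}})$ with $A = 1$,
$\tau_{rise} = 10$ ms, $\tau_{decay} = 700$ ms. The transient peaks
$10 \ln 71 \approx 42.6$ ms after the spike at $0.927 A$. Because the
kernel is a difference of exponentials, traces are propagated analytically
between events and evaluated *exactly* at the requested sample times — the
package never convolves numerically.

Down-sampling emulates frame capture: the trace is sampled once per
acquisition bin (5, 10 or 20 ms), at the end of the bin, so that a spike
inside a bin is visible in that bin's frame. Acquisition noise is i.i.d.
Gaussian per retained sample with sd $0.1 A$. (Adding white noise at the
full 0.1 ms grid and then decimating yields the same distribution at the
retained samples; the package realizes the noise directly at the frame
times.)

Binary activity is re-extracted from the frames by derivative thresholding.
A candidate onset is a frame-to-frame rise above `onset_threshold`,
confirmed only if the rise is sustained one further bin (`confirm_bins`);
the segment ends when the derivative drops below `offset_threshold`.
Within a segment, only *strong-rise* bins are labeled active: a spike
contributes its full transient rise (≈ 0.58 A at 10 ms bins) to its own
frame, whereas the residual rising tail of the kernel spreads ≤ 0.2 A per
bin over the next ~3 bins. Labeling the whole rising phase was tried and
rejected: it inflates the active-bin count roughly fourfold relative to the
true spike raster and measurably blurs the delayed inhibitory TE signature.
The default thresholds scale with the bin size and the noise level (see
`?detect_spikes`); they were calibrated once on the control simulation so
that deterministic traces yield an essentially perfect reconstruction and
10%-noise traces recover ≈ 90% of spikes, and are exposed as parameters.

A spike that falls late in a bin leaves most of its rise to the *next*
frame and is recognized one frame late — an information-theoretic limit of
frame capture, not a detector defect. `detection_accuracy()` therefore
counts a spike as recovered if the detector is active in its bin or the
following one (`tolerance_bins = 1`, one-sided; set 0 for strict same-bin
accuracy).

# Transfer Entropy and its local decomposition

For binary series $X$ (target) and $Y$ (source) the plug-in estimator uses
empirical frequencies of the tuples
$(x_n,\, x_{n-1}^{(k_x)},\, y_{n-d}^{(k_y)})$:

$$TE_{Y \to X} = \sum P(x_n, x_{n-1}^{(k_x)}, y_{n-d}^{(k_y)})
  \log_2 \frac{P(x_n \mid x_{n-1}^{(k_x)}, y_{n-d}^{(k_y)})}
              {P(x_n \mid x_{n-1}^{(k_x)})}.$$

Defaults $k_x = 1$, $k_y = 2$. The bin delay $d$ offsets the source
embedding; $d = 0$ includes the same-bin value $y_n$, which matters because
excitatory synaptic transmission (≈ 1–10 ms) completes within one
acquisition bin. Base-2 logarithms (bits); any base change rescales all
entries uniformly and leaves every ROC unchanged.

The *local* decomposition routes each summand by the event content of its
state: to the excitatory component when the source embedding and the
target's current bin agree (both active or both inactive), to the
inhibitory component when they oppose. The source embedding counts as
active when **any** of its $k_y$ entries is 1; the full vector still enters
every probability. The two all-inactive/all-active combinations are
deliberate: $\{y\text{ inactive}, x_n = 0\}$ is treated as hidden
excitatory evidence (quiet drives quiet) and
$\{y\text{ inactive}, x_n = 1\}$ as hidden inhibitory evidence (a silent
inhibitor fails to silence its target). By construction
$TE_E + TE_I = TE$ exactly, which the tests assert to $10^{-12}$, along
with exhaustive agreement with a naive probability-table implementation on
short series.

Zero-count conventions are the standard plug-in ones: summands with zero
joint probability contribute nothing, and conditionals are only formed
where the conditioning count is positive.

**ROI (dynamical-state) conditioning.** Synchronous bursts dominate the
joint statistics and mask pairwise interactions, so the estimator can
restrict the tuple index $n$ to frames where the network-average
fluorescence lies below a threshold. Embedding vectors may reach outside
the selected set — only the current index is gated. `te_matrix()` sweeps 20
evenly spaced thresholds between the minimum and maximum of the average
trace in a single pass (the masks are nested, so the sweep costs one scan
of the data per pair), and the evaluation selects, per realization, the
threshold with the best ground-truth AUC. This mirrors best-ROI reporting
in benchmark studies and is **non-blind**: on real data, where no ground
truth exists, fix the threshold a priori (`score_component(roi_level = )`)
or use surrogate-based selection. The average trace used for the ROI always
matches the raster's provenance (noisy average for noisy rasters).

# Evaluation

The class-specific ground truth for component E (I) marks pair $j \to i$
positive when an excitatory (inhibitory) structural link runs from $j$ to
$i$; absent links *and* links of the other sign are negatives. All
$n(n-1)$ ordered off-diagonal pairs enter the ROC. The curve sweeps every
distinct TE value as a threshold; AUC is the trapezoidal integral, which
equals the Mann–Whitney concordance probability with ties counted one half
(cross-checked in the tests against an independent implementation and
against pROC). `NA` entries rank below every finite score: absence of
evidence must never create a predicted link. Youden's $J = \max(TPR - FPR)$
defines the operating threshold; exact ties break toward higher
specificity. Across realizations the package averages the per-realization
scalar metrics (not pooled curves).

# Choices made where the design was open

* **Realizations share the structural network** and differ only in the E/I
  sorting (the most literal reading of the benchmark design); an option
  redraws the adjacency instead.
* **External Poisson events bypass depression** and arrive undelayed: they
  model many extrinsic sources, none of which shares the recurrent
  synapses' resource pool.
* **Depression amplitude** uses $D_j$ read at the spike time, with
  depletion applied immediately after.
* **Noise is realized at the retained frames** (distributionally identical
  to full-resolution noise followed by decimation).
* **Decimation, not averaging,** models frame capture; within-bin averaging
  is available behind a flag (`downsample(average = TRUE)`).
* **ROI selection uses the noisy average for noisy rasters** — the analyst
  of real data has no access to a clean average.
* **TE is computed over all selected indices,** not only within contiguous
  quiet segments; embeddings may straddle segment boundaries.
* **`g_xi = 55` and the detector thresholds** are the two calibrated
  constants; both were fixed against stated properties of the *data
  generator* (burst rate; spike-recovery rates), never against the
  inference results.

# What the generator does and does not emulate

The synthetic data reproduce the features that matter for signed TE
benchmarking: spatially structured sparse connectivity, an 80/20 E/I mix,
burst/quiescence alternation, calcium-kernel smoothing, frame-rate
down-sampling and acquisition noise. They do **not** model indicator
binding kinetics, photobleaching, ΔF/F normalization, cell segmentation
errors, NMDA or slow-GABA currents, or 3D geometry. Passing benchmarks here
therefore demonstrates correctness of the estimator and its expected
behavior under these idealized conditions — not performance on any
particular experimental dataset. For real recordings, surrogate-based
significance testing should replace ground-truth ROI selection; the
estimator accepts any user-supplied binary raster (`read_raster()`).

# Problem sizes and reproducibility

The packaged benchmark (`run_benchmark()`, `scripts/acceptance.R`, the
acceptance tests) uses 3 model realizations of the 100-neuron network with
5-minute simulated recordings; the headline tables it mirrors average 10
realizations. Three realizations keep the full pipeline comfortably on a
single CPU while the realization-to-realization spread of AUC stays within
a few hundredths. Every random stage (placement, wiring, labels, dynamics,
acquisition noise) consumes an explicit seed derived from one master seed,
and simulations are bit-reproducible given that seed.

```{r, eval = FALSE}
library(neuroTE)
reals <- simulate_realizations(3, duration = 300000, seed = 1)
inf <- lapply(seq_along(reals), function(r)
  infer_realization(reals[[r]]$spikes, bin_size = 10, delays = c(0, 2),
                    noise_seed = 100 + r))
truthI <- lapply(reals, function(z) truth_matrix(z$topology, "I"))
evaluate_condition(lapply(inf, function(z) z$te$d2), truthI, "I")
```

# Known limitations

* The plug-in estimator is biased upward at small sample counts; the most
  restrictive ROI thresholds can leave too few tuples. The sweep reports
  `n_samples` per level so users can judge.
* The Youden operating point sits on a broad plateau of the inhibitory ROC:
  its sensitivity/specificity split varies more between runs than $J$
  itself.
* Best-ROI selection is non-blind (see above).
* The detector's one-frame recognition delay slightly advances apparent
  source offsets; at 5 ms bins this strengthens delayed anti-correlations,
  which is visible as a higher inhibitory AUC at $d = 2$ than the
  coarser-binned conditions show.
* Only fast (AMPA-like and GABA$_A$-like) synapses are modeled; slow
  currents would change the optimal delays.
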