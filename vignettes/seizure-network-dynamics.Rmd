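---
title: "Tracking seizure dynamics with phase-locking networks and link prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking seizure dynamics with phase-locking networks and link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epinetdyn)
```

# The method

Focal epileptic seizures are episodes of abnormal hypersynchronous firing
that start in a circumscribed epileptogenic focus and spread. With
intracranial electrodes both inside the focus ("intrafocus" sites) and
outside it ("extrafocus" sites), the reorganization of the functional
network around a seizure can be tracked quantitatively. `epinetdyn`
implements that workflow end to end:

1. **Preprocess** the multichannel recording: wavelet denoising, a 50 Hz
   notch, and an 8000 µV amplitude-artifact mask.
2. **Decompose** into the five canonical subbands — delta (0.5–4 Hz),
   theta (4–8), alpha (8–13), beta (13–30), gamma (30–45) — with
   zero-phase filters.
3. **Build time-varying networks**: one weighted graph per
   non-overlapping, frequency-dependent window, with edge weights given
   by the phase-locking value (PLV) between channels.
4. **Rank node pairs** with common-neighbour link-prediction indices and
   verify, via a randomized edge-split AUC protocol, that resource
   allocation (RA) is the strongest ranker.
5. **Track the seizure** through per-window *node sequences* (each
   node's most similar partner under RA), their cosine/Euclidean
   variation over time, and the *node index summation* that separates
   intrafocus from extrafocus dominance.

## Phase-locking networks

For band-limited signals the instantaneous phase $\phi_i(t)$ is the
argument of the Hilbert-transform analytic signal. Over a window of $T$
samples the phase-locking value of channels $i, j$ is

$$\mathrm{PLV}_{ij} = \left| \frac{1}{T} \sum_{t=1}^{T}
  e^{\,\mathrm{i}\,(\phi_i(t) - \phi_j(t))} \right| \in [0, 1],$$

1 for a rigid phase relation and near 0 for unrelated phases. The
diagonal is forced to zero (no self-connections). Windows are
*frequency dependent*: `n_cycles` (default 6) cycles of the band's lower
edge, i.e. $\lceil 6 f_s / f_{\mathrm{low}} \rceil$ samples, tiled
without overlap, trailing remainder dropped. Six cycles is the usual
minimum for a stable PLV estimate; the count is configurable. Each
window inherits the condition (preictal / ictal / postictal) at its
midpoint sample, so windows straddling onset or offset get a single
unambiguous label. Weighted networks are optionally binarized by a
*strict* threshold `w > 0.3`; ties at exactly the threshold are dropped
(configurable).

Two properties of this estimator matter for interpretation. PLV is
invariant to channel amplitude scaling and to global phase offsets, so
zero-phase (forward–backward) band filters are mandatory — any
channel-dependent group delay would masquerade as phase locking. And on
short windows PLV is biased upward: with $T_{\mathrm{eff}}$ effectively
independent phasors per window, fully unrelated channels still measure
around $\sqrt{\pi / (4\,T_{\mathrm{eff}})}$. Gamma windows at 256 Hz are
only 52 samples, so weak couplings are overestimated there; comparisons
across conditions (which share the window length) remain valid.

## Link-prediction indices

On a simple undirected graph with neighbour sets $N(x)$ and degrees
$k(x)$:

$$\mathrm{CN}_{xy} = |N(x) \cap N(y)|, \qquad
  \mathrm{RA}_{xy} = \sum_{z \in N(x) \cap N(y)} \frac{1}{k(z)},$$
$$\mathrm{AA}_{xy} = \sum_{z \in N(x) \cap N(y)} \frac{1}{\ln k(z)}, \qquad
  \mathrm{Sor}_{xy} = \frac{2\,|N(x) \cap N(y)|}{k(x) + k(y)}.$$

The Adamic–Adar logarithm is natural: on the six-node worked example
below AA(2,5) evaluates to $2/\ln 2 = 2.8854$, which is the standard
published value for that configuration (base-10 would give 6.64). Every
common neighbour on a simple graph touches both endpoints, so
$k(z) \ge 2$ and the sums are finite; RA $\le$ CN/2 and AA $\le$ CN/ln 2
follow.

```{r toy}
g <- make_toy_network()
c(CN = common_neighbors(g, 2, 5), RA = resource_allocation(g, 2, 5),
  AA = adamic_adar(g, 2, 5), Sorenson = sorenson(g, 2, 5))
```

Because the indices are defined on neighbour sets, weighted PLV networks
are binarized (threshold 0.3 by default) before scoring. A weighted RA
variant, $\sum_z w_{xz} w_{zy} / s(z)$ with node strength $s$, is
available through `weighted_resource_allocation()` but is deliberately
not the default — the binary definitions are the canonical ones.

## AUC under randomized edge splits

Prediction quality is measured by hiding a random fraction of edges:
`split_edges()` partitions $E$ uniformly into a train set (70–95 % of
edges; the protocol caps the train share at 95 %) and a probe set.
Scores are computed **on the train graph only** — probe edges must not
leak into neighbour sets. `auc_score()` then draws $n$ random
(probe edge, non-edge) comparisons and reports

$$\mathrm{AUC} = \frac{n' + 0.5\, n''}{n},$$

where $n'$ counts comparisons won strictly by the probe edge and $n''$
exact-tie comparisons (floating-point equality; the half-credit rule
makes a constant scorer land on 0.5 exactly). Non-edges are pairs absent
from the *full* edge set. The default $n$ is
$\min(10^4,\ |E_p| \times |\text{non-edges}|)$. `benchmark()` repeats
this 100 times per (graph, ratio) cell with a deterministic
per-repetition seed stream, so repetition $r$ is independent of the
total repetition count and all indices are scored on identical splits
(a paired design). Splits are uniform with no connectivity
preservation; nothing in the protocol requires the train graph to stay
connected.

## Node sequences and seizure tracking

From each window's RA similarity matrix, `node_sequence()` assigns every
node its highest-similarity partner (row-wise argmax, diagonal
excluded). Ties break toward the smallest node index, which makes the
statistic deterministic; rows with no positive score default to the
smallest other index and are flagged. The assignment depends only on
score order, so any strictly monotone rescaling of the similarity leaves
it unchanged. An alternative "global top-k" reading (walk the k
highest-scoring pairs) is available behind a flag, but per-node argmax
is the default because it naturally yields length-N vectors with
repeats.

Consecutive windows are compared by cosine similarity and Euclidean
distance of the raw integer sequences in fixed node order. Cosine on
positive vectors lives in (0, 1] and is scale invariant — parallel
sequences score 1 even when different — which compresses its dynamic
range; the Euclidean distance does not share that caveat, and both are
reported. Cross-condition comparisons return the full pairwise
distribution between two conditions rather than a single scalar, since
no aggregate is canonical.

With intrafocus sites numbered 1–3 and extrafocus 4–6, the **node index
summation** $\sum_i \mathrm{partner}(i)$ ranges over [6, 36] for six
nodes; lower values mean the strongest similarity partners concentrate
on intrafocus sites. The workflow's central recovered effect is that
ictal gamma-band networks pull this sum *down* relative to preictal —
network organization collapses toward the focus during the seizure.

# The synthetic generator

Testing the pipeline requires recordings whose ground truth is known.
`simulate_seizure_eeg()` emulates the single property the analysis
depends on — controllable phase hypersynchrony concentrated on
intrafocus channels during the ictal epoch — with a driven Kuramoto
model per band. Each band has a sinusoidal driver at its midpoint
frequency; channel $c$'s phase deviation from the driver evolves as

$$\delta_{t+1} = \delta_t + (1-\kappa)\,\Delta\omega_c
  - \kappa g \sin \delta_t + \sigma \varepsilon_t,$$

with a per-channel natural-frequency offset $\Delta\omega_c$ (Gaussian,
sd `freq_jitter` of the carrier), coupling gain $g$
(`coupling_gain`, rad/sample) and phase jitter $\sigma$. The sine term
gives a genuine locking threshold,
$\kappa g > (1-\kappa) |\Delta\omega_c|$: coupled channels entrain to
the driver and lock pairwise, uncoupled ones precess at their own
frequency and decohere. $\kappa = 1$ entrains exactly (with a common
start and zero noise the channels are sample-for-sample identical,
hence PLV $= 1$); $\kappa = 0$ leaves a free phase random walk.
Intrafocus channels switch from `base_coupling` to `ictal_coupling`
during ictal segments; extrafocus channels keep base coupling to the
same driver throughout, so intra–extra pairs sit between the intrafocus
and baseline synchrony levels rather than exactly at baseline — the
price of a single-driver model, accepted for its simplicity and
monotonicity in $\kappa$.

Default operating point (all overridable):

| parameter | default | rationale |
|---|---|---|
| `fs` | 256 Hz | typical clinical intracranial sampling rate |
| `n_channels` / `n_intrafocus` | 6 / 3 | the montage the node-index encoding assumes |
| `base_coupling` | 0.25 | locking radius $\approx$ 1.4 Hz: roughly a third of channels entrain interictally, giving heterogeneous, fluctuating baseline graphs |
| `ictal_coupling` | 0.95 | locking radius $\approx$ 7.7 Hz $\approx 2.6$ sd of the frequency offsets: essentially all intrafocus channels entrain (gamma PLV $\approx$ 0.98) |
| `coupling_gain` | 0.1 rad/sample | with `freq_jitter` sets the two radii above |
| `freq_jitter` | 0.08 | $\pm$3 Hz frequency spread in gamma — enough pairwise detuning that unsynchronized pairs decohere within seconds |
| `phase_jitter_sd` | 0.1 rad | keeps locked-pair PLV high (OU variance $\sigma^2 / 2\kappa g \approx 0.03$ ictally) while adding window-to-window variability near the locking boundary |
| `amplitude_uV`, `noise_sd` | 40, 5 µV | physiological amplitude scale, far below the 8000 µV artifact limit |

Seizure onset/offset sample indices are recorded exactly, so the
segmentation stage (3-minute preictal/postictal margins, clipped to the
record) can be validated against ground truth.

**What the generator does not emulate** — and therefore what passing
tests do *not* establish about clinical data: ictal waveform morphology
(spikes, spike–wave complexes, amplitude evolution), seizure
propagation across sites, volume conduction, electrode artifacts beyond
amplitude excursions, and any distinction between epilepsy subtypes.
The tests demonstrate that *if* seizures manifest as focal phase
hypersynchrony, the pipeline recovers them; they cannot show that real
seizures always do.

```{r recover, eval = FALSE}
cfg <- simulation_config(band_targets = list(c(30, 45)), seed = 1)
rec <- simulate_seizure_eeg(cfg, data.frame(
  label = c("preictal", "ictal", "postictal"), duration_s = c(30, 30, 30)))
ser <- build_network_series(bandpass_decompose(rec, canonical_bands()["gamma"]),
                            segment_conditions(rec))$gamma
seqs <- window_node_sequences(ser)
node_index_summation(seqs)$per_condition
```

# Numerical choices

* **Band filters**: order-4 Butterworth band-pass run forward–backward
  (`signal::filtfilt`) — exactly zero phase, verified numerically stable
  down to the delta band's low normalized corner (0.5 Hz at 256 Hz).
  The notch is an order-3 band-stop at ±2 Hz around the mains frequency
  (measured: ≥ 30 dB at 50 Hz, < 1 dB at 47 Hz).
* **Wavelet denoising**: Daubechies-4 pyramid, 4 levels, universal
  threshold $\hat\sigma \sqrt{2 \ln n}$ with $\hat\sigma =
  \mathrm{mad}(d_1)/0.6745$, **hard** thresholding. Soft shrinkage was
  evaluated and rejected: on a 50 µV rhythm in noise of $\sigma = 10$ µV
  it biases the retained oscillatory coefficients enough that the
  residual variance exceeds the injected noise variance (≈ 118 vs 100),
  while hard thresholding leaves ≈ 27. Soft remains available via
  `rule = "soft"`.
* **Artifact handling** is a per-channel-sample validity mask rather
  than sample deletion, so window timestamps stay aligned with seizure
  markers; a window is skipped if *any* channel has an invalid sample
  inside it.
* **Intervals** are half-open `[start, end)` in samples (1-based
  starts); node labels are 1-based throughout.
* **Weighted metrics**: clustering uses the geometric-mean triangle
  formula on the raw weights — PLV is already bounded by 1, so the
  maximum-weight normalization is off by default (a uniform complete
  graph of weight $w$ then has clustering $w$). Path length uses edge
  distance $1/w$; $1-w$ was rejected because weights of 0 would make
  absent links finite-distance.
* **Random graphs** (Watts–Strogatz, Barabási–Albert, fixed-edge-count
  uniform) come from igraph, redrawn (up to 100 times, seeded) until
  connected; a realized mean degree more than 20 % from the target is
  rejected as unreachable. A mean degree equal to $n-1$ is allowed — it
  is the complete graph, which the fixed-edge-count model realizes
  exactly.

# Scope of the test suite

The suite regenerates every fixture in code: 30-node benchmark graphs
with mean degree 4, 100-repetition AUC cells at train ratio 0.9,
90-second single-band simulated seizures over 20 seeds for the recovery
tests, and the 160-second five-band default run for the end-to-end
reproducibility check. The brute-force oracles (set-enumeration index
scoring, full-enumeration rank AUC, elementwise complex-sum PLV) live in
the test helpers and never share code with the package paths they
check.

# Known limitations

* The intrafocus/extrafocus encoding is positional (lowest channel
  indices are intrafocus); recordings with interleaved focus labels must
  be reordered on ingestion.
* Gamma-band windows of 6 cycles are short; absolute PLV values there
  carry the small-sample upward bias discussed above.
* Cosine similarity of node sequences has low dynamic range (all-ones
  vs all-sixes scores 1); the Euclidean distance is the more sensitive
  variation measure in practice.
* The 0.3 binarization threshold is a fixed operating point, not
  estimated from data; surrogate-based significance testing of PLV is
  out of scope.
* Recordings are exchanged as CSV + JSON sidecar; EDF ingestion is not
  provided.
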