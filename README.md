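# epinetdyn

Dynamic phase-locking networks and link prediction for tracking
epileptic seizures in multichannel intracranial EEG.

Focal seizures are episodes of hypersynchronous neural firing that start
in a circumscribed epileptogenic focus. With electrodes both inside the
focus (*intrafocus* sites, numbered 1–3) and outside it (*extrafocus*,
4–6), the reorganization of the functional brain network around a
seizure can be measured. `epinetdyn` is for researchers who want that
measurement pipeline as reproducible, testable code:

* **Connectivity** — subband decomposition (delta/theta/alpha/beta/gamma)
  with zero-phase filters, Hilbert instantaneous phase, and per-window
  phase-locking networks
  `PLV_ij = |mean_t exp(i(φ_i(t) − φ_j(t)))|` on non-overlapping,
  frequency-dependent windows (6 cycles of each band's low edge),
  optionally binarized at a strict 0.3 threshold.
* **Link prediction** — the four common-neighbour similarity indices
  CN, RA (`Σ_z 1/k(z)`), AA (`Σ_z 1/ln k(z)`), Sorenson
  (`2|N(x)∩N(y)|/(k(x)+k(y))`), randomized train/probe edge splits
  (train share 70–95 %), and the sampled comparison AUC
  `(n′ + 0.5 n″)/n` with a 100-repetition benchmark harness.
* **Seizure dynamics** — per-window node sequences (each node's
  highest-similarity RA partner), their cosine/Euclidean variation over
  time and across conditions, and the node index summation that
  separates intrafocus from extrafocus dominance (lower sum = network
  organized around the focus).
* **Synthetic ground truth** — a driven Kuramoto phase-oscillator EEG
  simulator with a controllable hypersynchronous ictal epoch confined
  to the intrafocus channels, plus seeded scale-free / small-world /
  uniform random graph generators and plain-text edge-list I/O.

Preprocessing (wavelet denoising, 50 Hz notch, 8000 µV artifact
masking, 3-minute preictal/ictal/postictal segmentation around marked
seizures) is included, so the package runs from raw numeric recordings
to the final per-condition statistics. See the vignette
(`vignettes/seizure-network-dynamics.Rmd`) for the model details and
design rationale.

## Worked example

The six-node example network (edges 1–2, 1–5, 2–4, 4–5, 2–3, 2–6) pins
down the similarity indices exactly:

```r
library(epinetdyn)
g <- make_toy_network()
c(CN = common_neighbors(g, 2, 5), RA = resource_allocation(g, 2, 5),
  AA = adamic_adar(g, 2, 5), Sorenson = sorenson(g, 2, 5))
#>        CN        RA        AA  Sorenson
#> 2.0000000 1.0000000 2.8853901 0.6666667
```

Nodes 2 and 5 share the two common neighbours {1, 4}; each has degree 2,
so RA contributes 1/2 + 1/2 = 1 and AA contributes 2/ln 2 = 2.8854.

A full synthetic seizure run — simulate, segment, build gamma-band PLV
networks, extract node sequences, summarize:

```r
cfg <- simulation_config(band_targets = list(c(30, 45)), seed = 1)
rec <- simulate_seizure_eeg(cfg, data.frame(
  label = c("preictal", "ictal", "postictal"), duration_s = c(30, 30, 30)))
rec
#> <eeg_recording> 6 channels x 23040 samples @ 256 Hz (90.0 s)
#>   focus: 3 intrafocus, 3 extrafocus | seizures: 1

ser <- build_network_series(
  bandpass_decompose(rec, canonical_bands()["gamma"]),
  segment_conditions(rec))$gamma
ser
#> <plv_network_series> band gamma (30-45 Hz): 443 windows x 6 nodes
#>   conditions: ictal=147, postictal=148, preictal=148

node_index_summation(window_node_sequences(ser))$per_condition
#>   condition     mean       sd n_windows
#> 1     ictal 12.48299 4.989515       147
#> 2 postictal 13.50000 5.560429       148
#> 3  preictal 13.71622 5.603741       148
```

The ictal mean node index summation (12.48) sits below the preictal
mean (13.72): during the simulated seizure the strongest similarity
partners concentrate on the intrafocus sites 1–3, exactly the effect
the statistic is designed to expose. Over 20 simulation seeds the test
suite confirms the drop at α = 0.01.

The whole workflow, manifest and CSVs included, is one call (or the
bundled CLI wrapper `inst/scripts/epinetdyn.R`):

```r
run_pipeline(list(seed = 17), out_dir = "out/")   # all five bands
```

## Layout

```
R/                 implementation: simulator & graphs, preprocessing,
                   connectivity, link prediction, seizure dynamics, pipeline
tests/testthat/    unit + property + acceptance suites (fixtures generated
                   in code; brute-force oracles in helper-oracles.R)
scripts/           acceptance.R
vignettes/         methods vignette
inst/scripts/      epinetdyn.R command-line wrapper
```
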