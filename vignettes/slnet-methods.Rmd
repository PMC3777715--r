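---
title: "Synchronization-likelihood network analysis of resting EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization-likelihood network analysis of resting EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnet)
```

## What the package computes

`slnet` implements a complete resting-state EEG functional-connectivity
analysis for two-group clinical comparisons: preprocessing of multichannel
recordings, synchronization likelihood (SL) as the pairwise coupling
measure, density-thresholded weighted graph metrics, and permutation-based
group inference including the network-based statistic (NBS). Because
clinical EEG is rarely shareable, the package also contains a first-class
synthetic cohort generator whose planted effects make every downstream
stage testable.

## Preprocessing chain

The chain is: EOG regression, segmentation into 2 s epochs with a
±150 µV amplitude rejection rule, selection of the first 10 artifact-free
epochs, decimation from the native rate (1000 Hz by convention) to 250 Hz,
and zero-phase band-pass filtering into delta (1–4 Hz), theta (4–8),
alpha (8–12), beta (12–30) and gamma (30–50 Hz). Ten clean 2 s epochs at
250 Hz give the standard 5000-sample analysis segment per subject.

Choices the chain fixes where conventions differ:

* **Ocular correction** is ordinary least-squares regression of every EEG
  channel on VEOG and HEOG over the whole recording. Blink-aware variants
  that fit separate propagation coefficients for blinks and saccades are
  an extension point; the regression form captures the propagation
  structure and is exactly testable against construction.
* **Filters** are order-4 Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero phase — phase distortion would bias a
  synchronization measure. The decimator low-passes at 0.4 × the target
  rate before keeping every fourth sample.
* **Rejection** tests EEG channels only, before baseline correction; any
  single sample beyond ±150 µV rejects the whole epoch. Baseline
  correction subtracts the per-epoch per-channel mean.

## Synchronization likelihood

SL is a generalized-synchronization measure: both signals are delay-embedded,
and SL asks how often state-space recurrences of one signal coincide in
time with recurrences of the other. For each reference time the critical
distance of each channel is set so that a fixed fraction `p_ref` of
candidate vectors counts as recurrences; the instantaneous SL is the
number of *joint* recurrences divided by the larger single-channel
recurrence count, and the reported value averages over reference times.
Independent signals give SL ≈ `p_ref`; identical or affinely rescaled
signals give exactly 1 (the measure only sees distance ranks, which affine
maps preserve).

Embedding parameters derive from the band of interest at sampling rate
`fs`:

* lag `l = round(fs / (3 f_hi))` — about a third of the period of the
  fastest band component;
* dimension `m = round(3 f_hi / f_lo) + 1` — enough coordinates to span
  the slowest component;
* Theiler window `w1 = 2 l (m − 1)` — excludes trivially autocorrelated
  neighbours;
* outer window `w2 = w1 + round(n_ref / p_ref)` — sized so that about
  `n_ref` recurrences are expected per reference time.

Defaults are `p_ref = 0.01`, `n_ref = 10`; both are conventions, exposed
as arguments. For alpha at 250 Hz these give `l = 7`, `m = 6`, `w1 = 70`,
`w2 = 1070`. Rounding is half-up throughout so the worked values above are
reproduced exactly.

Numerical conventions that matter:

* **Epoch handling.** Embedding vectors never span epoch boundaries.
  Candidate recurrences, however, may come from *any* epoch: the
  `w1 < |i − j| < w2` window is evaluated on the concatenated sample
  index. A within-epoch-only rule would make the delta band undecidable —
  its Theiler window (504 samples at 250 Hz) exceeds a whole 500-sample
  epoch — while cross-epoch candidates are always at least as separated
  in real time as the window demands.
* **Ties** at the critical distance are included in the recurrence set;
  the joint count is normalized by the larger realized set, which keeps
  SL ≤ 1 exactly.
* **Candidate counts** use the realized number per reference time (edge
  effects shrink windows near epoch boundaries), with
  `k = max(1, round(p_ref × n_cand))`.
* Euclidean state-space distance is the default; Chebyshev is available.
* Constant (zero-variance) channels are an error: their distance
  distribution is degenerate and SL undefined.

The production kernel is compiled (Rcpp) and is tested for *exact*
equality against a literal double-loop R implementation of the definition.

## Graph metrics

The 29 × 29 SL matrix is thresholded by connection density: at density
`d` the `K = round(d × 406)` strongest edges are retained *with their
weights* (no binarization); ties at the K-th weight break by channel-pair
order for determinism. Metrics:

* **C** — mean weighted clustering, geometric-mean triangle form on
  weights normalized by the network maximum;
* **L** — characteristic path length on edge lengths 1/weight, averaged
  over pairs of the largest connected component (sparse networks fragment;
  restricting to the giant component keeps L finite while preserving its
  ordering in density sweeps);
* **Eg** — global efficiency, mean inverse shortest-path length over all
  pairs with disconnected pairs contributing 0;
* **s, b, El** — nodal strength, betweenness on the 1/weight graph, and
  local efficiency of each node's neighbourhood subgraph (on
  max-normalized weights, hence in [0, 1]);
* **γ, λ, σ = γ/λ** — C and L normalized by the means of a surrogate
  ensemble that rewires the thresholded topology preserving the degree
  sequence and randomly reassigns the retained weights (default 50
  surrogates, seeded).

The Erdős–Rényi bound `2 ln N / N` (≈ 23.2% for 29 nodes) marks the
density above which a random graph is almost surely connected; below it,
fragmentation drives the metric curves.

## Group inference

* **Permutation tests** on per-subject scalars use the t of the group
  coefficient in `lm(value ~ group + covariates)` with the Freedman–Lane
  scheme: residuals of the covariates-only model are permuted, added back
  to its fitted values, and the group t is recomputed; `p = (1 + b)/(1 +
  n_perm)`. The default is two-sided; the one-sided variant is an option.
  Age, sex and IQ are the conventional covariates.
* **NBS** thresholds edge-wise pooled-variance t statistics at `t = 2.61`
  (the upper 0.005 quantile at 142 df; configurable), extracts connected
  components of suprathreshold edges, and corrects each component by the
  permutation distribution of the *maximal* component size. This is the
  canonical max-size rule; a literal reading of some descriptions scores
  "components of two or more links" instead, which is not
  size-monotonic and is not used here.
* **Partial correlations** between network metrics and clinical scores
  (MADRS, YMRS) correlate the residuals of both variables after
  regressing out the covariates, with `df = n − k − 2`. Local measures
  and correlations are evaluated at 30% density, where C and L peak in
  density sweeps.
* No correction is applied across the density sweep — each density is
  reported at its uncorrected p, which mirrors common practice and is
  stated here prominently as a caveat.

## The synthetic cohort generator

Each subject's channels are convex mixtures of shared band-limited latent
fields and private noise, `x = c·s_shared + (1 − c)·s_private`, with the
coupling `c` set per band and group. The latent field is spatial: one
global source plus nine regional sources at standard 10–20 sites, mixed
into channels by a Gaussian kernel in electrode distance (σ = 0.6 head
radii, global weight 0.55, rows unit-norm). Neighbouring electrodes
therefore share most of their drive while distant pairs share only the
global component — reproducing the distance structure of scalp
connectivity, which matters: with a single common source every pair is
equally coupled, and a planted deficit throws its edges clean out of the
retained set instead of lowering their weights as clinical data do.

Defaults and their calibration:

* group sizes 57 patients / 87 controls; 120 s eyes-closed recordings at
  1000 Hz; montage of 29 standard 10–20 electrodes plus VEOG/HEOG.
  (The published channel listing this montage follows contains a
  duplicated P7; the slot between C3 and CPz is taken as T7, mirroring
  T8.)
* band couplings: control 0.90 in every band; patients 0.80 in alpha on
  the effect channels F4, FC3, FC4, Cz, CPz only. These values were set
  so that (i) retained-edge SL sits near 0.4, the scale implied by
  clinically reported nodal strengths of 3–4.4 at 30% density, and
  (ii) the planted deficit lowers effect-node strengths gradedly (to
  roughly 0.7 of control) rather than zeroing them.
* band amplitude weights 1/1/2/0.7/0.3 (delta…gamma), alpha-dominant as
  in eyes-closed rest; channels scaled to 30 µV RMS so the ±150 µV rule
  sits at 5 σ of clean data; EOG leakage coefficients 0.10/0.05.
* artifacts: `round(rate)` distinct epochs receive a 200 ms raised-cosine
  pulse of 400 µV peak on one EEG channel — an unambiguous threshold
  crossing at an exactly known epoch.
* clinical scores: a latent Gaussian with population correlation
  `score_coupling` to any supplied metric, scaled to MADRS mean 13.0 /
  SD 11.1, rounded and clipped at zero (which attenuates the realized
  correlation by a few percent).
* Determinism: one master seed; per-subject streams are drawn from it
  once, so cohorts are bit-identical under a fixed seed.

What the generator does *not* emulate: 1/f background spectra, volume
conduction, non-stationarity, electrode impedance drift, or realistic
artifact morphology beyond amplitude. Passing tests therefore demonstrate
correctness of the analysis chain and recoverability of planted effects
under this model — not clinical validity on real recordings.

## Problem sizes used in the test suite

End-to-end statistical checks run at deliberately reduced sizes chosen as
the smallest cohorts at which the planted phenotype is reliably expressed:
10 + 10 to 12 + 12 subjects, 12–16 s recordings at a native 250 Hz,
5 retained epochs, SL windows `p_ref = 0.02, n_ref = 5`, 300–2000
permutations, and 20 replicate cohorts for recovery rates. Null
calibration of the inference modules (p-uniformity, NBS family-wise error)
draws per-subject scalars and connectivity stacks directly from their null
models, which is what those invariants concern. All stage-level unit tests
run the study-scale parameters (10 × 2 s epochs, `p_ref = 0.01`).

## Known limitations

* The SL parameter strategy is frequency-prior based; adaptive per-subject
  selection (e.g. fixing ε from a target recurrence count empirically) is
  not implemented.
* L on fragmented networks is a largest-component quantity; comparing L
  across groups at very low densities conflates fragmentation with path
  length (Eg is the better-behaved quantity there).
* The EDF writer emits plain continuous EDF with one-second records and
  16-bit quantization (~0.001 µV at typical amplitudes); EDF+ annotations
  and discontinuous files are out of scope.
* The weighted clustering and efficiency formulas follow the
  geometric-mean / inverse-shortest-path conventions; other weighted
  generalizations exist and give systematically different absolute values.
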