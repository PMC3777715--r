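# slnet — synchronization-likelihood network analysis of resting EEG

`slnet` is an R package for graph-theoretic analysis of resting-state EEG
functional connectivity in two-group clinical designs (e.g. patients vs.
healthy controls). It answers questions of the form: *is large-scale
synchronization reduced in the patient group, in which frequency band, at
which electrodes, and does the network topology built on that
connectivity differ?*

## The method

For each subject, multichannel EEG is cleaned (EOG regression, ±150 µV
epoch rejection, decimation to 250 Hz) and band-filtered into δ, θ, α, β,
γ. Coupling between every pair of the 29 scalp channels is measured by
**synchronization likelihood (SL)**: both signals are time-delay embedded,
a per-time critical distance ε is fixed so that a fraction *p<sub>ref</sub>*
of candidate state-space vectors count as recurrences, and SL is the rate
of *joint* recurrences normalized by the single-channel recurrence count —
≈ *p<sub>ref</sub>* for independent signals, exactly 1 for identical ones,
sensitive to both linear and nonlinear dependence.

The resulting 29 × 29 weighted matrix is thresholded at connection density
*d* (keeping the `round(d·406)` strongest edges) and summarized by the
standard weighted graph measures — clustering coefficient *C*,
characteristic path length *L* (edge length 1/w), global and local
efficiency *E<sub>g</sub>*, *E<sub>l</sub>*, nodal strength *s*,
betweenness *b*, and the surrogate-normalized *γ*, *λ* and small-worldness
*σ = γ/λ*. Group inference uses covariate-adjusted (Freedman–Lane)
permutation tests, the **network-based statistic** (edge-wise t threshold
2.61, permutation null of the maximal suprathreshold component size), and
partial correlations with clinical scores (MADRS/YMRS).

A synthetic cohort generator produces two-group cohorts with a planted,
band- and region-specific coupling deficit (default: alpha band over
F4/FC3/FC4/Cz/CPz), spatially structured connectivity, amplitude
artifacts, and clinical scores with a controllable correlation to any
network metric — so the whole pipeline is testable without clinical data.

## Worked example

```r
library(slnet)

spec <- cohort_spec(n_patients = 10, n_controls = 10, fs = 250,
                    duration = 12, artifact_rate = 0, seed = 101)
cohort <- generate_cohort(spec)

cfg  <- preprocess_config(n_keep = 5)
par  <- embed_parameters(8, 12, fs = 250, p_ref = 0.02, n_ref = 5)
sl   <- lapply(cohort$recordings, function(r)
  sl_matrix(preprocess_recording(r, cfg, "alpha")$alpha, par))

groups <- factor(cohort$meta$group, levels = c("control", "patient"))
ms <- sapply(sl, mean_sl)
round(tapply(ms, groups, mean), 3)
#> control patient
#>   0.178   0.174

net <- lapply(sl, threshold_by_density, d = 0.30)
gm  <- sapply(net, function(n) unlist(global_metrics(n)))
round(rbind(control = rowMeans(gm[, groups == "control"]),
            patient = rowMeans(gm[, groups == "patient"])), 3)
#>             C     L    Eg
#> control 0.397 6.996 0.191
#> patient 0.367 7.355 0.181

res <- nbs(lapply(sl, unclass), groups, t_threshold = 2.61,
           n_perm = 500, seed = 1)
res$component_sizes[1]; res$corrected_p[1]
#> [1] 25
#> [1] 0.0379
```

The patient group shows the planted alpha deficit: lower mean SL, lower
clustering and efficiency, longer paths, and one significant NBS component
(25 links, corrected p = 0.038) concentrated around the fronto-central
effect channels. `run_pipeline(analysis_config(...), cohort)` runs the
same chain for all bands, a density sweep, nodal tests and clinical
correlations in one call, and `inst/cli/slnet-cli.R` exposes `simulate` /
`run-all` subcommands for shell use.

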