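# tacsdose

Dose-response analysis of tACS aftereffects from individual
electric-field models and MEG source imaging — on fully synthetic,
seeded cohorts.

## The problem

Alpha-band (8–12 Hz) transcranial alternating current stimulation
raises post-stimulation alpha power on average, but the effect varies
widely across people. A leading explanation is dosimetric: with a fixed
montage and intensity, individual anatomy produces very different
electric fields inside the brain. `tacsdose` implements an analysis
framework that tests this account quantitatively. For each subject it
derives three targeting predictors:

* `PRECISION_spat` — Pearson correlation between the simulated
  electric-field magnitude |E| and the source-projected alpha
  topography (DICS beamformer, neural activity index), over brain
  voxels;
* `STRENGTH` — mean of the top-fraction of |E| inside the brain
  compartment (V/m);
* `PRECISION_freq` — signed mismatch `sf − df` between the integer
  stimulation frequency and the dominant baseline alpha frequency (Hz);

and models the ROI-averaged alpha-power increase `Δpower` as a
full-factorial multiple regression

    Δpower ~ CONDITION × PRECISION_spat × PRECISION_freq × STRENGTH

with all-subsets AIC model comparison, a per-arm 3-factor model, a
peripheral (skin/eye field) control model, leave-one-out
cross-validation, and a within-subject sham-controlled replication
variant. Group-level localization uses one-sided cluster-based
permutation t tests (cluster mass, Monte-Carlo p values) on source
grids.

Everything runs on synthetic cohorts from a seeded generator: analytic
layered-sphere volume conduction (Legendre-series tES solver, spherical
conductor MEG leadfields), subject-jittered anatomy and conductivity, a
drifting alpha oscillator, 1/f background, and a planted multiplicative
dose-response gain. The package is aimed at methodologists who want a
tested, deterministic sandbox for this analysis chain.

## Worked example

```r
library(tacsdose)
cfg <- read_pipeline_config(system.file("extdata/config/exp1_between.yaml",
                                        package = "tacsdose"))
report <- run_experiment(cfg, seed = 1)
print(report)
```

```
<run_report> design = between  seed = 1  hash = 5f456f76
  subjects: 40
  tACS vs sham cluster p = 0.000999
  full model R2 = 0.975; tACS R2 = 0.916; sham R2 = 0.568; LOOCV R2 = 0.509
```

Reading the output: the tACS-vs-sham cluster permutation test finds a
significant alpha-power increase (p ≈ 0.001 at 1,000 randomizations —
the smallest attainable value); the 16-term full-factorial model
explains 97% of the response variance across all 40 subjects; the
3-factor targeting model explains 92% in the tACS arm versus 57% in the
sham arm (an 8-parameter model on 20 noise observations already yields
R² ≈ 0.37 by chance, which is why the AIC ranking, not raw R², carries
the sham-side conclusion); and the leave-one-out cross-validated R² of
the tACS model is 0.51. `write_report(report, dir)` writes predictor tables, model terms,
AIC rankings, cluster summaries and LOOCV predictions as TSV plus a
JSON summary; `make_figures(report, dir)` draws predicted-vs-observed
scatters (with the identity diagonal of perfect prediction) and
response-by-predictor panels. Maps export to NIfTI-1 via
`write_map_nifti()`.

A thin CLI wrapper ships at
`inst/scripts/tacsdose-run.R` (`--config`, `--seed`, `--out`,
`--figures`).

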