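# lesionmap

Voxel-based lesion-symptom mapping (VLSM) with survival validation, for
cohorts of binary lesion masks on a shared reference grid.

## What it is for

In neuro-oncology (and lesion neuroscience generally), *where* a lesion
sits carries prognostic information beyond how big it is. Given

* one binary tumor/lesion mask per patient (NIfTI, already spatially
  normalized to a common grid),
* a clinical table (TSV/CSV) with performance score (KPS), survival time,
  event indicator, age, sex and subgroup,
* optionally a white-matter tract atlas (directory of binary NIfTI masks),

`lesionmap` answers three questions:

1. **Mapping** — which voxels are significantly associated with a worse
   outcome? At each voxel `v` with enough lesion contrast it fits the
   general linear model `Y_v = Xβ + ε`, where `Y_v` is the binary lesion
   indicator across patients and `X` = [intercept, outcome (KPS or OS),
   age, sex, volume], and reports the adverse-signed statistic
   `t_adv(v) = −t_outcome(v)` (positive = lesion here co-occurs with a
   worse outcome). Significance is a one-sided permutation test (default
   500 permutations, per-voxel 95th-percentile thresholds) combined with
   Benjamini–Hochberg FDR on the permutation p-values; surviving voxels
   form an ROI.
2. **Anatomy** — how much of each atlas tract does an ROI damage?
   (`overlap voxels`, `structure voxels`, and the floor-truncated
   percentage convention of published overlap tables.)
3. **Prognosis** — does ROI involvement stratify risk? Patients whose
   lesion touches any ROI (≥ 1 voxel) are high-risk; the package computes
   Kaplan–Meier curves, the log-rank test, a univariate Cox hazard ratio
   (low-vs-high orientation, Efron ties, Wald CI) and a fixed-horizon
   survival ROC (cases died by the horizon, controls followed past it,
   censored-before-horizon excluded; bootstrap CI).

Because real cohorts cannot ship with the package, a first-class
synthetic-cohort generator produces lesion masks, clinical tables, a
ground-truth effect region and a synthetic tract atlas with known
statistical structure, so the entire pipeline is testable end to end. See
`vignettes/lesionmap-methods.Rmd` for the model, simulation world, and
every numerical convention.

## Worked example

```r
library(lesionmap)

cfg <- pipeline_config(list(
  out_dir = "run1", seed = 1,
  simulation = list(n_patients = 150, kps_effect = -25)))
res <- run_pipeline(cfg)
```

This simulates a 150-patient GBM-like discovery cohort and an independent
validation cohort sharing the same ground-truth effect region, runs VLSM
for both outcomes, extracts ROI1 (KPS) and ROI2 (OS), quantifies tract
overlap against a 6-tract synthetic atlas, assigns risk groups in the
validation cohort and validates them. With seed 1 it logs

```
discovery: 150 patients, 76800 voxels
vlsm[kps]: 2864 analyzed voxels, 478 significant (ROI1)
vlsm[os]:  2864 analyzed voxels, 0 significant (ROI2)
validation: logrank p = 0.00168, HR(low vs high) = 0.537
```

(an empty OS ROI is a legitimate outcome — the raw-survival-time signal is
much weaker than the KPS signal; the source study likewise found no OS
region in one subgroup) and writes `run1/validation/stats.json`:

```json
{
  "horizon": 12,
  "n_high": 64,
  "n_low": 86,
  "logrank_p": 0.00168,
  "hr_low_vs_high": 0.537,
  "hr_ci": [0.362, 0.796],
  "auc": 0.589,
  "auc_ci": [0.489, 0.686],
  "n_excluded_censored": 26
}
```

Reading the numbers: `logrank_p` is the two-sided log-rank p-value
comparing survival of high- vs low-risk patients — small means ROI
involvement separates the survival curves. `hr_low_vs_high` < 1 means the
low-risk group (no ROI contact) has a proportionally lower death hazard
(e.g. 0.5 ≈ half the hazard), with its Wald 95% CI in `hr_ci`. `auc` is
the 12-month fixed-horizon AUC of the continuous marker "total ROI-overlap
voxels" (0.5 = uninformative, 1 = perfect ranking of who dies by one
year). All maps (`tmap_*.nii.gz`, `pmap_*.nii.gz`, `ROI*.nii.gz`), overlap
tables, KM curves, risk assignments and a manifest with per-stage seeds
and output checksums land under `run1/`.

The same run is available from the shell:

```sh
Rscript inst/cli/lesionmap.R run-all --config cfg.yaml --seed 42
```

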