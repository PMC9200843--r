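# radphen

Radiomic phenotyping of tumor CT with multi-batch harmonization and
prognostic survival modeling.

`radphen` is aimed at imaging researchers who extract quantitative
("radiomic") features from segmented CT tumor volumes across a cohort
scanned under heterogeneous acquisition settings, and who want to ask
whether unsupervised imaging phenotypes carry prognostic information for
progression-free survival (PFS) over and above established clinical
factors (PD-L1 expression, ECOG performance status, BMI, smoking status).

## What the pipeline does

1. **Feature extraction.** Image/mask pairs are resampled to the
   cohort-minimum voxel spacing (component-wise minimum over all scans;
   trilinear for the image, nearest-neighbor for the mask) and a fixed
   102-feature descriptor is computed per tumor across eight families:
   first-order intensity statistics, discretized-histogram statistics,
   intensity–volume-histogram features, morphology (iso-surface mesh
   area, sphericity, diameter, …), GLRLM, GLSZM, NGTDM and slice-wise
   rotation-invariant uniform LBP histograms.

2. **Nested ComBat harmonization.** Acquisition batch effects (e.g.
   contrast enhancement, reconstruction-kernel class) are removed with
   empirical-Bayes ComBat. Each feature *g* in batch level *i* is modeled
   as

   y<sub>ijg</sub> = α<sub>g</sub> + X β<sub>g</sub> + γ<sub>ig</sub> + δ<sub>ig</sub> ε<sub>ijg</sub>,

   with location shifts γ and scale factors δ shrunk by parametric
   empirical Bayes (normal and inverse-gamma priors, moment-matched),
   and the adjusted value is (y − α̂ − Xβ̂ − γ̂*)/δ̂* rescaled back. Clinical
   covariates are *protected*: they enter the standardization fit so
   their biological signal is not removed. With several batch variables,
   every ordering is applied sequentially and the ordering whose output
   has the fewest features still batch-associated (k-sample
   Anderson–Darling test at α = 0.05) is kept; features that remain
   significant are discarded as non-robust.

3. **Phenotype discovery.** Ward (`ward.D2`) hierarchical clustering on
   z-scored harmonized features; stability assessed by consensus
   clustering (subsampling, pairwise co-clustering proportions, area
   under the consensus CDF) and significance by SigClust (cluster index =
   within-cluster SS / total SS against a Gaussian null fitted to the
   data; 10,000 simulations by default).

4. **Prognostic models.** Five-fold cross-validated Cox
   proportional-hazards models (Efron ties) repeated over shuffles, with
   Harrell's concordance on pooled out-of-fold risk scores; Kaplan–Meier
   curves split at the median prognostic score with the log-rank test;
   therapy-line stratified analysis; chi-square phenotype–covariate
   association; random-forest prediction of PD-L1 class from phenotype.

Because studies of this design rarely deposit raw images, the package
ships a first-class synthetic-cohort generator
(`simulate_feature_cohort`, `simulate_survival`,
`simulate_tumor_volume`) that plants known batch shifts, cluster
structure, covariate effects and proportional-hazards outcomes, so every
stage is testable against ground truth.

## Worked example

```r
library(radphen)

cfg <- pipeline_config(out_dir = "demo_run", n_resamples = 200,
                       n_sim = 500, iterations = 50, seed = 42)
run_pipeline(cfg)

read.csv("demo_run/models.csv")
```

On the default synthetic 107-sample cohort (two batch variables with
80/27 and 90/17 level frequencies, two planted phenotypes, planted
cluster log hazard ratio 0.4) this prints:

```
               model    mean_c    ci_low   ci_high logrank_chisq    logrank_p
1             volume 0.5113259 0.4620036 0.5647037    0.01776796 8.939589e-01
2          phenotype 0.4813196 0.4316794 0.5073466    0.48615156 4.856490e-01
3           clinical 0.5697499 0.5157964 0.6136426   16.59281121 4.632629e-05
4    volume+clinical 0.5605800 0.5124291 0.6114467   12.89541631 3.293878e-04
5 phenotype+clinical 0.5634629 0.5130279 0.6077248   18.75354235 1.487468e-05
```

`mean_c` is the mean cross-validated concordance over iterations with
its percentile 95% CI: ~0.5 means no discrimination (the volume and
phenotype-only models here — the planted phenotype effect is
deliberately weak), higher is better. `logrank_p` tests the separation
of the Kaplan–Meier curves for patients above versus below the median
prognostic score of the full-cohort fit; the planted covariate and
phenotype effects make the clinical and combined models separate
strongly. The run directory also contains
`harmonization_report.json` (batch-order permutations and residual
batch-associated feature counts), `phenotypes.csv`, `consensus.json`,
`stats.json` (association tests, PD-L1 AUCs, therapy-line strata) and
`provenance.json` (config hash, seeds, per-stage counts).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/radphen.R simulate --n 107 --seed 1 --out cohort
Rscript inst/cli/radphen.R run-all --input cohort --seed 1 --out results_dir
```

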