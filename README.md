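# sccproc

Process–outcome analysis of **self-concept clarity (SCC)** measured
repeatedly during psychotherapy, for psychotherapy-process researchers who
collect biweekly SCCS ratings alongside pre/post symptom inventories.

Patients with neurotic and personality disorders rate their self-concept
clarity (SCCS, 12–60) every two weeks, plus neurotic symptoms (KS-II) at
intake and discharge and neurotic personality traits (KON-2006) at intake.
`sccproc` turns a long-format table of those measurements into:

1. **Per-subject trajectory features.** A logarithmic trend
   *Y<sub>i</sub> = a + b ln t<sub>i</sub> + e<sub>i</sub>* is fitted per
   subject, and the fluctuation statistic is
   RMSE = √(Σ(Y<sub>i</sub> − Ŷ<sub>i</sub>)² / k) — the SD of the ratings
   around the individual log trajectory.
2. **A five-class shape taxonomy** driven by the SCCS reliable-change
   threshold (3.48 points): monotonic increase, "V" shape (one reliable
   drop immediately followed by a reliable rise — the destabilization–
   reintegration signature), discontinuous change, plateau, and monotonic
   decrease. Every series gets exactly one label.
3. **Four personality dispositions** from crossing baseline SCCS ≥ 34
   (integrated) with baseline KON-2006 below the integrated-subgroup median
   (functional), validated against k-means clusters via Cramér's V.
4. **The inferential battery**: likelihood-ratio G-tests of each shape
   against improvement (KS-II change > 56.6) per stratum, a
   fluctuation × disposition interaction regression with sequential-R²
   variance shares, a two-factor (shape × disposition) Type-III ANOVA with
   partial η², a three-level variance-components null model (subjects in
   therapy groups in units, REML with Wald statistics), and
   fluctuation–outcome correlations by stratum.
5. **A synthetic cohort generator** (`simulate_scc_cohort()`) whose
   defaults reproduce the study-like conditions (disposition sizes
   22/21/10/32, published baseline means/SDs, published shape frequencies,
   6 occasions, 3 units / 7 groups), with ground-truth labels for
   end-to-end validation.

## Worked example

```r
library(sccproc)

coh <- simulate_scc_cohort(seed = 7)   # study-like cohort, n = 85
fit <- scc_process(coh, seed = 7)      # full pipeline
fit
```

```
SCC process-outcome analysis: 85 subjects
Cutoffs: SCC RCI 3.48, KS-II RCI 56.6, SCC cutoff 34, KON cutoff 33.12

Shape counts:
 monotonic_increase             v_shape discontinuous_other             plateau
                 11                  31                  22                   6
 monotonic_decrease
                 15

Disposition counts:
      integrated_functional    integrated_dysfunctional
                         21                          22
   disintegrated_functional disintegrated_dysfunctional
                         11                          31

Improved (change > 56.6): 39 / 85
```

The KON cutoff (33.12 here) is recomputed from the cohort's integrated
subgroup; 39/85 subjects cleared the 56.6-point reliable-change bar on the
KS-II. `summary(fit)` adds the test battery; highlights from this seed:

```
k-means vs disposition split: Cramer's V(9, N = 85) = 0.82

Variance components of the change score (n = 85, REML)
 parameter estimate wald_z        p
  residual  9313.63   6.32 2.57e-10
 var_group   499.30   0.54 5.92e-01
  var_unit   154.06   0.19 8.47e-01

Symptom change ~ SCC fluctuation x disposition (IF vs rest)
        term estimate     t      p
 (Intercept)   -8.347 -0.29 0.7720
        rmse   27.181  2.71 0.0083
       is_if   57.930  1.07 0.2890
  rmse:is_if  -34.341 -1.81 0.0739
Sequential R2: rmse 4.8%, is_if 1.7%, rmse:is_if 3.6%; total R2 = 0.102 (n = 85)
```

Read: change-score variance lives almost entirely at the subject level
(groups and units add ~5% and ~2%, neither credible), SCC fluctuation
predicts symptom improvement in the pooled non-integrated-functional
strata (slope 27.2 points of KS-II change per RMSE point), and the negative
interaction says that slope flattens for integrated-functional patients.
`coef(fit)`, `residuals(fit)`, `fitted(fit)` and `plot(fit)` expose the
usual model-object surface; `write_scc_report(fit, dir)` emits the
per-subject CSV, the test tables, and a JSON summary.

Individual stages are available directly, e.g.:

```r
classify_shape(c(38, 33, 39))          # "v_shape"
fluctuation_rmse(c(30, 36, 35, 39))    # 1.236
g_test_2x2(20, 19, 9, 37)$statistic    # 9.59
midpoint_cutoff(23.76, 7.44, 44.88, 11.28)  # raw 34.32, applied 34
```

A thin command-line front end with `simulate` / `validate` / `classify` /
`analyze` verbs is installed at `inst/scripts/scc-pipeline.R`.

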