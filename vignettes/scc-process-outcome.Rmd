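---
title: "Self-concept clarity trajectories in psychotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-concept clarity trajectories in psychotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Patients in intensive group psychotherapy fill in the Self-Concept Clarity
Scale (SCCS, 12 items, range 12–60) every two weeks, alongside a
neurotic-symptom inventory (KS-II) at the start and end of treatment and a
neurotic-personality questionnaire (KON-2006) at baseline. The question this
package operationalizes is a process–outcome one: do the *shape* and the
*turbulence* of a patient's SCC trajectory predict symptom improvement, and
does that relationship differ across personality dispositions? The
theoretical backdrop is Piagetian: assimilation (small adjustments to
self-schemas) should show up as smooth, monotone SCC growth, while
accommodation (restructuring of self-schemas) should show up as a transient
destabilization — a dip followed by recovery, the "V" shape.

`sccproc` implements the full analysis pipeline as one fitting function,
`scc_process()`, over a long-format measurement table, plus a synthetic
cohort generator with known ground truth so that every stage can be
validated end to end without access to patient data.

## Trajectory model

For each subject with scores \(Y_1, \dots, Y_k\) at occasions
\(t = 1, \dots, k\), a logarithmic trend
\[ Y_i = a + b \ln t_i + e_i \]
is fitted by ordinary least squares. The log — rather than linear — trend
reflects the typical decelerating course of change across a course of
therapy. The fluctuation statistic is
\[ \mathrm{RMSE} = \sqrt{\tfrac1k \sum_{i=1}^k (Y_i - \hat Y_i)^2}, \]
deliberately with denominator \(k\) (the population SD of the residuals),
not the regression convention \(k-2\). The time variable is the 1-based
occasion index, not the calendar week: occasions are near-equally spaced
(every two weeks), index 1 keeps \(\ln t\) defined, and an occasion-index
fit is invariant to when therapy started. Week-based fitting can be obtained
by passing `occasions = week + 1` if ever needed.

## Shape taxonomy

Consecutive differences \(d_i = Y_{i+1} - Y_i\) are compared against the
SCCS reliable-change threshold of 3.48 raw points (95% confidence). A
change of *exactly* 3.48 is not reliable — the inequality is strict. The
five labels form a total partition:

| label | rule |
|---|---|
| plateau | no reliable change in either direction |
| monotonic increase | ≥ 1 reliable rise, no reliable drop |
| monotonic decrease | ≥ 1 reliable drop, no reliable rise |
| "V" shape | exactly one reliable drop, immediately followed by a reliable rise |
| discontinuous (other) | both directions occur, and the V rule fails |

Two readings of the verbal definitions were genuinely open and are resolved
as follows. First, "from one measurement to the second following
measurement" is read as *consecutive* occasions (lag-1); a lag-2 reading
would make the plateau definition incoherent (a plateau would then have to
be flat over skip-one windows while drifting freely between neighbours).
Second, the V shape restricts only the number of reliable *decreases* (one)
and the immediacy of the rebound; additional reliable increases elsewhere in
the series do not disqualify a V, and the post-dip score need not recover
to the pre-dip level. The classifier is exhaustively checked against an
independently coded pattern-matching oracle over every integer series with
up to five occasions in a 17-point score window.

## Personality dispositions

The integration cutoff of 34 SCCS points is the midpoint of two published
reference distributions — a clinical sample at 23.76 (SD 7.44) and a
non-clinical sample at 44.88 (SD 11.28) — rounded to the nearest integer
(34.32 → 34). `midpoint_cutoff()` also exposes the SD-weighted Jacobson
criterion (which would give ≈ 32.15, documenting that the plain midpoint,
not the weighted one, reproduces the published 34). Baseline SCCS ≥ 34 is
"integrated", ≤ 33 "disintegrated". The functionality cutoff is the median
baseline KON-2006 score *within the integrated subgroup* (34 in the study),
applied to all subjects; KON-2006 strictly below the cutoff is
"functional". The resulting four groups are validated by k-means (k = 4,
z-standardized features, 10 restarts, seeded) cross-tabulated against the
cutoff labels and summarized by Cramér's V. Standardization matters:
KON-2006 spans roughly four times the range of the SCCS and would otherwise
dominate the Euclidean metric.

The reliable-change thresholds 3.48 (SCCS) and 56.6 (KS-II) are treated as
configured constants of the instruments rather than re-derived: the
standard Jacobson–Truax formula with the published SDs and reliabilities
does not reproduce them exactly (e.g. SD 10, α = .88 gives 9.60 at 95%
two-sided; an SEM-style rule SD·√(1−α) ≈ 3.46 comes close to 3.48 but is
not documented). The formula itself is exposed as
`reliable_change_threshold()` for users who want to derive thresholds for
other instruments.

## Outcome statistics

The outcome is the pre-minus-post KS-II change (positive = fewer symptoms);
"improvement" is a change strictly above 56.6. The inferential battery
mirrors the study's analysis plan:

* **G-tests.** For the whole sample and within each disposition, each shape
  is tested against improvement on the fourfold table (improvement / not) ×
  (in-shape / all other shapes) with the likelihood-ratio statistic
  \(G = 2\sum O \ln(O/E)\), zero cells contributing 0, on 1 df — the
  recommended alternative to Pearson's χ² with continuity correction when
  expected counts are small. Strata with a zero margin are skipped with a
  notice rather than tested.
* **Interaction regression.** `change ~ rmse * is_if`, where `is_if`
  contrasts the integrated-functional group against the pooled other three.
  Per-term "explained variance" is sequential (Type I) incremental R² in
  the order fluctuation, disposition, interaction; the study does not define
  its variance decomposition, and the sequential convention has the virtue
  that the shares sum exactly to the total R².
* **Two-factor ANOVA.** Change on shape (5 levels) × disposition contrast
  (2 levels) with interaction, Type III sums of squares with sum-to-zero
  contrasts (the common SPSS convention for unbalanced factorials), partial
  η² = SS_effect / (SS_effect + SS_error), plus per-cell means and SDs.
* **Variance components.** The null (intercept-only) three-level model —
  subjects in therapy groups in units — fitted by REML via `lme4`. Wald
  statistics (estimate/SE against a normal reference) are computed from the
  numerical curvature of a directly coded REML deviance at the estimates,
  because `lme4` intentionally does not report variance-component standard
  errors. This Wald approximation is known to misbehave near the zero
  boundary; components estimated at zero are reported with `NA` Wald
  statistics, and the limitation is inherited from the analysis plan being
  mirrored rather than endorsed.
* **Correlations.** Pearson correlations between fluctuation and change
  within the integrated-functional stratum and within the pooled remainder.

No multiple-testing correction is applied across the 25 G-tests, matching
the original analysis; `p.adjust` can be applied to the returned table by
users who want it.

## The synthetic cohort generator

`simulate_scc_cohort()` draws cohorts whose *defaults are the study's
conditions*: four dispositions of sizes 22/21/10/32; baseline
(SCCS, KON-2006, KS-II) means and SDs per disposition of
(45/8, 17/11, 233/85), (41/5, 54/15, 315/99), (28/3, 18/10, 260/104),
(26/5, 60/15, 339/84), drawn from normals truncated to the instrument
ranges (SCCS 12–60, KS-II 0–595, KON-2006 0–235); per-disposition shape
frequencies equal to the published frequency table; six occasions per
subject (the study's mean is 5.8 over a 4–9 range; a range can be
configured); and a 3-unit / 7-group clustering layout with group sizes
9/9/9/16/16/13/13.

Each subject's SCC series is an archetype curve for their true shape —
e.g. a +7 first step then gentle +1 drift for monotonic increase, a
+1, −7, +8 pattern for the V — anchored at the subject's drawn baseline
SCCS and perturbed by independent Gaussian occasion noise (SD 1 point by
default). Step sizes clear the 3.48 threshold with enough margin that
classification survives occasion noise of SD 1 with ≥ 95% accuracy, which
is exactly the recovery property the tests assert. Two details are worth
knowing:

* The anchor is clamped so that the *noise-free* curve stays inside 12–60;
  the clamped value becomes the subject's baseline. Without this, subjects
  drawn near the ceiling would have their first rise clipped and the
  archetype would no longer classify as its own shape at zero noise. The
  cost is a mild truncation of baseline spread for extreme draws.
* Occasion noise is independent across occasions. Real SCC measurements
  are likely autocorrelated within subject; nothing in the study constrains
  that autocorrelation, so the generator does not model it, and passing
  recovery tests say nothing about robustness to serially correlated noise.

The KS-II outcome is generated in one of two modes. The default (`"cells"`)
draws the change from a normal per (shape × disposition-contrast) cell.
Four cell parameters are published and used verbatim: V shape 103/87
(non-IF) and 30/116 (IF); plateau 129/58 (IF) and −15/68 (non-IF). The
remaining cells are not published; they were fixed once, before any testing,
to be consistent with the published improvement frequencies (monotonic
increase 120/60 IF and 85/85 non-IF; discontinuous 20/80 and 25/95;
monotonic decrease −45/50 and −55/55 — the last implying a ≈ 2% improvement
probability, matching the observed 0/15). Improvement status is *not*
assigned first: it emerges from the drawn change relative to 56.6. The
second mode (`"rmse"`) generates the change from the published fixed-effect
estimates (intercept 1.92, fluctuation slope 29.76, disposition 61.25,
interaction −48.49, residual SD 80 ≈ the null-model residual scaled by the
model's unexplained share) applied to the subject's *realized* fluctuation;
it exists for parameter-recovery simulations where the true interaction
sign is known by construction.

What the generator does **not** emulate: dropout and missingness, serial
noise correlation, floor/ceiling item-level artifacts, and any mechanistic
coupling between the SCC trajectory and the symptom course beyond the cell
means. Passing tests on synthetic cohorts therefore demonstrate the
*pipeline's* correctness and the recoverability of effects of the
configured size — not that real data would show those effects.

## Numerical choices and degenerate inputs

* OLS fits use closed-form least squares (`lm.fit` / `lm`); the trajectory
  fit refuses series shorter than 2 and designs with equal log-times.
* Series of 2–3 occasions are analyzable but warned about (study range
  4–9); subjects with fewer than 2 occasions are rejected at I/O with a
  per-subject list, so no subject is silently dropped.
* The G-test requires all four margins positive; the battery converts that
  error into a skipped, flagged row.
* k-means uses 10 restarts under a user seed; Cramér's V drops all-zero
  rows/columns before computing χ².
* Variance components at the zero boundary get `NA` Wald statistics rather
  than a misleading z.
* Ties at the cutoffs are resolved exactly as printed: SCCS 34 is
  integrated, KON-2006 34 is dysfunctional (strict `< 34` is functional).

## Problem sizes used in the test suite

The suite checks the classifier exhaustively over all integer series with
\(k \le 5\) in the 30–46 window (≈ 1.5 million series), the fluctuation
statistic against a normal-equations oracle on 1000 random series,
interaction-sign recovery over 200 simulated cohorts of n = 85, and
variance-component recovery over 30 replicates — sizes chosen to keep the
whole suite comfortably under a minute or two while leaving Monte-Carlo
error well below the asserted margins.

## Known limitations

* The Wald test on variance components is a boundary-unfriendly
  approximation, reported because the mirrored analysis plan reports it.
* The sequential-R² variance decomposition is order-dependent; the order
  fluctuation → disposition → interaction is fixed and documented.
* The shape taxonomy is rule-based, not model-based: it was chosen over
  growth-mixture modelling deliberately (the confirmatory taxonomy is the
  object of study, and mixture models are unstable at n = 85), so the
  package does not estimate latent trajectory classes.
* The KS-II score range is treated as 0–595 (weighted item scoring); the
  published subgroup means (233–339) are incompatible with a 0–255 reading
  of the 85-item scale.
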