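---
title: "mmstate: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mmstate: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: what is being
modelled, which knobs matter, what the synthetic world does and does not
emulate, and where genuinely open design choices were resolved. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. Feature derivation

Driver-level inputs are consumed, never called: mutation flags per gene,
locus-level absolute copy number with a precomputed focal (<5 Mb) vs large
(≥5 Mb) segment-size class, IGH translocation partners, the APOBEC
(SBS2+SBS13) signature fraction, and a boolean chromothripsis
copy-number-signature flag. Derived features follow fixed thresholds:

* **Copy-number class.** With a diploid baseline: 0 = biallelic loss,
  1 = loss, 2 = neutral, 3 = gain, >3 = amplification. The baseline is
  *not* shifted for hyperdiploid genomes — thresholds are expressed in
  absolute copies, so a trisomic arm in a hyperdiploid genome is still a
  gain.
* **Hyperdiploidy.** At least two distinct odd-numbered chromosomes with a
  large-class gain. Focal gains never count, and repeated gains on one
  chromosome count once.
* **Allelic TSG status.** Biallelic iff mutation + locus deletion, or
  0 copies; monoallelic iff exactly one hit class. The TSG→locus map is an
  editable registry; the default covers the main recurrently inactivated
  genes (TRAF3, CYLD, TP53, RB1, MAX, TENT5C, CDKN2C, DNMT3A). The full
  supplementary peak tables of real analyses are not bundled, so users with
  complete GISTIC output should extend the registry (a stated limitation).
* **Hyper-APOBEC.** Fixed-threshold mode flags fraction > 0.11 (the
  published decile cutoff); decile mode recomputes the top tenth among
  patients with nonzero APOBEC evidence within the supplied cohort.
  Tie policy in decile mode: `k = floor(0.1 · n_eligible)` patients are
  flagged by rank, with ties at the boundary value all included — a
  deterministic rule that flags exactly `k` patients on distinct-valued
  inputs. Fixed-threshold is the package default because it is
  per-patient deterministic; decile mode is cohort-dependent by nature.
* **Masking.** Each assay class (mutations / CNV / translocations /
  signatures) carries an availability flag; derived features of an
  unavailable class are `NA`, never silently false. Classification refuses
  masked inputs; the risk model handles them by the missing-genomics
  mechanism below.

## 2. The twelve-group classification

The classifier is an ordered rule set; the first matching rule wins:

1. t(MAF/MAFB) or hyper-APOBEC → `MAF_APOBEC`
2. t(NSD2): + del13q + 1q gain/amp → `NSD2_1q_13q`; + del13q →
   `NSD2_13q`; otherwise `NSD2_Simple`
3. del13q + 1q gain/amp without t(NSD2) → `1q_13q`
4. t(CCND1): complex genome → `CCND1_Complex`, else `CCND1_Simple`
5. hyperdiploid without canonical translocation: complex → `HRD_Complex`;
   simple + RAS mutation → `HRD_RAS`; simple otherwise → `HRD_Gains`
6. remainder: complex → `Multiple_Losses`, else `Simple`

**Complexity** is `chromothripsis OR ≥D large deletions OR ≥B biallelic
events` with defaults `D = 2`, `B = 1` (configurable; the exact published
cutoffs live in supplementary material unavailable here).

Two precedence questions are not settled by the narrative source and were
resolved as package policy:

* Hyper-APOBEC routes to `MAF_APOBEC` even in the presence of another
  translocation, **except** t(NSD2), which wins by default
  (`nsd2_overrides_apobec = TRUE`, switchable). Rationale: the merge of
  MAF and high-APOBEC is outcome-motivated, while t(4;14) defines its own
  groups; a patient with both is more informatively filed under NSD2.
* t(CCND1) co-occurring with hyperdiploidy routes to `CCND1_*` (rule 4
  precedes rule 5), mirroring the legacy translocation-first conventions.

Totality is a tested invariant: every fully observed point of the
discretized feature lattice maps to exactly one of the 12 labels.

## 3. Staging comparators

ISS (β2-microglobulin 3.5/5.5 mg/L, albumin 3.5 g/dL), R-ISS (ISS + LDH
ratio + del17p/t(4;14)/t(14;16)), and the additive R2-ISS score
(ISS II +1, ISS III +1.5, del17p +1, high LDH +1, t(4;14) +1, 1q +0.5;
groups 0 / 0.5–1 / 1.5–2.5 / 3–5). The R2-ISS 1q component counts gain and
amplification alike — whether the published comparator used gain-only is
not stated in the main text; combining both is the package default and is
config-visible.

## 4. The multi-state model

Six states, two phases, seven transitions (see README diagram). Modelling
assumptions, in order of consequence:

* **Semi-Markov clock reset.** Phase-I hazards run on months from
  diagnosis; on entry into remission (S3) the clock resets and every
  phase-II hazard runs on months from the end of induction. Within a
  phase the process is Markov on the phase clock.
* **Treatment as covariates, not states.** HDM-ASCT and maintenance are
  indicators on the phase-II design set by the treatment course at S3
  entry; induction drug-class indicators (IMID / PI / chemotherapy) enter
  both phases. This matches a six-state topology with time-dependent
  treatment features.
* **S2 (lost to follow-up / non-disease death in phase I) is absorbing**
  for model purposes and excluded from the OS event by default
  (configurable).
* **Per-transition hazards.** λ(t|x) = λ₀(t)·exp g(x, t), with
  g = xβ [+ tanh hidden layer, width 16 by default when enabled]
  [+ per-time-bin offsets, 4 quantile bins per phase]. With hidden width 0
  and time interactions off, g ≡ xβ and the fit reduces — verifiably, to
  1e-3 — to an independent Newton–Raphson Cox solver. The published
  architecture details are supplementary-only; this package's contract is
  the reduction property plus configurability, not architectural
  replication. Fitting is full-batch BFGS on the exact Efron partial
  likelihood with analytic gradients (no stochastic epochs), an
  appropriate choice at cohort sizes of 10²–10⁴ where exact risk sets are
  cheap; determinism given the seed is a tested contract.
* **Ties and baseline.** Efron by default (Breslow available); the
  baseline cumulative hazard is the tie-consistent Breslow/Efron step
  estimator, with jumps only at event times (tested invariant).
* **Missing genomics.** The design carries a `genomics_missing` mask bit;
  masked patients have genomic columns zeroed. `mask_dropout` randomly
  masks a fraction of training patients so one model serves both modes.
  **Deviation from the drafted design:** dropout defaults to 0, not on,
  because enabling it attenuates fitted effects and would silently bias
  the parameter-recovery contract (±0.15); the no-genomics mode is
  exercised in tests with dropout explicitly enabled.
* **Regularization.** A small ridge (1e-4, on the scaled objective) keeps
  hidden-layer fits well-posed; it is provably negligible for the linear
  reduction (the tested 1e-3 agreement holds with it in place at the
  default, and the reduction test itself sets it to 0).

**Occupancy.** State-occupation probabilities are computed by a discrete
product integral on a uniform grid (default monthly to 120 months). Within
a step, increments act as constant competing hazards: stay probability
`exp(−ΣΔ)`, movers split proportionally — exact for piecewise-constant
hazards, hence the 1e-3 closed-form acceptance suite passes by
construction rather than by grid refinement. Phase chaining integrates the
phase-I entry-time distribution against the phase-II sub-chain evaluated
on the reset clock, with a midpoint correction (entries land mid-step on
average) giving O(δ²) accuracy. Conservation (rows sum to 1) holds
identically; grid times beyond the fitted baseline support carry zero
increments and flag the trajectory as extrapolated.

## 5. Treatment courses, PFS and treatment variance

The induction taxonomy is the set of drug-class combinations of
{IMID, PI, chemotherapy}. A subset lattice has seven non-empty elements;
to keep the documented count of eight categories an explicit `other`
reference category is included (the drafted "lattice plus top element"
phrasing double counts). Post-induction: observation, HDM-ASCT,
HDM-ASCT+MCT, MCT — 32 courses in all.

5-year PFS is the summed occupation probability of the remission states
{S0, S3} at 60 months (both configurable). Treatment variance is the
within-patient max−min of per-course PFS; benefit clustering uses Ward
agglomeration on Euclidean distances of the per-course PFS matrix
(`k = 6` default). The published clustering algorithm is unnamed; Ward was
chosen as the deterministic, variance-minimizing default, and identical
profiles short-circuit to a single cluster. Clustering defaults to the 4
VRd courses (the published figure's scope) with an all-32 option.

## 6. Evaluation

* **C-index.** Harrell's pairwise definition: comparable pairs are
  (earlier observed event, later anything) and time-ties with exactly one
  event; risk ties score 0.5. Verified against a naive O(n²) oracle and
  monotone-transform invariance.
* **Risk score.** 1 − predicted endpoint-free probability at 5 years
  (EFS-free = P(S0)+P(S3); OS-free = 1−P(S5)). The model is
  non-proportional, so a linear predictor is not a valid ranking; a fixed
  horizon's predicted risk is. No truncation is applied to observed
  follow-up when counting comparable pairs (the source is silent; this is
  the package's choice).
* **Cross-validation.** Stratified k-fold × repeats (5 × 10 default);
  stratification is ISS × event-indicator (unspecified in the source;
  chosen to balance both outcome rate and case mix). Splits are
  deterministic given the seed; within a repeat, test folds partition the
  cohort with stratum proportions within one member.
* **Ablation** masks one design block (age / ISS / other clinical /
  genomics / treatment) at fit *and* predict time and reports the mean CV
  c-index drop.
* **Knowledge bank.** A fitted model applied without refitting to a
  schema-validated external cohort, reporting external c-indices.

## 7. The synthetic world

The generator is first-class, tested code, and its defaults are fixed:

* **Group-first sampling.** A group label is drawn from the 12-group
  mixture (weights = the published cohort prevalences, renormalized from
  their printed sum of 99.5), then raw driver calls are sampled under the
  group's defining constraints so the classifier provably recovers the
  label (≥99% tested; the mechanisms that previously leaked — accidental
  biallelic hits from background TSG mutations under pool deletions,
  del13q∧1q co-occurrence re-routing to `1q_13q` — are excluded by
  construction).
* **Marginal prevalences.** KRAS 24.3%, NRAS 20.1%, BRAF 7.8%, DIS3 9.4%
  are hit exactly in expectation by analytically correcting free-sampling
  rates for the groups where RAS/DIS3 are forced or excluded.
  Chromothripsis (26.4%) and APOBEC-positivity (39%) are matched by
  solving the group-conditional rates against the mixture weights.
  Hyper-APOBEC lands near the MAF_APOBEC mass (~7%) rather than the
  published 10%: under a strict rule set every hyper-APOBEC patient is
  routed to MAF_APOBEC (8.7%), so a 10% hyper-APOBEC marginal is
  unattainable — the published figures come from overlapping but unequal
  patient subsets.
* **Clinical covariates** are independent of genomic group (correlation
  unreported; the table is editable as the hook). β2-microglobulin rises
  with age, so ISS carries real prognostic signal through the age effects
  — this is what makes the staging-only comparator honestly beat chance.
* **Hazards.** Cause-specific exponentials per edge,
  rate = base·exp(x'θ), phase-II clock reset, uniform administrative
  censoring over 24–96 months (bracketing a ~43-month median follow-up).
  Base rates reproduce the published event flow (~15% progression during
  induction, ~7% phase-I loss, induction ≈ 6 months, ~53% overall
  relapse). True effects θ are deliberately placed on covariates whose
  Fisher information at n = 2000 supports recovery within ±0.15 (age per
  decade on most edges; ISS III on the event-rich remission edge; the
  large-deletion count, HDM-ASCT and maintenance on post-induction
  progression). Low-prevalence binaries (e.g. TP53 biallelic, 1q amp)
  exist in the data but carry no true effect, because no estimator could
  recover them to that tolerance at this size — a green recovery test
  therefore establishes calibration of the fitter, not detectability of
  rare-lesion effects.
* **Not emulated:** real co-occurrence beyond the rule-defining
  constraints, clinical-genomic correlation, non-exponential sojourns,
  informative censoring, cohort batch structure, and any real-cohort
  c-index levels. Green tests establish internal correctness (oracles,
  closed forms, recovery, orderings) on this stated world — not clinical
  performance.

## 8. Numerical choices and degenerate inputs

* BFGS with `reltol = 1e-10`, max 300 iterations; parameters initialized
  at zero except hidden weights (seeded N(0, 0.1²)); with zero output
  weights the initial predictor is exactly 0, so `loglik0` is the null
  partial likelihood and likelihood ascent is testable.
* Transitions with zero events degenerate to a zero-hazard model with a
  warning, never an error; prediction through a degenerate edge
  contributes zero increments.
* Zero-length sojourns (states entered and left at the same recorded
  time) are widened by 1e-6 months to keep risk intervals valid.
* The occupancy grid must be uniform (required by the convolution);
  `occupancy_at` refuses extrapolation beyond the grid.
* Decile flagging requires ≥10 patients; empty cohorts, negative copies,
  out-of-range fractions, unknown loci/genes/blocks and mismatched label
  vectors raise immediate errors.

## 9. Known limitations

* The locus/TSG registry covers main-text entries only; full GISTIC peak
  tables must be supplied by the user.
* The flexible hazard (hidden layer + time bins) is a stand-in for an
  architecture whose published details are supplementary-only; only the
  Cox-reduction contract is guaranteed.
* Benefit-cluster *labels* are not comparable across cohorts (cluster
  identity depends on the fitted model and course set).
* No frailty/random effects, interval censoring, Bayesian inference, or
  causal interpretation of treatment effects; course comparisons are
  predictions under an observational fit, not causal estimates.
* New-agent therapies and measurable-residual-disease dynamics are out of
  scope.
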