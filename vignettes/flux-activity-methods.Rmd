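---
title: "Inferring condition-specific metabolic activity: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring condition-specific metabolic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models the package implements, the parameters
that matter, the numerical and design choices that were genuinely open,
and what the synthetic benchmarks do and do not demonstrate.

## 1. The constraint-based model

A genome-scale metabolic model is held as a `MetabolicModel`: a sparse
stoichiometric matrix S (metabolites × reactions), per-reaction flux
bounds in the model's own units (mmol/gDW/h for human reconstructions),
parsed gene–protein–reaction (GPR) Boolean trees, subsystem labels and a
reaction *kind* (`internal`, `exchange`, `sink`,
`transport-to-boundary`). The steady-state assumption S·v = 0 together
with the box bounds defines the feasible flux space; exchange fluxes are
positive for secretion and negative for uptake.

SBML ingestion accepts Level 2 (kinetic-law `LOWER_BOUND`/`UPPER_BOUND`
parameters, `GENE_ASSOCIATION` notes) and Level 3 with the FBC package;
when both bound encodings are present the FBC parameters win. Species
flagged `boundaryCondition="true"` are outside the balanced system and
are dropped on import, the usual convention in constraint-based analysis.
Subsystems and kinds travel in COBRA-style notes so the package's own
SBML output round-trips exactly; the output is also readable by cobrapy,
which the test suite verifies.

### Model preparation

Whole-cell lipid measurements cannot be assigned to one compartment.
`expandLipidBoundary()` therefore adds a boundary compartment: each
measured lipid present in several compartments gains one boundary
metabolite, a transport reaction from every intracellular instance, and a
sink on the pool; single-compartment lipids get a sink directly. Added
reactions are reversible (±1000) so that measured bounds of either sign
can be imposed later. The pipeline default is expand-then-reduce, so that
the added sinks can unblock lipid pools before blocked reactions are
removed.

Reduction removes *blocked* reactions — flux variability range [0, 0]
within 1e−9, the solver noise floor — then *dead-end* metabolites
(participating in no remaining reaction), iterated to a fixed point. The
FVA used for blocked detection deliberately imposes **no**
objective-optimality constraint: restricting to optimal-biomass flux
states would misclassify reactions that only carry flux away from that
optimum. Reversible reactions are kept as single signed variables; no
direction splitting is needed for FVA over box bounds.

## 2. Expression integration

Per-gene replicate means are classified against the `lower`/`upper`
percentiles of the metabolic-gene distribution (genes appearing in GPRs;
a flag widens this to the full transcriptome). Percentiles use linear
interpolation between order statistics (`quantile()` type 7) — the
convention is recorded in the result for provenance, since percentile
definitions differ across software. Classification is strict: a gene
exactly at a threshold is moderate. Classes propagate through GPRs with
AND = min and OR = max over {−1, 0, +1}, the convention of the original
iMAT formulation; genes missing from the data count as moderate, so an
unmeasured complex partner never pushes a reaction into R_H or R_L, and
reactions with empty GPRs belong to neither set.

## 3. The iMAT program and its analysis

Variables: fluxes v; for i ∈ R_H two binaries y⁺_i, y⁻_i (forward /
reverse activity, at most one set); for i ∈ R_L one binary x_i
(inactivity). The objective maximizes the count of expression-consistent
reactions. The forward-activity implication is
v_i + y⁺_i(v_min,i − ε) ≥ v_min,i. For reverse activity the package uses
v_i + y⁻_i(v_max,i + ε) ≤ v_max,i, i.e. y⁻ = 1 forces v_i ≤ −ε. The
"≥" direction sometimes seen in print cannot encode reverse activity —
substituting y⁻ = 1 there leaves v_i ≥ −ε, which v_i = 0 satisfies, so it
awards activity credit without flux; the package keeps that literal
variant behind `eq5 = "printed"` for comparison, and a test demonstrates
the free-credit artifact on a blocked reaction.

* **ε (activity threshold)**: default 1 flux unit, with ±1000 box bounds
  on otherwise unbounded reactions — the standard iMAT scaling. The
  source analyses do not print their ε; this default is a documented
  assumption, configurable everywhere.
* **Objective-equality tolerance**: 1e−6 absolute. The objective is
  integer-valued, so any tolerance below 0.5 yields identical calls.

**Sensitivity analysis.** iMAT optima are non-unique, so per reaction two
forced MILPs are solved: forced-active (|v_i| ≥ ε as a disjunction via
one auxiliary binary — direction-agnostic) and forced-inactive
(v_i = 0). Calls follow from which forced problems attain the
unconstrained optimum; an infeasible forced problem counts as −∞. All
2n problems are dispatched as one solver batch. **Robustness consensus**
across the 30/70, 33/66 and 40/60 percentile pairs keeps a call only
under determinate unanimity. Pathways whose per-pair activity ratios
spread by more than the differential threshold within a condition are
flagged `threshold_sensitive` rather than dropped, so downstream users
can decide.

**Solver.** Generic LP/MILP solving is delegated to HiGHS via
`scipy.optimize.milp`, driven in batches through a small Python bridge
(`inst/python/milp_backend.py`); no R MILP interface is part of this
environment's package set. HiGHS proves optimality (gap 0 within
integrality tolerance) and is deterministic for a fixed problem, which
makes objectives and calls reproducible; flux vectors of alternative
optima are explicitly *not* part of the contract. The `seed` arguments on
solver entry points are recorded for provenance.

## 4. Metabolite bounds

For concentrations measured in triplicate at 0 h and 5 h,
ub = (c5 + Sd5) − (c0 − Sd0) and lb = (c5 − Sd5) − (c0 + Sd0), so
ub − lb = 2(Sd0 + Sd5) ≥ 0 always. Whether such differences should be
divided by the sampling interval is not fixed by convention; since
exchange fluxes are rates, the package divides by the 5 h interval by
default and offers `rate = FALSE` for the raw-difference reading. Medium
measurements map to exchange reactions, cell measurements to sinks.

After application, a feasibility LP is run. Measurement noise can bracket
a near-zero rate strictly away from zero on a side the network cannot
realize; `on_conflict = "drop"` discards such individually conflicting
bounds with a warning (the pipeline default), while the stricter default
`"error"` reports them and aborts.

## 5. Pathway statistics

Pathway activity is the fraction of subsystem reactions called active
(undetermined is not active; unlabeled reactions pool under
`unassigned`). Between conditions, each threshold pair contributes a 2×2
Fisher table of active vs. not-active counts — undetermined pooled with
inactive, the natural reading when comparing activity states — with
Bonferroni correction by the number of subsystems tested and the
*maximum* corrected p across pairs retained, a conservative choice. The
differential rule is |mean ratio difference| > 10% **and** max corrected
p < 0.05. Differential *reactions* require consensus active in exactly
one condition and inactive in the other. Transport subsystems are flagged
so reports can exclude them from figures, where their extreme ratios
distort scales.

## 6. Enrichment and signatures

GSEA ranks genes by Pearson correlation with the phenotype (binary 0/1
encoding for two-class designs; an ordinal vector can be supplied for
staged phenotypes — the encoding is a documented choice). The weighted
running sum uses hit increments |score|^p normalized over hits (p = 1)
and miss decrements 1/(N − N_hits); ES is the signed extremum. The null
comes from phenotype-label permutation with full re-ranking; NES divides
by the mean |null ES| of matching sign, and the FDR q-value is the
sign-matched null/observed tail ratio of the original GSEA procedure.
"Leading-edge signal" is interpreted as the fraction of the set's
in-list genes at or before the extremum — the term has no published
formula, so this definition is stated rather than assumed. Ranking ties
break by gene id for determinism. Two significance conventions are
reported side by side: FDR ≤ 0.1 with NES > 1.5 and leading-edge signal
> 50% (two-condition designs), and FDR ≤ 0.25 (exploratory cohort
screens).

PLS-DA fits (via mixOmics) use autoscaled genes and 2 components by
default — neither is fixed by the source analyses; both are recorded in
the returned object. VIP_j = sqrt(p Σ_a SS_a w²_ja / Σ_a SS_a) satisfies
Σ VIP² = p exactly (checked to 1e−8 on every fit over the genes entering
the fit; zero-variance genes are excluded and report VIP 0). Signatures
take VIP ≥ 1.5, inclusive.

## 7. The synthetic benchmark and its limits

`generateToyGem()` builds pathway chains sharing one uptake hub, each
ending in its own exchange. Per condition the first and last pathways are
planted active/inactive (swapped between conditions — the differential
ground truth); middle pathways are *moderate*, supplying the mid-stratum
gene mass that keeps all three percentile pairs' thresholds clear of the
planted high and low strata. GPR sizes cycle 1/2/3 deterministically so
stratum proportions (≈¼ low, ½ mid, ¼ high) hold for every seed; all
genes of a reaction share its stratum, so any monotone AND/OR mix
propagates correctly. Planted blocked reactions feed dead-end
metabolites. Feasibility of the planted states is verified by LP before a
model is emitted.

Expression: strata at 6/8/10 on a log-like scale, shared per-gene
baseline jitter (sd 0.15), Gaussian replicate noise at 5% CV, four
replicates per condition (the two-condition microarray design), and a
`flip_fraction` of genes mislabelled per condition. Metabolomics:
triplicates at 0 and 5 h, multiplicative log-normal noise (10% CV
default), baseline 25 concentration units. Two panel choices reflect
assay reality and are deliberate: species with a planted rate of zero are
not measured (no quantifiable change exists for them — including them
plants pure-noise constraints), and the shared uptake hub is excluded
because its net rate aggregates demand from pathways whose planted state
makes no flux claim, so constraining it caps throughput and forces
truth-undefined calls.

Benchmark problem sizes, chosen so the full suite exercises every
contract at desk scale: 50 random instances (≤12 reactions,
|R_H|+|R_L| ≤ 10, smaller sets more frequent) for the
enumeration-oracle comparisons; 20 seeds for end-to-end recovery, GSEA
detection and VIP recovery; 200 phenotype permutations in benchmark GSEA
runs (1000 remains the analysis default). The generic expression panel
plants a 3-SD shift in 20 of 200 genes at four replicates per condition
for enrichment benchmarks; the VIP *recovery* benchmark instead uses 10
samples per class with a 4-SD shift, because at four samples per class
the sampling noise of a per-gene correlation (Fisher z s.e. ≈ 0.45)
spans any fixed VIP cutoff, so "every planted gene above VIP 1.5" is
only a well-posed property at cohort scale — the setting where
discriminant signatures are applied.

What passing does **not** show: real microarray data are not three clean
strata (classification boundaries blur, GPR propagation loses more
information); real GEMs have loops, currency metabolites and promiscuous
GPRs that make undetermined calls far more common; real exometabolomics
has batch effects beyond multiplicative noise; and the hold-out
sign-agreement rates on these fixtures say nothing quantitative about any
particular published dataset.

## 8. Known limitations

* No thermodynamic (loop-law) constraints; cycles among reversible
  internal reactions can carry bounded loop flux and FVA treats them as
  unblocked.
* One MILP backend (HiGHS via scipy); the formulation is exported per
  problem, but no LP-file writer is included.
* The pipeline's stages are R functions with a config list (optionally
  YAML); there is no shell entry point, as the intended interface is the
  R session and scripts.
* GSEA FDR follows the sign-matched pooled-null convention; with very few
  gene sets the q-value is coarse (the nominal p is then the better
  guide).
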