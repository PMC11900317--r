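---
title: "kinasepred: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinasepred: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Protein kinases share a highly conserved ATP-binding site, so a small
molecule active on one kinase is often active on others — and molecules
designed for non-kinase targets frequently hit kinases as off-targets.
`kinasepred` implements a ligand-based workflow for this setting: curate
compound activity tables into a balanced *kinase family* dataset (active
against any kinase vs. presumed-inactive decoys), train fingerprint-based
classifiers, explain individual predictions at atom resolution, screen
compound libraries, and refine calls with per-kinase models that carry
class-imbalance diagnostics.

Everything runs from plain text inputs (SMILES lists, SDF, activity CSV)
and a deterministic synthetic-fixture generator, so the full pipeline is
testable offline.

# The molecular layer

No cheminformatics toolkit is assumed: the package contains its own SMILES
reader, molecular graph, and canonicalization.

* **Parsing.** Organic-subset and bracket atoms, aromatic lowercase forms,
  ring closures, branches, multi-fragment input. Stereochemistry markers
  and isotope labels are parsed and *dropped*: standardization is
  constitution-level (a stated non-goal is stereo-aware canonicalization).
  Valence violations are classed errors, reported as `valence_error`
  rejections by the curation pipeline rather than exceptions.
* **Aromaticity.** A pragmatic Hückel rule on 5- and 6-membered rings
  evaluated on Kekulé bond orders: atoms with an in-ring double bond
  contribute one π electron, heteroatoms with a free lone pair contribute
  two, and a ring is aromatic at π = 6. This makes `C1=CC=CC=C1` and
  `c1ccccc1` identical, covers the azole/azine/fused-benzo chemistry of
  kinase ligands, and deliberately leaves exocyclic tautomer cases
  (2-pyridone) in Kekulé form — a known limitation.
* **Canonical ranks.** Iterative partition refinement over atom invariants
  (element, degree, hydrogen count, charge, aromaticity, ring membership),
  then individualization of the first tied cell guided by an index-free
  partition signature. Atoms with identical signatures are treated as
  symmetry-equivalent. This is not a certified graph-canonization
  algorithm; for chemically sensible graphs it is exact, and the test
  suite asserts invariance over hundreds of random atom reorderings.

# Curation rules

The activity filter keeps records with IC50/Ki/Kd/EC50 at most 10 µM
(10,000 nM) and target-assignment confidence at least 9. Structural
filters keep molecules with all elements in {H, B, C, N, O, F, Si, P, S,
Cl, Se, Br, I}, molecular weight ≤ 800 Da (inclusive), and ≥ 15 heavy
atoms (inclusive). Duplicates are collapsed on the canonical SMILES of the
standardized structure, first occurrence kept.

Vendor "washing"-style structure standardization is replaced by an open,
documented rule set:

1. keep the largest fragment by heavy-atom count (ties: larger molecular
   weight, then lexicographically smaller canonical SMILES);
2. neutralize charges where a proton can be added/removed (charge-separated
   groups such as nitro are left intact);
3. re-ionize at pH 7.4: carboxylic, sulfonic and phosphonic acid hydroxyls
   become anions (*all* equivalent acidic OH groups, so the outcome cannot
   depend on input atom order); aliphatic amines and amidine/guanidine
   imine nitrogens become cations; anilines, amides and aromatic nitrogens
   stay neutral.

Exact vendor outcomes are unknowable; the regression tests freeze *this*
rule table, not any vendor's.

Balanced family datasets take all curated actives plus an equal number of
decoys sampled uniformly without replacement (no property matching — the
sampling is deliberately simple and seeded). Splits are stratified by
label with `|train| = floor(fraction × N)`; stratification is a package
choice (it preserves the designed 50/50 balance in both partitions) even
though the protocol text does not require it.

# Fingerprints

Three binary fingerprints, each carrying **bit → atom provenance** (the
atom set of every environment/subgraph/match that fired a bit), which is
what makes atom-level explanation possible downstream:

* **Morgan (circular), radius 2, 2048 bits.** Invariants: element, heavy
  degree, hydrogen count, charge, aromaticity, ring membership; no
  chirality; binary (not count) bits. Folding is `hash %% 2048`; colliding
  environments all keep their atom sets.
* **Path/subgraph, 2048 bits.** Every connected bond subgraph of 1–7
  bonds (the common default range; configurable), hashed by an
  order-invariant code (atom codes, bond codes with endpoint elements,
  internal degree sequence).
* **881 substructure keys.** The published 881-key dictionary cannot be
  redistributed, so the package defines its own 881-slot table with the
  same sectioning: hierarchic element counts (count-type, no atom
  provenance, excluded from retro-mapping), a ring census (sizes 3–10 by
  aromaticity/heteroatom content and multiplicity), bonded element pairs,
  and ~120 substructure patterns. Undefined slots are reserved and always
  zero. All containment and provenance semantics of a key-type fingerprint
  hold; absolute bit positions are package-specific.

# Models and evaluation

Three algorithms are implemented natively over binary features:

* **Random forest** — CART-style trees on bit splits, per-node feature
  subsampling (`sqrt`, `all`, `log2` of 2048, floored), bootstrap
  resampling, forests average leaf class probabilities. Grid:
  `n_estimators` ∈ {100, 500} × `max_features` ∈ {sqrt, all, log2}.
* **Gaussian naive Bayes** — per-class feature means/variances with
  `var_smoothing` ∈ {1e-9, 1e-8, 1e-7, 1e-6} (grid chosen by the package;
  the protocol names the parameter but not its grid).
* **MLP** — ReLU hidden layers, sigmoid output, Adam, mini-batches of 32,
  early stopping on a 10% validation split (patience 10, max 200 epochs).
  Architecture grid: {100, 200, 1000} neurons × {1, 2} layers, all width
  combinations for 2 layers (12 points). The layer-count bound and the
  optimizer details are package choices.

**Grid search** scores every point with 3-fold stratified CV by mean MCC;
ties resolve to the first point in canonical grid order. **"k-fold CV"**
in this workflow is k independent stratified random 70/30 resplits (that
is what the protocol describes; it is not canonical k-fold partitioning).
Metrics: Precision, Recall, NPV, Specificity, BA = (Recall+Specificity)/2,
and MCC. Any statistic with a zero denominator is *undefined* (`NA`),
propagated into summaries as an exclusion count — never silently zero.
Summaries report mean ± population standard deviation (N, not N−1;
configurable). Display rounding in reports is half-even at 2 d.p.

The family-model decision threshold defaults to 0.5; the per-target
models use the fixed 0.75 rule (probability ≥ 0.75 ⇒ active), and the
boundary is tested exactly.

# Explainability

Kernel SHAP is computed over fingerprint bits with a restriction that cuts
cost on 2048-bit inputs: only the bits *set* in the query molecule are
treated as players; unset bits always take the background's values. Under
this scheme `base_value` is the mean model output over the background,
`model_output` is the mean output with every set bit forced on, and the
local-accuracy identity `base + Σφ = model_output` is enforced exactly as
the equality constraint of the weighted regression (the model's output on
the query fingerprint itself is reported separately as `point_output`).
Coalition budget: `2M + 2048` for `M` set bits; when `2^M − 2` fits the
budget all coalitions are enumerated and the values are the exact Shapley
values (the single-feature indicator tests exploit this). Per-coalition
expectations are averaged over `k` seeded background rows, with `k` set by
an evaluation budget (default 50,000 model calls; the default background
is 100 training molecules sampled with a fixed seed). Averaging matters:
pairing each coalition with a single background row makes atom-level
attributions too noisy to rank motif atoms reliably.

**Retro-mapping** splits each mapped bit's φ equally across its
provenance occurrences, then equally across the atoms of each occurrence;
atom weights are the sums. The scheme conserves φ mass exactly (tested to
1e-9); bits without atom provenance (count-type keys) are skipped and
their total φ reported. The equal-partition choice is the package's
interpretation of binary-representation retro-mapping; proportional
schemes would not conserve mass per occurrence as cleanly. The SVG
renderer shades atoms orange in proportion to positive normalized weight
(blue for negative) and writes a per-atom CSV.

# Target-specific models and screening

Per-target datasets need ≥ 100 compounds; the per-compound label follows
its most potent record for that target (≤ 10 µM ⇒ active). Each model is
a 100-tree RF with balanced class weights, evaluated by 5 stratified
70/30 resplits under the 0.75 rule. The *inactive ratio*
(n_inactive/n_active) flags datasets below 0.25 (strictly) as highly
imbalanced; ensemble reports are produced with and without flagged
models. Panel predictions binarize experimental inhibition at ≥ 50% and
score per-compound success rates as percent agreement.

Screening refuses any library sharing a standardized structure with the
model's training manifest (leak guard). Hit clustering is
sphere-exclusion/leader clustering on Tanimoto distance of Morgan
fingerprints (default cutoff 0.4), hits processed in descending
probability order for deterministic leaders; cluster representatives are
centroids (maximal mean similarity) rather than manual visual
inspection, which is not automatable.

# The synthetic fixtures: what they do and do not establish

`kp_generate_family_fixture()` enumerates substituent × linker × core
products: actives carry a planted 7-azaindole-like bicycle (a classic
hinge-binder chemotype; purely an aesthetic choice — any motif works),
decoys use benzene/naphthalene/piperidine/etc. cores. Every product
passes the curation filters by construction, carries no ionizable group
that standardization would rewrite (so the curation round trip is exact),
and a single fingerprint bit separates the classes at noise 0 (asserted
by a brute-force decision-stump oracle). Label noise flips exactly
`round(noise × N)` seeded labels. The per-target generator draws
activity values log-uniformly (actives in [10, 10⁴] nM, inactives in
(10⁴, 10⁶]), confidence 9, with controllable per-target inactive ratios;
`value_noise` re-draws a fraction of records from the opposite range to
emulate assay noise.

A green test on these fixtures establishes that the pipeline machinery is
correct (labels conserved, separable signal recovered, attributions land
on the planted atoms, imbalance degrades the expected metrics in the
expected direction). It does **not** establish real-world kinase
performance: the fixtures have no SAR, no activity cliffs, no
property-matched decoys, and far less chemical diversity than a
database-scale corpus, so database-scale headline performance is out of
desk-scale reach by design.

The acceptance world for the imbalance analysis — 20 targets, 120 actives
each, requested ratios spanning 0.05–1.5, value noise 0.1, seed 42 — was
fixed before measurement. Noise shifts realized ratios upward, so 3 of 20
targets end up flagged; the filtered-ensemble NPV/Specificity improvement
is required strictly.

# Numerical and degenerate-input choices

* Zero-denominator statistics are `NA`, excluded-with-count in summaries.
* MW boundary inclusive at 800; heavy-atom boundary inclusive at 15;
  inactive-ratio flag strict at < 0.25; activity label inclusive at
  ≤ 10 µM; classification inclusive at probability ≥ threshold.
* Grid-search ties: first point in canonical order. Clustering ties for
  representative: higher probability, then lexicographic id.
* The SHAP regression adds a 1e-10 ridge to guard rank deficiency; the
  equality constraint keeps local accuracy exact regardless.
* All seeded code paths go through one helper that sets and restores
  `.Random.seed`, so library calls never perturb the caller's RNG state.

# Known limitations

* The canonicalizer and aromaticity model are built for drug-like
  chemistry; exotic tautomers, pathological symmetric graphs, and
  organometallics are out of scope (disallowed by curation anyway).
* 881-key bit *positions* are package-defined; cross-toolkit bit-level
  compatibility is not a goal.
* The MLP is a compact native implementation; at database scale a
  dedicated framework would be preferred.
* SHAP values for non-enumerable coalition spaces are estimates; their
  seeds are fixed and their variance is controlled by the evaluation
  budget, but they are not exact Shapley values.
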