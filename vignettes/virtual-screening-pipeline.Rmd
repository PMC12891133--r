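---
title: "Ligand-based virtual screening with fingerprint QSAR models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based virtual screening with fingerprint QSAR models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandscreen)
```

## The problem

Given a set of molecules with known activity against a protein target (here
motivated by FABP5, an intracellular fatty-acid chaperone), ligand-based
virtual screening builds a classifier over molecular fingerprints and uses it
to triage a large compound library down to a short list of predicted actives,
which are then prioritized with structure-based evidence (docking scores and
MM-PBSA binding-energy decompositions supplied as tables). `ligandscreen`
implements this workflow end to end as composable R functions:

1. **Curation** — SMILES standardization, class balancing, stratified 8:2
   train/test splitting.
2. **Featurization** — six physicochemical descriptors; five modeling
   fingerprints plus a 2048-bit clustering fingerprint; Tanimoto similarity.
3. **Chemical-space analysis** — exact t-SNE to 3-D, Ward.D2 hierarchical
   clustering into k = 3 groups, one representative molecule per cluster.
4. **Model selection** — four model families crossed with five fingerprints,
   each tuned on its hyperparameter grid by five-fold cross-validation and
   scored with an eight-metric suite.
5. **Screening and prioritization** — score a library with the selected
   model, then rank predicted hits by binding energy and record
   hydrogen-bond interactions and the docking-box configuration.

Because curated bioactivity sets and vendor libraries cannot be shipped, a
seeded synthetic generator produces structurally meaningful stand-ins for
every input; all tests and the acceptance script run against it.

## The synthetic benchmark

`gen_benchmark_set()` plants a *motif* — by default
`r DEFAULT_MOTIF`, a carboxylic-acid head on an unsaturated chain of at
least eight carbons — in every active, and draws decoys from a built-in
scaffold list (benzenes, pyridines, naphthalenes, furans, thiophenes,
pyrimidines, a pyranose sugar, cyclohexanol, benzamide) with random small
decorations. The motif echoes the fatty-acid chemotype that motivates the
application and gives every fingerprint type a learnable signal; each decoy
is verified against the motif with a SMARTS match and resampled if it
accidentally contains it. Labels can then be flipped independently with a
configurable noise rate. Everything is driven by one integer seed; each
operation derives its own named substream, so the benchmark, the library and
the energy tables are reproducible independently of evaluation order.

The default study conditions used by the tests and the acceptance script are
125 actives + 125 decoys (200 training molecules after the 8:2 split), zero
label noise, and a 100-molecule screening library with 10 planted actives.
These sizes keep the full pipeline deterministic-fast while leaving enough
held-out molecules (50) for stable metric estimates.

What the generator does *not* emulate: real bioactivity data has assay
noise, activity cliffs, scaffold redundancy, and property distributions
(molecular weight 300–500, TPSA 50–150 for actives) that the synthetic set
makes no attempt to match. A perfect held-out AUC here certifies that the
pipeline machinery is correct and leak-free, not that comparable accuracy
would be reached on curated screening data.

## Standardization

`standardize_molecule()` applies, in a fixed order: keep the largest organic
fragment → delete metal atoms → neutralize formal charges → canonicalize
mobile-hydrogen tautomers → drop explicit hydrogens → emit canonical SMILES.
The order is deliberate: neutralizing *after* salt stripping avoids
re-ionized counter-fragments. Decisions worth knowing:

* **Validity gate.** The OpenBabel SMILES reader silently repairs some
  malformed strings, so a syntactic well-formedness check (balanced
  brackets and parentheses, paired ring-bond digits) runs first;
  failures are retained as records with a `parse_error` flag and excluded
  downstream, never dropped silently.
* **Neutralization** uses OpenBabel's `neutralize` operation, which
  protonates/deprotonates only ±1 centers that can bear the change —
  nitro groups and quaternary ammonium survive untouched.
* **Tautomers.** No installed toolkit exposes a canonical-tautomer
  algorithm, so normalization is realized as a standard-InChI round-trip,
  which collapses mobile-hydrogen protomers to one fixed form. This does
  not merge keto–enol pairs; it is documented as a limited normalization.
* The cascade is idempotent (a property test feeds outputs back in), which
  makes re-standardizing merged datasets safe.

## Descriptors and fingerprints

The six descriptors (MolWt, TPSA, NumHDonors, NumHAcceptors, MolLogP, and
MolMR as the molecular-volume proxy) come from OpenBabel and are kept at
full precision internally; rounding is a display concern.

Fingerprint types and mandated lengths:

| type | bits | construction |
|---|---|---|
| `morgan1024` | 1024 | circular, radius 2 (ECFP4-like) |
| `rdkit_path` | 2048 | linear paths of 1–7 bonds |
| `maccs166` | 166 | MACCS keys (OpenBabel; keys occupy bits 1–166) |
| `atompairs1024` | 1024 | atom-type pairs with topological distance |
| `toptorsion1024` | 1024 | 4-atom linear torsion paths |
| `extended2048` | 2048 | path ∪ circular hybrid, used for clustering |

The hashed types are computed on the molecular graph with a fixed
polynomial string hash (base 31, prime modulus below 2^29 so all
intermediates are exact in doubles), making bit positions identical across
platforms and sessions. Fingerprints are always computed on the canonical
SMILES, which is what makes them invariant to the atom ordering of the
input string. Morgan radius 2 was chosen because the 1024-bit circular type
is described as extended-connectivity-like; the 2048-bit clustering type is
realized as a path/circular hybrid and flagged as an approximation of the
original "extended" fingerprint, which came from a different toolkit.
Tanimoto similarity is defined as 1 for two all-zero vectors (a convention
exercised by tests, relevant only for degenerate inputs).

## Chemical-space embedding and clustering

t-SNE runs in exact mode (theta = 0) with dims = 3 and perplexity = 40 by
default, per-point bandwidths calibrated by binary search, early
exaggeration (×12) for the first half of a 600-iteration gradient descent,
momentum 0.5→0.8, learning rate 200, and a seeded Gaussian initialization.
It is implemented in the package because no t-SNE package is available in
the installed stack; on the problem sizes used here (n ≤ a few hundred) the
exact O(n²) gradients are fast and reproducible to the bit under a fixed
seed.

Clustering uses `hclust(method = "ward.D2")` on Euclidean distances of the
*embedded* coordinates (a `cluster_on = "fingerprints"` escape hatch exists
for comparison), cut at k = 3. The representative of each cluster is the
member with the highest mean Tanimoto similarity to its co-members with
self-similarity excluded. Including self-similarity would shift every mean
by the same amount within a cluster of fixed size, so the ranking — and
hence the representative — is unchanged; a test asserts exactly this rank
invariance, which is why the exclusion choice is benign.

## Model grid and evaluation

The four families map to R backends as follows:

* `random_forest` → **ranger**. The printed `criterion` axis
  (gini/entropy) is carried through the grid and recorded in metadata, but
  ranger only implements Gini splitting — the one backend deviation, kept
  visible rather than papered over. `max_features = "auto"` is treated as
  the conventional alias of `"sqrt"`. `max_depth = "none"` maps to
  unlimited depth.
* `svm` → **e1071** (libsvm), RBF kernel; `gamma = "scale"` resolves to
  1/(p·Var(X)) and `"auto"` to 1/p.
* `mlp` → implemented in the package: a dense feed-forward network with
  arbitrary hidden layers, tanh/relu, sgd (momentum 0.9) or adam, logistic
  output and cross-entropy loss. nnet cannot express the grid (two hidden
  layers, relu, adam), hence the in-package implementation. Training stops
  early when the loss improves by less than 1e-4 for 10 consecutive
  epochs, so the grid's `max_iter = 10000` is an upper bound, not a cost.
* `gradient_boosting` → **xgboost** (binary:logistic, 100 rounds, single
  thread); only `max_depth` is tuned, other parameters stay at library
  defaults and are recorded.

Cross-validation folds are stratified by class — the protocol says only
"randomly partitioned", and stratification prevents class-absent folds at
these sample sizes. The selection criterion is mean CV AUC (ties: higher
mean ACC, then first in deterministic grid order), AUC being the headline
comparison metric. Test-set metrics are computed exactly once, after
selection, and are kept distinct from CV metrics in all outputs to avoid
selection leakage.

The metric suite reports SE, SP, ACC, MCC, P, F1, BA and AUC from the
confusion counts; AUC uses the midrank Mann–Whitney statistic. Ratios with
a zero denominator are reported as 0 and flagged; MCC is 0 when any
marginal is zero. All formulas are checked against brute-force oracles
(exhaustive pair counting for AUC, direct hand evaluation for the rest) in
the test suite.

## Screening and prioritization

`screen_library()` applies the selected model at threshold 0.5 (the
threshold is an argument; 0.5 is the probability-calibrated default since
no published cutoff exists). Energy aggregation computes
ΔG_gas = ΔE_vdW + ΔE_ele and ΔG_total = ΔG_gas + ΔG_solv at full precision
with two-decimal (round-half-even) display columns; uncertainties, when
present, are propagated in quadrature into separate `*_sd_prop` columns and
never compared against published ± values, whose provenance is unstated and
inconsistent with standard propagation. Ranking is ascending (most negative
first) with alphabetical tie-breaks. Hydrogen-bond annotations are parsed
into validated (ligand, residue, position) records restricted to the 20
standard residue codes, and the docking-box writer emits the six
`key = value` lines at input precision and round-trips exactly.

## Numerical choices and degenerate inputs

* Random draws all flow from one integer seed through named substreams
  (`with_stream`), so stages are independently reproducible.
* Energy comparisons in tests use a 0.005 kcal/mol tolerance, matching the
  two-decimal precision of published tables.
* Degenerate cases with defined behavior: empty fingerprint vs empty
  fingerprint has Tanimoto 1; singleton clusters represent themselves;
  `k = n` clustering yields singletons; a zero-size library screens to an
  empty hit list.

## Known limitations

* MACCS keys come from OpenBabel and may differ bit-by-bit from other
  toolkits' MACCS implementations; only internal consistency is relied on.
* The tautomer step is an InChI round-trip, not a full canonical-tautomer
  enumeration.
* The random-forest backend cannot switch to entropy splitting.
* Synthetic benchmarks certify machinery, not real-world accuracy (see
  above); published performance figures from curated datasets are treated
  as non-reproducible context, not as targets.
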