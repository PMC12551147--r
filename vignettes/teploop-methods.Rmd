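---
title: "Methods: descriptor-based modelling and iterative design of translation-enhancing tetrapeptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor-based modelling and iterative design of translation-enhancing tetrapeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Arrest peptides such as SecM (FSTPVWISQAQGIRAGP) interact with the ribosome
exit tunnel and stall elongation. Certain N-terminal tetrapeptides placed
immediately after the initiator methionine — the reference example being SKIK
(Ser-Lys-Ile-Lys) — alleviate that stalling and increase downstream reporter
output. The design question is: among the 20^4 = 160,000 possible
tetrapeptides, which are the strongest translation enhancers, given that only
a few hundred can be measured?

`teploop` implements the computational loop for answering it: featurize
peptides, regress measured activity on the features under cross-validation,
score the entire design space, select a diverse batch of candidates for
measurement, retrain, and repeat. A synthetic activity landscape stands in
for cell-free protein synthesis (CFPS) measurements so the whole machinery is
testable end to end.

## Featurization

Each tetrapeptide is represented by 157 named features:

* Four published amino-acid descriptor sets — Z-scale (5 components),
  T-scale (5), ST-scale (8), VHSE-scale (8); 26 numeric components per
  residue. The component tables are bundled as plain-text TSVs under
  `inst/extdata/scales/` with their sources cited in the file headers.
* Each component is evaluated at the five residue positions of the
  translated N-terminus — position 0 is the constant initiator methionine,
  positions 1–4 the variable residues — and as the arithmetic mean over the
  five positions. Naming: `z1_3` is Z-scale component 1 at position 3; the
  unsuffixed `z1` is the sequence average. That yields 26 × 6 = 156
  amino-acid-based features. Position-0 features are constant across
  peptides; they are deliberately retained so the feature count and naming
  match the 157-feature convention (tree ensembles ignore constant columns).
  The sequence average includes the initiator Met; this choice is isolated in
  one code path of `encode_table()` and can be flipped if a four-position
  average is preferred.
* One mRNA-level feature, `energy`: the ensemble free energy of the first 11
  codons of the open reading frame (ATG + the 12-nt randomized region +
  the first six SecM arrest-peptide codons, read from the published library
  primer). For designed peptides the randomized region uses CAI-optimal
  E. coli codons (maximum relative-adaptiveness codon per residue, ties
  broken alphabetically); NNK codons observed by sequencing can be supplied
  through `dna_override` instead.

No feature scaling is applied: both ensemble backends are trees, which are
invariant to monotone feature transforms.

## The ensemble free-energy feature

The `energy` feature is `-RT ln Z`, with `Z` the partition function over all
pseudoknot-free secondary structures of the 33-nt prefix, computed by a
McCaskill-style interval dynamic programme (`partition_function()`). The
built-in energy model is intentionally simple: one free energy per pair type
(defaults G-C −3, A-U −2, G-U −1 kcal/mol), an optional stacking bonus per
directly nested pair (default 0), minimum hairpin loop 3 nt, RT = 0.616
kcal/mol (310 K). The open chain contributes 1, so `Z >= 1` and the energy is
always ≤ 0 kcal/mol.

This is a documented proxy, not a Turner-parameter implementation: the
feature's role in the model is to carry mRNA-structure information
consistently across peptides, and its absolute values are not comparable to
those of full-parameter folding programs. Users who want externally computed
energies can pass them through the `precomputed` backend of
`ensemble_energy()`, which reproduces a supplied (dna, energy) table exactly.
Correctness of the dynamic programme is established against
`brute_force_partition()`, an independent exhaustive enumeration of all valid
pair sets, to 1e-9 relative tolerance on hundreds of short sequences (both
with and without stacking, with and without G-U pairs). Energies are cached
per (DNA, model) key so scoring all 160,000 peptides takes seconds rather
than minutes.

## Regression model

`tep_train(x, y, config)` fits either a random forest (default; the `ranger`
implementation, chosen for single-core speed on full-space prediction) or
gradient-boosted trees (`xgboost`) under k-fold cross-validation (default 5).
Hyperparameters come from a grid — for the forest, features-per-split `mtry`
with default grid {√p, p/3, p/2} rounded; for boosting a small documented
grid over `eta`, `max_depth` and friends — and the candidate with the lowest
pooled out-of-fold RMSE wins (ties: first grid row). The chosen configuration
is refit on all data for full-space prediction and importance ranking.

Reported metrics are Pearson r and RMSE, computed on the concatenated
out-of-fold predictions (per-fold values are also kept). Pooled rather than
fold-averaged metrics were chosen because they are what the pred-vs-obs
"across all folds" panels display and they remain stable with small folds. A
constant response leaves r undefined; the model flags it (`r_defined =
FALSE`) rather than failing, and RMSE is still reported. Feature importance
is impurity-based, normalized to sum to one, ranked with ties broken by
feature name, and always reported for all training features (unused features
get zero).

Everything is reproducible given `config$seed`: fold assignment, tree
growth (single-threaded), and all downstream selection randomness derive
from it.

## Candidate selection

Each round scores all 160,000 peptides and assembles a batch (default 50)
from three strata, after excluding everything already measured:

* `n_top` (default 30) highest-predicted peptides, ties broken
  lexicographically;
* one representative from each of `k_clusters` (default 10) k-means clusters
  computed over the 156 descriptor features (energy excluded) of the
  `pool_size` (default 5000) highest-predicted peptides — the representative
  is the cluster's highest-predicted member not already chosen; k-means uses
  10 restarts, which planted-cluster tests showed is needed to cover
  well-separated clusters reliably;
* `n_random` (default 10) uniform draws from the remaining unseen space.

The stratum sizes are this package's defaults: the original campaign mixed
top-ranked, cross-model and random picks in varying (and partly
inconsistent) counts, so exact stratum sizes are a free choice here. The
"pool of 5000" is interpreted as the top 5000 predictions after exclusions.

`run_campaign()` iterates train → score → select → measure → augment. With
batch sizes `c(50, 40)` the training table grows 158 → 208 → 248, matching
the accounting of the three-round experimental campaign.

## The synthetic landscape

`make_landscape()` builds a hidden ground truth over the design space:

1. a sparse linear score over the 156 descriptor features — by default 5% of
   the features (8 of 156) carry Gaussian weights; background weights avoid
   position-4-specific features so that the planted positional effect below
   is the only position-4 signal and its recovery is attributable;
2. the score is standardized and soft-saturated at 3 SD
   (`s / sqrt(1 + (s/3)^2)`), giving diminishing returns so no single
   descriptor direction can dominate the extreme tail;
3. an additive bonus (default +0.6 score units) for aspartate at position 4,
   the enrichment reported among strong enhancers in the screen;
4. an exponential transform `a = exp(0.5 * score)` produces the
   right-skewed activity distribution in which highly active peptides are
   rare;
5. the reference peptide SKIK is pinned at the 0.9 quantile of the score and
   activities are normalized to it, so 90% of random tetrapeptides fall
   below SKIK = 1 and the best peptides reach roughly twice the reference —
   comparable to the measured in vitro range.

Measurements draw `replicates` (default 3) Gaussian replicates with SD 0.1
relative units per peptide and report their mean and SD, mimicking
triplicate fluorescence assays normalized to SKIK.

What the landscape does *not* emulate: real CFPS data have correlated,
heteroscedastic errors, batch effects, and a ground truth that is certainly
not a sparse linear function of these descriptors. Because the synthetic
truth lives in the model's own feature space, cross-validated correlations
on it run high (≈0.9 in round 1, ≈0.99 by round 3 at the default problem
sizes) — much higher than the 0.5–0.66 achieved on real measurements.
Passing the campaign tests therefore demonstrates that the loop's machinery
(training, scoring, exclusion-aware diverse selection, retraining) works and
that planted signals are recovered; it says nothing quantitative about
predictive accuracy on laboratory data.

## NGS extraction

Negative-clone reads (simulated here as 81-bp single-end reads of the 161-bp
amplicon) are processed by flank-anchored extraction: find the upstream
anchor `CATATG` (the end of the forward primer region, terminating in the
start codon), take the following 12 nt, and require the downstream anchor
`TTCAGCACG` immediately after. Because the reads are half the amplicon
length, anchoring uses these short internal flanks rather than full primers.
Failures are statuses (`flank_missing`, `bad_length`, `ambiguous_base`,
`contains_stop`), never errors, and tallies conserve reads: recovered counts
plus failures equal the input. Matching is exact by default with an optional
one-mismatch mode; no quality filtering is applied by default. Whether the
original analysis deduplicated reads per clone is unstated; `tally_peptides()`
counts raw reads.

## Activity tables

Fluorescence tables are normalized by dividing by the single reference (SKIK)
record, which then equals 1 exactly; normalization is idempotent. Duplicate
handling averages records with identical *sequences* (a composition-level
mode exists behind a flag; sequence-level is the default because positional
logos would be destroyed by anagram pooling). Positive classification is
strict: a record is positive only if its relative intensity exceeds 1;
equality counts as negative ("surpassing" the reference read strictly).
Worked example kept as a test: raw intensities 16 (no peptide) and 86 (SKIK)
normalize to 16/86 ≈ 0.186 and 1.

## Numerical and design choices

* Enumeration and all tie-breaks are lexicographic over the one-letter
  amino-acid alphabet; CAI ties break alphabetically by codon. This makes
  every ranking deterministic.
* Partition-function equivalence is asserted to 1e-9 relative tolerance;
  the dynamic programme and the enumeration oracle share only the energy
  definition, not code.
* One global seed fans out to per-module seeds through a documented integer
  derivation kept below 2^31.
* Degenerate inputs are first-class: empty peptide sets encode to 0 x 157
  matrices; constant responses train with an explicit undefined-r flag; a
  zero-variance property gives a flagged degenerate regression; empty read
  sets tally to empty counts.
* The workflow surface is functions plus configuration files
  (`validate_config()`, `run_demo()`), not a shell executable: the package's
  users drive it from R.

## Problem sizes used by the tests and the acceptance script

The bundled checks run the campaign at the package's simulation scale:
random-forest `num.trees = 200` with fixed `mtry = 52` (p/3) for the
20-replicate campaign re-runs, versus the fitting default of 1000 trees plus
a 3-point `mtry` grid for single analyses. Campaign replicates use the full
160,000-peptide space, 158-point initial sets (157 random peptides + SKIK),
and batches of 50 then 40. The oracle-equivalence suite uses 200 random
sequences of length 5–14; the NGS round trip uses a 50-peptide pool and
10,000 error-free reads. The acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recomputes all headline quantities from scratch at these sizes and finishes
in under ten minutes on one core.

## Known limitations

* The bundled descriptor tables are transcriptions of the published scale
  sets; the file headers cite the sources and the values should be checked
  against the original tables before scientific use. All packaged checks
  depend only on table structure, not on individual values.
* The codon-usage table is an approximate E. coli K-12 frequency table; only
  the per-amino-acid ranking (the argmax codon) affects reverse translation.
* The built-in energy model is a proxy; absolute ensemble energies from
  full nearest-neighbour parameter sets differ. The precomputed backend
  exists for exactly that reason.
* The synthetic campaign's high correlations reflect the landscape's
  learnability, not expected real-data performance (see above).
* Whether the original work computed the energy feature from CAI-optimal or
  observed NNK codons for its first-round training set is unknown; the
  default here is CAI-optimal with an explicit override.
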