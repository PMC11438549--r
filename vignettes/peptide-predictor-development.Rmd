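---
title: "Developing peptide bioactivity predictors with homology-aware evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing peptide bioactivity predictors with homology-aware evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peptideml` automates the development life-cycle of binary peptide
bioactivity predictors: assembling a labeled dataset from known positives,
partitioning it so that evaluation measures generalization rather than
memorization, representing peptides as fixed-length vectors, optimizing and
ensembling classical ML classifiers, and reporting reproducible metrics.
This vignette explains the model behind each stage, the tunable parameters
and their defaults, and the design decisions taken where more than one
reasonable choice existed.

## The problem

Bioactive peptides are short amino-acid chains (3-50 residues) with
functions such as antibacterial or antihypertensive activity. Predicting
bioactivity from sequence is a binary classification task, but two dataset
decisions dominate the outcome more than any modelling choice:

1. **Where negatives come from.** Random protein fragments are easy to
   tell apart from bioactive peptides for confounded reasons (length,
   composition), inflating apparent performance.
2. **How train and test are split.** Peptide datasets are clustered into
   homologous families; a random split places near-duplicates on both
   sides of the boundary, so the test set partially measures memorization.

`peptideml` addresses the first with bioactivity-aware negative sampling
and the second with a partitioning algorithm that is leakage-free by
construction.

## Negative sampling

Negatives are drawn from a database of peptides tagged with *other*
bioactivities — peptides that are plausible, real molecules rather than
random strings. Two safeguards apply:

* **Exclusion**: all tags that may overlap with the target activity are
  excluded with an any-match rule (a peptide that is both antibacterial
  and antioxidant is removed when either tag is excluded), limiting false
  negatives.
* **Length matching**: a histogram of the positives' lengths is built with
  bin width 5 residues, on half-open bins `[lower, upper)` aligned to
  multiples of the width (a convention-free choice the package fixes so
  binning is reproducible). Each bin is filled with an equal count of
  database peptides of matching length, drawn uniformly without
  replacement. A bin's shortfall carries to the next bin in ascending
  length order — the literal reading of "next" — continuing past the last
  histogram bin if the database has longer peptides; any residual deficit
  is backfilled from the nearest preceding bins (configurable off) and
  reported explicitly, never silently.

The negatives-to-positives ratio defaults to 1:1 and is configurable.
Draws within a bin are uniform; whether stratifying them by tag would be
preferable is unresolved, and uniformity is the simplest defensible
choice.

## The sequence-identity criterion

Two peptides are *similar* when the fraction of identical aligned residue
pairs in their optimal local alignment, divided by the **longer**
sequence's length, strictly exceeds 0.30. Alignments are Smith-Waterman
with affine gaps (BLOSUM62, gap open 10, extend 1 — i.e. a gap of length
L costs 10 + L). These alignment parameters are declared package
defaults: the identity criterion itself (matches over longest length,
strict 30%) is the load-bearing definition, and identity counts exact
matches only, never positive-scoring substitutions. When several optimal
alignments exist, the tie is broken toward the maximum match count, making
the identity value deterministic.

A k-mer prefilter (k = 3, at least 1 shared k-mer) restricts which pairs
are aligned when building the similarity graph. It is an approximation of
the prefilters used by large-scale search tools, not a clone, and it can
miss pairs whose identity comes from scattered single-residue matches with
no three consecutive identities. For desk-scale datasets the exhaustive
mode (`use_prefilter = FALSE`) is cheap — the aligner is compiled code and
peptides are short — and the package uses it wherever completeness of the
graph is the point, as in the leakage guarantees below.

## Homology-based partitioning

The similarity graph (peptides as nodes, edges where identity > 30%) is
clustered with the connected-components algorithm. Whole clusters are then
transferred to the test set in ascending size order until the test set
first reaches the target fraction (default 20%). Two properties follow:

* **Zero leakage.** No cluster straddles the boundary and distinct
  components share no edge, so no training peptide has a similar test
  peptide: the interdependence statistic (fraction of training peptides
  with at least one similar test peptide) is exactly 0, for every graph
  and every valid target.
* **Diverse, hard test sets.** Small clusters are the most unusual
  sequences in the dataset; transferring smallest-first packs many
  distinct clusters into the test set, emulating prediction on novel
  sequences.

Design details the algorithm fixes: ties among equal-size clusters are
broken by a seeded shuffle and then by lowest member id (determinism under
a seed); the stop rule is "first crossing", so the test set may overshoot
the target by at most the last transferred cluster minus one, and the
overshoot is recorded in the split metadata; if one cluster is so large
that the remaining clusters cannot fill the test target, no valid split
exists at this threshold and the function says so rather than returning a
degenerate split. Class balance is *not* enforced: clusters carry whole
families, and when the smallest clusters all belong to one class the test
set can end single-class — this is reported as a degenerate-evaluation
warning, not corrected, because rebalancing would reintroduce leakage.

Cross-validation folds over the training set are random-stratified over
peptides (each class dealt round-robin after a seeded shuffle, so per-fold
class counts are within one peptide of proportionality). Folding is *not*
homology-aware; within-training leakage across folds is a known,
accepted channel — folds guide hyperparameter selection only, while the
final claim rests on the homology-partitioned test set.

## Representations

All backends share one contract: a backend maps a sequence to an n x e
per-residue matrix, and the peptide vector is the column mean
r = (1/n) sum_i M_i. Mean pooling applied to the one-hot baseline
(e = 20) yields exactly the amino-acid composition vector, which makes the
baseline interpretable and the pooling rule uniform across backends.

Pretrained protein language models slot in behind the same interface, but
the package deliberately ships no model weights: per-peptide embeddings
computed elsewhere are imported as TSV (`backend_precomputed()`), and a
deterministic mock backend (`backend_mock()`) stands in during testing. The
mock hashes each residue's 3-residue context window into a seeded
pseudo-random vector (e = 32) using an internal generator that never
touches the session RNG; it is position-sensitive and reproducible but
carries no biological information — it tests the plumbing, not the
biology. Embeddings are cached by backend name and sequence, and a cache
hit is bit-identical to a cold computation.

## Physico-chemical descriptors

For dataset diagnostics the package computes, per peptide: aliphatic index
(100 (x_A + 2.9 x_V + 3.9 (x_I + x_L)) over mole fractions); Boman
interaction index (negated mean residue transfer free energy,
water-to-cyclohexane scale; proline has no measured value in that scale
and contributes 0, a documented convention); net charge at pH 7 by
Henderson-Hasselbalch over the EMBOSS pKa set including both termini;
isoelectric point by bisection on the monotone charge-pH curve to
|charge| < 1e-4; and the hydrophobic moment at the ideal helix angle of
100 degrees on the Eisenberg consensus scale. Scales ship as CSV data
files, not code, so alternatives can be substituted. Distribution
comparisons between datasets report aligned histograms plus the
Wasserstein-1 distance computed exactly from the empirical CDFs.

## Optimized ML ensemble

Three algorithm families are tuned independently: k-nearest neighbours
(probability = neighbour class fraction, optionally inverse-distance
weighted — stated explicitly because ensemble averaging needs calibrated
probabilities from every member), a leaf-wise gradient-boosted tree
classifier, and a probability random forest. Default search spaces: KNN
neighbours 1-30, weights uniform/distance; boosting rounds 50-500,
learning rate 1e-3 to 0.3 (log), leaves 8-128, minimum child weight 2-50;
forest trees 50-500, depth 2-32, minimum leaf size 1-10. The trial budget
defaults to 100 per algorithm and is configurable.

The objective of a trial is the mean over the k cross-validation folds of
the Matthews correlation coefficient on the held-out fold, training on the
remaining folds. The default optimizer is sequential model-based: after a
random warm-up (a quarter of the budget, at least 5), candidates are
scored by a random-forest surrogate fitted to completed trials, with an
epsilon-random exploration step; a pure seeded random search is available
so results never depend on optimizer internals. Every trial's
configuration and score is recorded in a trace, and the whole search is
reproducible from its seed.

After optimization, each algorithm is fitted once per fold on the
remaining folds at its best configuration, giving algorithms x folds
members (30 under the defaults). The ensemble score is the unweighted mean
of member probabilities — a convex combination, so always inside the
member range — and the reported uncertainty of a prediction is the
standard deviation of the member scores. The uncertainty definition is a
declared package convention: member dispersion is a natural spread measure
for an averaging ensemble, but it is not a calibrated probability
interval.

## Evaluation

A peptide is called positive only when its score strictly exceeds 0.5; a
score exactly at the threshold is negative. The headline metric is MCC,
with 0 returned by the standard convention whenever a confusion-matrix
marginal is zero; accuracy, precision, recall, specificity and AUROC are
reported as secondary metrics, and AUROC never enters the optimization
objective. Evaluation refuses — as an error, not a warning — any test
peptide whose id appears in the ensemble's recorded training set, and the
report embeds the interdependence of the actual split so a reader can see
whether the estimate is homology-corrected.

## The synthetic-data generator

Every stage is testable without downloads through a generator that
emulates the cluster structure of real datasets: each family grows from a
random seed sequence by per-residue substitution at a set rate
(substitutions only by default, keeping within-family identity
analytically boundable; indels are available for alignment stress tests).
Family-level labels and a ground-truth family map support partitioning
tests; a tagged random-peptide database stands in for the curated
bioactivity collection; and a learnable signal is injected by inserting a
motif into a chosen fraction of positives. The motif can be inserted
contiguously or scattered residue-by-residue: scattering produces the same
composition shift — visible to mean-pooled representations — without
creating a local-alignment anchor, so signal strength and homology
structure can be varied independently.

What the generator does *not* emulate: real amino-acid usage biases,
secondary-structure constraints, families related by indels and domain
shuffling, and database tag correlations. Passing tests therefore
demonstrate the pipeline's structural guarantees and its ability to
recover a known signal, not field performance on real bioactivity data.

## Study conditions used by the test suite

The package's checks run at sizes chosen to exercise every stage
meaningfully on one CPU: the zero-leakage property is asserted over 50
randomized family datasets (5-14 families of 3-9 members, substitution
rates 0-0.25) against exhaustively built graphs; prefilter/exhaustive
graph equivalence over 30 datasets of at most 50 peptides at substitution
rate 0.05 with seed lengths 18-35, conditions under which homologs retain
shared 3-mers and the exact-k-mer prefilter is lossless; MCC is checked
against the Pearson correlation of the underlying 0/1 vectors on 1000
random confusion tables; and signal recovery uses 200 peptides (100 per
class), the one-hot backend, a trial budget of 10 per algorithm, 10
folds, and 5 seeds per signal fraction (0, 0.5, 1), asserting chance-level
MCC without signal and monotone mean MCC in the injected fraction. For
the signal-recovery experiment the 200 peptides are independent singleton
sequences rather than families: labels are then unrelated to ancestry, so
the no-signal condition is a true permutation null, and the homology
partition on singletons cannot leak.

## Known limitations

* The gradient-boosting member uses leaf-wise boosted trees with a
  LightGBM-style parameter space; other boosting implementations would
  slot behind the same algorithm interface.
* The exact-k-mer prefilter under-collects heavily diverged homolog pairs;
  use the exhaustive mode when the graph must be complete.
* CV folds are not homology-aware (by design, see above).
* Physico-chemical scales are single published choices; descriptor values
  shift with the scale and pKa set selected.
* The mock embedding backend validates the representation contract only;
  conclusions about real protein language models require imported real
  embeddings.

```{r example}
library(peptideml)

# A synthetic development run, end to end:
fam <- generate_families(10, 10, mutation_rate = 0.1, seed = 1)
fam <- inject_label_signal(fam, "WWKWW", fraction = 1, scatter = TRUE,
                           seed = 2)
db <- generate_tagged_db(3000, seed = 3)
build <- build_model(fam[fam$label == 1, ], db = db,
                     excluded_tags = "antibacterial",
                     budget = 10, seed = 4)
glance(build)
```
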