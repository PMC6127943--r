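---
title: "Screening drug-disease combinations with knowledge-graph path features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drug-disease combinations with knowledge-graph path features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

A drug is represented by the set of proteins it targets, a disease by the
set of proteins its associated genes code for. Working at the protein level
keeps the model mechanistically interpretable: if a drug is efficacious, its
targets should relate to the disease proteins through concrete molecular
relationships. Those relationships live in a protein-level knowledge graph:
subject-predicate-object triples (e.g. *OPRM1 - forms protein complex with -
GNAT2*), each attested by one or more provenance sources (databases,
literature-mining systems). The classification unit is a **combination** — a
drug-target set paired with a disease-protein set — labelled positive
(known indication) or negative (random non-indicated pairing).

`kgscreen` asks the question: over and above the mere *existence* of paths
between the two sets, do the *predicate types* and *provenance sources* on
those paths carry information about efficacy? It answers it by building
binary path-label features, classifying with random forests under repeated
balanced cross-validation, and benchmarking against a purely topological
network-proximity score.

## Path scenarios

Paths between a drug-target set DT and a disease-protein set DP are
restricted to length at most two — one intermediate protein (IP) — which is
known to cover the large majority of connected pairs while keeping the
feature space interpretable. Three scenarios are distinguished:

1. **Overlap** — a protein is in both DT and DP; it may additionally carry a
   self-relationship (e.g. homodimerization), though many overlapping
   proteins have none.
2. **Direct** — a triple joins a drug target and a distinct disease protein.
3. **Indirect** — a two-step path through one IP, whose steps (DT-IP and
   IP-DP) are featurized separately because the biology of "drug target
   regulates intermediate" differs from "intermediate is associated with
   disease protein".

Connectivity is treated as **undirected**: an edge is the set of all triples
between an unordered protein pair, whichever way they were written. Many
protein-protein predicates are inherently symmetric, and nothing in the
feature semantics depends on orientation; storing the original orientation
but matching both ways avoids silently losing half the paths. The
intermediate of an indirect path may itself be a member of DT or DP (only
the two endpoints of that specific path are excluded): excluding set members
as intermediates would systematically drop paths for large sets, and there
is no mechanistic reason to do so.

## Feature spaces

All features are **presence/absence bits**, not counts — a deliberately
coarse representation that is robust to the wildly varying edge multiplicity
of curated versus text-mined sources. For each of four triple slots (SELF:
self-relationships of overlapping proteins; DIRECT; DTIP; IPDP) there is one
bit per predicate type and one per provenance source, set when the label
occurs on at least one triple of that slot among the combination's paths;
plus a single overlap flag. With *P* predicate types and *S* sources the
full space has `1 + 4 (P + S)` bits — 281 at the reference scale of 45
predicates and 25 sources. Variants isolate the information sources:

| variant         | contents                                   | purpose |
|-----------------|--------------------------------------------|---------|
| `baseline`      | 3 co-occurrence flags                      | path existence only |
| `predicate`     | overlap flag + predicate bits              | value of predicates |
| `provenance`    | overlap flag + provenance bits             | value of provenance |
| `full`          | overlap flag + both                        | the complete method |
| `indirect_only` | DTIP/IPDP bits only                        | performance without proximity |

The feature space is derived from the graph's full vocabularies, not from
training folds: vocabulary derivation is label-free, so no leakage is
possible, and columns stay identical across folds and repeats.

Leave-one-source-out ablation (`restrict_to_sources()`) removes what only
the excluded source supports: its provenance columns, every triple attested
*solely* by it, and any predicate column left without a supporting triple
graph-wide. Triples the source shares with others survive, so redundantly
attested knowledge is retained — the ablation measures the source's unique
contribution. Removal is triple-level rather than column-level because a
predicate column may be supported by many sources at once; the implemented
semantics equal re-running the whole pipeline on a graph with the
sole-source triples deleted, and the test suite asserts exactly that
equivalence. The function takes the combination list (not pre-computed
vectors) because the surviving columns must be re-extracted from the reduced
graph.

## Classification protocol

Random forests (500 trees, probability forests, impurity importance; the
`ranger` backend) are trained on all positive combinations plus an
equally-sized random sample of negatives. Performance is the mean and
standard deviation over repeated stratified 10-fold cross-validation
(default 100 repeats); AUC and precision-recall AUC are computed per repeat
from that repeat's pooled out-of-fold scores. Design choices where the
protocol was genuinely open:

* **A fresh negative sample per repeat** (default): the reported sd then
  reflects negative-sampling variability as well as fold variability.
  `cv_config(resample_negatives = FALSE)` freezes the first sample instead.
* **Stratified folds**: prevents single-class folds at small n; a
  degenerate split is re-dealt once with an offset seed and logged.
* **Importance** is averaged over every forest of the run and normalized by
  its maximum, so the top feature scores 1.
* **AUC** is computed by the rank (Mann-Whitney) statistic with midrank tie
  handling (identical to the trapezoidal ROC area; cross-checked against
  `pROC` in the tests). **AUPR** is average precision with tied scores
  collapsed into single thresholds, for the positive class.
* The **class-ratio experiment** enlarges only the training folds with
  extra negatives; held-out folds stay balanced 1:1 so AUCs remain
  comparable across ratios, and ratio 1 reproduces the plain protocol
  bit-for-bit.
* **Stratification by drug-target count** (1, 2, >2) re-scores each
  repeat's out-of-fold predictions within the stratum; repeats where a
  stratum lacks both classes are skipped and logged.

Everything derives from one master seed: repeat *r* seeds fold assignment
and negative sampling with `seed + r`, and each forest gets its own derived
seed, so the entire experiment matrix is bit-reproducible
(`experiment_json()` serializes it canonically to prove it).

## The proximity benchmark

The topological baseline scores a combination by the mean over drug targets
of the hop distance to the closest disease protein, standardized against a
null of `n_random` (default 1000) random set pairs matched in size and
degree: proteins are grouped into degree bins grown over adjacent degree
values until each holds at least 100 proteins (reduced with a warning on
small graphs), and each member is replaced by a random protein from its
bin, distinct within the drawn set. The score is `-z`, so higher means
closer than expected. Drug targets with no finite distance are excluded
from the mean rather than assigned a magic constant (a finite penalty is
available via `unreachable_penalty` for sensitivity analysis); combinations
with no finite distance at all are ranked below every connected one.

## What the synthetic generator emulates — and what it does not

The commercial graph the method was developed on is not redistributable, so
the generator reproduces its *statistical shape*: a heavy-tailed degree
distribution (Pareto-tail fitness model; configurable to uniform), edges
carrying 1-3 predicates each attested by 1-3 sources with Zipf-like label
frequencies, vocabularies of 45 predicate types and 25 sources, drug-target
sets of median size 2 and disease-protein sets of median size about 5 with
long right tails (capped at the published maxima of 51 and 273). The default
benchmark uses 1000 proteins with 4 expected edges per protein and 100
positive / 300 negative combinations — large enough for stable estimates,
small enough that the full experiment matrix runs in minutes on one core.

Class signal is planted under a deliberately strict null: positives and
negatives get the *same* number and scenario mix of planted paths (default
3 per combination; 10% overlap / 40% direct / 50% indirect), so
co-occurrence features are uninformative by construction, and only the
labels differ — planted triples of positives carry designated signal
predicates/sources with probability `effect` (default 0.8; separable into
`effect_predicate` and `effect_provenance`), background labels otherwise.
Background edges never use signal labels. The `truth` record lists exactly
which feature columns can carry signal. Setting
`fixed_plant_source` stamps every planted triple of both classes with one
source, concentrating all planted structure there — the construction used
to validate ablation sensitivity.

What passing tests on this generator do **not** show about real data: real
predicate/provenance label distributions are correlated with topology and
with each other (here they are independent given the planted/background
split); real signal is far weaker and entangled with co-occurrence (here
the separation is nearly clean, which is why synthetic AUCs approach 100%
rather than the 70-80% regime of real reference sets); and real negatives
are unverified random pairings that contain undiscovered positives. The
synthetic benchmark validates *correctness and calibration* of the
machinery, not expected field performance. One consequence worth knowing:
with a few hundred combinations on one graph, accidental associations
between graph structure and labels give signal-free AUCs a graph-level
spread of several points around 50% (repeats share the graph, so they
cannot average this away); calibration statements therefore always average
over independently generated graphs.

## Numerical and degenerate-input conventions

Duplicate (subject, predicate, object) records merge their provenance sets;
merging never shrinks a set. Proteins named in a reference set but absent
from the graph are kept in their sets (they simply contribute no paths) and
flagged in a load report — combinations are only dropped from analyses by
the explicit qualifying-path test. Feature ordering is deterministic (slot,
kind, lexicographic value), importance ties break by feature order, and a
proximity null with zero standard deviation yields an undefined z that is
flagged rather than silently zeroed.

## Problem sizes used by the shipped checks

The test suite verifies path extraction and featurization exactly against
brute-force enumeration on graphs of up to 50 nodes (100+ random graphs),
proximity against Floyd-Warshall and an exhaustive null enumeration on a
12-node graph, and the statistical properties (null calibration, variant
ordering, ablation sensitivity, determinism) on 300-500-protein graphs with
100-200 combinations, 5-10 repeats and 10 seeds. The acceptance script runs
the default 1000-protein benchmark with 25 repeats and 250 proximity draws
per combination. These sizes were chosen so a complete run takes minutes on
a single core while keeping every standard deviation it reports meaningful.

## Known limitations

Path length is capped at two steps; diseases whose proteins sit farther
from any drug target are invisible to the features (the qualifying-path
report quantifies this). Features ignore edge multiplicity and direction.
The negative-sampling scheme assumes unlabelled pairings are negative. The
proximity benchmark implements only the closest-distance variant with a
degree-binned null; centre/kernel/separation variants are out of scope.
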