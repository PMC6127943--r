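# kgscreen

Drug efficacy screening from a protein-level knowledge graph, using the
**predicate types** and **provenance sources** of the paths between a drug's
target proteins and a disease's proteins as machine-learning features.

## The problem and the method

A drug is represented by its set of target proteins (DT), a disease by its
set of disease proteins (DP). A knowledge graph stores
subject-predicate-object triples between proteins, each attested by one or
more provenance sources. Most graph-based screening methods only use
topology — how *close* DT is to DP. `kgscreen` tests and exploits the
information in *what kind* of relationships connect the sets and *who
asserts them*:

1. **Path extraction.** All paths of length ≤ 2 between DT and DP are
   enumerated in three scenarios: a shared protein (optionally with a
   self-relationship such as homodimerization), a direct triple, or a
   two-step path through one intermediate protein (IP), whose steps DT-IP
   and IP-DP are kept separate. Matching ignores triple orientation.
2. **Featurization.** For each triple slot (SELF, DIRECT, DTIP, IPDP), one
   presence/absence bit per predicate type and per provenance source —
   `1 + 4(P + S)` bits for `P` predicates and `S` sources (281 at the
   reference scale of 45 and 25) — plus reduced variants (`baseline`
   co-occurrence flags only, `predicate` only, `provenance` only,
   `indirect_only`).
3. **Classification.** Random forests (500 trees) on all positives plus an
   equal random negative sample, scored by ROC AUC and PR AUC over repeated
   stratified 10-fold cross-validation, with normalized impurity feature
   importances, leave-one-source-out ablation, stratification by number of
   drug targets, and a training-class-ratio experiment.
4. **Benchmark.** The network-proximity score: mean closest hop distance
   from drug targets to disease proteins, z-scored against `n_random`
   degree-matched random set pairs (degree bins of ≥ 100 proteins);
   `-z` is the efficacy score.

Because the commercial knowledge graph the method targets is not
redistributable, the package ships a **synthetic generator** that emulates
its statistical shape (heavy-tailed degrees, multi-predicate multi-source
edges, realistic set-size distributions) and plants class signal in
predicate/provenance labels while keeping path co-occurrence identical
between classes — so the claim "labels carry signal beyond topology" is
testable end to end.

## Worked example

```r
library(kgscreen)

cfg <- synth_config(n_proteins = 300, n_pos = 50, n_neg = 150, seed = 42)
g <- generate_graph(cfg)
g
#> <kg_graph> 300 proteins, 1763 triples, 45 predicate types, 25 sources

b <- generate_reference(g, cfg)   # plants signal, default effect 0.8
spec <- build_feature_space(b$graph, "full")
nrow(spec)
#> [1] 281

mat <- extract_feature_matrix(b$combos, b$graph, spec)
res <- run_repeated_cv(mat, combo_labels(b$combos),
                       cv_config(n_repeats = 10, seed = 7))
res
#> <kg_cv_result> 10 repeats x 10 folds: AUC 96.4% (1.1%), AUPR 95.6% (1.9%)

rank_feature_importance(res, 5)[, c("rank", "id", "importance")]
#>   rank                      id importance
#> 1    1   IPDP:provenance:SRC02  1.0000000
#> 2    2 DIRECT:provenance:SRC01  0.8144024
#> 3    3   IPDP:predicate:pred02  0.7593234
#> 4    4 DIRECT:provenance:SRC02  0.7568659
#> 5    5   DTIP:predicate:pred03  0.7336590

sc <- proximity_score_combos(b$graph, b$combos, n_random = 200, seed = 7)
100 * kgscreen:::.auc(sc$label, sc$score)
#> [1] 48.0
```

Reading the numbers: the forest recovers the planted signal almost
perfectly (AUC 96.4% against the all-zero-information chance level of 50%),
and every top-ranked feature is one of the planted signal labels
(`pred01-pred03`, `SRC01`/`SRC02`) in a path slot the generator planted
into — the `truth` record in `b$truth` lists them. The proximity benchmark
sits at chance (48.0%) *by construction*: positives and negatives receive
identical planted path structure, so topology alone cannot separate them.
On real reference sets, where topology does differ between classes,
proximity lands in the mid-60s while the full feature set reaches the
mid-70s to low-80s.

File-based workflows use `read_triples()` / `read_reference_set()` (4-column
TSV dialects documented on those help pages), and
`inst/scripts/kgscreen.R` exposes `simulate`, `cv`, `proximity`, `ablate`
and `stratify` subcommands for shell use.

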