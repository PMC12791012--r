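# igpair

Antibody heavy–light chain pairing analysis in R.

B cell receptors and antibodies are heterodimers of a heavy (H) and a
light (L) chain; whether a given VH and VL form a stable pair is decided
at the VH–VL interface, dominated by the CDRH3 and CDRL3 loops. Paired
single-cell sequencing observes *cognate* pairs (an H and an L sharing a
cell barcode) but never the incompatible pairs that B cell development
eliminates — so learning pairing preference is a positive/pseudo-negative
classification problem. `igpair` is for immunoinformaticians and antibody
engineers who want that entire workflow in one place:

- **AIRR ingestion** — read AIRR-C rearrangement TSVs, assemble per-cell
  H–L pairs (`read_airr()`, `assemble_pairs()`), with lossless flat pair
  TSVs (`write_pairs()`/`read_pairs()`).
- **Curation** — balanced pseudo-negatives by CDRL3-length-matched
  light-chain exchange with duplicate rejection and a 250-trial drop rule
  (`make_pseudo_negatives()`); greedy CD-HIT-style clustering of
  concatenated CDR3s at 90% identity (`cluster_pairs()`); cluster-disjoint
  train/test and K-fold splits that prevent clonotype leakage
  (`split_by_cluster()`); equal per-source sampling (`balance_sample()`).
- **Models** — one `pair_scorer` contract (score in [0, 1] = softmax
  probability that the pair is cognate) over: ridge-logistic and
  boosted-tree baselines on one-hot V/J gene usage, a two-stream CNN on
  one-hot CDR3 matrices, and a plug-in wrapper for external scorers such
  as fine-tuned protein language models (`load_external_scorer()`).
  κ/λ-specific models are trained per light-chain locus and applied by
  routing (`train_type_specific()`, `route_and_score()`).
- **Evaluation** — accuracy, precision, recall, F1, Matthews correlation,
  Mann–Whitney AUC, and a cross-validation harness in which every fold
  model faces one common withheld test partition (`metrics()`,
  `cross_validate()`).
- **Applications** — maturation annotation by isotype / germline-identity
  bins with reshuffled-light controls (`annotate_repertoire()`,
  `reshuffled_control()`); spatial H–L candidate ranking against a
  colocalization score (`rank_spatial_candidates()`); cancer cell-line
  clone-table filtering to one H–L pair per sample
  (`filter_cancer_clonesets()`); and germline CDRH3-grafting library
  screens with global-alignment identity analysis
  (`build_graft_library()`, `screen_library()`, `pairwise_identity()`).
- **Simulation** — a paired-repertoire generator with a planted,
  tunable H–L compatibility rule and the κ-first/λ-rescue light-chain
  choice process (`synthetic_config()`, `generate_repertoire()`), so the
  whole pipeline is testable end to end with known ground truth,
  including the rule's own accuracy ceiling
  (`bayes_reference_accuracy()`).

The methods vignette (`vignettes/pairing-methods.Rmd`) documents the
model, the planted rule, all defaults and the design reasoning.

## A worked example

Simulate a 2,000-cell paired repertoire, curate a balanced labeled
dataset with leakage-free splits, train the CDR3 CNN and evaluate it on
the withheld clonotypes:

```r
library(igpair)

cfg <- synthetic_config(seed = 42, n_cells = 2000)
rep <- generate_repertoire(cfg)
table(rep$pairs$light_locus)
#>  IGK  IGL
#> 1384  288

dataset <- attach_clusters(make_pseudo_negatives(rep$pairs, seed = 43))
split <- split_by_cluster(dataset, seed = 44)
part <- split$partition[match(dataset$pairs$pair_id, split$pair_id)]
train <- dataset$pairs[part != "test", ]
test <- dataset$pairs[part == "test", ]

cnn <- train_pair_scorer(train, "cdr3_cnn", seed = 45)
metrics(pair_labels(test), score_pairs(cnn, test))
#>     n threshold accuracy precision recall   f1   mcc auc_roc
#> 1 326       0.5    0.825     0.808  0.853 0.83 0.651   0.888

bayes_reference_accuracy(dataset$pairs, cfg)
#> 0.875
```

Reading the output: 17% of surviving cells carry λ light chains (the
rescue pathway); the CNN reaches 0.825 held-out accuracy against the
planted rule's own ceiling of 0.875 — the pairing signal lives in CDR3
composition, which gene-usage baselines (≈0.5 accuracy here, since the
default rule ignores genes) cannot see.

A thin command-line wrapper over the same functions ships at
`inst/cli/igpair.R` with subcommands `simulate`, `curate`, `train`,
`score`, `evaluate`, `annotate`, `screen-library`, `filter-clones` and
`rank-spatial` (see `--help`).

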