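# mphgcl

Multi-class drug–drug interaction (DDI) **event** prediction with meta-path
based heterogeneous graph contrastive learning.

Combining drugs can change what a drug does — "the metabolism decreases",
"the serum concentration increases" — and catalogues of such typed events are
deeply imbalanced: a few event types dominate while most have few labeled
pairs. This package is for computational pharmacology researchers who want a
fully inspectable, CPU-scale implementation of a contrastive
heterogeneous-graph approach to this multi-class problem, with cold-start
evaluation and a synthetic benchmark generator built in.

## The model

Drugs, chemical substructures (C), target proteins (P), enzymes (E) and
transport pathways (T) form a heterogeneous graph with edge types
{D–C, D–P, D–E, D–T, P–P}. Five meta-paths (DCD, DPD, DED, DTD, and the
PPI-mediated 3-hop DPPD) induce drug–drug similarity via PathSim,

    s(i,j) = 2 p(i,j) / (p(i,i) + p(j,j)),

over path-instance counts; top-K neighbor filtering turns each meta-path into
a binary drug sub-graph. Two contrastive views are encoded with multi-head
graph attention: the **average view** (mean of the clean sub-graph
adjacencies) and the **augmented view** (semantic attention over sub-graphs
corrupted each epoch by three masking levels — attribute nodes, whole
sub-graphs, edges). Drug-pair representations
`z(i,j) = z_iC || z_iF || z_jC || z_jF` feed a softmax MLP, trained with

    L = L_s + alpha * (L_uc + L_sc)

— cross-entropy plus cross-view InfoNCE and supervised contrastive losses
(cosine similarity, temperature tau). Evaluation covers known–known pairs
(Task 1) and the cold-start settings with one (Task 2) or two (Task 3) unseen
drugs, reporting accuracy, micro-AUPR, and macro precision/recall/F1 with
event-frequency-grouped breakdowns.

See `vignettes/mphgcl-methods.Rmd` for the full model description, parameter
defaults and design notes.

## Worked example

```r
library(mphgcl)

# planted-structure study data: 200 drugs in 4 clusters, 4 event types,
# long-tailed labels, ~4,000 labeled pairs
syn <- generate_synthetic(synth_config())
sp  <- split_task1(syn$pairs, seed = 1)          # stratified 7:1:2

cfg   <- train_config(d = 32, H = 8, epochs = 200, seed = 1)
model <- train_model(syn$hg, syn$pairs, sp, cfg)

te    <- sp == "test"
probs <- predict_model(model, syn$hg, syn$pairs[te, ])
y     <- match(syn$pairs$event[te], model$event_levels)
evaluate(probs, y)
#> acc=0.9489 aupr=0.9443 macro_f1=0.9439 macro_rec=0.9383 macro_pre=0.9504

ytr <- match(syn$pairs$event[sp == "train"], model$event_levels)
majority_class_metrics(ytr, y, length(model$event_levels))
#> acc=0.3691 aupr=0.3462 macro_f1=0.1348 macro_rec=0.2500 macro_pre=0.0923
```

The model recovers the planted cluster-pair labels almost to the 5% label
noise floor, while the majority-class baseline is stuck at the head event:
macro-F1 0.94 versus 0.13. `rank_novel_pairs(model, syn$hg, syn$pairs,
top_n = 10)` scores all unlabeled pairs and returns the top predictions per
event.

A command-line interface wraps the same functions:

```sh
inst/cli/mphgcl simulate --config synth.yaml --out fixture_dir
inst/cli/mphgcl build-graph --drugs drugs.tsv --chem chem.tsv --target targ.tsv --ppi ppi.tsv --out graph_dir
inst/cli/mphgcl train --graph fixture_dir --ddis fixture_dir/ddis.tsv --task 1 --config cfg.yaml --out run_dir
inst/cli/mphgcl evaluate --run run_dir --split test     # writes metrics.json
inst/cli/mphgcl predict --run run_dir --top-n 10        # ranked TSV
```

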