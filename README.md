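# lagnet

Supervised gene regulatory network (GRN) inference from pseudotime-ordered
single-cell RNA-seq expression.

## What it does

Regulation takes time: when a transcription factor (TF) drives a target
gene, the target's expression echoes the TF's after a delay.  Given cells
ordered along a pseudotime trajectory, `lagnet` turns each directed
TF → target candidate pair into a **time-delay correlation matrix** — entry
(k, l) is the Pearson correlation between the TF's k-th sliding window of
`w` cells (windows step by `m`) and the target's window lagged by
`(l−1)·n` cells:

    M[k, l] = cor( x_tf[(k−1)m+1 … (k−1)m+w],
                   x_tg[(k−1)m+(l−1)n+1 … (k−1)m+(l−1)n+w] )

Each entry is then standardized against two context-specific backgrounds in
the spirit of the CLR (context likelihood of relatedness) scheme — its row
(that TF window across all delays) and its column (all TF windows at the
same delay) — with zero-clipped z-scores combined as
`Z = sqrt(max(0,z_row)² + max(0,z_col)²)`, which filters weak correlations
and sharpens strong ones.  A hybrid **BiGRU + CNN** classifier (bidirectional
GRU over the window axis, two convolution layers, dense head with sigmoid
output; implemented from scratch in RcppArmadillo with gradient-checked
backpropagation) is trained on balanced positive/negative pairs from a
gold-standard network and scores every candidate pair.  The top-ranked
pairs, matched in number to the gold standard, are exported with categories
(`known` / reference labels / `novel`).

The package also provides: the five-step preprocessing pipeline
(validation, low-expression filtering with the `floor(T/10)` rule,
highly-variable-gene selection, gold-standard filtering, balanced pair
sampling), correlated-neighbor expression smoothing, ranking metrics
(AUROC, AUPR, precision@k, early precision, FDR-controlled subnetwork
size), a pseudotime-perturbation robustness analysis, a planted-edge
synthetic benchmark generator, and a command-line wrapper
(`inst/cli/lagnet.R`) with `simulate / preprocess / featurize / train /
predict / evaluate / export / run` subcommands.

Intended users: computational biologists benchmarking GRN inference on
trajectory data, and methods developers who need a transparent, fully
seeded reference implementation of delay-correlation features with
CLR-style enhancement.

## Worked example

Simulate the default planted-edge study (60 genes, 600 cells, 30 true
edges, additive noise) and run the full pipeline:

```r
library(lagnet)

sim <- simulate_dataset(synthetic_config())   # seeded: seed = 7
sim$expr
#> <lagnet_expr> 60 genes x 600 cells, pseudotime-ordered
sim$network
#> <lagnet_network> 'gold': 30 directed edges, 10 regulators

res <- run_pipeline(sim$expr, sim$network, run_config(seed = 7))
res$window
#> <lagnet_window> p=32 q=32 m=5 n=5 w=290 (requires T >= 600)
res$model
#> <lagnet_model> BIGRU + CNN[64-32], input 32x32, 29,110,433 parameters, trained (best epoch 3)
res$report
#> <lagnet_eval> n=12  AUROC=0.7778  AUPR=0.8215  EP=0.8333  FDR|0.05 size=2
table(res$grn$category)
#> known novel
#>    25     5
```

Reading the output: the trajectory (600 cells) is encoded with an
automatically solved 32×32 window grid of width 290.  On the 12 held-out
pairs (6 true edges, 6 non-edges) the classifier reaches AUROC 0.78 and
AUPR 0.82; early precision 0.83 means 5 of the top 6 ranked held-out pairs
are true edges.  The exported network keeps the 30 top-scoring pairs to
match the gold standard's size; 25 of them are known edges, 5 are novel
predictions.  Reruns with the same configuration reproduce these numbers
exactly — every random draw derives from the configuration seed.

Single pairs can be inspected directly:

```r
win <- default_window_config(ncol(sim$expr$values))
e   <- sim$lags[1, ]                 # a planted edge and its true lag
M   <- build_delay_matrix(sim$expr$values[e$tf, ],
                          sim$expr$values[e$target, ], win,
                          tf_id = e$tf, target_id = e$target)
which.max(colMeans(M$values))        # delay column -> 1 + round(lag / n)
Z   <- enhance(M)                    # dual-background standardization
plot_delay_heatmap(M, "pair_raw.png")
plot_delay_heatmap(Z, "pair_enhanced.png")
```

See `vignette("lagnet-methods")` for the full method description, every
tunable parameter with its default and rationale, and what results on the
synthetic benchmark do and do not show.

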