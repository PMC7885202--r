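# splicedarts

Differentiable architecture search for splice-site classification of raw
DNA sequences, in pure R (with Rcpp compute kernels).

## What it does, and for whom

Precisely classifying a fixed-length DNA window as a true or false splice
site — donor (exon→intron, canonical GT) or acceptor (intron→exon,
canonical AG) — is a standard benchmark task in gene annotation. The
canonical dimer occurs constantly by chance, so the signal is the
positional consensus context around it, and convolutional networks are the
usual tool. Instead of hand-designing the network, this package *searches*
for it: the repeated convolutional cell is a DAG whose every edge holds a
softmax-weighted mixture over a candidate operation set

```
sep_conv_3x3  sep_conv_5x5  sep_conv_7x7  dil_conv_3x3
conv_7x1_1x7  max_pool_3x3  avg_pool_3x3  zero
```

and the mixing coefficients α are optimized jointly with the network
weights ω by bilevel gradient descent:

    min_α  L_val(ω*(α), α)    s.t.  ω*(α) = argmin_ω L_train(ω, α)

where each edge computes the continuous relaxation
`ō(x) = Σ_o softmax(α)_o · o(x)`. The best mixture is discretized into a
cell **genotype** (per node: top-2 incoming edges, each with its argmax
non-zero operation), rebuilt as a fixed network, retrained, and evaluated
with accuracy / sensitivity / specificity / F-score / AUC.

It is intended for method work at desk scale: everything runs on one CPU,
and a synthetic planted-motif generator makes search, training, and
evaluation fully testable offline. See `vignette("methods")` for the model,
its assumptions, and every design decision.

## Worked example

```r
library(splicedarts)

# balanced donor-like dataset: GT at offset 30 of a 60-mer with canonical
# consensus flanks; false windows never carry GT at the site
cfg  <- synthetic_config(n = 600, length = 60, motif = donor_motif(30),
                         decoy_rate = 0, seed = 1)
seqs <- generate_splice_dataset(cfg)
sp   <- split_dataset(encode_dataset(seqs), seed = 1)   # 480 / 60 / 60

nc  <- network_config(input_length = 60, layers = 2, init_channels = 8)
res <- run_search(sp, nc, search_config(batch_size = 100, epochs = 3,
                                        seed = 1))
res$best_genotype
#> <cell_genotype> 4 nodes, concat = [0,1,2,3]
#> normal:
#>   node 0: sep_conv_7x7(0) + sep_conv_7x7(1)
#>   node 1: conv_7x1_1x7(0) + sep_conv_3x3(2)
#>   node 2: dil_conv_3x3(0) + sep_conv_7x7(2)
#>   node 3: conv_7x1_1x7(1) + sep_conv_3x3(4)
#> reduce:
#>   node 0: avg_pool_3x3(0) + avg_pool_3x3(1)
#>   ...

model <- train_fixed(res$best_genotype, sp, nc,
                     train_config(epochs = 10, batch_size = 100, seed = 1))
count_parameters(model)$omega
#> [1] 8058
evaluate_model(model, sp$test)
#> <eval_metrics> accuracy 0.5000  sensitivity 0.3214  specificity 0.6562
#>   F-score 0.3750  AUC 0.5134
#>   confusion @0.50: TP=9 FP=11 TN=21 FN=19
```

The numbers are the honest output of this desk-scale run: 3 search + 10
retraining epochs give only ~65 gradient steps, far too few for the
reference learning rate (0.0025 cosine-annealed to 0.001) to train the
network — the per-epoch log shows the cross-entropy creeping from 0.693
to 0.692. This is exactly the situation quantified by the deliberately
red end-to-end acceptance criterion in
`tests/testthat/test-acceptance.R` (see the header comment there):
search, discretization and retraining all function, the task is provably
separable (a logistic baseline on the same split reaches 0.98), but the
specified retraining budget cannot reach 0.90 test accuracy at desk
scale at any learning rate we swept. With more epochs and data the same
code trains normally.

One-hot encoding uses the channel order A, T, C, G:

```r
unclass(encode_sequence("ACGTAC"))[, ]
#>      A T C G
#> [1,] 1 0 0 0
#> [2,] 0 0 1 0
#> [3,] 0 0 0 1
#> [4,] 0 1 0 0
#> [5,] 1 0 0 0
#> [6,] 0 0 1 0
```

(rows: A, C, G, T, A, C; the one-hot channel order is A, T, C, G.)

## Command line

```sh
Rscript -e 'splicedarts::dispatch(commandArgs(TRUE))' \
    simulate --n 1000 --length 141 --seed 1 --out data.tsv
# ... search --in data.tsv --epochs 50 --seed 1 --out genotype.json
# ... train  --in data.tsv --genotype genotype.json --seed 1 --out model.rds
# ... eval   --in data.tsv --model model.rds --seed 1 --out metrics.tsv
```

(or use the installed script `exec/splicedarts`). Subcommands: `simulate`,
`encode`, `search`, `train`, `eval`; every run writes a
`<out>.manifest.json` with the fully resolved configuration so it can be
reproduced exactly. A `--config file` with `[data]/[search]/[network]/
[train]/[eval]` sections supplies defaults that explicit flags override.
`eval --genotype g.json --repeats 10` runs the repeated re-split/retrain
protocol and reports mean ± sd per metric.

## File formats

* **TSV**: `sequence<TAB>label`, no header; labels 0/1.
* **FASTA**: standard records with a `label=<0|1>` token in the header.
* **Genotype JSON**: `{"normal": [[["sep_conv_3x3", 0], ...] x4],
  "reduce": ..., "concat": [0,1,2,3], "nodes": 4}` — per node, a list of
  `[primitive, predecessor]` pairs; predecessors 0/1 are the outputs of
  cells k−2/k−1.
* **History/metrics TSV**: per-epoch `epoch, L_train, L_val, val_accuracy`;
  metrics as `metric, mean, sd` plus `.roc.tsv` / `.pr.tsv` curve points.
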