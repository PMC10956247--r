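# motifgraph

Discovery of variable-length transcription factor binding motifs in
ATAC-seq-derived DNA sequences, via a multi-view k-mer graph and a small
transductive graph neural network.

ATAC-seq footprints mark where transcription factors protected open
chromatin from Tn5 transposition. Each 101 bp window around a footprint
center either contains transcription factor binding sites (TFBSs) or not,
and the aligned TFBSs of one factor form a motif, summarized as a position
weight matrix (PWM). Convolutional motif finders inherit the fixed width of
their kernels; `motifgraph` instead builds a heterogeneous graph whose nodes
are the corpus's k-mers and sequences, connected by four edge views:

* **co-occurrence** — negated pointwise mutual information of a k-mer pair
  across sequences, `-log( (nums/n) / (num_p/n)(num_j/n) )`;
* **similarity** — Hamming distance between the k-mer strings;
* **Jaccard** — intersection over union of the two k-mers' occurrence sets;
* **inclusion** — TF-IDF, `tf(p,i) · log(n / num(p))`, linking sequences to
  their k-mers.

A three-layer network learns per-view k-mer embeddings, pools them into
sequence embeddings through the inclusion view, and predicts TFBS content
with a shared logistic read-out; training is transductive (validation/test
nodes are in the graph but masked from the loss) with an iterative
cross-entropy objective, `iterloss_e = bce_{e-1}·sigmoid(bce_{e-1}) + bce_e`.
Binding sites are then extracted from the embeddings: label-informative
k-mers are selected against a shuffled-negative background, expanded to
`2·lenk` candidate windows, filtered by a background co-occurrence test,
and overlapping candidates merge into variable-length sites, which an
align-and-cluster assembler turns into PWMs. An eight-metric evaluation
suite plus the radar-area summary (maximum `2·sqrt(2)`) scores predictions.

Negatives are base-shuffles of the positives, so no external control data is
needed; a planted-motif simulator with exact ground truth makes every stage
testable offline.

## Worked example

Plant one width-8 motif (1.8 bits/column, consensus `CCTATAAT`) in 150
sequences of 101 bp, train with defaults, and recover it:

```r
library(motifgraph)

pwm    <- make_pwm(8, ic_per_col = 1.8, seed = 11)
sim    <- simulate_corpus(150, seq_len = 101, motifs = pwm, seed = 1)
corpus <- prepare_corpus(sim$sequences, seed = 1)   # shuffled negatives + 80/10/10 paired split
graph  <- build_graph(corpus, lenk = 5)
#> <multiview_graph> 1024 k-mer nodes (lenk = 5), 300 sequence nodes, 4 views

fit <- train_gnn(graph, corpus, epochs = 30, seed = 1)
glance(fit)
#> # A tibble: 1 x 4
#>   epochs train_loss val_auc test_auc
#> 1     30      0.580   0.849    0.938

ms <- find_motifs(fit, graph, corpus)
#> <motif_set> 12 motif(s) from 514 binding site(s)
head(tidy(ms), 3)
#>   motif length nsites consensus               ic_per_col
#> 1     1      5     13 AATGC                        0.807
#> 2     2     23      8 GCCCTATAATCCGTCCTATAATC     0.966
#> 3     3     15      7 ATGCCTATAATTGAA             0.892

interval_recall(sim$truth, ms$tfbs)                       # planted instances overlapped
#> 0.993
max(sapply(ms$motifs, function(m) pwm_similarity(m$pwm, pwm)$r))
#> 0.994                                                   # best-offset column Pearson vs planted

evaluate_predictions(dplyr::filter(fit$predictions, split == "test"))
#>   metric      value
#> 1 precision   0.857
#> 2 recall      0.8
#> ...
#> 7 auc         0.938
#> 8 prc         0.953
#> 9 aemr        2.01
```

The training loss falls from 0.744 to 0.580 over the 30 epochs, the held-out
test AUC is 0.94, reported sites overlap 99% of the planted instances, and
several reported PWMs contain the planted consensus at their core
(column-wise Pearson 0.99 at the best alignment offset). `write_meme(ms,
"motifs.meme")` exports the PWMs for database matching with external tools;
`autoplot(fit)`, `autoplot(ms)` and `plot_metrics_radar()` draw the training
curves, motif profiles, and metric radar.

A command-line front end wrapping the same functions (subcommands
`simulate`, `prepare`, `train`, `find-motifs`, `evaluate`, `sweep`) is
installed at `inst/cli/motifgraph-cli.R`.

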