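---
title: "Multi-view k-mer graphs for ATAC-seq motif discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view k-mer graphs for ATAC-seq motif discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifgraph)
```

## The problem

ATAC-seq probes open chromatin, and short protected *footprints* inside
accessible regions mark where transcription factors were bound. Each
footprint window (101 bp around the footprint center, by default) either
contains transcription factor binding sites (TFBSs) or it does not, and the
aligned TFBSs of one factor form a *motif*, summarized as a position weight
matrix (PWM) of per-column base probabilities. Convolutional models find
such motifs but inherit the fixed width of their kernels; this package
instead represents a sequence corpus as a heterogeneous graph over k-mer and
sequence nodes, trains a small transductive graph neural network to predict
which sequences contain TFBSs, and then extracts *variable-length* binding
sites from the learned embeddings.

The intended user starts from either footprint intervals (BED, from any
footprint caller) plus a reference FASTA, or directly from fixed-length
positive sequences, and ends with a MEME-format motif library, per-sequence
binding-site intervals, and a nine-score evaluation report.

## Corpus construction

Positives are the footprint windows (label 1). Each negative is the same
sequence with its bases uniformly permuted (label 0), so positives and
negatives have identical mono-nucleotide composition and differ only in base
order — the matching null for k-mer-composition methods. Sequences are split
80/10/10 into train/validation/test *as pairs*: a positive and its shuffle
always share a split, preventing composition leakage. Sequences containing
non-ACGT letters are dropped (k-mer identity is undefined over N).

Each sequence is decomposed into overlapping k-mers with step 1. We use
`lenk = 5` by default (configurable 3–8): wide enough that k-mer statistics
are informative, small enough that the vocabulary (at most $4^5 = 1024$
nodes) stays dense across a corpus of a few hundred sequences.

## The four-view graph

With $n$ sequences, $m$ unique k-mers, $num(p)$ the number of sequences
containing k-mer $p$, $nums(p,j)$ the number containing both $p$ and $j$,
and $tf(p,i)$ the count of $p$ in sequence $i$:

* **Co-occurrence view** ($m \times m$): for pairs with $nums(p,j) > 0$,
  $w_{co}(p,j) = -\log\frac{nums(p,j)/n}{(num(p)/n)(num(j)/n)}$ — the
  *negated* pointwise mutual information. Strongly associated pairs thus get
  negative weights; the motif-merge test below ("smaller than background")
  is consistent with this sign, so we keep it rather than flipping to
  conventional PMI. Natural log; no self-edges.
* **Similarity view** ($m \times m$): the Hamming distance between the two
  k-mer strings (0 on the diagonal). The literal definition weighs
  *dissimilar* pairs more; a `sim_transform = "reverse"` option
  (`lenk` − Hamming) is provided for propagation experiments.
* **Jaccard view** ($m \times m$): intersection over union of the two
  k-mers' sequence-occurrence sets (1 on the diagonal).
* **Inclusion view** ($m \times n$): TF-IDF,
  $w_{inclu}(p,i) = tf(p,i)\,\log(n/num(p))$ when $p$ occurs in $i$, else 0.

Initial k-mer embeddings are the L1-row-normalized view matrices. We
normalize by the row sum of *absolute* values: the signed co-occurrence
rows can nearly cancel, and dividing by a near-zero signed sum (the literal
alternative, available as `normalize = "signed"`) is numerically explosive.

## The network

Three layers, all trained jointly:

1. Per view $v \in \{co, sim, jac\}$, k-mer embeddings
   $E_v = \mathrm{ReLU}(\tilde W_v W_v A_v)$, where $\tilde W_v$ is the
   row-normalized view, $W_v$ the raw view, and $A_v$ an $m \times d_v$
   trainable matrix (defaults $d_{co} = d_{sim} = d_{jac} = 50$). The three
   embeddings are concatenated into $M_{sc} \in \mathbb{R}^{m \times D}$,
   $D = 150$.
2. Sequence embeddings pool their constituent k-mers through the inclusion
   view: $E_{sq}(i) = \mathrm{ReLU}(\bar w_i^{\top} M_{sc} A_{inclu})$ with
   $A_{inclu} \in \mathbb{R}^{D \times d_{sq}}$, $d_{sq} = 150$. We require
   $d_{sq} = d_{co}+d_{sim}+d_{jac}$ so k-mer and sequence embeddings share
   a space for the extraction stage.
3. A logistic read-out $\hat y_i = \sigma(w^\top E_{sq}(i) + b)$ **shared
   across sequence nodes**. A variant with one weight row per sequence node
   would leave the masked test nodes' rows untrained and make transductive
   prediction vacuous, so we use the standard shared read-out.

**Numerical conditioning.** Two normalizations are ours and matter in
practice. The fixed propagation operators $\tilde W_v W_v$ are scaled once
to unit root-mean-square so all three views enter layer 1 on a common scale,
and the pooling weights $\bar w_i$ are each sequence's inclusion column
L1-normalized — a TF-IDF-weighted *mean* over its ~97 k-mers rather than a
sum. Without these, initial logits reach $|z| \approx 150$, the sigmoid
saturates, and no fixed small epoch budget can recover.

**Training.** Transductive full-batch: every sequence node (train,
validation, test) participates in the forward pass, but only training nodes
contribute loss and gradient. Per-sequence binary cross-entropy
$\ell_i = -[y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]$ (probabilities
clipped at $10^{-12}$) is augmented into the *iterative loss*

$$\mathrm{iterloss}_i^{(e)} = \ell_i^{(e-1)}\,\sigma(\ell_i^{(e-1)}) + \ell_i^{(e)},$$

where the first term is the previous epoch's cached loss, re-weighted by its
own sigmoid and treated as a constant (no gradient flows through it; the
cache starts at 0, so epoch 1 is plain BCE). Sequences that stayed hard in
the previous epoch therefore raise the reported loss, while the gradient
each epoch is exactly the BCE gradient over training nodes. Optimization is
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) for 30
epochs at learning rate $10^{-3}$ with natural exponential decay
$\eta_e = \eta_0 e^{-0.001(e-1)}$. Gradients are computed analytically
(there is no autodiff here) and are verified against central finite
differences to $10^{-4}$ relative error in the test suite. Initialization is
Glorot-style, $\mathcal N(0, 1/\mathrm{fan_{in}})$, from a single integer
seed; training is deterministic given the seed.

## Extracting variable-length binding sites

The extraction stage turns embeddings into intervals in four steps.

**Scoring k-mers.** Each (k-mer, sequence) pair receives a
mutual-information score, with the matrix computed separately over the
positive set and the negative set; the grand mean of the negative-set matrix
is the *background noise*, subtracted from every positive-set entry, and
k-mers with strictly positive denoised score in a sequence become seeds.
The scorer itself is pluggable. The default, `"saliency"`, scores a k-mer by
its rectified, squared, linearized contribution to the positive-class logit,
$\mathrm{mi}(p, i) = \mathrm{ReLU}(E_{sc}(p)^\top A_{inclu} w)^2$ — the
information the trained read-out extracts from that k-mer. Squaring matters:
the negative-set mean of a squared score is dominated by its upper tail, so
the noise threshold lands between the bulk of uninformative k-mers and the
small informative tail, and only decisively label-informative k-mers seed.
The geometric alternatives (`"cosine"`, `"dot"`) are retained for
sensitivity analyses, but on planted benchmarks they are not selective:
post-ReLU embeddings all lie in the positive orthant, cosines concentrate
near a common value for informative and uninformative k-mers alike, and any
scorer of the product form $s(p)\,t(i)$ has a grand mean that factorizes to
roughly the background median — admitting about half of all background
k-mers as seeds and merging entire sequences into single "sites".

**Expanding seeds.** Every occurrence of a seed k-mer at position $strk$
defines a center $ck = strk + \lceil (lenk-1)/2 \rceil$, a left flank k-mer
$[ck-lenk+1,\,ck]$, a right flank k-mer $[ck+1,\,ck+lenk]$, and a candidate
site of exactly $2\,lenk$ bases spanning both; occurrences whose flanks
leave the sequence are skipped.

**Background co-occurrence test.** The candidate survives only if its two
flank k-mers are more strongly associated in the positives than in the
shuffled negatives: $w_{co}$ computed on positive-set counts must be
*smaller* (stronger, under the negated-PMI sign) than the same weight on
negative-set counts. A pair that never co-occurs in the negatives has
background $+\infty$ (co-occurrence with no shuffle support is the strongest
evidence), and a pair that never co-occurs in the positives is rejected.

**Merging.** Surviving candidates that overlap by at least one base are
unioned transitively (adjacency alone does not merge). This is the step
that produces sites longer than $2\,lenk$ and hence motifs of different
widths.

## From sites to PWMs

Site-to-motif assembly is entirely this package's design. Binding sites
recur at shifted *registers*: which of a motif's constituent k-mers seeded
decides where the $2\,lenk$ window falls, so two sites supporting the same
motif rarely share coordinates or even length. Exact-position clustering
therefore fragments; we assemble by greedy **align-and-cluster** instead.
Sites are processed longest first; each is aligned ungapped at every offset
against each cluster's running consensus (shorter fully contained in
longer) and joins the best cluster whose mismatch fraction over the overlap
is at most 25%, otherwise it founds a new cluster. One refinement pass
re-aligns all sites against the final consensi. Clusters with at least
`min_sites = 5` members become motifs: aligned base counts plus a
pseudocount of 0.25, normalized per column by that column's coverage, with
frame edges covered by fewer than half the sites trimmed. The 25% mismatch
budget is the conventional "three mismatches in a 12-mer" neighborhood
scale; the pseudocount is the standard quarter-per-base Laplace smoothing
for DNA counts.

Motifs are written in MEME minimal format (6-decimal probabilities, `nsites`
from cluster support) for downstream comparison against motif databases with
external tools; binding sites are written as BED (converting the internal
1-based inclusive coordinates to BED's 0-based half-open) and FASTA.

## Evaluation

`evaluate_predictions()` reports precision, recall, F1, accuracy,
specificity, and Matthews correlation from the 0.5-threshold confusion
counts (ties count positive; zero-denominator metrics report 0 with an
`undefined` flag rather than NaN), plus the ROC area computed as the
mid-rank Mann–Whitney statistic and the PR area by step-wise interpolation
(trapezoids are optimistic for PR curves). All six threshold metrics use
their standard textbook definitions. The nine-th score is the radar area:
the eight metrics placed on eight equiangular spokes, summing the triangle
areas $\tfrac12 R_i R_{i+1} \sin(\pi/4)$ with wrap-around — maximum
$2\sqrt2 \approx 2.83$ for a perfect classifier. A negative MCC enters the
formula literally (a signed triangle) and flags the report, since a radar
chart cannot draw a negative radius.

## The synthetic-data generator

`simulate_corpus()` generates the study conditions every test runs under:
fixed-length sequences (101 bp) over an i.i.d. background (uniform A/C/G/T
by default; a first-order Markov background is available but off, matching
the base-shuffle null of the negatives), with 1–3 motif instances per
positive sequence sampled column-wise from configurable PWMs at
non-overlapping uniform-random positions, and exact ground-truth intervals.
`make_pwm()` builds PWMs at a requested information content per column by
placing probability mass on one random dominant base per column; 2
bits/column yields an exact consensus, 0 bits a uniform column.

What it deliberately does not emulate: Tn5 insertion bias, nucleosome
positioning, GC-skewed or repeat-laden genomic background, overlapping or
strand-reversed sites, and read-level noise. Passing tests on this generator
therefore demonstrate the machinery end to end — graph statistics, training,
extraction, assembly — under a clean null, not performance on real ATAC-seq
libraries, where footprint quality and background structure dominate.

The benchmark used by the test suite and the acceptance script plants one
width-8 PWM at 1.8 bits/column (≈ 98% dominant base per column) in 150
positive sequences — 300 sequences and ≈ 1 024 k-mer nodes in the graph, a
size chosen so a full pipeline run (graph, 30 training epochs, extraction)
completes in ≈ 10 s on one CPU; the variable-width check plants widths 8
and 14 together.

## Defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `flank` | 50 bp | half-window around footprint center (101 bp windows) |
| `top_n` | 1500 | top-scored footprints kept before cross-caller intersection |
| `lenk` | 5 | k-mer width (bases), nodes of the graph |
| `dc, ds, dj` | 50 | per-view k-mer embedding widths |
| `dsq` | 150 | sequence embedding width (= dc+ds+dj) |
| `epochs` | 30 | full-batch Adam steps |
| `lr`, `decay` | 0.001, 0.001 | initial learning rate, exponential decay rate |
| `loss` | iterloss | iterative BCE (see above) |
| `threshold` | 0.5 | probability cut for confusion counts |
| `min_sites` | 5 | minimum sites per reported motif |
| `pseudocount` | 0.25 | Laplace smoothing per base count |
| `max_mismatch` | 0.25 | consensus mismatch budget in assembly |

## Known limitations

* Single strand: sites are found on the given strand only; plant and search
  reverse complements explicitly if needed.
* The co-occurrence statistics need a few hundred sequences to stabilize;
  below ~50 pairs the background test loses power.
* Memory grows as $m^2$ with dense view matrices ($m \le 4^{lenk}$);
  `lenk > 8` is rejected by configuration for this reason.
* The saliency scorer linearizes through the second-layer ReLU; it is
  faithful near the trained operating point but is a first-order surrogate,
  not an exact decomposition of the logit.
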