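Package: motifgraph
Title: Multi-View k-mer Graph Neural Networks for ATAC-seq Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers variable-length transcription factor binding motifs in
    ATAC-seq-derived DNA sequences. Sequences and their constituent k-mers are
    assembled into a four-view heterogeneous graph (k-mer co-occurrence,
    Hamming similarity, Jaccard overlap, and TF-IDF inclusion edges); a
    three-layer transductive graph neural network trained with an iterative
    binary cross-entropy objective scores sequences for binding-site content;
    and motifs are extracted from the learned embeddings by mutual-information
    denoising against shuffled negatives followed by a background
    co-occurrence merge test, yielding position weight matrices of different
    widths. Includes a planted-motif simulator with ground truth, an
    eight-metric evaluation suite with a radar-area summary score, and
    readers/writers for FASTA, BED, and MEME minimal motif formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    tools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
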