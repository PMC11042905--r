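Package: phyloaug
Title: Phylogenetic Augmentation for Sequence-to-Function Deep Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training-time phylogenetic augmentation for supervised
    sequence-to-function models: regulatory DNA training sequences are
    replaced, at batch generation and with a configurable rate, by homologous
    sequences sampled from other species, while labels are inherited from the
    reference sequence. Provides readers and writers for FASTA/BED/label
    tables, per-sequence homolog archives with species subsetting, phylogeny
    utilities (distance ordering, branch-length-preserving pruning, total
    evolutionary distance budgets), convolutional architectures for DNA with
    a compact built-in network engine, a training loop with fine-tuning and
    early stopping, experiment drivers (training-set down-sampling, species
    sweeps, augmentation-rate sweeps), global importance analysis of motifs,
    and a motif-conserving sequence-evolution simulator that generates fully
    synthetic benchmark datasets with ground-truth labels and homologs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
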