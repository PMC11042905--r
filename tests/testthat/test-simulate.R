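test_that("generated labels follow the grammar's label rule exactly", {
  # no motifs: labels are pure noise around zero
  g0 <- grammar_spec(n_sequences = 400, seq_len = 80, lambda = 0, noise_sd = 0.5)
  ds0 <- generate_dataset(g0, seed = 1)
  expect_identical(nrow(ds0$truth), 0L)
  expect_lt(abs(mean(ds0$labels$activity)), 0.1)
  expect_lt(abs(sd(ds0$labels$activity) - 0.5), 0.08)
  # single motif, effect 1, no noise: label equals the planted count
  g1 <- grammar_spec(motifs = tibble::tibble(consensus = "TGTAAATA", effect = 1),
                     n_sequences = 300, seq_len = 80, lambda = 1.5, noise_sd = 0)
  ds1 <- generate_dataset(g1, seed = 2)
  counts <- table(factor(ds1$truth$id, levels = ds1$labels$id))
  expect_equal(unname(ds1$labels$activity), as.numeric(counts))
  # planted instances sit where the truth says
  for (i in sample(nrow(ds1$truth), 20)) {
    row <- ds1$truth[i, ]
    s <- ds1$sequences$seq[ds1$sequences$id == row$id]
    expect_identical(substr(s, row$start, row$end), row$motif)
  }
  # reproducible and chromosome labels round-robin
  expect_identical(generate_dataset(g1, seed = 2)$sequences, ds1$sequences)
  expect_identical(unique(ds1$sequences$chrom), paste0("chr", 1:4))
})

test_that("least squares on the true counts recovers the planted effect size", {
  g <- grammar_spec(motifs = tibble::tibble(consensus = "GATTACA", effect = 1.5),
                    n_sequences = 5000, seq_len = 60, lambda = 1, noise_sd = 0.4)
  ds <- generate_dataset(g, seed = 3)
  counts <- as.numeric(table(factor(ds$truth$id, levels = ds$labels$id)))
  fit <- stats::lm(ds$labels$activity ~ counts)
  expect_lt(abs(unname(coef(fit)[2]) - 1.5) / 1.5, 0.05)
})

test_that("zero-rate evolution copies the reference; conserved motifs survive while flanks drift", {
  g <- grammar_spec(n_sequences = 60, seq_len = 100, lambda = 1, noise_sd = 0.1)
  ds <- generate_dataset(g, seed = 4)
  tree <- parse_newick(ladder_newick(3))
  frozen <- evolve_homologs(ds$sequences, ds$truth,
                            evolution_spec(tree, "ref", mu = 0, seed = 5))
  ref_of <- stats::setNames(ds$sequences$seq, ds$sequences$id)
  expect_true(all(frozen$seq == ref_of[frozen$ref_id]))

  hot <- evolve_homologs(ds$sequences, ds$truth,
                         evolution_spec(tree, "ref", mu = 1, conservation = 0,
                                        kill_rate = 0, seed = 6))
  # motif instances are copied verbatim in every species, flanks diverge
  for (i in seq_len(nrow(ds$truth))) {
    row <- ds$truth[i, ]
    homs <- dplyr::filter(hot, ref_id == row$id)
    expect_true(all(substr(homs$seq, row$start, row$end) == row$motif))
  }
  expect_true(mean(hot$seq == ref_of[hot$ref_id]) < 0.05)
})

test_that("neutral-site divergence matches the Jukes-Cantor closed form within 3 SD", {
  g <- grammar_spec(n_sequences = 150, seq_len = 150, lambda = 0)
  ds <- generate_dataset(g, seed = 7)
  tree <- parse_newick("(ref:0.02,a:0.08,b:0.23,c:0.48);")
  mu <- 0.8
  arc <- evolve_homologs(ds$sequences, ds$truth,
                         evolution_spec(tree, "ref", mu = mu, seed = 8))
  dists <- distances_from(tree, "ref")
  mism <- function(a, b) {
    mean(mapply(function(x, y) {
      mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, a, b))
  }
  ref_of <- stats::setNames(ds$sequences$seq, ds$sequences$id)
  n_sites <- 150 * 150
  for (i in seq_len(nrow(dists))) {
    sp <- dists$species[i]
    expected <- 0.75 * (1 - exp(-4 * mu * dists$distance[i] / 3))
    homs <- dplyr::filter(arc, species == sp)
    observed <- mism(homs$seq, ref_of[homs$ref_id])
    sd3 <- 3 * sqrt(expected * (1 - expected) / n_sites)
    expect_lt(abs(observed - expected), sd3 + 1e-12)
  }
  # divergence is monotone in tree distance
  by_sp <- vapply(dists$species, function(sp) {
    homs <- dplyr::filter(arc, species == sp)
    mism(homs$seq, ref_of[homs$ref_id])
  }, numeric(1))
  expect_true(!is.unsorted(by_sp))
})

test_that("a motif-count oracle predicts low-noise labels almost perfectly", {
  g <- grammar_spec(motifs = tibble::tibble(consensus = "TGTAAATA", effect = 1),
                    n_sequences = 1000, seq_len = 80, lambda = 1, noise_sd = 0.1)
  ds <- generate_dataset(g, seed = 9)
  counts <- as.numeric(table(factor(ds$truth$id, levels = ds$labels$id)))
  expect_gt(pcc(counts, ds$labels$activity), 0.9)
})

test_that("turnover kills motif conservation more often in more distant species", {
  g <- grammar_spec(n_sequences = 150, seq_len = 60, lambda = 1, noise_sd = 0)
  ds <- generate_dataset(g, seed = 10)
  tree <- parse_newick(ladder_newick(6))
  arc <- evolve_homologs(ds$sequences, ds$truth,
                         evolution_spec(tree, "ref", mu = 2, conservation = 0,
                                        kill_rate = 0.3, seed = 11))
  intact_rate <- function(sp) {
    homs <- dplyr::filter(arc, species == sp)
    ok <- 0; tot <- 0
    for (i in seq_len(nrow(ds$truth))) {
      row <- ds$truth[i, ]
      h <- homs$seq[homs$ref_id == row$id]
      tot <- tot + 1
      ok <- ok + (substr(h, row$start, row$end) == row$motif)
    }
    ok / tot
  }
  near <- intact_rate("s1")
  far <- intact_rate("s6")
  expect_gt(near, far) # turnover accumulates along the path
  expect_lt(far, 0.6)
})

test_that("indels exercise the midpoint-resize path while keeping archive lengths fixed", {
  g <- grammar_spec(n_sequences = 40, seq_len = 80, lambda = 0)
  ds <- generate_dataset(g, seed = 12)
  tree <- parse_newick("(ref:0.1,a:0.3);")
  arc <- evolve_homologs(ds$sequences, ds$truth,
                         evolution_spec(tree, "ref", mu = 0.2, indel_rate = 1,
                                        seed = 13))
  expect_true(all(nchar(arc$seq) == 80L))
  expect_identical(attr(arc, "target_len"), 80L)
})

test_that("a full synthetic dataset round-trips through its on-disk form", {
  g <- grammar_spec(n_sequences = 30, seq_len = 40, lambda = 1)
  ds <- generate_dataset(g, seed = 14)
  tree <- parse_newick("(ref:0.05,a:0.2,b:0.4);")
  arc <- evolve_homologs(ds$sequences, ds$truth,
                         evolution_spec(tree, "ref", seed = 15))
  dir <- withr::local_tempdir()
  write_dataset(ds, arc, dir)
  refs <- read_fasta(file.path(dir, "refs.fa"))
  expect_identical(refs$seq, ds$sequences$seq)
  labels <- read_label_table(file.path(dir, "labels.tsv"))
  expect_equal(labels, ds$labels)
  back <- read_archive(file.path(dir, "homologs.fa"),
                       file.path(dir, "manifest.json"))
  expect_equal(dplyr::arrange(tibble::as_tibble(back), ref_id, species),
               dplyr::arrange(tibble::as_tibble(arc), ref_id, species))
})
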