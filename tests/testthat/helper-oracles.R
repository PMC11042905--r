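# Independent oracles used across the suite. Each deliberately recomputes
# its quantity by a different route than the implementation under test.

# All-pairs shortest paths over the tree's edge graph (Floyd-Warshall),
# returning the tip-to-tip distance matrix.
fw_tip_distances <- function(tree) {
  n_nodes <- max(tree$edge)
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(n_nodes)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  tips <- seq_along(tree$tip.label)
  out <- d[tips, tips, drop = FALSE]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Pearson correlation from the raw covariance formula.
brute_pcc <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# AUPRC by explicit enumeration: one operating point per distinct score,
# precision/recall computed by direct counting at each threshold.
brute_auprc <- function(scores, labels) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(labels == 1 & called)
    precision <- tp / sum(called)
    recall <- tp / P
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Caterpillar (ladder) tree: species s1..sn at increasing distance from the
# reference leaf, with the number of edges on the path also increasing.
ladder_newick <- function(n, ref = "ref") {
  s <- sprintf("%s:0.01", ref)
  for (k in seq_len(n)) {
    s <- sprintf("(%s,s%d:%0.3f):0.02", s, k, 0.03 * k + 0.01)
  }
  paste0(substr(s, 1L, nchar(s) - 5L), ";")
}

# A model that counts exact occurrences of `motif`, built by hand-setting
# the weights of a single-filter convolution (+1 on each matching channel,
# bias -(k-1), so only a full match survives the ReLU) followed by
# all-ones dense layers that sum the match indicators.
motif_count_model <- function(motif, input_len) {
  k <- nchar(motif)
  spec <- architecture_spec("motif_deepstarr", input_len = input_len,
                            n_tasks = 1L, conv_filters = 1, kernels = k,
                            pools = 1, fc = c(1, 1), dropout = 0)
  m <- build_model(spec, seed = 1L)
  W <- array(0, c(k, 4L, 1L))
  chan <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- strsplit(toupper(motif), "")[[1L]]
  for (j in seq_len(k)) W[j, chan[[chars[j]]], 1L] <- 1
  Lout <- input_len - k + 1L
  weights <- list(
    list(W = W, b = -(k - 1)),                       # conv: 1 iff exact match
    list(),                                          # flatten
    list(W = matrix(1, Lout, 1L), b = 0),            # sum of matches
    list(W = matrix(1, 1L, 1L), b = 0),
    list(W = matrix(1, 1L, 1L), b = 0)               # identity head
  )
  phyloaug:::set_weights(m, weights)
}

# Lazily built shared fixtures (one R session runs the whole suite).
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, create) {
  if (!exists(name, envir = .fixtures)) assign(name, create(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small regression dataset + homologs used by several training tests.
small_regression_world <- function() {
  fixture("small_regression_world", function() {
    g <- grammar_spec(n_sequences = 480, seq_len = 100, lambda = 1,
                      noise_sd = 0.2)
    ds <- generate_dataset(g, seed = 42)
    tree <- parse_newick(ladder_newick(5))
    arc <- evolve_homologs(ds$sequences, ds$truth,
                           evolution_spec(tree, "ref", seed = 43))
    split <- make_split(ds$labels, "chromosome_holdout",
                        test_chrom = "chr4", val_chrom = "chr3")
    list(ds = ds, tree = tree, arc = arc, split = split)
  })
}
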