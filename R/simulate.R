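# Synthetic benchmark generator. Reference sequences carry a planted
# regulatory grammar (consensus motifs with effect sizes, Poisson instance
# counts) that determines ground-truth labels; homologs are then evolved
# from each reference along a species tree under Jukes-Cantor substitution
# with reduced rates inside motif instances (elevated conservation at
# functional positions) and an optional per-branch "kill" that models
# regulatory element turnover. Everything the training, sweep and GIA
# machinery needs can be generated this way without external data.

#' Describe a synthetic regulatory grammar
#'
#' @param motifs A data frame with columns `consensus` (DNA string over
#'   A,C,G,T) and `effect` (additive effect size per planted instance), or
#'   a single consensus string (effect 1).
#' @param background Named base probabilities for A,C,G,T (must sum to 1).
#' @param label_rule `"linear"`: label = sum of planted effects plus
#'   Gaussian noise (`noise_sd`), a regression task. `"logistic"`: label is
#'   Bernoulli with success probability `plogis(intercept + sum of
#'   effects)`, a binary task.
#' @param noise_sd Label noise (linear rule), in label units.
#' @param intercept Baseline log-odds (logistic rule).
#' @param lambda Poisson mean number of motif instances per sequence.
#' @param seq_len,n_sequences Sequence length (bp) and dataset size.
#' @param n_chroms Chromosome labels are assigned round-robin over this
#'   many chromosomes so chromosome-based splits are well defined.
#' @return An object of class `grammar_spec`.
#' @export
grammar_spec <- function(motifs = "TGTAAATA",
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         label_rule = c("linear", "logistic"),
                         noise_sd = 0.3, intercept = -2, lambda = 1,
                         seq_len = 200L, n_sequences = 700L, n_chroms = 4L) {
  label_rule <- match.arg(label_rule)
  if (is.character(motifs)) motifs <- tibble::tibble(consensus = motifs, effect = 1)
  motifs <- tibble::as_tibble(motifs)
  stopifnot(all(c("consensus", "effect") %in% names(motifs)),
            all(grepl("^[ACGT]+$", motifs$consensus)),
            all(is.finite(motifs$effect)),
            abs(sum(background) - 1) < 1e-8, lambda >= 0)
  if (any(nchar(motifs$consensus) > seq_len)) {
    rlang::abort("motif longer than the sequence length")
  }
  structure(list(motifs = motifs, background = background[c("A", "C", "G", "T")],
                 label_rule = label_rule, noise_sd = noise_sd,
                 intercept = intercept, lambda = lambda,
                 seq_len = as.integer(seq_len),
                 n_sequences = as.integer(n_sequences),
                 n_chroms = as.integer(n_chroms)),
            class = "grammar_spec")
}

#' Generate a synthetic dataset
#'
#' Draws background sequences from the grammar's base composition, plants
#' `k ~ Poisson(lambda)` motif instances per sequence at non-overlapping
#' uniform positions (instances that cannot be placed without overlap are
#' skipped), and computes labels from the label rule. The returned ground
#' truth records every planted instance, which downstream oracles (e.g.
#' motif-count predictors for GIA checks) rely on.
#'
#' @param grammar A [grammar_spec()].
#' @param seed Integer seed.
#' @return A list with `sequences` (tibble `id, seq, species, chrom`),
#'   `labels` (a label table with task `activity` or `bound`), and `truth`
#'   (tibble `id, motif, start, end`, 1-based inclusive coordinates).
#' @export
generate_dataset <- function(grammar, seed = 1L) {
  stopifnot(inherits(grammar, "grammar_spec"))
  n <- grammar$n_sequences; L <- grammar$seq_len
  with_preserved_rng({
    set.seed(seed)
    chars <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                           prob = grammar$background), nrow = n)
    ids <- sprintf("synth%05d", seq_len(n))
    n_inst <- stats::rpois(n, grammar$lambda)
    truth <- vector("list", n)
    score <- numeric(n)
    for (i in which(n_inst > 0L)) {
      placed <- integer(0) # occupied positions
      rows <- vector("list", n_inst[i])
      for (m in seq_len(n_inst[i])) {
        w <- sample.int(nrow(grammar$motifs), 1L)
        k <- nchar(grammar$motifs$consensus[w])
        for (try in 1:50) {
          s <- sample.int(L - k + 1L, 1L)
          if (!any(s:(s + k - 1L) %in% placed)) {
            chars[i, s:(s + k - 1L)] <- strsplit(grammar$motifs$consensus[w], "")[[1L]]
            placed <- c(placed, s:(s + k - 1L))
            score[i] <- score[i] + grammar$motifs$effect[w]
            rows[[m]] <- tibble::tibble(id = ids[i],
                                        motif = grammar$motifs$consensus[w],
                                        start = s, end = s + k - 1L)
            break
          }
        }
      }
      truth[[i]] <- dplyr::bind_rows(rows)
    }
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0L) {
      truth <- tibble::tibble(id = character(), motif = character(),
                              start = integer(), end = integer())
    }
    seqs <- apply(chars, 1L, paste, collapse = "")
    chrom <- paste0("chr", ((seq_len(n) - 1L) %% grammar$n_chroms) + 1L)
    if (grammar$label_rule == "linear") {
      y <- score + stats::rnorm(n, sd = grammar$noise_sd)
      labels <- tibble::tibble(id = ids, chrom = chrom, activity = y)
    } else {
      p <- stats::plogis(grammar$intercept + score)
      labels <- tibble::tibble(id = ids, chrom = chrom,
                               bound = stats::rbinom(n, 1L, p))
    }
    list(sequences = tibble::tibble(id = ids, seq = seqs,
                                    species = "reference", chrom = chrom),
         labels = labels, truth = truth)
  })
}

#' Describe a sequence-evolution process
#'
#' @param tree A `phylo` species tree with branch lengths in substitutions
#'   per site; homologs are produced for every leaf except `reference`.
#' @param reference The leaf the reference sequences belong to.
#' @param mu Substitution-rate scale: a neutral site differs from the
#'   reference at tree distance `d` with the Jukes-Cantor probability
#'   `0.75 * (1 - exp(-4 * mu * d / 3))`.
#' @param conservation Factor in `[0, 1]` multiplying `mu` inside motif
#'   instances (0 = perfectly conserved motifs).
#' @param kill_rate Per-branch probability that a motif instance loses its
#'   functional constraint; a killed instance evolves neutrally. Models
#'   regulatory element turnover; more distant species are more likely to
#'   have lost an element.
#' @param indel_rate Per-homolog probability of one short indel (the
#'   homolog is then re-centred to the dataset length); default off, so all
#'   homologs share the reference length.
#' @param seed Integer seed.
#' @return An object of class `evolution_spec`.
#' @export
evolution_spec <- function(tree, reference, mu = 0.4, conservation = 0.05,
                           kill_rate = 0, indel_rate = 0, seed = 1L) {
  validate_phylogeny(tree)
  if (!reference %in% tree$tip.label) {
    rlang::abort(sprintf("reference '%s' is not a leaf of the tree", reference))
  }
  stopifnot(mu >= 0, conservation >= 0, conservation <= 1,
            kill_rate >= 0, kill_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  structure(list(tree = tree, reference = reference, mu = mu,
                 conservation = conservation, kill_rate = kill_rate,
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "evolution_spec")
}

.jc_prob <- function(mu, d) 0.75 * (1 - exp(-4 * mu * d / 3))

#' Evolve homologs of the reference sequences along a tree
#'
#' For every non-reference leaf, each reference sequence is evolved
#' independently along the path from the reference leaf: every site is
#' substituted with the Jukes-Cantor probability for the path distance,
#' with the rate scaled by `conservation` inside motif instances unless the
#' instance was "killed" (probability `kill_rate` per branch on the path),
#' in which case its sites drift neutrally. Realised divergence from the
#' reference therefore increases with tree distance, and motif positions
#' stay recognisable in close species.
#'
#' @param refs A tibble `(id, seq)` of reference sequences (e.g.
#'   `generate_dataset(...)$sequences`).
#' @param truth The ground-truth motif instance table from
#'   [generate_dataset()].
#' @param evo An [evolution_spec()].
#' @return A `homolog_archive` containing one homolog per (reference id,
#'   species) for every non-reference leaf.
#' @export
evolve_homologs <- function(refs, truth, evo) {
  stopifnot(inherits(evo, "evolution_spec"))
  tree <- evo$tree
  leaves <- setdiff(tree$tip.label, evo$reference)
  dists <- ape::cophenetic.phylo(tree)[evo$reference, , drop = TRUE]
  ref_tip <- match(evo$reference, tree$tip.label)
  n_edges <- vapply(leaves, function(sp) {
    length(ape::nodepath(tree, ref_tip, match(sp, tree$tip.label))) - 1L
  }, integer(1L))

  n <- nrow(refs); L <- nchar(refs$seq[1L])
  stopifnot(all(nchar(refs$seq) == L))
  base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  code_mat <- matrix(base_codes[unlist(strsplit(refs$seq, ""), use.names = FALSE)],
                     nrow = L)
  code_mat <- t(code_mat) # (n, L)

  # motif-instance membership: list of per-row site indices, by sequence
  truth_by_id <- if (nrow(truth) > 0L) split(truth, truth$id) else list()
  row_of_id <- stats::setNames(seq_len(n), refs$id)

  out <- vector("list", length(leaves))
  with_preserved_rng({
    for (li in seq_along(leaves)) {
      sp <- leaves[li]
      d <- dists[[sp]]
      set.seed(.item_seed(evo$seed, li, 104729L))
      p_neutral <- .jc_prob(evo$mu, d)
      p_cons <- .jc_prob(evo$conservation * evo$mu, d)
      p_site <- matrix(p_neutral, n, L)
      if (length(truth_by_id) > 0L) {
        p_kill <- 1 - (1 - evo$kill_rate)^n_edges[[li]]
        for (id in names(truth_by_id)) {
          ti <- truth_by_id[[id]]
          r <- row_of_id[[id]]
          for (j in seq_len(nrow(ti))) {
            killed <- stats::runif(1L) < p_kill
            if (!killed) p_site[r, ti$start[j]:ti$end[j]] <- p_cons
          }
        }
      }
      mut <- matrix(stats::runif(n * L), n, L) < p_site
      codes <- code_mat
      n_mut <- sum(mut)
      if (n_mut > 0L) {
        codes[mut] <- (codes[mut] + sample.int(3L, n_mut, replace = TRUE)) %% 4L
      }
      seqs <- apply(matrix(c("A", "C", "G", "T")[codes + 1L], n, L), 1L,
                    paste, collapse = "")
      if (evo$indel_rate > 0) {
        hit <- which(stats::runif(n) < evo$indel_rate)
        for (i in hit) {
          len <- sample.int(5L, 1L)
          pos <- sample.int(L - len, 1L)
          if (stats::runif(1L) < 0.5) { # deletion
            seqs[i] <- paste0(substr(seqs[i], 1L, pos - 1L),
                              substr(seqs[i], pos + len, L))
          } else { # insertion
            ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
            seqs[i] <- paste0(substr(seqs[i], 1L, pos), ins,
                              substr(seqs[i], pos + 1L, L))
          }
        }
      }
      out[[li]] <- tibble::tibble(ref_id = refs$id, species = sp, seq = seqs)
    }
  })
  build_archive(dplyr::bind_rows(out), target_len = L, ref_ids = refs$id)
}

#' Write a synthetic dataset to disk
#'
#' Writes `refs.fa`, `labels.tsv`, `homologs.fa`, `manifest.json` and
#' `truth.tsv` under `dir`, the flat-file form of one simulated dataset.
#'
#' @param dataset A list from [generate_dataset()].
#' @param archive A `homolog_archive` from [evolve_homologs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, archive, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$sequences, file.path(dir, "refs.fa"))
  write_label_table(dataset$labels, file.path(dir, "labels.tsv"))
  write_archive(archive, file.path(dir, "homologs.fa"),
                file.path(dir, "manifest.json"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
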