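# Training-time phylogenetic augmentation. At batch generation each training
# item is, with probability `phylo_rate`, replaced by a homolog drawn
# uniformly from the species available for it (falling back to the reference
# sequence when none is available), and independently reverse-complemented
# with probability `rc_rate`. Labels always come from the reference
# sequence. Validation/test batches are never augmented.
#
# Randomness is counter-based: every per-item decision is keyed by
# (seed, epoch, item index in the training id vector), so the realised batch
# stream is independent of batch size and reproducible per epoch.

#' Augmentation policy
#'
#' @param phylo_rate Probability in `[0,1]` that a training item is replaced
#'   by a homolog at batch generation (1 applies it to every sequence that
#'   has homologs).
#' @param rc_rate Probability of reverse-complementing an item
#'   (default 0.5; use 0 for single-stranded RNA tasks).
#' @param species Character vector of species to draw homologs from, or
#'   `"all"`.
#' @param seed Integer seed for all augmentation randomness.
#' @param finetune_mode If `TRUE`, phylogenetic augmentation is disabled
#'   (reverse complements still apply) — the policy used during the
#'   fine-tuning phase on original sequences.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(phylo_rate = 1, rc_rate = 0.5, species = "all",
                                seed = 1L, finetune_mode = FALSE) {
  stopifnot(phylo_rate >= 0, phylo_rate <= 1, rc_rate >= 0, rc_rate <= 1)
  structure(list(phylo_rate = phylo_rate, rc_rate = rc_rate, species = species,
                 seed = as.integer(seed), finetune_mode = isTRUE(finetune_mode)),
            class = "augmentation_policy")
}

# Lehmer-style mixing of (seed, epoch, index) into one 31-bit stream seed;
# all arithmetic stays below 2^53 so it is exact in doubles.
.item_seed <- function(seed, epoch, idx) {
  m <- 2147483647
  a <- ((abs(as.double(seed)) %% m) * 48271) %% m
  ((a + (epoch %% m) * 69621 + idx * 16807) %% m)
}

.epoch_order <- function(n, seed, epoch) {
  with_preserved_rng({
    set.seed(.item_seed(seed, epoch, 0))
    sample.int(n)
  })
}

.refs_as_vector <- function(refs) {
  if (is.data.frame(refs)) {
    stopifnot(all(c("id", "seq") %in% names(refs)))
    stats::setNames(refs$seq, refs$id)
  } else {
    stopifnot(is.character(refs), !is.null(names(refs)))
    refs
  }
}

.label_matrix <- function(labels) {
  labels <- validate_label_table(labels)
  m <- as.matrix(labels[label_tasks(labels)])
  rownames(m) <- labels$id
  m
}

#' Generate one epoch of (optionally augmented) training batches
#'
#' Produces the batch stream for one training epoch: each training id
#' appears exactly once, in an order shuffled from `(policy$seed, epoch)`.
#' Per item, with probability `phylo_rate` and if the item has at least one
#' homolog in the policy's species set, the input sequence is a homolog
#' drawn uniformly over its available species; otherwise the reference
#' sequence is used. Independently the sequence is reverse-complemented with
#' probability `rc_rate`. The label is always the reference sequence's.
#'
#' @param train_ids Character vector of training sequence ids.
#' @param labels A label table (see [read_label_table()]).
#' @param refs Reference sequences: tibble `(id, seq)` (e.g. from
#'   [read_fasta()]) or a named character vector.
#' @param archive A `homolog_archive`, or `NULL` for no phylogenetic
#'   augmentation.
#' @param policy An [augmentation_policy()].
#' @param batch_size Items per batch (the final batch may be smaller).
#' @param epoch Epoch number (1-based); part of the random stream key, so a
#'   sequence can be represented by a different species each epoch.
#' @return A list of batches; each batch is a list with `x` (a `(B, L, 4)`
#'   one-hot array), `y` (a `(B, n_tasks)` matrix), and `provenance` (a
#'   tibble `(ref_id, species, rc)` where species is `"reference"` for
#'   unaugmented items).
#' @export
make_batches <- function(train_ids, labels, refs, archive = NULL,
                         policy = augmentation_policy(), batch_size = 128L,
                         epoch = 1L) {
  if (batch_size < 1L) rlang::abort("`batch_size` must be at least 1")
  refs <- .refs_as_vector(refs)
  missing_ref <- setdiff(train_ids, names(refs))
  if (length(missing_ref) > 0L) {
    rlang::abort(sprintf("id(s) missing from reference sequences: %s",
                         paste(utils::head(missing_ref, 5L), collapse = ", ")))
  }
  ymat <- .label_matrix(labels)
  missing_lab <- setdiff(train_ids, rownames(ymat))
  if (length(missing_lab) > 0L) {
    rlang::abort(sprintf("id(s) missing from label table: %s",
                         paste(utils::head(missing_lab, 5L), collapse = ", ")))
  }
  use_phylo <- !is.null(archive) && !policy$finetune_mode && policy$phylo_rate > 0
  idx <- NULL
  if (use_phylo) {
    if (!identical(policy$species, "all")) {
      archive <- suppressWarnings(subset_species(archive, policy$species))
    }
    idx <- archive_index(archive)
  }

  n <- length(train_ids)
  ord <- .epoch_order(n, policy$seed, epoch)
  seqs <- character(n)
  prov_species <- character(n)
  prov_rc <- logical(n)
  with_preserved_rng({
    for (pos in seq_len(n)) {
      i <- ord[pos] # item index in dataset order keys the random stream
      id <- train_ids[i]
      set.seed(.item_seed(policy$seed, epoch, i))
      u <- stats::runif(3L)
      s <- refs[[id]]
      sp <- "reference"
      if (use_phylo && u[1L] < policy$phylo_rate) {
        hs <- idx[[id]]
        if (!is.null(hs) && nrow(hs) > 0L) {
          j <- 1L + floor(u[2L] * nrow(hs))
          sp <- hs$species[j]
          s <- hs$seq[j]
        }
      }
      seqs[pos] <- s
      prov_species[pos] <- sp
      prov_rc[pos] <- u[3L] < policy$rc_rate
    }
  })
  if (any(prov_rc)) seqs[prov_rc] <- reverse_complement(seqs[prov_rc])
  ids_in_order <- train_ids[ord]
  .assemble_batches(seqs, ids_in_order, ymat, prov_species, prov_rc, batch_size)
}

.assemble_batches <- function(seqs, ids, ymat, prov_species, prov_rc, batch_size) {
  n <- length(seqs)
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    sel <- s:min(s + batch_size - 1L, n)
    list(
      x = encode_seqs(seqs[sel]),
      y = ymat[ids[sel], , drop = FALSE],
      provenance = tibble::tibble(ref_id = ids[sel],
                                  species = prov_species[sel],
                                  rc = prov_rc[sel])
    )
  })
}

#' Deterministic, unaugmented batches for evaluation
#'
#' Validation and test data are never augmented: batches are emitted in
#' input id order, with no reverse complements and no homolog substitution,
#' identically on every call.
#'
#' @inheritParams make_batches
#' @param ids Character vector of sequence ids to evaluate.
#' @return As [make_batches()]; all provenance species are `"reference"`.
#' @export
eval_batches <- function(ids, labels, refs, batch_size = 128L) {
  if (batch_size < 1L) rlang::abort("`batch_size` must be at least 1")
  refs <- .refs_as_vector(refs)
  missing_ref <- setdiff(ids, names(refs))
  if (length(missing_ref) > 0L) {
    rlang::abort(sprintf("id(s) missing from reference sequences: %s",
                         paste(utils::head(missing_ref, 5L), collapse = ", ")))
  }
  ymat <- .label_matrix(labels)
  .assemble_batches(unname(refs[ids]), ids, ymat,
                    rep("reference", length(ids)), rep(FALSE, length(ids)),
                    batch_size)
}

#' Summarise augmentation provenance over an epoch
#'
#' @param batches A list of batches from [make_batches()].
#' @return A one-row tibble with `n_items`, `n_reference`, `n_homolog`,
#'   `n_rc`, plus a nested `per_species` tibble of homolog counts.
#' @export
provenance_summary <- function(batches) {
  prov <- dplyr::bind_rows(lapply(batches, `[[`, "provenance"))
  hom <- dplyr::filter(prov, .data$species != "reference")
  tibble::tibble(
    n_items = nrow(prov),
    n_reference = sum(prov$species == "reference"),
    n_homolog = nrow(hom),
    n_rc = sum(prov$rc),
    per_species = list(dplyr::count(hom, .data$species, name = "n"))
  )
}
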