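# Experiment drivers: training-set down-sampling, the ascending-distance
# species sweep, and the augmentation-rate sweep. Each driver returns a
# tidy tibble with one row per (grid point, replicate, task), the shape the
# plotting helpers and downstream summaries expect. Within a grid point the
# paired conditions always share training ids and seeds, so differences are
# attributable to augmentation alone.

.replicate_seed <- function(base, replicate, salt = 0L) {
  as.integer(.item_seed(base, replicate, 7919L + salt))
}

#' Down-sampling experiment
#'
#' For each training-set fraction and replicate, draws one fresh uniform
#' sample of training ids (validation and test untouched) and trains the
#' baseline (no augmentation, no fine-tuning) and the augmented +
#' fine-tuned condition on that same sample.
#'
#' @param labels,refs,archive,split,spec,schedule,policy As in [fit_run()];
#'   `policy` describes the augmented condition.
#' @param fractions Numeric vector of training-set fractions in `(0, 1]`.
#' @param n_replicates Replicates per fraction (each with its own sample
#'   and initialisation seed).
#' @param seed Base seed; per-replicate seeds are derived from it.
#' @return A tibble `(fraction, condition, replicate, task, metric, value)`
#'   with `condition` in `{"baseline", "phylo_ft"}`.
#' @export
downsample_experiment <- function(labels, refs, archive, split, spec,
                                  fractions, n_replicates = 3L,
                                  schedule = training_schedule(),
                                  policy = augmentation_policy(), seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  all_train <- split_ids(split, "train")
  grid <- tidyr::expand_grid(fraction = fractions,
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(fraction, replicate) {
    n_take <- round(fraction * length(all_train))
    if (n_take < schedule$batch_size && n_take < length(all_train)) {
      rlang::abort(sprintf(
        "fraction %.3g leaves %d training sequences, fewer than the batch size %d",
        fraction, n_take, schedule$batch_size))
    }
    rs <- .replicate_seed(seed, replicate, round(1000 * fraction))
    ids <- with_preserved_rng({
      set.seed(rs)
      sample(all_train, n_take)
    })
    base_policy <- policy
    base_policy$phylo_rate <- 0
    base_policy$seed <- rs
    aug_policy <- policy
    aug_policy$seed <- rs
    runs <- list(
      baseline = fit_run(labels, refs, NULL, split, spec, schedule,
                         base_policy, finetune = FALSE, seed = rs,
                         train_ids = ids),
      phylo_ft = fit_run(labels, refs, archive, split, spec, schedule,
                         aug_policy, finetune = TRUE, seed = rs,
                         train_ids = ids)
    )
    dplyr::bind_rows(lapply(names(runs), function(cond) {
      dplyr::mutate(runs[[cond]]$metrics, fraction = fraction,
                    condition = cond, replicate = replicate, .before = 1L)
    }))
  })
  dplyr::bind_rows(rows)
}

#' Species sweep
#'
#' Trains with augmentation restricted to the closest species, then the two
#' closest, and so on in ascending evolutionary distance from the reference
#' species, with the fine-tuning phase applied. Each grid point reports the
#' total evolutionary distance of its species subset (reference leaf
#' included) under branch-length-preserving pruning.
#'
#' @inheritParams downsample_experiment
#' @param tree A `phylo` species tree.
#' @param reference Reference species (a leaf of `tree`).
#' @param n_species_grid Integer vector: numbers of closest species to use.
#' @return A tibble `(n_species, total_distance, replicate, task, metric,
#'   value)`.
#' @export
species_sweep <- function(labels, refs, archive, split, spec, tree, reference,
                          n_species_grid, n_replicates = 3L,
                          schedule = training_schedule(),
                          policy = augmentation_policy(), seed = 1L) {
  stopifnot(length(n_species_grid) > 0L)
  ord <- distances_from(tree, reference)
  stopifnot(max(n_species_grid) <= nrow(ord))
  grid <- tidyr::expand_grid(n_species = sort(unique(as.integer(n_species_grid))),
                             replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(n_species, replicate) {
    sp <- ord$species[seq_len(n_species)]
    td <- total_distance(tree, c(reference, sp))
    rs <- .replicate_seed(seed, replicate, n_species)
    pol <- policy
    pol$species <- sp
    pol$seed <- rs
    run <- fit_run(labels, refs, archive, split, spec, schedule, pol,
                   finetune = TRUE, seed = rs)
    dplyr::mutate(run$metrics, n_species = n_species, total_distance = td,
                  replicate = replicate, .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' Augmentation-rate sweep
#'
#' Trains at each phylogenetic augmentation rate in `rates` (0 = no
#' augmentation); all runs share splits and per-replicate seeds, so the
#' rate is the only moving part within a replicate.
#'
#' @inheritParams downsample_experiment
#' @param rates Numeric vector of augmentation rates in `[0, 1]`.
#' @param finetune Whether the fine-tuning phase is applied after each run.
#' @return A tibble `(rate, replicate, task, metric, value)`.
#' @export
rate_sweep <- function(labels, refs, archive, split, spec, rates,
                       n_replicates = 3L, schedule = training_schedule(),
                       policy = augmentation_policy(), finetune = TRUE,
                       seed = 1L) {
  stopifnot(length(rates) > 0L, all(rates >= 0), all(rates <= 1))
  grid <- tidyr::expand_grid(rate = rates, replicate = seq_len(n_replicates))
  rows <- purrr::pmap(grid, function(rate, replicate) {
    rs <- .replicate_seed(seed, replicate)
    pol <- policy
    pol$phylo_rate <- rate
    pol$seed <- rs
    run <- fit_run(labels, refs, if (rate > 0) archive else NULL, split, spec,
                   schedule, pol, finetune = finetune, seed = rs)
    dplyr::mutate(run$metrics, rate = rate, replicate = replicate, .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' Scrambled-label control
#'
#' Returns a copy of the label table with task values permuted over
#' training ids (validation/test rows untouched) — the negative control for
#' small-dataset classification runs.
#'
#' @param labels A label table.
#' @param split A split tibble from [make_split()].
#' @param seed Seed of the permutation (logged as an attribute).
#' @return The label table with permuted training labels.
#' @export
scramble_labels <- function(labels, split, seed = 1L) {
  labels <- validate_label_table(labels)
  train <- labels$id %in% split_ids(split, "train")
  perm <- with_preserved_rng({ set.seed(seed); sample(which(train)) })
  tasks <- label_tasks(labels)
  labels[which(train), tasks] <- labels[perm, tasks]
  attr(labels, "scramble_seed") <- as.integer(seed)
  labels
}
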