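# Train/validation/test assignment. Three rules cover the dataset designs
# supported: hold out whole chromosomes, split one chromosome in half into
# validation and test, or draw seeded fractional splits.

#' Assign sequences to train/validation/test sets
#'
#' @param labels A label table (see [read_label_table()]); the `chrom`
#'   column drives the chromosome-based rules.
#' @param rule One of:
#'   * `"chromosome_holdout"`: `test_chrom` chromosomes become the test
#'     set, optional `val_chrom` chromosomes the validation set, the rest
#'     train (a dataset with no validation set simply omits `val_chrom`).
#'   * `"chromosome_half"`: the ids of `split_chrom` are split in half in
#'     table order — first half validation, second half test; all other
#'     chromosomes train.
#'   * `"fractional"`: a seeded shuffle split by `fractions`
#'     (train/val/test proportions summing to 1).
#' @param test_chrom,val_chrom,split_chrom Chromosome names, per rule.
#' @param fractions Named numeric vector `c(train=, val=, test=)` for the
#'   fractional rule.
#' @param seed Seed for the fractional shuffle.
#' @return A tibble `(id, set)` with `set` in `{"train","val","test"}`;
#'   the three sets are disjoint and cover every id.
#' @export
make_split <- function(labels,
                       rule = c("chromosome_holdout", "chromosome_half", "fractional"),
                       test_chrom = NULL, val_chrom = NULL, split_chrom = NULL,
                       fractions = c(train = 0.93, val = 0.035, test = 0.035),
                       seed = 1L) {
  rule <- match.arg(rule)
  labels <- validate_label_table(labels)
  set <- rep("train", nrow(labels))
  if (rule == "chromosome_holdout") {
    if (is.null(test_chrom)) rlang::abort("`test_chrom` is required for chromosome_holdout")
    set[labels$chrom %in% test_chrom] <- "test"
    if (!is.null(val_chrom)) set[labels$chrom %in% val_chrom] <- "val"
  } else if (rule == "chromosome_half") {
    if (is.null(split_chrom)) rlang::abort("`split_chrom` is required for chromosome_half")
    on_chrom <- which(labels$chrom %in% split_chrom)
    if (length(on_chrom) < 2L) rlang::abort("`split_chrom` must contain at least two sequences")
    half <- length(on_chrom) %/% 2L
    set[on_chrom[seq_len(half)]] <- "val"
    set[on_chrom[(half + 1L):length(on_chrom)]] <- "test"
  } else {
    stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
    n <- nrow(labels)
    ord <- with_preserved_rng({ set.seed(seed); sample.int(n) })
    n_train <- round(fractions[["train"]] * n)
    n_val <- round(fractions[["val"]] * n)
    set[ord] <- rep(c("train", "val", "test"),
                    c(n_train, n_val, n - n_train - n_val))
  }
  tibble::tibble(id = labels$id, set = set)
}

split_ids <- function(split, which) split$id[split$set == which]
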