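small_spec <- function(L = 100L, ...) {
  architecture_spec("motif_deepstarr", input_len = L, n_tasks = 1,
                    conv_filters = 16, kernels = 11, fc = c(16, 16),
                    dropout = 0, ...)
}

test_that("splits are disjoint and cover all ids under every rule", {
  w <- small_regression_world()
  labels <- w$ds$labels
  splits <- list(
    make_split(labels, "chromosome_holdout", test_chrom = "chr4", val_chrom = "chr3"),
    make_split(labels, "chromosome_holdout", test_chrom = "chr4"), # no val set
    make_split(labels, "chromosome_half", split_chrom = "chr2"),
    make_split(labels, "fractional", fractions = c(train = 0.8, val = 0.1, test = 0.1),
               seed = 3)
  )
  for (s in splits) {
    expect_setequal(s$id, labels$id)
    expect_identical(anyDuplicated(s$id), 0L)
    expect_true(all(s$set %in% c("train", "val", "test")))
    expect_gt(sum(s$set == "train"), 0)
    expect_gt(sum(s$set == "test"), 0)
  }
  expect_identical(sum(splits[[2]]$set == "val"), 0L)
  # chromosome_half: the split chromosome divides into val/test halves
  on2 <- splits[[3]][labels$chrom == "chr2", ]
  expect_setequal(unique(on2$set), c("val", "test"))
  expect_lte(abs(sum(on2$set == "val") - sum(on2$set == "test")), 1L)
})

test_that("training is seed-deterministic and learns a single-motif task", {
  w <- small_regression_world()
  ids <- split_ids(w$split, "train")[1:200]
  val <- split_ids(w$split, "val")
  sch <- training_schedule(max_epochs = 30, finetune_epochs = 0,
                           early_stop_patience = NULL, batch_size = 16)
  pol <- augmentation_policy(phylo_rate = 0, seed = 5)
  fit1 <- train_model(build_model(small_spec(), seed = 6), ids, w$ds$labels,
                      w$ds$sequences, NULL, pol, sch, val)
  fit2 <- train_model(build_model(small_spec(), seed = 6), ids, w$ds$labels,
                      w$ds$sequences, NULL, pol, sch, val)
  expect_identical(fit1$history, fit2$history)
  # the validation fit is strong within 30 epochs on 200 training sequences
  preds <- predict(fit1$model, w$ds$sequences$seq[match(val, w$ds$sequences$id)])
  obs <- w$ds$labels$activity[match(val, w$ds$labels$id)]
  expect_gt(pcc(preds[, 1], obs), 0.5)
  # training loss decreased substantially
  expect_lt(dplyr::last(fit1$history$train_loss), 0.5 * fit1$history$train_loss[1])
})

test_that("early stopping halts after `patience` stale epochs and restores best weights", {
  w <- small_regression_world()
  ids <- split_ids(w$split, "train")[1:60]
  val <- split_ids(w$split, "val")
  # high learning rate forces val loss to bounce so stopping engages early
  sch <- training_schedule(lr_main = 5e-2, max_epochs = 60, finetune_epochs = 0,
                           early_stop_patience = 3, batch_size = 16)
  pol <- augmentation_policy(phylo_rate = 0, seed = 9)
  fit <- train_model(build_model(small_spec(), seed = 10), ids, w$ds$labels,
                     w$ds$sequences, NULL, pol, sch, val)
  n_run <- nrow(fit$history)
  expect_lt(n_run, 60L)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  expect_identical(n_run, fit$best_epoch + 3L) # stopped `patience` epochs later
  # restored weights equal a rerun truncated at the best epoch
  sch2 <- training_schedule(lr_main = 5e-2, max_epochs = fit$best_epoch,
                            finetune_epochs = 0, early_stop_patience = NULL,
                            batch_size = 16)
  fit2 <- train_model(build_model(small_spec(), seed = 10), ids, w$ds$labels,
                      w$ds$sequences, NULL, pol, sch2, val)
  expect_equal(phyloaug:::get_weights(fit$model),
               phyloaug:::get_weights(fit2$model), tolerance = 1e-12)
})

test_that("fine-tuning uses original sequences only and zero epochs is a no-op", {
  w <- small_regression_world()
  ids <- split_ids(w$split, "train")[1:80]
  sch <- training_schedule(max_epochs = 2, finetune_epochs = 3,
                           early_stop_patience = NULL, batch_size = 16)
  pol <- augmentation_policy(phylo_rate = 1, rc_rate = 0.5, seed = 2)
  fit <- train_model(build_model(small_spec(), seed = 1), ids, w$ds$labels,
                     w$ds$sequences, w$arc, pol, sch)
  ft <- finetune_model(fit, ids, w$ds$labels, w$ds$sequences, sch)
  ft_prov <- dplyr::filter(ft$provenance, epoch > 2)
  expect_identical(nrow(ft_prov), 3L)
  expect_true(all(ft_prov$n_homolog == 0L)) # no phylo augmentation
  expect_gt(sum(ft_prov$n_rc), 0L)          # reverse complements still applied
  expect_identical(sum(ft$history$phase == "finetune"), 3L)
  # zero fine-tuning epochs leaves the model untouched
  sch0 <- training_schedule(max_epochs = 2, finetune_epochs = 0,
                            early_stop_patience = NULL, batch_size = 16)
  expect_identical(finetune_model(fit, ids, w$ds$labels, w$ds$sequences, sch0), fit)
})

test_that("a diverging loss aborts with a diagnostic and schedules are validated", {
  w <- small_regression_world()
  ids <- split_ids(w$split, "train")[1:40]
  huge <- w$ds$labels
  huge$activity <- huge$activity * 1e200 # squared error overflows
  sch <- training_schedule(max_epochs = 2, finetune_epochs = 0,
                           early_stop_patience = NULL, batch_size = 16)
  expect_error(
    train_model(build_model(small_spec(), seed = 1), ids, huge,
                w$ds$sequences, NULL, augmentation_policy(phylo_rate = 0), sch),
    "non-finite")
  expect_error(training_schedule(lr_main = 1e-4, lr_finetune = 1e-3))
  expect_error(training_schedule(finetune_epochs = -1))
  # loss/task-type mismatch is rejected
  expect_error(
    train_model(build_model(small_spec(), seed = 1), ids, w$ds$labels,
                w$ds$sequences, NULL, augmentation_policy(phylo_rate = 0),
                training_schedule(loss = "bce", max_epochs = 1,
                                  early_stop_patience = NULL)),
    "inconsistent")
})

test_that("scrambled labels permute training rows only", {
  w <- small_regression_world()
  scr <- scramble_labels(w$ds$labels, w$split, seed = 8)
  train <- w$ds$labels$id %in% split_ids(w$split, "train")
  expect_identical(scr$activity[!train], w$ds$labels$activity[!train])
  expect_identical(sort(scr$activity[train]), sort(w$ds$labels$activity[train]))
  expect_false(identical(scr$activity[train], w$ds$labels$activity[train]))
})

test_that("experiment drivers produce complete, paired result tables", {
  w <- small_regression_world()
  sch <- training_schedule(max_epochs = 2, finetune_epochs = 1,
                           early_stop_patience = NULL, batch_size = 16)
  ds_tbl <- downsample_experiment(w$ds$labels, w$ds$sequences, w$arc, w$split,
                                  small_spec(), fractions = c(0.5, 1),
                                  n_replicates = 2, schedule = sch, seed = 3)
  expect_identical(nrow(ds_tbl), 2L * 2L * 2L) # fractions x replicates x conditions
  expect_setequal(unique(ds_tbl$condition), c("baseline", "phylo_ft"))
  rs <- rate_sweep(w$ds$labels, w$ds$sequences, w$arc, w$split, small_spec(),
                   rates = c(0, 1), n_replicates = 2, schedule = sch, seed = 3)
  expect_identical(nrow(rs), 4L)
  ss <- species_sweep(w$ds$labels, w$ds$sequences, w$arc, w$split, small_spec(),
                      w$tree, "ref", n_species_grid = c(1, 3), n_replicates = 1,
                      schedule = sch, seed = 3)
  expect_identical(nrow(ss), 2L)
  # budgets come from branch-length-preserving pruning of the same tree
  ord <- distances_from(w$tree, "ref")
  expect_equal(unique(ss$total_distance),
               c(total_distance(w$tree, c("ref", ord$species[1])),
                 total_distance(w$tree, c("ref", ord$species[1:3]))))
  expect_error(downsample_experiment(w$ds$labels, w$ds$sequences, w$arc, w$split,
                                     small_spec(), fractions = 0.05,
                                     n_replicates = 1, schedule = sch),
               "batch size")
})

test_that("tidiers and plots expose fits and runs in broom/ggplot form", {
  w <- small_regression_world()
  sch <- training_schedule(max_epochs = 2, finetune_epochs = 1,
                           early_stop_patience = NULL, batch_size = 16)
  run <- fit_run(w$ds$labels, w$ds$sequences, w$arc, w$split, small_spec(),
                 sch, augmentation_policy(seed = 4), seed = 5)
  expect_s3_class(tidy(run), "tbl_df")
  expect_identical(names(tidy(run)), c("task", "metric", "value"))
  g <- glance(run$fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_finetune_epochs, 1L)
  expect_s3_class(autoplot(run$fit), "ggplot")
  h <- tidy(run$fit)
  expect_identical(nrow(h), 3L) # 2 main + 1 finetune epochs
})
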