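# Training loop: Adam on MSE or cross-entropy, augmented batches at every
# epoch, optional early stopping with best-weight restore, and a short
# low-learning-rate fine-tuning phase on original (unaugmented) sequences.

#' Training schedule
#'
#' Defaults follow the enhancer-activity setup: Adam at learning rate
#' `2e-3`, squared-error loss, early stopping with patience 10, then five
#' fine-tuning epochs at `1e-4` on original sequences only. Accessibility
#' (20 epochs, cross-entropy) and small-dataset (50 epochs, no validation
#' set, no early stopping) setups are reached by overriding fields.
#'
#' @param lr_main Learning rate of the main phase.
#' @param lr_finetune Learning rate of the fine-tuning phase (must be lower
#'   than `lr_main`).
#' @param max_epochs Maximum training epochs of the main phase.
#' @param finetune_epochs Epochs of the fine-tuning phase (0 disables it).
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best-epoch weights are restored), or `NULL` to train
#'   for all `max_epochs`.
#' @param loss `"mse"` for regression tasks, `"bce"` for binary tasks.
#' @param batch_size Training batch size.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(lr_main = 2e-3, lr_finetune = 1e-4,
                              max_epochs = 100L, finetune_epochs = 5L,
                              early_stop_patience = 10L,
                              loss = c("mse", "bce"), batch_size = 128L) {
  loss <- match.arg(loss)
  stopifnot(lr_finetune < lr_main, finetune_epochs >= 0L, max_epochs >= 1L,
            batch_size >= 1L)
  if (!is.null(early_stop_patience)) stopifnot(early_stop_patience >= 1L)
  structure(list(lr_main = lr_main, lr_finetune = lr_finetune,
                 max_epochs = as.integer(max_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 early_stop_patience = early_stop_patience,
                 loss = loss, batch_size = as.integer(batch_size)),
            class = "training_schedule")
}

.check_loss_task <- function(schedule, model) {
  ok <- (schedule$loss == "mse" && model$spec$task_type == "regression") ||
    (schedule$loss == "bce" && model$spec$task_type == "binary")
  if (!ok) {
    rlang::abort(sprintf("loss '%s' is inconsistent with task type '%s'",
                         schedule$loss, model$spec$task_type))
  }
}

.epoch_pass <- function(model, batches, schedule, state, step, lr, training = TRUE) {
  total <- 0; n_items <- 0
  for (b in batches) {
    fwd <- nn_forward(model, b$x, training = training)
    ls <- nn_loss(fwd$out, b$y, schedule$loss)
    if (!is.finite(ls$value)) {
      rlang::abort(sprintf("non-finite training loss at step %d; aborting run", step))
    }
    total <- total + ls$value * nrow(b$y)
    n_items <- n_items + nrow(b$y)
    if (training) {
      grads <- nn_backward(model, fwd$caches, ls$dlogits)
      step <- step + 1L
      upd <- adam_update(model, grads, state, step, lr)
      model <- upd$model
      state <- upd$state
    }
  }
  list(model = model, state = state, step = step, loss = total / n_items)
}

.eval_loss <- function(model, batches, schedule) {
  total <- 0; n_items <- 0
  for (b in batches) {
    out <- nn_forward(model, b$x, training = FALSE)$out
    total <- total + nn_loss(out, b$y, schedule$loss)$value * nrow(b$y)
    n_items <- n_items + nrow(b$y)
  }
  total / n_items
}

#' Train a model with phylogenetic augmentation
#'
#' Runs the main training phase: per epoch, a fresh augmented batch stream
#' from [make_batches()] (a sequence may be represented by a different
#' species each epoch), Adam updates at `schedule$lr_main`, validation loss
#' on fixed unaugmented batches, and optional early stopping that restores
#' the best-epoch weights. Everything is seeded: identical inputs and seeds
#' give identical loss curves.
#'
#' @param model A `phyloaug_model` from [build_model()].
#' @param train_ids,labels,refs,archive,policy As in [make_batches()].
#' @param schedule A [training_schedule()].
#' @param val_ids Ids of the validation set, or `NULL` for no validation
#'   (then early stopping must be disabled).
#' @param verbose Print per-epoch losses.
#' @return A `phyloaug_fit`: list with the trained `model`, a `history`
#'   tibble (epoch, phase, train_loss, val_loss), `best_epoch`, the
#'   per-epoch `provenance` tibble, and the schedule/policy used.
#' @export
train_model <- function(model, train_ids, labels, refs, archive = NULL,
                        policy = augmentation_policy(),
                        schedule = training_schedule(), val_ids = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "phyloaug_model"))
  .check_loss_task(schedule, model)
  patience <- schedule$early_stop_patience
  if (is.null(val_ids) && !is.null(patience)) {
    rlang::abort("early stopping requires a validation set; set early_stop_patience = NULL")
  }
  val <- if (!is.null(val_ids)) eval_batches(val_ids, labels, refs, schedule$batch_size)
  state <- adam_state(model)
  step <- 0L
  history <- vector("list", schedule$max_epochs)
  prov <- vector("list", schedule$max_epochs)
  best_loss <- Inf; best_epoch <- NA_integer_; best_weights <- NULL
  since_best <- 0L
  n_epochs <- 0L
  with_preserved_rng({
    for (epoch in seq_len(schedule$max_epochs)) {
      batches <- make_batches(train_ids, labels, refs, archive, policy,
                              schedule$batch_size, epoch)
      set.seed(.item_seed(policy$seed, epoch, 999983L)) # dropout stream
      pass <- .epoch_pass(model, batches, schedule, state, step,
                          schedule$lr_main)
      model <- pass$model; state <- pass$state; step <- pass$step
      val_loss <- if (!is.null(val)) .eval_loss(model, val, schedule) else NA_real_
      history[[epoch]] <- tibble::tibble(epoch = epoch, phase = "main",
                                         train_loss = pass$loss,
                                         val_loss = val_loss)
      prov[[epoch]] <- dplyr::mutate(provenance_summary(batches), epoch = epoch,
                                     .before = 1L)
      n_epochs <- epoch
      if (verbose) {
        message(sprintf("epoch %d train %.4f val %s", epoch, pass$loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
      }
      if (!is.null(val)) {
        if (val_loss < best_loss) {
          best_loss <- val_loss; best_epoch <- epoch
          best_weights <- get_weights(model)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
        }
        if (!is.null(patience) && since_best >= patience) break
      }
    }
  })
  if (!is.null(patience) && !is.null(best_weights)) {
    model <- set_weights(model, best_weights)
  }
  structure(list(model = model,
                 history = dplyr::bind_rows(history[seq_len(n_epochs)]),
                 best_epoch = best_epoch,
                 provenance = dplyr::bind_rows(prov[seq_len(n_epochs)]),
                 schedule = schedule, policy = policy),
            class = "phyloaug_fit")
}

#' Fine-tune on original sequences
#'
#' After augmented training, runs exactly `schedule$finetune_epochs` epochs
#' at the lower learning rate on the original (reference) training
#' sequences only — phylogenetic augmentation is off, reverse-complement
#' augmentation stays on unless `keep_rc = FALSE`. No early stopping.
#'
#' @param fit A `phyloaug_fit` from [train_model()].
#' @inheritParams train_model
#' @param keep_rc Keep reverse-complement augmentation during fine-tuning.
#' @return The updated `phyloaug_fit` with fine-tuning epochs appended to
#'   its history.
#' @export
finetune_model <- function(fit, train_ids, labels, refs,
                           schedule = fit$schedule, keep_rc = TRUE) {
  stopifnot(inherits(fit, "phyloaug_fit"))
  if (schedule$finetune_epochs == 0L) return(fit)
  model <- fit$model
  .check_loss_task(schedule, model)
  policy <- fit$policy
  policy$finetune_mode <- TRUE
  if (!keep_rc) policy$rc_rate <- 0
  state <- adam_state(model)
  step <- 0L
  history <- vector("list", schedule$finetune_epochs)
  prov <- vector("list", schedule$finetune_epochs)
  offset <- max(fit$history$epoch)
  with_preserved_rng({
    for (e in seq_len(schedule$finetune_epochs)) {
      epoch <- offset + e
      batches <- make_batches(train_ids, labels, refs, archive = NULL, policy,
                              schedule$batch_size, epoch)
      set.seed(.item_seed(policy$seed, epoch, 999983L))
      pass <- .epoch_pass(model, batches, schedule, state, step,
                          schedule$lr_finetune)
      model <- pass$model; state <- pass$state; step <- pass$step
      history[[e]] <- tibble::tibble(epoch = epoch, phase = "finetune",
                                     train_loss = pass$loss, val_loss = NA_real_)
      prov[[e]] <- dplyr::mutate(provenance_summary(batches), epoch = epoch,
                                 .before = 1L)
    }
  })
  fit$model <- model
  fit$history <- dplyr::bind_rows(fit$history, dplyr::bind_rows(history))
  fit$provenance <- dplyr::bind_rows(fit$provenance, dplyr::bind_rows(prov))
  fit
}

#' Evaluate a model on held-out sequences
#'
#' Computes per-task test metrics (PCC for regression tasks, AUPRC for
#' binary tasks) from deterministic unaugmented batches.
#'
#' @param model A `phyloaug_model` or `phyloaug_fit`.
#' @param ids Ids of the evaluation set.
#' @inheritParams make_batches
#' @return A tibble `(task, metric, value)`.
#' @export
evaluate_model <- function(model, ids, labels, refs, batch_size = 128L) {
  if (inherits(model, "phyloaug_fit")) model <- model$model
  stopifnot(inherits(model, "phyloaug_model"))
  batches <- eval_batches(ids, labels, refs, batch_size)
  pred <- do.call(rbind, lapply(batches, function(b) {
    predict(model, b$x, type = "response")
  }))
  obs <- do.call(rbind, lapply(batches, `[[`, "y"))
  tasks <- colnames(obs) %||% paste0("task", seq_len(ncol(obs)))
  metric <- if (model$spec$task_type == "regression") "pcc" else "auprc"
  value <- vapply(seq_len(ncol(obs)), function(j) {
    if (metric == "pcc") pcc(pred[, j], obs[, j]) else auprc(pred[, j], obs[, j])
  }, numeric(1L))
  tibble::tibble(task = tasks, metric = metric, value = value)
}

#' Run one complete training replicate
#'
#' The standard end-to-end unit of the experiment drivers: build a model,
#' train (optionally with phylogenetic augmentation), optionally fine-tune
#' on original sequences, then evaluate once on the held-out test set.
#'
#' @param labels,refs,archive As in [make_batches()].
#' @param split A split tibble from [make_split()].
#' @param spec An [architecture_spec()].
#' @param schedule A [training_schedule()].
#' @param policy An [augmentation_policy()]; use `phylo_rate = 0` for the
#'   baseline condition.
#' @param finetune Whether to run the fine-tuning phase.
#' @param seed Seed for weight initialisation (the augmentation stream is
#'   seeded by `policy$seed`).
#' @param train_ids Optional subset of training ids (e.g. a down-sampled
#'   training set); defaults to all ids with `set == "train"`.
#' @return A `phyloaug_run`: list with the `fit`, the test `metrics`
#'   tibble, and the condition description.
#' @export
fit_run <- function(labels, refs, archive = NULL, split, spec,
                    schedule = training_schedule(),
                    policy = augmentation_policy(), finetune = TRUE,
                    seed = 1L, train_ids = NULL) {
  train_ids <- train_ids %||% split_ids(split, "train")
  val_ids <- split_ids(split, "val")
  if (length(val_ids) == 0L) val_ids <- NULL
  test_ids <- split_ids(split, "test")
  model <- build_model(spec, seed = seed)
  fit <- train_model(model, train_ids, labels, refs, archive, policy,
                     schedule, val_ids)
  if (finetune && schedule$finetune_epochs > 0L) {
    fit <- finetune_model(fit, train_ids, labels, refs, schedule)
  }
  metrics <- evaluate_model(fit$model, test_ids, labels, refs,
                            schedule$batch_size)
  structure(list(fit = fit, metrics = metrics,
                 condition = list(phylo_rate = policy$phylo_rate,
                                  species = policy$species,
                                  finetune = finetune && schedule$finetune_epochs > 0L,
                                  seed = seed)),
            class = "phyloaug_run")
}
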