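# Tidiers for the package's fitted objects, following the broom convention:
# tidy() returns one row per elementary result, glance() one row per object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training fit
#'
#' @param x A `phyloaug_fit` from [train_model()].
#' @param ... Unused.
#' @return The per-epoch history tibble `(epoch, phase, train_loss,
#'   val_loss)`.
#' @export
tidy.phyloaug_fit <- function(x, ...) x$history

#' @rdname tidy.phyloaug_fit
#' @export
glance.phyloaug_fit <- function(x, ...) {
  main <- dplyr::filter(x$history, .data$phase == "main")
  tibble::tibble(
    n_epochs = nrow(main),
    n_finetune_epochs = sum(x$history$phase == "finetune"),
    best_epoch = x$best_epoch,
    best_val_loss = if (all(is.na(main$val_loss))) NA_real_ else min(main$val_loss, na.rm = TRUE),
    final_train_loss = dplyr::last(x$history$train_loss),
    phylo_rate = x$policy$phylo_rate,
    n_parameters = count_parameters(x$model)
  )
}

#' Tidy a training replicate
#'
#' @param x A `phyloaug_run` from [fit_run()].
#' @param ... Unused.
#' @return `tidy`: the test metrics tibble `(task, metric, value)`;
#'   `glance`: one row with the condition and summary metrics.
#' @export
tidy.phyloaug_run <- function(x, ...) x$metrics

#' @rdname tidy.phyloaug_run
#' @export
glance.phyloaug_run <- function(x, ...) {
  tibble::tibble(
    phylo_rate = x$condition$phylo_rate,
    finetune = x$condition$finetune,
    seed = x$condition$seed,
    mean_metric = mean(x$metrics$value),
    metric = x$metrics$metric[1L]
  )
}

#' Tidy a global importance analysis
#'
#' @param x A `gia_result` from [run_gia()].
#' @param ... Unused.
#' @return `tidy`: per-background paired predictions in long form
#'   `(background_id, position, condition, prediction)`; `glance`: the
#'   one-row summary with mean paired gaps.
#' @export
tidy.gia_result <- function(x, ...) {
  tidyr::pivot_longer(x$per_background,
                      cols = c("pred_bg", "pred_motif", "pred_scrambled"),
                      names_to = "condition", names_prefix = "pred_",
                      values_to = "prediction")
}

#' @rdname tidy.gia_result
#' @export
glance.gia_result <- function(x, ...) {
  dplyr::mutate(x$summary, motif = x$config$motif,
                scrambled = x$config$scrambled, .before = 1L)
}
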