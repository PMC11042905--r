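# ggplot2 presentation of the package's result objects and experiment
# tables.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot training curves
#'
#' @param object A `phyloaug_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss against epoch, with the
#'   fine-tuning phase marked.
#' @export
autoplot.phyloaug_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  h <- dplyr::filter(h, !is.na(.data$loss))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series,
                                  linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a global importance analysis
#'
#' @param object A `gia_result`.
#' @param ... Unused.
#' @return A ggplot of the per-background prediction distributions for the
#'   background, motif-inserted and scrambled-inserted conditions.
#' @export
autoplot.gia_result <- function(object, ...) {
  long <- tidy(object)
  long$condition <- factor(long$condition,
                           levels = c("bg", "motif", "scrambled"),
                           labels = c("background", "motif", "scrambled"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$prediction)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "model prediction",
                  title = sprintf("Global importance of %s", object$config$motif)) +
    ggplot2::theme_minimal()
}

.mean_se_plot <- function(tbl, xvar, xlab) {
  summ <- dplyr::summarise(
    dplyr::group_by(tbl, .data[[xvar]], .data$condition, .data$task),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                                     colour = .data$condition)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(x = xlab, y = "test metric", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot experiment tables
#'
#' Presentation helpers for the tidy tables returned by the experiment
#' drivers: test metric (mean +/- sd over replicates) against training
#' fraction, species subset, or augmentation rate.
#'
#' @param tbl The result tibble of [downsample_experiment()],
#'   [species_sweep()] or [rate_sweep()].
#' @param x For `plot_species_sweep`, which x-axis to use:
#'   `"total_distance"` (total evolutionary distance of the species subset)
#'   or `"n_species"`.
#' @return A ggplot.
#' @export
plot_downsample <- function(tbl) .mean_se_plot(tbl, "fraction", "fraction of training data")

#' @rdname plot_downsample
#' @export
plot_species_sweep <- function(tbl, x = c("total_distance", "n_species")) {
  x <- match.arg(x)
  tbl$condition <- "phylo_ft"
  .mean_se_plot(tbl, x, if (x == "total_distance") {
    "total evolutionary distance (substitutions/site)"
  } else "number of species")
}

#' @rdname plot_downsample
#' @export
plot_rate_sweep <- function(tbl) {
  tbl$condition <- "phylo"
  .mean_se_plot(tbl, "rate", "phylogenetic augmentation rate")
}
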