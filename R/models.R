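# Architecture families for DNA sequence-to-function models. Four builders
# are provided: a multi-layer enhancer-activity CNN ("deepstarr"), a
# single-convolution motif-level variant ("motif_deepstarr"), an additive
# per-motif-unit architecture ("explainn"), and a deeper accessibility CNN
# ("basset"). Every width, kernel, pool and dropout value is overridable in
# the spec, so scaled-down variants of the same family can be built for
# CPU-sized experiments.

.family_defaults <- list(
  deepstarr = list(conv_filters = c(256, 60, 60, 120),
                   kernels = c(7, 3, 5, 3),
                   pools = c(2, 2, 2, 2),
                   fc = c(256, 256),
                   dropout = 0.4),
  motif_deepstarr = list(conv_filters = 256,
                         kernels = 19,
                         pools = Inf, # global max pool over positions
                         fc = c(256, 256),
                         dropout = 0.4),
  explainn = list(units = 256, kernels = 19, unit_hidden = 8),
  basset = list(conv_filters = c(300, 200, 200),
                kernels = c(19, 11, 7),
                pools = c(3, 4, 4),
                fc = c(1000, 1000),
                dropout = 0.3)
)

#' Describe a model architecture
#'
#' Builds an architecture specification for [build_model()]. Defaults follow
#' the published shapes of each family; any field can be overridden (e.g.
#' fewer filters for a CPU-scale run) without leaving the family.
#'
#' @param family One of `"deepstarr"`, `"motif_deepstarr"`, `"explainn"`,
#'   `"basset"`.
#' @param input_len Model input length in bp (all sequences in a dataset
#'   share one length).
#' @param n_tasks Number of output tasks (e.g. 2 enhancer-activity
#'   regressions, or 164 binary accessibility calls).
#' @param task_type `"regression"` (linear heads, squared-error loss) or
#'   `"binary"` (sigmoid heads, cross-entropy loss).
#' @param ... Named overrides of the family defaults: `conv_filters`,
#'   `kernels`, `pools`, `fc`, `dropout`, and for `"explainn"` `units` and
#'   `unit_hidden`.
#' @return An object of class `architecture_spec`.
#' @examples
#' architecture_spec("motif_deepstarr", input_len = 249, n_tasks = 2)
#' @export
architecture_spec <- function(family = c("deepstarr", "motif_deepstarr", "explainn", "basset"),
                              input_len, n_tasks = 1L,
                              task_type = c("regression", "binary"), ...) {
  family <- match.arg(family)
  task_type <- match.arg(task_type)
  stopifnot(input_len >= 1L, n_tasks >= 1L)
  cfg <- .family_defaults[[family]]
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L) {
    rlang::abort(sprintf("unknown override(s) for family '%s': %s",
                         family, paste(bad, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  if (input_len < cfg$kernels[1L]) {
    rlang::abort(sprintf("input_len %d is shorter than the first filter (%d)",
                         input_len, cfg$kernels[1L]))
  }
  structure(c(list(family = family, input_len = as.integer(input_len),
                   n_tasks = as.integer(n_tasks), task_type = task_type), cfg),
            class = "architecture_spec")
}

.build_trunk <- function(spec) {
  layers <- list()
  L <- spec$input_len; C <- 4L
  if (spec$family == "explainn") {
    layers[[1L]] <- nn_conv1d(C, spec$units, spec$kernels[1L])
    layers[[2L]] <- nn_maxpool(Inf)
    layers[[3L]] <- nn_flatten()
    layers[[4L]] <- nn_unitwise_mlp(spec$units, spec$unit_hidden)
    layers[[5L]] <- nn_dense(spec$units, spec$n_tasks, "linear")
    return(layers)
  }
  for (i in seq_along(spec$conv_filters)) {
    k <- spec$kernels[i]
    if (L - k + 1L < 1L) {
      rlang::abort(sprintf("layer %d: input length %d shorter than kernel %d", i, L, k))
    }
    layers[[length(layers) + 1L]] <- nn_conv1d(C, spec$conv_filters[i], k)
    L <- L - k + 1L
    C <- spec$conv_filters[i]
    p <- spec$pools[i]
    pool <- if (is.finite(p)) p else L
    if (pool > 1L) {
      if (L < pool) rlang::abort(sprintf("layer %d: nothing left to pool", i))
      layers[[length(layers) + 1L]] <- nn_maxpool(if (is.finite(p)) p else Inf)
      L <- L %/% pool
    }
  }
  layers[[length(layers) + 1L]] <- nn_flatten()
  D <- L * C
  for (h in spec$fc) {
    layers[[length(layers) + 1L]] <- nn_dense(D, h, "relu", dropout = spec$dropout)
    D <- h
  }
  layers[[length(layers) + 1L]] <- nn_dense(D, spec$n_tasks, "linear")
  layers
}

#' Build a model from an architecture spec
#'
#' Instantiates the network with seeded random initial weights; the same
#' spec and seed always produce identical initial weights. The final layer
#' is linear; for binary tasks [predict.phyloaug_model()] applies the
#' sigmoid, and training uses cross-entropy on the logits.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `phyloaug_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  layers <- .build_trunk(spec)
  with_preserved_rng({
    set.seed(seed)
    layers <- lapply(layers, .init_layer)
  })
  structure(list(layers = layers, spec = spec, seed = as.integer(seed)),
            class = "phyloaug_model")
}

# Evaluate a block while leaving the caller's RNG stream untouched.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' Count trainable parameters
#'
#' @param model A `phyloaug_model`.
#' @return Integer: total number of trainable weights and biases.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "phyloaug_model"))
  sum(vapply(model$layers,
             function(l) sum(vapply(l$params, length, integer(1L))),
             numeric(1L)))
}

#' Predict from a sequence model
#'
#' @param object A `phyloaug_model`.
#' @param newdata Either a `(B, L, 4)` one-hot array or a character vector
#'   of equal-length DNA sequences (encoded internally).
#' @param type `"response"` (sigmoid-transformed for binary tasks) or
#'   `"link"` (raw linear outputs).
#' @param ... Unused.
#' @return A numeric matrix `(B, n_tasks)`.
#' @export
predict.phyloaug_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  x <- if (is.character(newdata)) encode_seqs(newdata, object$spec$input_len) else newdata
  stopifnot(length(dim(x)) == 3L, dim(x)[2L] == object$spec$input_len)
  out <- nn_forward(object, x, training = FALSE)$out
  if (type == "response" && object$spec$task_type == "binary") {
    out <- 1 / (1 + exp(-out))
  }
  out
}

#' @export
print.phyloaug_model <- function(x, ...) {
  cat(sprintf("<phyloaug_model> family=%s input_len=%d n_tasks=%d (%s), %s parameters\n",
              x$spec$family, x$spec$input_len, x$spec$n_tasks, x$spec$task_type,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Save / load a model
#'
#' Checkpoints are plain JSON: the architecture spec, the initialisation
#' seed, and every weight array written at 17 significant digits, so a
#' restored model reproduces predictions to double precision.
#'
#' @param model A `phyloaug_model`.
#' @param path Checkpoint path (JSON).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `phyloaug_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "phyloaug_model"))
  spec <- unclass(model$spec)
  payload <- list(
    spec = spec,
    seed = model$seed,
    weights = lapply(model$layers, function(l) lapply(l$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.numeric(p))
    }))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- payload$spec
  if (!is.null(sp$pools)) sp$pools <- as.numeric(sp$pools) # "Inf" round-trips as text
  fixed <- c("family", "input_len", "n_tasks", "task_type")
  overrides <- sp[setdiff(names(sp), fixed)]
  spec <- do.call(architecture_spec,
                  c(list(family = sp$family, input_len = sp$input_len,
                         n_tasks = sp$n_tasks, task_type = sp$task_type),
                    overrides))
  model <- build_model(spec, seed = payload$seed)
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      w <- payload$weights[[i]][[nm]]
      model$layers[[i]]$params[[nm]] <-
        if (length(w$dim) > 1L) array(w$data, w$dim) else as.numeric(w$data)
    }
  }
  model
}

#' Per-unit outputs of an additive model
#'
#' For the `"explainn"` family, returns the vector of per-unit scalar
#' outputs for each input; the model's prediction is exactly the final
#' linear layer applied to these (additivity holds by construction).
#'
#' @param model An `"explainn"`-family `phyloaug_model`.
#' @param newdata As in [predict.phyloaug_model()].
#' @return A `(B, units)` matrix of unit outputs.
#' @export
explainn_units <- function(model, newdata) {
  stopifnot(inherits(model, "phyloaug_model"), model$spec$family == "explainn")
  x <- if (is.character(newdata)) encode_seqs(newdata, model$spec$input_len) else newdata
  sub <- model
  sub$layers <- model$layers[seq_len(length(model$layers) - 1L)]
  nn_forward(sub, x, training = FALSE)$out
}
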