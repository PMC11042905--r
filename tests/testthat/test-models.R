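test_that("motif-level architecture has one wide convolution and the right output shape", {
  spec <- architecture_spec("motif_deepstarr", input_len = 249, n_tasks = 2)
  m <- build_model(spec, seed = 1)
  convs <- Filter(function(l) l$type == "conv1d", m$layers)
  expect_length(convs, 1L)
  expect_identical(convs[[1]]$filters, 256)
  expect_identical(convs[[1]]$kernel, 19)
  set.seed(2)
  x <- phyloaug:::encode_seqs(replicate(3, paste(
    sample(c("A", "C", "G", "T"), 249, replace = TRUE), collapse = "")))
  expect_identical(dim(predict(m, x)), c(3L, 2L))
})

test_that("additive architecture predictions are exactly linear in the unit outputs", {
  spec <- architecture_spec("explainn", input_len = 60, n_tasks = 2,
                            units = 16, kernels = 7, unit_hidden = 4)
  m <- build_model(spec, seed = 3)
  set.seed(4)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                             collapse = ""))
  u <- explainn_units(m, seqs)
  expect_identical(dim(u), c(5L, 16L))
  head_layer <- m$layers[[length(m$layers)]]
  manual <- u %*% head_layer$params$W +
    rep(head_layer$params$b, each = nrow(u))
  expect_equal(predict(m, seqs, type = "link"), manual, tolerance = 1e-12)
  # zeroing one unit's head weight shifts predictions by exactly that unit's
  # contribution (rank-1 change)
  m2 <- m
  m2$layers[[length(m2$layers)]]$params$W[3, ] <- 0
  delta <- predict(m, seqs, type = "link") - predict(m2, seqs, type = "link")
  expect_equal(delta, outer(u[, 3], head_layer$params$W[3, ]), tolerance = 1e-12)
})

test_that("all families produce finite outputs on all-N (zero) input", {
  for (fam in c("deepstarr", "motif_deepstarr", "explainn", "basset")) {
    spec <- architecture_spec(fam, input_len = 300, n_tasks = 2,
                              task_type = "binary")
    m <- build_model(spec, seed = 5)
    x <- array(0, c(2, 300, 4))
    out <- predict(m, x)
    expect_true(all(is.finite(out)))
    expect_true(all(out > 0 & out < 1)) # sigmoid heads stay in (0,1)
  }
})

test_that("parameter counts are exact and monotone in width", {
  # single dense map of 10 features to 1 output: 10 weights + 1 bias
  lin <- phyloaug:::nn_dense(10, 1)
  expect_identical(sum(vapply(lin$params, length, integer(1))), 11L)
  spec <- architecture_spec("motif_deepstarr", input_len = 50, n_tasks = 1,
                            conv_filters = 8, kernels = 5, fc = c(4, 4))
  m <- build_model(spec, seed = 1)
  # conv (5*4*8 + 8) + fc1 (8*4 + 4) + fc2 (4*4 + 4) + head (4 + 1)
  expect_identical(count_parameters(m), 168 + 36 + 20 + 5)
  wider <- build_model(architecture_spec("motif_deepstarr", input_len = 50,
                                         n_tasks = 1, conv_filters = 16,
                                         kernels = 5, fc = c(4, 4)), seed = 1)
  expect_gt(count_parameters(wider), count_parameters(m))
})

test_that("the default multi-layer CNN at input 200 lands near half a million parameters", {
  spec <- architecture_spec("deepstarr", input_len = 200, n_tasks = 1)
  n <- count_parameters(build_model(spec, seed = 1))
  expect_gte(n, 2.5e5)
  expect_lte(n, 1e6)
})

test_that("initialisation is seed-deterministic and input length is validated", {
  spec <- architecture_spec("motif_deepstarr", input_len = 40, n_tasks = 1,
                            conv_filters = 4, kernels = 5, fc = c(3, 3))
  m1 <- build_model(spec, seed = 7)
  m2 <- build_model(spec, seed = 7)
  m3 <- build_model(spec, seed = 8)
  expect_identical(phyloaug:::get_weights(m1), phyloaug:::get_weights(m2))
  expect_false(identical(phyloaug:::get_weights(m1), phyloaug:::get_weights(m3)))
  expect_error(architecture_spec("motif_deepstarr", input_len = 10),
               "shorter than the first filter")
})

test_that("checkpoints restore bit-identical predictions", {
  spec <- architecture_spec("explainn", input_len = 30, n_tasks = 1,
                            units = 6, kernels = 5, unit_hidden = 3)
  m <- build_model(spec, seed = 11)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  set.seed(12)
  seqs <- replicate(4, paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                             collapse = ""))
  expect_equal(predict(back, seqs), predict(m, seqs), tolerance = 1e-12)
  # the global-pool variant round-trips its non-finite pool marker too
  m2 <- build_model(architecture_spec("motif_deepstarr", input_len = 40,
                                      n_tasks = 1, conv_filters = 4,
                                      kernels = 5, fc = c(3, 3)), seed = 2)
  save_model(m2, path)
  expect_equal(predict(load_model(path), array(0, c(1, 40, 4))),
               predict(m2, array(0, c(1, 40, 4))), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  check_grads <- function(spec, loss) {
    m <- build_model(spec, seed = 20)
    set.seed(21)
    # jitter biases away from 0 so no ReLU sits exactly on its kink
    for (i in seq_along(m$layers)) {
      for (nm in intersect(names(m$layers[[i]]$params), c("b", "b1", "b2"))) {
        p <- m$layers[[i]]$params[[nm]]
        m$layers[[i]]$params[[nm]] <- p + stats::rnorm(length(p), sd = 0.05)
      }
    }
    x <- phyloaug:::encode_seqs(replicate(3, paste(
      sample(c("A", "C", "G", "T"), spec$input_len, replace = TRUE),
      collapse = "")))
    y <- if (loss == "bce") {
      matrix(rbinom(3 * spec$n_tasks, 1, 0.5), 3)
    } else matrix(rnorm(3 * spec$n_tasks), 3)
    fwd <- phyloaug:::nn_forward(m, x)
    gr <- phyloaug:::nn_backward(m, fwd$caches,
                                 phyloaug:::nn_loss(fwd$out, y, loss)$dlogits)
    eps <- 1e-6
    for (i in seq_along(m$layers)) {
      for (nm in names(m$layers[[i]]$params)) {
        p <- m$layers[[i]]$params[[nm]]
        for (j in sample(seq_along(p), min(6, length(p)))) {
          m2 <- m
          m2$layers[[i]]$params[[nm]][j] <- p[j] + eps
          l2 <- phyloaug:::nn_loss(phyloaug:::nn_forward(m2, x)$out, y, loss)$value
          m2$layers[[i]]$params[[nm]][j] <- p[j] - eps
          l1 <- phyloaug:::nn_loss(phyloaug:::nn_forward(m2, x)$out, y, loss)$value
          num <- (l2 - l1) / (2 * eps)
          ana <- gr[[i]][[nm]][j]
          expect_lt(abs(num - ana) / max(1e-4, abs(num) + abs(ana)), 1e-4)
        }
      }
    }
  }
  check_grads(architecture_spec("deepstarr", input_len = 40, n_tasks = 2,
                                conv_filters = c(6, 4), kernels = c(5, 3),
                                pools = c(2, 2), fc = c(5, 4), dropout = 0), "mse")
  check_grads(architecture_spec("explainn", input_len = 30, n_tasks = 1,
                                task_type = "binary", units = 5, kernels = 5,
                                unit_hidden = 3), "bce")
  check_grads(architecture_spec("motif_deepstarr", input_len = 30, n_tasks = 1,
                                conv_filters = 6, kernels = 7, fc = c(5, 4),
                                dropout = 0), "mse")
})
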