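test_that("model builds respect head contracts and seed determinism", {
  arch <- architecture_spec("tiny", 3, "regression", side = 32)
  m <- build_model(arch, seed = 5)
  x <- array(runif(32 * 32 * 4 * 3), c(32, 32, 4, 3))
  est <- predict(m, x)
  expect_length(est, 4)
  expect_true(all(est >= 1 & est <= 10))

  mc <- build_model(architecture_spec("tiny", 3, "classification",
                                      side = 32), seed = 5)
  probs <- predict(mc, x)
  expect_equal(dim(probs), c(4, 10))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)

  m2 <- build_model(arch, seed = 5)
  expect_equal(m$layers, m2$layers)
  m3 <- build_model(arch, seed = 6)
  expect_false(identical(m$layers, m3$layers))

  expect_error(architecture_spec("tiny", in_channels = 4), "3 or 9")
})

test_that("the vgg-style profiles expose 8 and 13 freezable conv layers", {
  a11 <- architecture_spec("vgg11_like", 3, "regression", side = 32,
                           fc_widths = c(32L, 32L))
  expect_equal(build_model(a11, 1)$n_conv, 8)
  a16 <- architecture_spec("vgg16_like", 9, "regression", side = 32,
                           fc_widths = c(32L, 32L))
  m16 <- build_model(a16, 1)
  expect_equal(m16$n_conv, 13)
  # the study's freezing grid 0/4/8/12 is valid on this profile
  for (n in c(0L, 4L, 8L, 12L)) {
    expect_silent(freeze_layers(m16, n))
  }
})

test_that("training loss follows the mean-of-squared-differences formula", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(2, 1), 1)
  expect_equal(mse_loss(c(1, 4), c(2, 2)), 2.5)
  expect_error(mse_loss(1:3, 1:2), "equal length")
})

test_that("one epoch over a sub-batch dataset processes a single partial batch", {
  arch <- architecture_spec("tiny", 3, "regression", side = 32, dropout_p = 0)
  model <- build_model(arch, seed = 1)
  x <- array(runif(32 * 32 * 8 * 3), c(32, 32, 8, 3))
  y <- runif(8, 1, 10)
  fit <- train_model(model, list(x = x, y = y),
                     config = train_config(batch_size = 32L, epochs = 1L,
                                           dropout_p = 0, seed = 2))
  expect_equal(nrow(fit$history), 1)
  expect_named(fit$history, c("epoch", "loss", "train_acc", "val_acc"))
})

test_that("a vanishing learning rate leaves the weights untouched", {
  arch <- architecture_spec("tiny", 3, "regression", side = 32, dropout_p = 0)
  model <- build_model(arch, seed = 3)
  x <- array(runif(32 * 32 * 6 * 3), c(32, 32, 6, 3))
  y <- runif(6, 1, 10)
  fit <- train_model(model, list(x = x, y = y),
                     config = train_config(learning_rate = 1e-300,
                                           epochs = 2L, dropout_p = 0,
                                           seed = 2))
  for (i in seq_along(model$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(model$layers[[i]][[nm]])) {
        expect_equal(fit$model$layers[[i]][[nm]], model$layers[[i]][[nm]],
                     tolerance = 1e-200)
      }
    }
  }
})

test_that("training descends on a learnable noiseless subset", {
  mf <- build_dataset(20, conditions = neutral_condition(),
                      rotations = "front", seed = 41, size = 32,
                      noise_sigma = 0)
  spec <- input_tensor_spec("LAB", 32)
  data <- prepare_tensors(mf, spec)
  model <- build_model(architecture_spec("tiny", 3, "regression",
                                         side = 32), seed = 7)
  fit <- train_model(model, data,
                     config = train_config(learning_rate = 1e-3,
                                           epochs = 15L, seed = 8))
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  # smoothed curve decreases over halves
  expect_lt(mean(tail(fit$history$loss, 5)), mean(head(fit$history$loss, 5)))
})

test_that("training histories are reproducible given one seed", {
  mf <- build_dataset(6, conditions = lighting_conditions()[1:2, ],
                      rotations = "front", seed = 51, size = 32)
  data <- prepare_tensors(mf, input_tensor_spec("LAB", 32))
  run <- function() {
    model <- build_model(architecture_spec("tiny", 3, "regression",
                                           side = 32), seed = 9)
    train_model(model, data, config = train_config(learning_rate = 1e-3,
                                                   epochs = 3L, seed = 10))
  }
  expect_equal(run()$history, run()$history, tolerance = 1e-12)
})

test_that("training rejects mismatched losses and empty splits", {
  model <- build_model(architecture_spec("tiny", 3, "regression",
                                         side = 32), seed = 1)
  x <- array(runif(32 * 32 * 4 * 3), c(32, 32, 4, 3))
  expect_error(
    train_model(model, list(x = x, y = runif(4, 1, 10)),
                config = train_config(loss = "cross_entropy")),
    "does not match"
  )
  expect_error(
    train_model(model, list(x = x[, , 0, , drop = FALSE], y = numeric(0))),
    "empty"
  )
})

test_that("freezing excludes early conv layers from updates, head stays live", {
  arch <- architecture_spec("tiny", 3, "regression", side = 32, dropout_p = 0)
  model <- build_model(arch, seed = 11)
  expect_error(freeze_layers(model, model$n_conv + 1), "n_frozen")

  n_full <- monktone:::n_trainable_tensors(model)
  expect_equal(monktone:::n_trainable_tensors(freeze_layers(model, 0)),
               n_full)
  n1 <- monktone:::n_trainable_tensors(freeze_layers(model, 1))
  n3 <- monktone:::n_trainable_tensors(freeze_layers(model, 3))
  expect_lt(n3, n1)
  expect_lt(n1, n_full)

  frozen <- freeze_layers(model, model$n_conv)
  x <- array(runif(32 * 32 * 6 * 3), c(32, 32, 6, 3))
  fit <- train_model(frozen, list(x = x, y = runif(6, 1, 10)),
                     config = train_config(learning_rate = 0.01,
                                           epochs = 1L, dropout_p = 0,
                                           seed = 3))
  for (i in seq_along(frozen$layers)) {
    layer <- frozen$layers[[i]]
    if (!is.null(layer$conv_index) && layer$type == "conv") {
      expect_identical(fit$model$layers[[i]]$W, layer$W)
    }
    if (layer$type == "dense") {
      expect_false(identical(fit$model$layers[[i]]$W, layer$W))
    }
  }
})

test_that("fine-tuning demands one light type and zero epochs is a no-op", {
  mf <- build_dataset(4, conditions = lighting_conditions()[c(1, 4), ],
                      rotations = "front", seed = 61, size = 32)
  model <- build_model(architecture_spec("tiny", 3, "regression",
                                         side = 32), seed = 1)
  expect_error(fine_tune(model, mf, train_config()), "single light_type")

  one_light <- dplyr::filter(mf, light_type == "fluorescent_cool")
  ft <- fine_tune(model, one_light,
                  train_config(learning_rate = 1e-3, epochs = 0L, seed = 2),
                  spec = input_tensor_spec("LAB", 32))
  expect_equal(nrow(ft$history), 0)
  for (i in seq_along(model$layers)) {
    if (!is.null(model$layers[[i]]$W)) {
      expect_equal(ft$model$layers[[i]]$W, model$layers[[i]]$W)
    }
  }
  # the fine-tuning config reduces the learning rate tenfold by default
  expect_equal(ft$config$learning_rate, 1e-4)
})

test_that("regression outperforms classification at threshold 0.5 on the benchmark", {
  verdict <- majority_verdict(1:3, function(s) {
    cfg_r <- ablation_config(s)
    cfg_c <- ablation_config(s)
    cfg_c$model$head <- "classification"
    acc05(run_experiment(cfg_r, quiet = TRUE)) >=
      acc05(run_experiment(cfg_c, quiet = TRUE))
  })
  expect_true(verdict)
})
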