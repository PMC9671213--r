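make_training_fixture <- function(n_samples = 32L, n_snps = 32L, seed = 5L,
                                  mask_ratio = 0.1) {
  gm <- tiny_panel(n_samples, n_snps, seed = seed)
  m <- mask_random(gm, mask_ratio, seed = seed + 1L)
  list(gm = gm, input = encode_onehot(m$masked), target = encode_onehot(gm),
       plan = m$plan, masked = m$masked)
}

test_that("training config validates its fields", {
  expect_error(training_config(epochs = 0), "positive")
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(alpha = -1), "alpha")
  expect_error(training_config(loss_mode = "bogus"))
})

test_that("training is bit-reproducible under a fixed seed", {
  fx <- make_training_fixture(16, 16, seed = 2)
  cfg <- training_config(epochs = 3, seed = 11)
  f1 <- train(build_model(model_spec(16), seed = 4), fx$input, fx$target,
              config = cfg)
  f2 <- train(build_model(model_spec(16), seed = 4), fx$input, fx$target,
              config = cfg)
  expect_identical(f1$model$params, f2$model$params)
  cols <- setdiff(names(f1$history), "seconds")
  expect_identical(f1$history[cols], f2$history[cols])
})

test_that("averaged mode with k = 1 reproduces per-batch training exactly", {
  fx <- make_training_fixture(48, 16, seed = 3)
  cfg_pb <- training_config(epochs = 2, seed = 7, loss_mode = "per_batch")
  cfg_k1 <- training_config(epochs = 2, seed = 7, loss_mode = "averaged_k",
                            k = 1)
  f_pb <- train(build_model(model_spec(16), seed = 1), fx$input, fx$target,
                config = cfg_pb)
  f_k1 <- train(build_model(model_spec(16), seed = 1), fx$input, fx$target,
                config = cfg_k1)
  expect_identical(f_pb$model$params, f_k1$model$params)
})

test_that("accumulated gradients differ from per-batch stepping at k = 2", {
  fx <- make_training_fixture(64, 16, seed = 4)
  f_pb <- train(build_model(model_spec(16), seed = 1), fx$input, fx$target,
                config = training_config(epochs = 2, seed = 7))
  f_k2 <- train(build_model(model_spec(16), seed = 1), fx$input, fx$target,
                config = training_config(epochs = 2, seed = 7,
                                         loss_mode = "averaged_k", k = 2))
  expect_false(identical(f_pb$model$params, f_k2$model$params))
})

test_that("smoothed training loss decreases on the tiny fixture", {
  fx <- make_training_fixture(32, 32, seed = 5)
  fit <- train(build_model(model_spec(32), seed = 2), fx$input, fx$target,
               config = training_config(epochs = 24, seed = 3))
  loss <- fit$history$train_loss
  smooth20 <- mean(loss[20:24])
  expect_lt(smooth20, loss[1])
  expect_identical(nrow(fit$history), 24L)
  acc <- fit$history$train_accuracy
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("validation metrics are recorded when a validation set is given", {
  fx <- make_training_fixture(24, 16, seed = 6)
  vx <- make_training_fixture(8, 16, seed = 7)
  fit <- train(build_model(model_spec(16), seed = 1), fx$input, fx$target,
               vx$input, vx$target, training_config(epochs = 2, seed = 1))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_true(all(fit$history$val_accuracy >= 0 &
                  fit$history$val_accuracy <= 1))
})

test_that("accuracy is 1 against targets the model itself produces", {
  fx <- make_training_fixture(10, 16, seed = 8)
  model <- build_model(model_spec(16), seed = 9)
  calls <- decode_calls(forward(model, fx$input))
  self_target <- encode_onehot(calls)
  expect_equal(evaluate_accuracy(model, fx$input, self_target), 1)
})

test_that("an untrained model scores near chance on balanced classes", {
  set.seed(21)
  # balanced three-class genotypes, no structure to learn
  gm <- genotype_matrix(matrix(sample(0:2, 40 * 16, replace = TRUE), 40, 16))
  enc <- encode_onehot(gm)
  model <- build_model(model_spec(16), seed = 22)
  acc <- evaluate_accuracy(model, enc, enc)
  # binomial error around 1/3 over 640 positions
  expect_gt(acc, 1 / 3 - 4 * sqrt(1 / 3 * 2 / 3 / 640))
  expect_lt(acc, 1 / 3 + 4 * sqrt(1 / 3 * 2 / 3 / 640))
})

test_that("accuracy is invariant to partitioning the evaluation set", {
  fx <- make_training_fixture(20, 16, seed = 10)
  model <- build_model(model_spec(16), seed = 3)
  whole <- evaluate_accuracy(model, fx$input, fx$target)
  half1 <- evaluate_accuracy(
    model,
    dcimpute:::new_encoded_tensor(unclass(fx$input)[1:10, , , drop = FALSE],
                                  "diploid"),
    dcimpute:::new_encoded_tensor(unclass(fx$target)[1:10, , , drop = FALSE],
                                  "diploid")
  )
  half2 <- evaluate_accuracy(
    model,
    dcimpute:::new_encoded_tensor(unclass(fx$input)[11:20, , , drop = FALSE],
                                  "diploid"),
    dcimpute:::new_encoded_tensor(unclass(fx$target)[11:20, , , drop = FALSE],
                                  "diploid")
  )
  # all samples carry the same number of scored positions here
  expect_equal(whole, mean(c(half1, half2)), tolerance = 1e-12)
})

test_that("imputation preserves observed entries and fills only missing", {
  fx <- make_training_fixture(12, 16, seed = 12, mask_ratio = 0.25)
  model <- build_model(model_spec(16), seed = 5)
  imp <- impute(model, fx$masked, preserve_observed = TRUE)
  obs <- !is.na(unclass(fx$masked))
  expect_identical(unclass(imp$calls)[obs], unclass(fx$masked)[obs])
  expect_false(anyNA(unclass(imp$calls)))
  # a missing-free matrix passes through unchanged
  imp2 <- impute(model, fx$gm, preserve_observed = TRUE)
  expect_identical(gt_values(imp2$calls), gt_values(fx$gm))
})

test_that("an all-missing sample still yields valid posterior simplexes", {
  gm <- genotype_matrix(matrix(NA_integer_, 1, 16))
  model <- build_model(model_spec(16), seed = 5)
  imp <- impute(model, gm)
  sums <- apply(unclass(imp$posterior), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_false(anyNA(unclass(imp$calls)))
  expect_true(all(imp$dosage >= 0 & imp$dosage <= 2))
})

test_that("imputing with a mismatched SNP count points at truncation", {
  gm <- tiny_panel(4, 20, seed = 1)
  model <- build_model(model_spec(16), seed = 1)
  expect_error(impute(model, gm), "truncate_to_multiple")
})
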