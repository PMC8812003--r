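fake_record <- function(L, id = "r") {
  s <- secondary_structure(L)
  q <- rna_sequence(paste(rep("A", L), collapse = ""), id = id)
  structure_record(q, s)
}

test_that("batching isolates long records and caps batch size", {
  recs <- lapply(c(40L, 45L, 1200L, 50L), fake_record)
  cfg <- train_config(max_batch = 16L)
  set.seed(1)
  batches <- make_batches(recs, cfg)
  sizes <- lengths(batches)
  long_batch <- which(vapply(batches, function(b) 3L %in% b, logical(1)))
  expect_equal(sizes[long_batch], 1L)
  expect_equal(sort(unlist(batches)), 1:4)

  recs20 <- lapply(rep(30L, 20L), fake_record)
  set.seed(1)
  sizes20 <- sort(lengths(make_batches(recs20, cfg)), decreasing = TRUE)
  expect_equal(sizes20, c(16L, 4L))

  set.seed(5); b1 <- make_batches(recs20, cfg)
  set.seed(5); b2 <- make_batches(recs20, cfg)
  expect_identical(b1, b2)
  expect_error(make_batches(list(), cfg), "empty dataset")
})

test_that("padded cells are excluded from the loss by the mask", {
  set.seed(81)
  rec <- make_dataset(1, synthetic_config(length_range = c(12, 16)))[[1]]
  e <- list(X = unclass(encode_sequence(rec$sequence)),
            T_ = encode_target(rec$structure),
            V = valid_mask(rec$sequence))
  p <- pairfold:::pad_sample(e$X, e$T_, e$V, 24L)
  L <- rec$structure$length
  expect_true(all(p$X[(L + 1):24, , 8] == 1))
  expect_false(any(p$V[(L + 1):24, ]))
  # perturbing scores on padded cells leaves the loss unchanged
  Y <- matrix(rnorm(24 * 24), 24, 24)
  base <- masked_mse_loss(Y, p$T_, p$V)
  Y[24, 1] <- Y[24, 1] + 1e6
  Y[1, 24] <- -1e6
  expect_identical(masked_mse_loss(Y, p$T_, p$V), base)
})

test_that("variant presets encode the published training regimes", {
  full <- variant_preset("full")
  expect_equal(full$model$M, 2L)
  expect_equal(full$model$N, 2L)
  expect_equal(full$train$epochs, 30L)
  expect_null(full$train$max_train_length)
  short <- variant_preset("short")
  expect_equal(c(short$model$M, short$model$N, short$train$epochs,
                 short$train$max_train_length), c(2L, 2L, 400L, 600L))
  big <- variant_preset("short-big")
  expect_equal(c(big$model$M, big$model$N, big$train$epochs,
                 big$train$max_train_length), c(10L, 2L, 45L, 600L))
})

test_that("training reduces the loss and is seed-deterministic", {
  recs <- make_dataset(2, synthetic_config(length_range = c(15, 20)), seed = 31)
  mc <- model_config(M = 1, N = 2, channels = 8, seed = 13)
  tc <- train_config(epochs = 40L, max_steps = 40L, seed = 13)
  fit1 <- train(recs, mc, tc)
  expect_lt(fit1$history$loss[fit1$steps], fit1$history$loss[1])
  fit2 <- train(recs, mc, tc)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_equal(fit1$model$params, fit2$model$params, tolerance = 1e-14)
})

test_that("the length filter drops long records before training", {
  recs <- c(make_dataset(2, synthetic_config(length_range = c(15, 20)), seed = 32),
            lapply(700L, fake_record))
  tc <- train_config(epochs = 1L, max_steps = 1L, seed = 1,
                     max_train_length = 600L)
  fit <- train(recs, model_config(M = 0, N = 1, channels = 4), tc)
  expect_equal(fit$steps, 1L)
  expect_error(train(lapply(700L, fake_record),
                     model_config(M = 0, N = 1, channels = 4), tc),
               "length filter")
})

test_that("mix prediction dispatches on the length threshold inclusively", {
  m_short <- build_model(model_config(M = 0, N = 1, channels = 4, seed = 1))
  m_long <- build_model(model_config(M = 0, N = 1, channels = 4, seed = 2))
  q30 <- rna_sequence(paste(rep("A", 30), collapse = ""))
  q31 <- rna_sequence(paste(rep("A", 31), collapse = ""))
  y30 <- mix_predict(q30, m_short, m_long, threshold = 30L)
  y31 <- mix_predict(q31, m_short, m_long, threshold = 30L)
  ref30 <- forward(m_short, encode_sequence(q30))
  ref31 <- forward(m_long, encode_sequence(q31))
  expect_equal(y30, ref30[[length(ref30)]])
  expect_equal(y31, ref31[[length(ref31)]])
  # and the short model differs from the long one on the same input
  alt30 <- forward(m_long, encode_sequence(q30))
  expect_false(isTRUE(all.equal(y30, alt30[[length(alt30)]])))
  expect_error(mix_predict(q30, NULL, m_long), "both models")
})

test_that("training history can monitor F1 and stop early", {
  recs <- make_dataset(2, synthetic_config(length_range = c(12, 16)), seed = 33)
  tc <- train_config(epochs = 100L, max_steps = 30L, seed = 3,
                     eval_every = 10L, stop_f1 = 2)  # unreachable: never stops
  fit <- train(recs, model_config(M = 0, N = 1, channels = 4, seed = 3), tc)
  expect_equal(fit$steps, 30L)
  expect_equal(sum(!is.na(fit$history$f1)), 3L)
})
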