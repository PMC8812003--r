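small_cfg <- function(...) model_config(channels = 6L, seed = 99L, ...)

test_that("model construction is seeded and monotone in M", {
  m1 <- build_model(small_cfg(M = 2, N = 2))
  m2 <- build_model(small_cfg(M = 2, N = 2))
  expect_identical(m1$params, m2$params)
  big <- build_model(small_cfg(M = 10, N = 2))
  expect_gt(n_parameters(big), n_parameters(m1))
  # exactly one set of shared-block weights exists, whatever N is
  shared <- grep("^shared\\.conv", names(m1$params), value = TRUE)
  expect_equal(sort(shared), c("shared.convA.W", "shared.convB.W"))
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(N = 0), "N must be")
  expect_error(model_config(M = -1), "M must be")
  expect_error(model_config(kernel = 2), "odd")
  expect_error(model_config(channels = 0), "channels")
})

test_that("forward returns N deterministic score matrices for any length", {
  m <- build_model(small_cfg(M = 1, N = 2))
  we <- worked_example()
  X <- encode_sequence(we$q)
  Ys <- forward(m, X)
  expect_length(Ys, 2L)
  expect_equal(dim(Ys[[1]]), c(31L, 31L))
  expect_identical(Ys, forward(m, X))  # bitwise determinism in eval mode

  # fully convolutional: the same instance accepts other lengths
  q2 <- rna_sequence(strrep("GACU", 5))
  Y2 <- forward(m, encode_sequence(q2))
  expect_equal(dim(Y2[[2]]), c(20L, 20L))

  bad <- unclass(X); bad[1, 5, ] <- 0
  expect_error(forward(m, bad), "one-hot")
})

test_that("the loss matches its definition exactly", {
  we <- worked_example()
  T_ <- encode_target(we$s)
  V <- valid_mask(we$q)
  # zero residual
  expect_equal(masked_mse_loss(list(T_, T_), T_, V), 0)
  # one cell off by 1 in one of N=2 passes: 1/(2m)
  Y <- T_
  cell <- which(V & upper.tri(V), arr.ind = TRUE)[1, ]
  Y[cell[1], cell[2]] <- Y[cell[1], cell[2]] + 1
  expect_equal(masked_mse_loss(list(Y, T_), T_, V), 1 / (2 * sum(V)))
  expect_error(masked_mse_loss(list(T_), T_, matrix(FALSE, 31, 31)), "empty")
})

test_that("the loss agrees with an independent double-loop summation", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- random_scored_instance(8L)
    T_ <- encode_target(random_pair_set(8L))
    Ys <- list(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8))
    expect_equal(masked_mse_loss(Ys, T_, inst$V), brute_loss(Ys, T_, inst$V))
  }
})

test_that("cells outside the valid mask never contribute to the loss", {
  set.seed(32)
  inst <- random_scored_instance(12L)
  T_ <- encode_target(random_pair_set(12L))
  Y <- matrix(rnorm(144), 12, 12)
  base <- masked_mse_loss(Y, T_, inst$V)
  outside <- which(!inst$V)
  for (cell in sample(outside, 10)) {
    Y2 <- Y
    Y2[cell] <- Y2[cell] + rnorm(1, sd = 100)
    expect_identical(masked_mse_loss(Y2, T_, inst$V), base)
  }
})

test_that("the training loss equals the standalone loss on the network output", {
  set.seed(33)
  rec <- make_dataset(1, synthetic_config(length_range = c(15, 20)))[[1]]
  m <- build_model(small_cfg(M = 1, N = 2))
  X <- unclass(encode_sequence(rec$sequence))
  T_ <- encode_target(rec$structure)
  V <- valid_mask(rec$sequence)
  res <- pairfold:::cpp_net_run(m$params, m$running, unclass(m$cfg),
                                list(X), list(T_), list(V * 1),
                                train = TRUE, want_grad = FALSE)
  Ys <- lapply(res$outputs, `[[`, 1L)
  expect_equal(res$loss, masked_mse_loss(Ys, T_, V))
})

test_that("analytic gradients match finite differences", {
  set.seed(34)
  q <- rna_sequence("GGGAAAACCCGAUC")
  X <- unclass(encode_sequence(q))
  T_ <- encode_target(secondary_structure(14, rbind(c(1, 10), c(2, 9), c(3, 8))))
  V <- valid_mask(q) * 1
  m <- build_model(model_config(M = 1, N = 2, channels = 3, seed = 5))
  run <- function(params, grad = FALSE) {
    pairfold:::cpp_net_run(params, m$running, unclass(m$cfg), list(X),
                           list(T_), list(V), TRUE, grad)
  }
  base <- run(m$params, grad = TRUE)
  for (nm in names(m$params)) {
    g <- as.numeric(base$grads[[nm]])
    for (i in sample(length(m$params[[nm]]), min(2, length(m$params[[nm]])))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + 1e-6
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - 1e-6
      fd <- (run(pp)$loss - run(pm)$loss) / 2e-6
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip through JSON", {
  m <- build_model(small_cfg(M = 1, N = 2))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$cfg, m$cfg)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  we <- worked_example()
  X <- encode_sequence(we$q)
  expect_equal(forward(m2, X), forward(m, X), tolerance = 1e-10)
})
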