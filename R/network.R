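#' Score-network configuration
#'
#' The network maps the `L x L x 8` pairwise relation tensor to `N`
#' successive `L x L` score matrices. It starts with two conv blocks,
#' followed by `M` residual blocks with distinct weights, then a single
#' residual block with shared weights applied `N` times like a recurrent
#' model; a shared readout (1x1 conv block plus a 1x1 convolution with one
#' output channel) is applied to the output of every shared pass. Every
#' conv block is convolution + batch normalization + LeakyReLU, all with
#' `channels` output channels, with padding chosen so the spatial size is
#' preserved.
#'
#' @param M Number of distinct residual blocks (>= 0).
#' @param N Number of shared-block iterations (>= 1).
#' @param channels Feature width of every conv block (default 32).
#' @param kernel Spatial kernel size of the non-readout convolutions
#'   (odd, default 3).
#' @param leaky_slope Negative slope of the LeakyReLU activations.
#' @param bn_eps,bn_momentum Batch-normalization stabilizer and
#'   running-statistics momentum.
#' @param seed Seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(M = 2L, N = 2L, channels = 32L, kernel = 3L,
                         leaky_slope = 0.01, bn_eps = 1e-5,
                         bn_momentum = 0.1, seed = 1L) {
  M <- as.integer(M); N <- as.integer(N)
  channels <- as.integer(channels); kernel <- as.integer(kernel)
  if (is.na(M) || M < 0L) stop("M must be >= 0", call. = FALSE)
  if (is.na(N) || N < 1L) stop("N must be >= 1", call. = FALSE)
  if (is.na(channels) || channels < 1L) stop("channels must be >= 1", call. = FALSE)
  if (is.na(kernel) || kernel < 1L || kernel %% 2L == 0L) {
    stop("kernel must be an odd positive integer", call. = FALSE)
  }
  structure(list(M = M, N = N, channels = channels, kernel = kernel,
                 leaky_slope = leaky_slope, bn_eps = bn_eps,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "model_config")
}

# He-style initialization for one conv kernel
init_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

bn_param_names <- function(cfg) {
  nm <- c("bn1", "bn2")
  if (cfg$M > 0L) nm <- c(nm, paste0("res", seq_len(cfg$M), ".bnA"),
                          paste0("res", seq_len(cfg$M), ".bnB"))
  c(nm, "shared.bnA", "shared.bnB", "read.bn")
}

#' Build a score network
#'
#' Allocates and seeds all parameters of the architecture described in
#' [model_config()]. Convolutions carry no bias (batch normalization
#' follows each of them); the final readout convolution has a scalar bias.
#'
#' @param cfg A [model_config()].
#' @return A list of class `score_network` with elements `cfg`, `params`
#'   (named list of numeric arrays) and `running` (batch-norm running
#'   statistics).
#' @examples
#' m <- build_model(model_config(M = 1, N = 2, channels = 8))
#' n_parameters(m)
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$seed)
  C <- cfg$channels; k <- cfg$kernel
  params <- list()
  params[["conv1.W"]] <- init_conv(k, 8L, C)
  params[["conv2.W"]] <- init_conv(k, C, C)
  for (m in seq_len(cfg$M)) {
    params[[sprintf("res%d.convA.W", m)]] <- init_conv(k, C, C)
    params[[sprintf("res%d.convB.W", m)]] <- init_conv(k, C, C)
  }
  params[["shared.convA.W"]] <- init_conv(k, C, C)
  params[["shared.convB.W"]] <- init_conv(k, C, C)
  params[["read.conv1.W"]] <- init_conv(1L, C, C)
  params[["read.conv2.W"]] <- init_conv(1L, C, 1L)
  params[["read.conv2.b"]] <- 0
  running <- list()
  for (nm in bn_param_names(cfg)) {
    params[[paste0(nm, ".gamma")]] <- rep(1, C)
    params[[paste0(nm, ".beta")]] <- rep(0, C)
    running[[paste0(nm, ".mean")]] <- rep(0, C)
    running[[paste0(nm, ".var")]] <- rep(1, C)
  }
  structure(list(cfg = cfg, params = params, running = running),
            class = "score_network")
}

#' Count trainable parameters
#' @param model A `score_network`.
#' @return Integer number of trainable scalars.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' @export
print.score_network <- function(x, ...) {
  cat(sprintf("<score_network> M = %d, N = %d, %d channels, %dx%d kernel, %d parameters\n",
              x$cfg$M, x$cfg$N, x$cfg$channels, x$cfg$kernel, x$cfg$kernel,
              n_parameters(x)))
  invisible(x)
}

check_one_hot <- function(X) {
  d <- dim(X)
  if (length(d) != 3L || d[1L] != d[2L] || d[3L] != 8L) {
    stop("input must be an L x L x 8 array", call. = FALSE)
  }
  s <- X[, , 1L] + X[, , 2L] + X[, , 3L] + X[, , 4L] +
    X[, , 5L] + X[, , 6L] + X[, , 7L] + X[, , 8L]
  if (any(abs(s - 1) > 1e-9) || any(X != 0 & X != 1)) {
    stop("input tensor is not one-hot: every cell must have exactly one active channel",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the network on one encoded sequence
#'
#' Evaluation-mode forward pass (deterministic: batch-norm uses the stored
#' running statistics). The network is fully convolutional, so one model
#' instance accepts any sequence length.
#'
#' @param model A `score_network`.
#' @param X An `L x L x 8` one-hot array from [encode_sequence()].
#' @return A list of `N` numeric `L x L` score matrices, one per shared
#'   pass (the last one, `Y_N`, is the network's final output).
#' @export
forward <- function(model, X) {
  stopifnot(inherits(model, "score_network"))
  check_one_hot(X)
  res <- cpp_net_run(model$params, model$running, unclass(model$cfg),
                     list(unclass(X)), list(), list(),
                     train = FALSE, want_grad = FALSE)
  lapply(res$outputs, function(per_b) per_b[[1L]])
}

#' Masked mean-squared-error loss
#'
#' The training loss of the score network:
#' `l = (1/N) * sum_n l_n` with
#' `l_n = (1/|V|) * sum_{(i,j) in V} (y_ij^(n) - t_ij)^2`, where `V` is the
#' set of valid cells ([valid_mask()]). Cells outside `V` (impossible
#' pairings) never contribute.
#'
#' @param Ys A list of `N` score matrices (or a single matrix).
#' @param T_ The binary target matrix from [encode_target()].
#' @param V The logical valid-cell mask from [valid_mask()].
#' @return A non-negative scalar.
#' @export
masked_mse_loss <- function(Ys, T_, V) {
  if (is.matrix(Ys)) Ys <- list(Ys)
  if (!length(Ys)) stop("need at least one score matrix", call. = FALSE)
  nv <- sum(V)
  if (nv == 0) stop("the valid mask is empty", call. = FALSE)
  per_n <- vapply(Ys, function(Y) {
    if (!all(dim(Y) == dim(T_))) stop("shape mismatch between Y and T", call. = FALSE)
    sum(((Y - T_)[V])^2) / nv
  }, numeric(1))
  mean(per_n)
}

#' Save a model checkpoint
#'
#' Writes a versioned JSON checkpoint containing the configuration, all
#' parameters (with their array dimensions) and the batch-norm running
#' statistics. Plain text, portable across platforms.
#'
#' @param model A `score_network`.
#' @param path Output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "score_network"))
  payload <- list(
    format = "pairfold-checkpoint",
    version = 1L,
    cfg = unclass(model$cfg),
    params = lapply(model$params, function(p) {
      list(dim = if (is.null(dim(p))) length(p) else dim(p), data = as.numeric(p))
    }),
    running = model$running
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path to a checkpoint written by [save_model()].
#' @return A `score_network`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "pairfold-checkpoint")) {
    stop(sprintf("%s is not a model checkpoint", path), call. = FALSE)
  }
  cfg <- do.call(model_config, payload$cfg[c("M", "N", "channels", "kernel",
                                             "leaky_slope", "bn_eps",
                                             "bn_momentum", "seed")])
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) > 1L) array(p$data, dim = p$dim) else p$data
  })
  running <- lapply(payload$running, as.numeric)
  structure(list(cfg = cfg, params = params, running = running),
            class = "score_network")
}
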