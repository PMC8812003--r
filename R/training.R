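#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.005).
#' @param epochs Number of passes over the dataset (ignored if
#'   `max_steps` is reached first).
#' @param max_steps Optional cap on optimization steps (mini-batch
#'   updates); `NULL` means no cap.
#' @param max_batch Largest mini-batch size (default 16).
#' @param solo_length_threshold Sequences longer than this many nt are
#'   always alone in their mini-batch (default 1000).
#' @param max_train_length Optional length filter: records longer than
#'   this are dropped from training (e.g. 600 for the short-sequence
#'   presets).
#' @param seed Seed controlling shuffling (parameter initialization is
#'   seeded by [model_config()]).
#' @param shuffle Reshuffle records every epoch (default `TRUE`).
#' @param eval_every Evaluate mean training-set F1 (argmax decoding of the
#'   final pass) every this many steps; `NULL` disables monitoring.
#' @param stop_f1 Stop early once the monitored mean F1 reaches this value
#'   (requires `eval_every`).
#' @param checkpoint_every Write a checkpoint every this many steps into
#'   `checkpoint_dir`; `NULL` disables.
#' @param checkpoint_dir Directory for checkpoints.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, epochs = 30L,
                         max_steps = NULL, max_batch = 16L,
                         solo_length_threshold = 1000L,
                         max_train_length = NULL, seed = 1L,
                         shuffle = TRUE, eval_every = NULL, stop_f1 = NULL,
                         checkpoint_every = NULL, checkpoint_dir = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  max_batch <- as.integer(max_batch)
  if (is.na(max_batch) || max_batch < 1L) stop("max_batch must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps),
                 max_batch = max_batch,
                 solo_length_threshold = as.integer(solo_length_threshold),
                 max_train_length = if (is.null(max_train_length)) NULL else as.integer(max_train_length),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 eval_every = eval_every, stop_f1 = stop_f1,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Model-variant presets
#'
#' The three standard training regimes: `"full"` (M = 2, N = 2, 30
#' epochs, all lengths), `"short"` (M = 2, N = 2, 400 epochs, only
#' sequences shorter than 600 nt) and `"short-big"` (M = 10, N = 2, 45
#' epochs, shorter than 600 nt). The length-600 ensemble dispatches
#' sequences of L <= 600 to the short-sequence model and everything longer
#' to the full model; see [mix_predict()].
#'
#' @param name One of `"full"`, `"short"`, `"short-big"`.
#' @param seed Seed forwarded to both configs.
#' @return A list with `model` (a [model_config()]) and `train` (a
#'   [train_config()]).
#' @export
variant_preset <- function(name = c("full", "short", "short-big"), seed = 1L) {
  name <- match.arg(name)
  spec <- switch(name,
    "full" = list(M = 2L, epochs = 30L, max_len = NULL),
    "short" = list(M = 2L, epochs = 400L, max_len = 600L),
    "short-big" = list(M = 10L, epochs = 45L, max_len = 600L)
  )
  list(name = name,
       model = model_config(M = spec$M, N = 2L, seed = seed),
       train = train_config(epochs = spec$epochs,
                            max_train_length = spec$max_len, seed = seed))
}

#' Group records into length-aware mini-batches
#'
#' Records are (optionally) shuffled with the configured seed and grouped
#' in order into batches of at most `max_batch`; any record longer than
#' `solo_length_threshold` nt forms a batch on its own. Within a batch,
#' samples are later padded to the batch maximum length; padded cells are
#' outside every sample's valid mask, so they never contribute to the
#' loss.
#'
#' @param records A list of `structure_record` objects.
#' @param cfg A [train_config()].
#' @param shuffle Override `cfg$shuffle` (used internally across epochs).
#' @return A list of integer index vectors into `records`.
#' @export
make_batches <- function(records, cfg = train_config(), shuffle = cfg$shuffle) {
  if (!length(records)) stop("empty dataset", call. = FALSE)
  lens <- vapply(records, function(r) r$structure$length, integer(1))
  ord <- seq_along(records)
  if (shuffle) ord <- sample(ord)
  solo <- ord[lens[ord] > cfg$solo_length_threshold]
  rest <- ord[lens[ord] <= cfg$solo_length_threshold]
  batches <- lapply(solo, function(i) i)
  if (length(rest)) {
    chunks <- split(rest, ceiling(seq_along(rest) / cfg$max_batch))
    batches <- c(batches, unname(chunks))
  }
  batches
}

# pad an encoded sample (tensor/target/mask) to length Lmax; padded cells
# carry the invalid channel and are excluded from the mask
pad_sample <- function(X, T_, V, Lmax) {
  L <- nrow(T_)
  if (L == Lmax) return(list(X = X, T_ = T_, V = V))
  Xp <- array(0, dim = c(Lmax, Lmax, 8L))
  Xp[, , 8L] <- 1
  Xp[seq_len(L), seq_len(L), ] <- X
  Tp <- matrix(0, Lmax, Lmax)
  Tp[seq_len(L), seq_len(L)] <- T_
  Vp <- matrix(FALSE, Lmax, Lmax)
  Vp[seq_len(L), seq_len(L)] <- V
  list(X = Xp, T_ = Tp, V = Vp)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

encode_records <- function(records) {
  lapply(records, function(r) {
    q <- r$sequence
    list(X = unclass(encode_sequence(q)),
         T_ = encode_target(r$structure),
         V = valid_mask(q),
         L = r$structure$length)
  })
}

#' Mean training-set F1 under argmax decoding
#'
#' Runs the model in evaluation mode on every record, decodes the final
#' pass with [argmax_decode()] and averages the per-record F1 against the
#' reference structures.
#'
#' @param model A `score_network`.
#' @param records A list of `structure_record` objects.
#' @return A scalar in `[0, 1]`.
#' @export
training_f1 <- function(model, records) {
  f1 <- vapply(records, function(r) {
    Ys <- forward(model, encode_sequence(r$sequence))
    dec <- argmax_decode(Ys[[length(Ys)]], valid_mask(r$sequence))
    pair_metrics(dec$structure, r$structure)$f1
  }, numeric(1))
  mean(f1)
}

#' Train a score network
#'
#' Adam optimization of the masked mean-squared-error loss
#' ([masked_mse_loss()]) over mini-batches from [make_batches()]. Batches
#' mix gradients across their samples; batch-norm statistics pool over the
#' whole mini-batch (padding included, as with any rectangular-tensor
#' framework). Fully seeded: identical `(records, model_cfg, train_cfg)`
#' give identical loss histories on the same machine.
#'
#' @param records A list of `structure_record` objects.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @return A list of class `train_result` with `model` (the trained
#'   `score_network`), `history` (data.frame: step, epoch, loss, and f1
#'   where monitored) and `steps` (total update count).
#' @export
train <- function(records, model_cfg = model_config(),
                  train_cfg = train_config()) {
  if (!length(records)) stop("empty dataset", call. = FALSE)
  if (!is.null(train_cfg$max_train_length)) {
    keep <- vapply(records, function(r) r$structure$length, integer(1)) <=
      train_cfg$max_train_length
    records <- records[keep]
    if (!length(records)) stop("no records left after the length filter", call. = FALSE)
  }
  model <- build_model(model_cfg)
  enc <- encode_records(records)
  state <- adam_init(model$params)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(train_cfg$seed)

  history <- list()
  step <- 0L
  stopped <- FALSE
  for (epoch in seq_len(train_cfg$epochs)) {
    batches <- make_batches(records, train_cfg)
    for (b in batches) {
      Lmax <- max(vapply(enc[b], `[[`, 1L, "L"))
      padded <- lapply(enc[b], function(e) pad_sample(e$X, e$T_, e$V, Lmax))
      res <- cpp_net_run(model$params, model$running, unclass(model$cfg),
                         lapply(padded, `[[`, "X"),
                         lapply(padded, `[[`, "T_"),
                         lapply(padded, function(p) p$V * 1),
                         train = TRUE, want_grad = TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite loss at step %d (epoch %d); try a lower learning rate",
                     step + 1L, epoch), call. = FALSE)
      }
      model$running <- res$running
      upd <- adam_step(model$params, res$grads, state, train_cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
      step <- step + 1L
      rec <- list(step = step, epoch = epoch, loss = res$loss, f1 = NA_real_)
      if (!is.null(train_cfg$eval_every) && step %% train_cfg$eval_every == 0L) {
        rec$f1 <- training_f1(model, records)
        if (!is.null(train_cfg$stop_f1) && rec$f1 >= train_cfg$stop_f1) {
          stopped <- TRUE
        }
      }
      history[[length(history) + 1L]] <- rec
      if (!is.null(train_cfg$checkpoint_every) &&
          step %% train_cfg$checkpoint_every == 0L &&
          !is.null(train_cfg$checkpoint_dir)) {
        dir.create(train_cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_model(model, file.path(train_cfg$checkpoint_dir,
                                    sprintf("checkpoint_%06d.json", step)))
      }
      if (stopped || (!is.null(train_cfg$max_steps) && step >= train_cfg$max_steps)) {
        break
      }
    }
    if (stopped || (!is.null(train_cfg$max_steps) && step >= train_cfg$max_steps)) {
      break
    }
  }
  history <- do.call(rbind, lapply(history, as.data.frame))
  structure(list(model = model, history = history, steps = step),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d steps, final loss %.5f\n",
              x$steps, x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Length-dispatched prediction with two models
#'
#' The short/long ensemble: sequences with `L <= threshold` are scored by
#' `model_short`, longer ones by `model_long` (threshold inclusive,
#' default 600 nt).
#'
#' @param q An `rna_sequence`.
#' @param model_short,model_long `score_network` objects.
#' @param threshold Length cutoff in nt.
#' @return The final-pass `L x L` score matrix.
#' @export
mix_predict <- function(q, model_short, model_long, threshold = 600L) {
  if (missing(model_short) || is.null(model_short) ||
      missing(model_long) || is.null(model_long)) {
    stop("both models must be provided", call. = FALSE)
  }
  model <- if (length(q$residues) <= threshold) model_short else model_long
  Ys <- forward(model, encode_sequence(q))
  Ys[[length(Ys)]]
}
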