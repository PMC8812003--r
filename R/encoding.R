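#' Channel layout of the pairwise input tensor
#'
#' The input representation of a sequence of length `L` is an
#' `L x L x 8` binary one-hot array: at cell `(i, j)` exactly one channel
#' is 1. Channels 1-6 mark the six canonical ordered base combinations
#' `(A,U), (U,A), (U,G), (G,U), (G,C), (C,G)` (in this fixed order, so
#' saved models are portable), channel 7 marks the main diagonal `i = j`
#' (where the unpaired state lives in the target), and channel 8 marks
#' cells where pairing is impossible: off-diagonal cells whose base
#' combination is non-canonical or whose distance `|i - j|` is below
#' [pair_min_distance()] (the distance rule dominates even for canonical
#' combinations).
#'
#' @return Character vector of the eight channel names, in order.
#' @export
pair_channels <- function() c(PAIR_CLASSES, "diagonal", "invalid")

#' Encode a sequence as an L x L x 8 one-hot relation map
#'
#' @param q An `rna_sequence` (possibly with blocked ambiguity codes, whose
#'   cells all land in the invalid channel).
#' @param min_dist Minimum pairing distance, default [pair_min_distance()].
#' @return A numeric array of dimension `c(L, L, 8)` (row = i, column = j,
#'   channel-last) of class `pair_tensor`; see [pair_channels()].
#' @examples
#' X <- encode_sequence(rna_sequence("GGGAAACCC"))
#' which(X[1, 9, ] == 1)  # (G,C) channel
#' @export
encode_sequence <- function(q, min_dist = pair_min_distance()) {
  stopifnot(inherits(q, "rna_sequence"))
  L <- length(q$residues)
  X <- array(0, dim = c(L, L, 8L))
  cls <- outer(q$residues, q$residues, paste0)     # cls[i, j] = qi qj
  chan <- match(cls, PAIR_CLASSES)                 # NA where non-canonical
  dist_ok <- abs(outer(seq_len(L), seq_len(L), `-`)) >= min_dist
  for (c_ in 1:6) {
    X[, , c_][!is.na(chan) & chan == c_ & dist_ok] <- 1
  }
  X[, , 7L][cbind(seq_len(L), seq_len(L))] <- 1
  X[, , 8L] <- 1 - X[, , 1L] - X[, , 2L] - X[, , 3L] - X[, , 4L] -
    X[, , 5L] - X[, , 6L] - X[, , 7L]
  class(X) <- c("pair_tensor", class(X))
  X
}

#' Valid-cell mask for the loss and the decoders
#'
#' The set `V` of cells that can carry pairing signal: the complement of
#' the invalid channel of [encode_sequence()]. It contains every cell whose
#' base combination is canonical at distance `>= min_dist`, plus the main
#' diagonal (where the unpaired state is encoded and learnable).
#'
#' @inheritParams encode_sequence
#' @return An `L x L` logical matrix; `TRUE` marks cells in `V`.
#' @export
valid_mask <- function(q, min_dist = pair_min_distance()) {
  X <- encode_sequence(q, min_dist = min_dist)
  X[, , 8L] == 0
}

#' Encode a structure as a binary target matrix
#'
#' `t[i, j] = t[j, i] = 1` for every pair `(i, j)`; `t[i, i] = 1` iff base
#' `i` is unpaired. Consequently every row (and column) sums to exactly 1.
#'
#' @param s A `secondary_structure` with at most one partner per base.
#' @return An `L x L` numeric 0/1 matrix.
#' @export
encode_target <- function(s) {
  stopifnot(inherits(s, "secondary_structure"))
  L <- s$length
  if (nrow(s$pairs) && anyDuplicated(c(s$pairs))) {
    stop("structure has a base with more than one partner", call. = FALSE)
  }
  p <- partner_vector(s)
  T_ <- matrix(0, L, L)
  paired <- which(p > 0L)
  T_[cbind(paired, p[paired])] <- 1
  unpaired <- which(p == 0L)
  T_[cbind(unpaired, unpaired)] <- 1
  T_
}

#' Decode a binary target matrix back into a structure
#'
#' Inverse of [encode_target()]: requires a symmetric 0/1 matrix with unit
#' row sums.
#'
#' @param T_ An `L x L` matrix satisfying the target-matrix invariants.
#' @return A `secondary_structure`.
#' @export
decode_target <- function(T_) {
  T_ <- as.matrix(T_)
  L <- nrow(T_)
  if (ncol(T_) != L) stop("target matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(T_, t(T_)))) {
    stop("target matrix must be symmetric", call. = FALSE)
  }
  if (!all(rowSums(T_) == 1)) {
    stop("every row of a target matrix must sum to exactly 1", call. = FALSE)
  }
  idx <- which(T_ == 1, arr.ind = TRUE)
  off <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  secondary_structure(L, off)
}
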