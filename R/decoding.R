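#' Decoding configuration
#'
#' @param method `"argmax"` (fast, may report violations) or `"blossom"`
#'   (maximum-weight matching, always valid). Argmax is the default
#'   post-processing method.
#' @param k Per-row candidate cap for the blossom graph (default 3; larger
#'   values rarely change the result but slow the matching down).
#' @param symmetrize Average the score matrix with its transpose before
#'   decoding with blossom (default `TRUE`; the matching needs one weight
#'   per undirected edge).
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(method = c("argmax", "blossom"), k = 3L,
                          symmetrize = TRUE) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(method = method, k = k, symmetrize = isTRUE(symmetrize)),
            class = "decode_config")
}

#' Symmetrize a score matrix
#'
#' Elementwise mean of `Y` and its transpose, so that each undirected
#' candidate pair carries a single weight.
#'
#' @param Y A square numeric matrix.
#' @return The symmetrized matrix.
#' @export
symmetrize_scores <- function(Y) {
  if (!is.matrix(Y) || nrow(Y) != ncol(Y)) stop("Y must be square", call. = FALSE)
  (Y + t(Y)) / 2
}

#' Argmax decoding of a score matrix
#'
#' Connects base `i` to base `j` when `y_ij` is the largest entry of row
#' `i` over the valid cells plus the diagonal (the diagonal winning means
#' "unpaired"); ties go to the lowest column index. The predicted pair set
#' is `{(i, j): i < j and (row i picked j or row j picked i)}`. The method
#' runs in O(L^2) but does not guarantee symmetric choices: conflicts where
#' a base ends up with two partners are reported as `multi_pairing`
#' violations, not silently repaired.
#'
#' @param Y An `L x L` score matrix.
#' @param V The logical valid-cell mask from [valid_mask()] (its diagonal
#'   is part of `V`).
#' @return A list with elements `structure` (a `secondary_structure`,
#'   unchecked if conflicts exist) and `violations` (data.frame as in
#'   [validate_structure()]; zero rows when the raw choices are mutually
#'   consistent).
#' @export
argmax_decode <- function(Y, V) {
  if (!is.matrix(Y) || nrow(Y) != ncol(Y)) stop("Y must be square", call. = FALSE)
  if (!all(dim(Y) == dim(V))) stop("Y and V must have equal dimensions", call. = FALSE)
  if (any(!is.finite(Y[V]))) stop("scores on valid cells must be finite", call. = FALSE)
  L <- nrow(Y)
  masked <- Y
  masked[!V] <- -Inf
  diag(masked) <- diag(Y)  # the unpaired state always competes
  choice <- integer(L)
  for (i in seq_len(L)) {
    row <- masked[i, ]
    if (all(row == -Inf)) stop(sprintf("row %d has no admissible cell", i), call. = FALSE)
    choice[i] <- which.max(row)  # ties: lowest column index
  }
  sel <- which(choice != seq_len(L))
  pairs <- unique(rbind(
    cbind(sel[sel < choice[sel]], choice[sel][sel < choice[sel]]),
    cbind(choice[sel][choice[sel] < sel], sel[choice[sel] < sel])
  ))
  s <- secondary_structure(L, pairs, check = FALSE)
  v <- violation_df()
  if (nrow(s$pairs)) {
    idx <- c(s$pairs)
    dup <- unique(idx[duplicated(idx)])
    if (length(dup)) {
      hit <- s$pairs[, 1L] %in% dup | s$pairs[, 2L] %in% dup
      v <- violation_df("multi_pairing", s$pairs[hit, 1L], s$pairs[hit, 2L])
    }
  }
  list(structure = s, violations = v)
}

# scale shifted non-negative weights to integers for the exact matcher
mwm_scale <- function(maxw) {
  if (maxw <= 0) return(1)
  2^42 / maxw
}

#' Blossom decoding of a score matrix
#'
#' Decodes by maximum-weight matching: each base must be paired with a
#' single other base or unpaired, and the total score is maximized with
#' unpaired bases contributing their diagonal score as a self-loop. Since
#' matching implementations do not handle self-loops, the graph is
#' duplicated: nodes `u_1..u_L, v_1..v_L`; every retained candidate pair
#' `(i, j)` contributes edges `(u_i, u_j)` and `(v_i, v_j)` with weight
#' `y_ij`, and every base contributes a rung `(u_i, v_i)` weighted with
#' twice its self-loop score `2 * y_ii`. Pairs are read from the `u` copy
#' of the optimal matching; bases unmatched there are unpaired.
#'
#' Per row only the `cfg$k` highest-scoring valid cells enter the graph
#' (an edge survives if either endpoint's row retained it). Scores are
#' shifted by a constant (pairs by `2c`, diagonal by `c`) so that all
#' weights are non-negative — this adds the same amount to every candidate
#' structure's objective, leaving the argmax unchanged — and then scaled to
#' integers so the matching is exact.
#'
#' @param Y An `L x L` score matrix (symmetrized internally when
#'   `cfg$symmetrize`).
#' @param V The logical valid-cell mask from [valid_mask()].
#' @param cfg A [decode_config()] (its `method` field is ignored here).
#' @return A `secondary_structure`; always passes [validate_structure()]
#'   against the encoding sequence, by construction. Degenerate inputs
#'   (no retained candidate with positive shifted weight) give the
#'   all-unpaired structure.
#' @export
blossom_decode <- function(Y, V, cfg = decode_config(method = "blossom")) {
  if (!is.matrix(Y) || nrow(Y) != ncol(Y)) stop("Y must be square", call. = FALSE)
  if (!all(dim(Y) == dim(V))) stop("Y and V must have equal dimensions", call. = FALSE)
  L <- nrow(Y)
  if (cfg$symmetrize) Y <- symmetrize_scores(Y)

  offdiag <- V
  diag(offdiag) <- FALSE
  keep <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    cand <- which(offdiag[i, ])
    if (!length(cand)) next
    top <- cand[order(Y[i, cand], decreasing = TRUE)[seq_len(min(cfg$k, length(cand)))]]
    keep[i, top] <- TRUE
  }
  keep <- keep | t(keep)  # an edge survives if either row retained it

  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  diagy <- diag(Y)
  if (nrow(idx) == 0L && all(diagy <= 0)) {
    return(secondary_structure(L))
  }

  # shift: pairs + 2c, diagonal + c => every structure's objective moves by
  # the same constant 2*c*L, so the optimum is preserved
  pairw <- if (nrow(idx)) Y[idx] else numeric(0)
  c_shift <- max(0, if (length(pairw)) -min(pairw) / 2 else 0, -min(diagy))
  pairw <- pairw + 2 * c_shift
  rungw <- 2 * (diagy + c_shift)

  scale <- mwm_scale(max(pairw, rungw, 0))
  eu <- c(idx[, 1L], idx[, 1L] + L, seq_len(L))
  ev <- c(idx[, 2L], idx[, 2L] + L, seq_len(L) + L)
  ew <- c(round(pairw * scale), round(pairw * scale), round(rungw * scale))
  m <- cpp_max_weight_matching(2L * L, as.integer(eu), as.integer(ev), as.numeric(ew))

  u <- m[seq_len(L)]
  i <- which(u > 0L & u <= L & seq_len(L) < u)
  secondary_structure(L, cbind(i, u[i]))
}

#' Structure objective of a score matrix
#'
#' The quantity maximized by [blossom_decode()] on the duplicated graph:
#' `sum over pairs of 2*y_ij + sum over unpaired bases of 2*y_ii` (each
#' structure appears once per graph copy, hence the factor two).
#'
#' @param s A `secondary_structure`.
#' @param Y The score matrix.
#' @return A scalar.
#' @export
structure_objective <- function(s, Y) {
  p <- s$pairs
  paired <- c(p)
  unpaired <- setdiff(seq_len(s$length), paired)
  2 * (if (nrow(p)) sum(Y[p]) else 0) + 2 * sum(diag(Y)[unpaired])
}

#' Decode a score matrix into a structure
#'
#' Front door over [argmax_decode()] and [blossom_decode()].
#'
#' @param Y Score matrix (typically the last element of [forward()]).
#' @param V Valid-cell mask of the underlying sequence.
#' @param cfg A [decode_config()].
#' @return A list with `structure` and `violations` (always zero rows for
#'   blossom).
#' @export
decode_structure <- function(Y, V, cfg = decode_config()) {
  if (cfg$method == "argmax") {
    argmax_decode(Y, V)
  } else {
    list(structure = blossom_decode(Y, V, cfg), violations = violation_df())
  }
}
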