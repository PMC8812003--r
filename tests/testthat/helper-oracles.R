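# Shared fixtures and independent oracles used across the test files.

# The 31-nt hairpin-within-hairpin worked example: a nested two-stem
# structure whose pairs are all canonical with distances >= 3.
worked_example <- function() {
  q <- rna_sequence("CGUGUCAGGUCCGGAAGGAAGCAGCACUAAC", id = "worked_example")
  s <- secondary_structure(31, cbind(c(2:5, 10:12), c(27:24, 19:17)))
  list(q = q, s = s, dotbracket = ".((((....(((....)))....))))....")
}

# Exhaustive maximization of the decoding objective
# sum over pairs of 2*y_ij + sum over unpaired of 2*y_ii
# over ALL pairings admitted by the valid mask. Exponential; only for
# small L.
brute_best_objective <- function(Y, V) {
  L <- nrow(Y)
  offd <- V
  diag(offd) <- FALSE
  best <- -Inf
  used <- logical(L)
  rec <- function(i, acc) {
    if (i > L) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (used[i]) {
      rec(i + 1L, acc)
      return(invisible())
    }
    rec(i + 1L, acc + 2 * Y[i, i])  # i unpaired
    for (j in which(offd[i, ] & !used & seq_len(L) > i)) {
      used[i] <<- TRUE; used[j] <<- TRUE
      rec(i + 1L, acc + 2 * Y[i, j])
      used[i] <<- FALSE; used[j] <<- FALSE
    }
  }
  rec(1L, 0)
  best
}

# Literal double-loop transcription of the masked-MSE loss definition,
# kept deliberately independent of masked_mse_loss().
brute_loss <- function(Ys, T_, V) {
  if (is.matrix(Ys)) Ys <- list(Ys)
  total <- 0
  for (Y in Ys) {
    l_n <- 0
    nv <- 0
    for (i in seq_len(nrow(T_))) {
      for (j in seq_len(ncol(T_))) {
        if (V[i, j]) {
          l_n <- l_n + (Y[i, j] - T_[i, j])^2
          nv <- nv + 1
        }
      }
    }
    total <- total + l_n / nv
  }
  total / length(Ys)
}

# A random sequence plus a symmetric score matrix over its valid mask.
random_scored_instance <- function(L) {
  q <- rna_sequence(paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                          collapse = ""))
  V <- valid_mask(q)
  Y <- symmetrize_scores(matrix(stats::rnorm(L * L), L, L))
  list(q = q, V = V, Y = Y)
}

# A random well-formed structure (not necessarily canonical-compatible
# with any particular sequence): used for metric property tests.
random_pair_set <- function(L, n_try = 10L) {
  p <- integer(0)
  avail <- seq_len(L)
  pairs <- NULL
  for (k in seq_len(n_try)) {
    if (length(avail) < 2L) break
    ij <- sort(sample(avail, 2L))
    if (ij[2L] - ij[1L] >= 3L) {
      pairs <- rbind(pairs, ij)
      avail <- setdiff(avail, ij)
    }
  }
  secondary_structure(L, pairs)
}
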