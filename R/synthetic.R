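#' Configuration for the synthetic structure generator
#'
#' Describes the stem/loop composition of generated structures: stems are
#' runs of consecutive base pairs `(i+t, j-t)`, loops are unpaired
#' intervals, and an optional extra stem placed from inside a loop into a
#' downstream region produces a pseudoknot (crossing pairs).
#'
#' @param length_range Integer range `[min, max]` of sequence lengths (nt).
#' @param stem_length Range of consecutive pairs per stem.
#' @param min_loop Minimum number of unpaired bases enclosed between the
#'   innermost pair of a stem; must be at least [pair_min_distance()] so
#'   that all generated pairs respect the minimum pairing distance.
#' @param n_stems Range of nested stems per structure.
#' @param pseudoknot_prob Probability that a structure receives one
#'   additional crossing stem.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(length_range = c(40L, 120L),
                             stem_length = c(3L, 8L),
                             min_loop = 3L,
                             n_stems = c(2L, 6L),
                             pseudoknot_prob = 0.3) {
  length_range <- as.integer(length_range)
  stem_length <- as.integer(stem_length)
  n_stems <- as.integer(n_stems)
  min_loop <- as.integer(min_loop)
  stopifnot(length(length_range) == 2L, length_range[1L] <= length_range[2L],
            length(stem_length) == 2L, stem_length[1L] >= 1L,
            stem_length[1L] <= stem_length[2L],
            length(n_stems) == 2L, n_stems[1L] >= 1L,
            n_stems[1L] <= n_stems[2L],
            pseudoknot_prob >= 0, pseudoknot_prob <= 1)
  if (min_loop < pair_min_distance()) {
    stop(sprintf("min_loop must be >= the minimum pairing distance (%d)",
                 pair_min_distance()), call. = FALSE)
  }
  structure(list(length_range = length_range, stem_length = stem_length,
                 min_loop = min_loop, n_stems = n_stems,
                 pseudoknot_prob = pseudoknot_prob),
            class = "synthetic_config")
}

# uniform integer draw from an inclusive range using the current RNG
draw_int <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(sample.int(hi - lo + 1L, 1L) + lo - 1L)
}

# maximal runs of unpaired positions within [lo, hi]; returns matrix (a, b)
unpaired_runs <- function(paired, lo, hi) {
  if (lo > hi) return(matrix(integer(0), ncol = 2L))
  free <- !paired[lo:hi]
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(a = lo + starts[keep] - 1L, b = lo + ends[keep] - 1L)
}

sample_structure_once <- function(cfg) {
  L <- draw_int(cfg$length_range[1L], cfg$length_range[2L])
  min_span <- 2L * cfg$stem_length[1L] + cfg$min_loop
  if (L < min_span) {
    stop(sprintf("length %d is too small for a stem of %d pairs with a %d-nt loop",
                 L, cfg$stem_length[1L], cfg$min_loop), call. = FALSE)
  }
  n_stems <- draw_int(cfg$n_stems[1L], cfg$n_stems[2L])
  slots <- matrix(c(1L, L), ncol = 2L)
  pairs <- NULL
  stems <- list()  # each: c(i, j) outermost pair of the stem
  for (k in seq_len(n_stems)) {
    width <- slots[, 2L] - slots[, 1L] + 1L
    ok <- which(width >= min_span)
    if (!length(ok)) break
    sl <- ok[draw_int(1L, length(ok))]
    a <- slots[sl, 1L]; b <- slots[sl, 2L]
    t_max <- (b - a + 1L - cfg$min_loop) %/% 2L
    t <- draw_int(cfg$stem_length[1L], min(cfg$stem_length[2L], t_max))
    i <- draw_int(a, b - (2L * t + cfg$min_loop) + 1L)
    j <- draw_int(i + 2L * t + cfg$min_loop - 1L, b)
    s_idx <- 0:(t - 1L)
    pairs <- rbind(pairs, cbind(i + s_idx, j - s_idx))
    stems[[length(stems) + 1L]] <- c(i, j)
    slots <- slots[-sl, , drop = FALSE]
    for (nw in list(c(a, i - 1L), c(i + t, j - t), c(j + 1L, b))) {
      if (nw[2L] - nw[1L] + 1L >= 1L) slots <- rbind(slots, nw)
    }
  }
  if (is.null(pairs)) {
    stop("could not place any stem; length too small for requested stems", call. = FALSE)
  }

  want_pk <- stats::runif(1L) < cfg$pseudoknot_prob
  got_pk <- FALSE
  if (want_pk) {
    paired <- logical(L)
    paired[c(pairs)] <- TRUE
    for (try in 1:50) {
      st <- stems[[draw_int(1L, length(stems))]]
      inside <- unpaired_runs(paired, st[1L] + 1L, st[2L] - 1L)
      after <- unpaired_runs(paired, st[2L] + 1L, L)
      before <- unpaired_runs(paired, 1L, st[1L] - 1L)
      t2 <- draw_int(2L, cfg$stem_length[1L])
      ins <- inside[inside[, 2L] - inside[, 1L] + 1L >= t2, , drop = FALSE]
      out_r <- after[after[, 2L] - after[, 1L] + 1L >= t2, , drop = FALSE]
      out_l <- before[before[, 2L] - before[, 1L] + 1L >= t2, , drop = FALSE]
      cand <- NULL
      if (nrow(ins) && nrow(out_r)) {
        ri <- ins[draw_int(1L, nrow(ins)), ]
        ro <- out_r[draw_int(1L, nrow(out_r)), ]
        cand <- list(left = ri[1L], right = ro[2L])           # inside -> after
      } else if (nrow(ins) && nrow(out_l)) {
        ro <- out_l[draw_int(1L, nrow(out_l)), ]
        ri <- ins[ins[, 2L] - ins[, 1L] + 1L >= t2, , drop = FALSE]
        ri <- ri[draw_int(1L, nrow(ri)), ]
        cand <- list(left = ro[1L], right = ri[2L])           # before -> inside
      }
      if (is.null(cand)) next
      x <- cand$left; y <- cand$right
      # innermost pair of the crossing stem must respect the distance rule
      if ((y - t2 + 1L) - (x + t2 - 1L) < pair_min_distance()) next
      s_idx <- 0:(t2 - 1L)
      pairs <- rbind(pairs, cbind(x + s_idx, y - s_idx))
      got_pk <- TRUE
      break
    }
    if (!got_pk) return(NULL)  # rejection: retry the whole structure
  }
  s <- secondary_structure(L, pairs)
  if (want_pk && !is_pseudoknotted(s)) return(NULL)
  s
}

#' Sample a random valid secondary structure
#'
#' Builds a nested stem/loop skeleton by placing stems into available
#' unpaired intervals (recursively splitting each interval into the region
#' before, inside and after the stem), then, with probability
#' `cfg$pseudoknot_prob`, adds one crossing stem from inside a stem's loop
#' region to an unpaired region outside it, rejection-sampled so the
#' single-partner and minimum-distance rules always hold. Uses the current
#' R random number generator; seed with [set.seed()] or use
#' [make_dataset()].
#'
#' @param cfg A [synthetic_config()].
#' @return A `secondary_structure`; pseudoknotted iff the pseudoknot branch
#'   fired.
#' @export
sample_structure <- function(cfg = synthetic_config()) {
  for (attempt in 1:100) {
    s <- sample_structure_once(cfg)
    if (!is.null(s)) return(s)
  }
  stop("failed to generate a structure satisfying the pseudoknot request; ",
       "increase length_range or stem counts", call. = FALSE)
}

#' Sample a sequence compatible with a structure
#'
#' Each base pair is assigned one of the six canonical ordered pair classes
#' uniformly at random; unpaired positions are drawn uniformly from
#' `{A, C, G, U}`. The result always passes [validate_structure()] against
#' `s`.
#'
#' @param s A `secondary_structure`.
#' @param id Identifier for the generated sequence.
#' @return An `rna_sequence` of length `s$length`.
#' @export
sample_sequence <- function(s, id = "synthetic") {
  res <- sample(RNA_BASES, s$length, replace = TRUE)
  np <- nrow(s$pairs)
  if (np > 0L) {
    cls <- PAIR_CLASSES[sample.int(6L, np, replace = TRUE)]
    res[s$pairs[, 1L]] <- substr(cls, 1L, 1L)
    res[s$pairs[, 2L]] <- substr(cls, 2L, 2L)
  }
  rna_sequence(res, id = id)
}

#' Generate a reproducible synthetic dataset
#'
#' @param n Number of records (must be at least 1).
#' @param cfg A [synthetic_config()].
#' @param seed Optional integer seed; when given, the current RNG state is
#'   saved and restored so the call is side-effect free.
#' @return A list of `structure_record` objects (see [structure_record()]).
#' @examples
#' recs <- make_dataset(3, synthetic_config(length_range = c(30, 60)), seed = 1)
#' sapply(recs, function(r) r$sequence$id)
#' @export
make_dataset <- function(n, cfg = synthetic_config(), seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  lapply(seq_len(n), function(k) {
    s <- sample_structure(cfg)
    q <- sample_sequence(s, id = sprintf("synth_%04d", k))
    structure_record(q, s, source = "synthetic")
  })
}

#' Inject a violation into a record (for negative tests)
#'
#' Deliberately corrupts a valid (sequence, structure) record so that
#' [validate_structure()] reports the requested violation kind. Not used by
#' the generator itself.
#'
#' @param record A `structure_record`.
#' @param kind One of `"non_canonical"`, `"min_distance"`,
#'   `"multi_pairing"`.
#' @return The corrupted `structure_record`.
#' @export
corrupt_record <- function(record,
                           kind = c("non_canonical", "min_distance", "multi_pairing")) {
  kind <- match.arg(kind)
  s <- record$structure; q <- record$sequence
  if (nrow(s$pairs) == 0L) stop("record has no pairs to corrupt", call. = FALSE)
  if (kind == "non_canonical") {
    i <- s$pairs[1L, 1L]
    # replace the 5' partner with a base that cannot pair with the 3' one
    j_base <- q$residues[s$pairs[1L, 2L]]
    bad <- setdiff(RNA_BASES, substr(PAIR_CLASSES[endsWith(PAIR_CLASSES, j_base)], 1L, 1L))
    q$residues[i] <- bad[1L]
  } else if (kind == "min_distance") {
    p <- partner_vector(s)
    free <- which(p == 0L)
    adj <- free[free + 1L <= s$length & (free + 1L) %in% free][1L]
    if (is.na(adj)) stop("no adjacent unpaired bases available", call. = FALSE)
    s <- secondary_structure(s$length, rbind(s$pairs, c(adj, adj + 1L)), check = FALSE)
  } else {
    i <- s$pairs[1L, 1L]
    p <- partner_vector(s)
    free <- which(p == 0L & abs(seq_len(s$length) - i) >= pair_min_distance())
    if (!length(free)) stop("no unpaired base available", call. = FALSE)
    s <- secondary_structure(s$length, rbind(s$pairs, c(i, free[1L])), check = FALSE)
  }
  structure_record(q, s, source = record$source)
}
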