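#' @useDynLib pairfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimum separation |i - j| between the two partners of a base pair.
# Single source of truth: threaded through encoding, decoding and validation.
MIN_PAIR_DIST <- 3L

RNA_BASES <- c("A", "C", "G", "U")

# The six canonical (Watson-Crick + wobble) ordered pair classes, in the
# fixed order also used for the input-tensor channels.
PAIR_CLASSES <- c("AU", "UA", "UG", "GU", "GC", "CG")

#' Minimum pairing distance
#'
#' The smallest allowed separation `|i - j|` between the two bases of a pair
#' (default 3). All encoding, decoding and validation code uses this single
#' constant.
#'
#' @return An integer scalar.
#' @export
pair_min_distance <- function() MIN_PAIR_DIST

#' Construct an RNA sequence
#'
#' Normalizes the input (T to U, lowercase to uppercase) and checks that all
#' residues are in `{A, C, G, U}`. Ambiguity codes (N, R, ...) are rejected
#' by default; with `ambiguous = "block"` they are kept verbatim and treated
#' as unable to pair with anything downstream (all their pairwise relation
#' cells fall into the invalid channel).
#'
#' @param residues A single string or a character vector of single bases.
#' @param id Free-text identifier.
#' @param ambiguous Either `"error"` (default) or `"block"`.
#' @return An object of class `rna_sequence` with fields `id` and
#'   `residues` (character vector of single upper-case bases).
#' @examples
#' q <- rna_sequence("CGUGUCAGGUCCGGAAGGAAGCAGCACUAAC", id = "example")
#' q$residues[2]
#' @export
rna_sequence <- function(residues, id = "seq", ambiguous = c("error", "block")) {
  ambiguous <- match.arg(ambiguous)
  if (is.character(residues) && length(residues) == 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  if (length(residues) < 1L) {
    stop("an RNA sequence must contain at least one residue", call. = FALSE)
  }
  residues <- toupper(residues)
  residues[residues == "T"] <- "U"
  bad <- !(residues %in% RNA_BASES)
  if (any(bad)) {
    if (ambiguous == "error") {
      stop(sprintf(
        "sequence '%s' contains non-AUCG residues (%s) at positions %s; use ambiguous = \"block\" to keep them as unpairable",
        id,
        paste(unique(residues[bad]), collapse = ","),
        paste(utils::head(which(bad), 5L), collapse = ",")
      ), call. = FALSE)
    }
    ok <- grepl("^[A-Z]$", residues[bad])
    if (!all(ok)) {
      stop(sprintf("sequence '%s' contains non-letter symbols", id), call. = FALSE)
    }
  }
  structure(list(id = as.character(id), residues = residues),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (L = %d)\n", x$id, length(x$residues)))
  s <- paste(x$residues, collapse = "")
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) length(x$residues)

#' Construct a secondary structure
#'
#' A secondary structure is a set of 1-based base pairs `(i, j)` with
#' `i < j` on a sequence of length `L`. On construction (with
#' `check = TRUE`, the default) every index may occur in at most one pair
#' and all indices must lie in `1..L`. Canonicity and minimum-distance
#' checks are *not* enforced here; use [validate_structure()] for those, so
#' that reference structures with unusual pairs can still be represented.
#'
#' @param length Sequence length `L`.
#' @param pairs A two-column matrix (or data.frame) of 1-based indices, or
#'   `NULL`/empty for an unpaired structure. Rows are reordered so `i < j`.
#' @param check Assert the single-partner and range invariants (default
#'   `TRUE`). Decoders that must report conflicts instead of failing use
#'   `check = FALSE`.
#' @return An object of class `secondary_structure` with fields `length`
#'   and `pairs` (integer matrix, columns `i`, `j`, sorted by `i`).
#' @examples
#' s <- secondary_structure(31, cbind(c(2:5, 10:12), c(27:24, 19:17)))
#' is_pseudoknotted(s)
#' @export
secondary_structure <- function(length, pairs = NULL, check = TRUE) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer", call. = FALSE)
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns", call. = FALSE)
    storage.mode(pairs) <- "integer"
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, c(2L, 1L), drop = FALSE]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    pairs <- unique(pairs)
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  if (check && nrow(pairs) > 0L) {
    if (any(pairs < 1L) || any(pairs > length)) {
      stop("pair indices out of range 1..L", call. = FALSE)
    }
    if (any(pairs[, 1L] == pairs[, 2L])) {
      stop("a base cannot pair with itself", call. = FALSE)
    }
    idx <- c(pairs)
    if (anyDuplicated(idx)) {
      stop(sprintf("base(s) %s occur in more than one pair",
                   paste(unique(idx[duplicated(idx)]), collapse = ",")),
           call. = FALSE)
    }
  }
  structure(list(length = length, pairs = pairs), class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> L = %d, %d pairs%s\n",
              x$length, nrow(x$pairs),
              if (is_pseudoknotted(x)) " (pseudoknotted)" else ""))
  invisible(x)
}

#' Number of pairs in a structure
#' @param s A `secondary_structure`.
#' @return Integer count of base pairs.
#' @export
n_pairs <- function(s) nrow(s$pairs)

#' Partner vector of a structure
#'
#' @param s A `secondary_structure`.
#' @return Integer vector `p` of length `L` with `p[i]` the 1-based partner
#'   of base `i`, or 0 if unpaired (the CT/BPSEQ convention).
#' @export
partner_vector <- function(s) {
  p <- integer(s$length)
  if (nrow(s$pairs) > 0L) {
    p[s$pairs[, 1L]] <- s$pairs[, 2L]
    p[s$pairs[, 2L]] <- s$pairs[, 1L]
  }
  p
}

#' Classify an ordered base combination
#'
#' Returns the canonical pair class of an ordered base combination:
#' Watson-Crick `(A,U), (U,A), (G,C), (C,G)` or wobble `(U,G), (G,U)`.
#' The remaining ten ordered combinations are not pairable and give `NA`.
#'
#' @param a,b Single bases in `{A, C, G, U}` (vectorized, recycled).
#' @return Character vector with values among `"AU", "UA", "UG", "GU",
#'   "GC", "CG"`, or `NA_character_` where the combination is non-canonical.
#' @examples
#' canonical_pair_type("G", "C")  # "GC"
#' canonical_pair_type("A", "G")  # NA
#' @export
canonical_pair_type <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (!all(a %in% RNA_BASES) || !all(b %in% RNA_BASES)) {
    stop("bases must be one of A, C, G, U", call. = FALSE)
  }
  cls <- paste0(a, b)
  ifelse(cls %in% PAIR_CLASSES, cls, NA_character_)
}

#' Test whether a structure is pseudoknotted
#'
#' A structure is pseudoknotted iff it contains two crossing pairs
#' `(i, j)` and `(k, l)` with `i < k < j < l`, i.e. pairs that break the
#' nested (well-parenthesized) arrangement. This is the exhaustive
#' O(P^2) crossing enumeration.
#'
#' @param s A `secondary_structure`.
#' @return `TRUE` or `FALSE`.
#' @export
is_pseudoknotted <- function(s) {
  p <- s$pairs
  np <- nrow(p)
  if (np < 2L) return(FALSE)
  i <- p[, 1L]; j <- p[, 2L]
  for (a in seq_len(np - 1L)) {
    b <- (a + 1L):np
    if (any((i[a] < i[b] & i[b] < j[a] & j[a] < j[b]) |
            (i[b] < i[a] & i[a] < j[b] & j[b] < j[a]))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Which pairs of a structure cross some other pair
#'
#' @param s A `secondary_structure`.
#' @return Logical vector, one entry per row of `s$pairs`.
#' @export
crossing_pairs <- function(s) {
  p <- s$pairs
  np <- nrow(p)
  out <- logical(np)
  if (np < 2L) return(out)
  i <- p[, 1L]; j <- p[, 2L]
  for (a in seq_len(np)) {
    out[a] <- any(i < i[a] & i[a] < j & j < j[a]) ||
              any(i[a] < i & i < j[a] & j[a] < j)
  }
  out
}

violation_df <- function(kind = character(), i = integer(), j = integer()) {
  data.frame(kind = kind, i = as.integer(i), j = as.integer(j),
             stringsAsFactors = FALSE)
}

#' Validate a structure against a sequence
#'
#' Checks the three pairing constraints: every pair must be one of the six
#' canonical base combinations, partners must be at least
#' [pair_min_distance()] apart, and each base may occur in at most one
#' pair. Indices outside `1..L` are reported as `out_of_range`.
#'
#' @param s A `secondary_structure` (may be unchecked, e.g. raw argmax
#'   output).
#' @param q An `rna_sequence` of the same length.
#' @param min_dist Minimum `|i - j|`; defaults to [pair_min_distance()].
#' @return A data.frame of violations with columns `kind`
#'   (`"non_canonical"`, `"min_distance"`, `"multi_pairing"`,
#'   `"out_of_range"`), `i` and `j`; zero rows iff the structure is valid
#'   for the sequence.
#' @examples
#' q <- rna_sequence("CGUGUCAGGUCCGGAAGGAAGCAGCACUAAC")
#' s <- secondary_structure(31, cbind(c(2:5, 10:12), c(27:24, 19:17)))
#' nrow(validate_structure(s, q))  # 0
#' @export
validate_structure <- function(s, q, min_dist = pair_min_distance()) {
  if (!inherits(s, "secondary_structure")) stop("s must be a secondary_structure", call. = FALSE)
  if (!inherits(q, "rna_sequence")) stop("q must be an rna_sequence", call. = FALSE)
  if (s$length != length(q$residues)) {
    stop(sprintf("structure length (%d) does not match sequence length (%d)",
                 s$length, length(q$residues)), call. = FALSE)
  }
  p <- s$pairs
  v <- violation_df()
  if (nrow(p) == 0L) return(v)

  oor <- p[, 1L] < 1L | p[, 2L] > s$length | p[, 1L] >= p[, 2L]
  if (any(oor)) {
    v <- rbind(v, violation_df("out_of_range", p[oor, 1L], p[oor, 2L]))
  }
  inr <- p[!oor, , drop = FALSE]

  idx <- c(inr)
  dup <- unique(idx[duplicated(idx)])
  if (length(dup)) {
    hit <- inr[, 1L] %in% dup | inr[, 2L] %in% dup
    v <- rbind(v, violation_df("multi_pairing", inr[hit, 1L], inr[hit, 2L]))
  }

  short <- (inr[, 2L] - inr[, 1L]) < min_dist
  if (any(short)) {
    v <- rbind(v, violation_df("min_distance", inr[short, 1L], inr[short, 2L]))
  }

  # tolerant of blocked ambiguity codes: anything not in the six classes is
  # non-canonical, including pairs that involve an N-like residue
  cls <- paste0(q$residues[inr[, 1L]], q$residues[inr[, 2L]])
  noncan <- !(cls %in% PAIR_CLASSES)
  if (any(noncan)) {
    v <- rbind(v, violation_df("non_canonical", inr[noncan, 1L], inr[noncan, 2L]))
  }
  rownames(v) <- NULL
  v
}
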