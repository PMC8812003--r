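#' Bundle a sequence with its reference structure
#'
#' @param sequence An `rna_sequence`.
#' @param structure A `secondary_structure` of the same length.
#' @param source Free-text provenance (file path, format, "synthetic", ...).
#' @return An object of class `structure_record`.
#' @export
structure_record <- function(sequence, structure, source = "") {
  stopifnot(inherits(sequence, "rna_sequence"),
            inherits(structure, "secondary_structure"))
  if (length(sequence$residues) != structure$length) {
    stop("sequence and structure lengths differ", call. = FALSE)
  }
  structure(list(sequence = sequence, structure = structure,
                 source = as.character(source)),
            class = "structure_record")
}

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record> %s: L = %d, %d pairs\n",
              x$sequence$id, x$structure$length, nrow(x$structure$pairs)))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; residues are then
#' normalized (T to U, upper-cased) and checked by [rna_sequence()].
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Policy for non-AUCG residues, see [rna_sequence()].
#' @return A list of `rna_sequence` objects, one per FASTA record.
#' @export
read_fasta <- function(path, ambiguous = c("error", "block")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  }
  ids <- trimws(names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate FASTA ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  mapply(function(s, id) rna_sequence(s, id = id, ambiguous = ambiguous),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs An `rna_sequence` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  lines <- unlist(lapply(seqs, function(q) {
    c(paste0(">", q$id), paste(q$residues, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

# split a line on whitespace into tokens
tok <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

# common core of CT/BPSEQ parsing: given per-base index/base/partner
# columns, check consistency and build a record
record_from_columns <- function(idx, base, partner, id, path, lineno) {
  L <- length(idx)
  if (!identical(idx, seq_len(L))) {
    bad <- which(idx != seq_len(L))[1L]
    stop(sprintf("%s: base indices are not 1..L (line %d)", path, lineno[bad]),
         call. = FALSE)
  }
  if (any(partner < 0L | partner > L)) {
    bad <- which(partner < 0L | partner > L)[1L]
    stop(sprintf("%s: partner index out of range on line %d", path, lineno[bad]),
         call. = FALSE)
  }
  if (any(partner == idx)) {
    bad <- which(partner == idx)[1L]
    stop(sprintf("%s: base %d is paired with itself (line %d)", path,
                 idx[bad], lineno[bad]), call. = FALSE)
  }
  has <- which(partner > 0L)
  sym <- partner[partner[has]] == has
  if (!all(sym)) {
    b <- has[!sym][1L]
    stop(sprintf(
      "%s: inconsistent partner columns: base %d says %d but base %d says %d (lines %d and %d)",
      path, b, partner[b], partner[b], partner[partner[b]],
      lineno[b], lineno[partner[b]]), call. = FALSE)
  }
  i <- has[has < partner[has]]
  s <- secondary_structure(L, cbind(i, partner[i]))
  q <- rna_sequence(base, id = id, ambiguous = "block")
  structure_record(q, s, source = path)
}

#' Read a connectivity-table (CT) structure file
#'
#' Standard 6-column CT: header line `L <title>`, then one row per base
#' with columns `index base index-1 index+1 partner index` (partner 0 means
#' unpaired). Anything after the length on the header line (titles, energy
#' annotations) is kept as the record id but never parsed. If the file
#' concatenates several structures, only the first is read, with a warning.
#'
#' @param path Path to a CT file.
#' @return A `structure_record`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop(sprintf("%s: empty CT file", path), call. = FALSE)
  head_tok <- tok(lines[keep[1L]])
  L <- suppressWarnings(as.integer(head_tok[1L]))
  if (is.na(L) || L < 1L) {
    stop(sprintf("%s: CT header must start with the sequence length", path),
         call. = FALSE)
  }
  id <- if (length(head_tok) > 1L) paste(head_tok[-1L], collapse = " ") else "ct"
  rows <- keep[-1L]
  if (length(rows) < L) {
    stop(sprintf("%s: CT header announces %d bases but only %d rows found",
                 path, L, length(rows)), call. = FALSE)
  }
  if (length(rows) > L) {
    warning(sprintf("%s: trailing content after the first CT structure ignored", path),
            call. = FALSE)
    rows <- rows[seq_len(L)]
  }
  cols <- lapply(lines[rows], tok)
  nc <- vapply(cols, length, 1L)
  if (any(nc < 6L)) {
    stop(sprintf("%s: CT row on line %d has fewer than 6 columns",
                 path, rows[which(nc < 6L)[1L]]), call. = FALSE)
  }
  idx <- as.integer(vapply(cols, `[`, "", 1L))
  base <- vapply(cols, `[`, "", 2L)
  partner <- as.integer(vapply(cols, `[`, "", 5L))
  record_from_columns(idx, base, partner, id, path, rows)
}

#' Write a structure record as CT
#'
#' @param record A `structure_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(record, path) {
  q <- record$sequence; s <- record$structure
  L <- s$length
  p <- partner_vector(s)
  lines <- c(sprintf("%d %s", L, q$id),
             sprintf("%d %s %d %d %d %d",
                     seq_len(L), q$residues, seq_len(L) - 1L,
                     c(seq_len(L - 1L) + 1L, 0L), p, seq_len(L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BPSEQ structure file
#'
#' Three whitespace-separated columns per base: `index base partner`
#' (partner 0 means unpaired). Lines starting with `#` are skipped.
#'
#' @param path Path to a BPSEQ file.
#' @param id Record id; defaults to the file name.
#' @return A `structure_record`.
#' @export
read_bpseq <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop(sprintf("%s: empty BPSEQ file", path), call. = FALSE)
  cols <- lapply(lines[keep], tok)
  nc <- vapply(cols, length, 1L)
  if (any(nc < 3L)) {
    stop(sprintf("%s: BPSEQ row on line %d has fewer than 3 columns",
                 path, keep[which(nc < 3L)[1L]]), call. = FALSE)
  }
  idx <- as.integer(vapply(cols, `[`, "", 1L))
  base <- vapply(cols, `[`, "", 2L)
  partner <- as.integer(vapply(cols, `[`, "", 3L))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  record_from_columns(idx, base, partner, id, path, keep)
}

#' Write a structure record as BPSEQ
#'
#' @param record A `structure_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bpseq <- function(record, path) {
  s <- record$structure
  writeLines(sprintf("%d %s %d", seq_len(s$length),
                     record$sequence$residues, partner_vector(s)),
             path)
  invisible(path)
}

# bracket alphabets for successive crossing layers
DB_OPEN <- c("(", "[", "{", "<", LETTERS)
DB_CLOSE <- c(")", "]", "}", ">", letters)

#' Convert a structure to dot-bracket notation
#'
#' Crossing (pseudoknotted) pairs are assigned to successive bracket layers
#' `()`, `[]`, `{}`, `<>`, `Aa` ... `Zz` by greedy first-fit coloring in
#' 5' to 3' pair order: each pair takes the first layer in which it crosses
#' no previously assigned pair. Up to 30 mutually crossing classes are
#' supported.
#'
#' @param s A `secondary_structure`.
#' @return A string of length `s$length`.
#' @examples
#' s <- secondary_structure(15, rbind(c(1, 10), c(5, 15)))
#' to_dotbracket(s)  # "(...[....)....]"
#' @export
to_dotbracket <- function(s) {
  out <- rep(".", s$length)
  p <- s$pairs
  if (nrow(p) == 0L) return(paste(out, collapse = ""))
  layers <- list()  # per layer: matrix of assigned pairs
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    placed <- FALSE
    for (ly in seq_along(layers)) {
      q <- layers[[ly]]
      crosses <- any((q[, 1L] < i & i < q[, 2L] & q[, 2L] < j) |
                     (i < q[, 1L] & q[, 1L] < j & j < q[, 2L]))
      if (!crosses) {
        layers[[ly]] <- rbind(q, c(i, j)); placed <- TRUE
        out[i] <- DB_OPEN[ly]; out[j] <- DB_CLOSE[ly]
        break
      }
    }
    if (!placed) {
      ly <- length(layers) + 1L
      if (ly > length(DB_OPEN)) {
        stop("structure needs more than 30 mutually crossing layers", call. = FALSE)
      }
      layers[[ly]] <- matrix(c(i, j), ncol = 2L)
      out[i] <- DB_OPEN[ly]; out[j] <- DB_CLOSE[ly]
    }
  }
  paste(out, collapse = "")
}

#' Parse pseudoknot-aware dot-bracket notation
#'
#' Inverts any string produced by [to_dotbracket()]: brackets `()`, `[]`,
#' `{}`, `<>` and letter pairs `Aa` ... `Zz` open/close pairs on separate
#' layers; `.` (or `-`) marks an unpaired base.
#'
#' @param db A dot-bracket string.
#' @return A `secondary_structure`.
#' @export
from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  L <- length(ch)
  if (L == 0L) stop("empty dot-bracket string", call. = FALSE)
  stacks <- vector("list", length(DB_OPEN))
  pairs <- NULL
  for (pos in seq_len(L)) {
    c_ <- ch[pos]
    if (c_ == "." || c_ == "-") next
    op <- match(c_, DB_OPEN)
    if (!is.na(op)) {
      stacks[[op]] <- c(stacks[[op]], pos)
      next
    }
    cl <- match(c_, DB_CLOSE)
    if (is.na(cl)) {
      stop(sprintf("unknown dot-bracket symbol '%s' at position %d", c_, pos),
           call. = FALSE)
    }
    st <- stacks[[cl]]
    if (!length(st)) {
      stop(sprintf("unbalanced '%s' at position %d", c_, pos), call. = FALSE)
    }
    pairs <- rbind(pairs, c(st[length(st)], pos))
    stacks[[cl]] <- st[-length(st)]
  }
  open_left <- which(vapply(stacks, length, 1L) > 0L)
  if (length(open_left)) {
    stop(sprintf("unbalanced '%s': %d opening bracket(s) never closed",
                 DB_OPEN[open_left[1L]], length(stacks[[open_left[1L]]])),
         call. = FALSE)
  }
  secondary_structure(L, pairs)
}

#' Write a record in dot-bracket (Vienna) format
#'
#' Three lines: `>id`, the sequence, and the dot-bracket string.
#'
#' @param record A `structure_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(record, path) {
  writeLines(c(paste0(">", record$sequence$id),
               paste(record$sequence$residues, collapse = ""),
               to_dotbracket(record$structure)),
             path)
  invisible(path)
}

#' Read a dot-bracket (Vienna) format file
#'
#' Expects the three-line layout written by [write_dotbracket()].
#'
#' @param path Path to the file.
#' @return A `structure_record`.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L || !startsWith(lines[1L], ">")) {
    stop(sprintf("%s: expected '>id', sequence and dot-bracket lines", path),
         call. = FALSE)
  }
  q <- rna_sequence(trimws(lines[2L]), id = sub("^>", "", trimws(lines[1L])),
                    ambiguous = "block")
  s <- from_dotbracket(trimws(lines[3L]))
  structure_record(q, s, source = path)
}
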