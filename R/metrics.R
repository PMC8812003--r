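pair_key <- function(p) {
  if (!nrow(p)) return(character(0))
  paste(p[, 1L], p[, 2L], sep = ":")
}

metrics_from_counts <- function(tp, fp, fn) {
  # conventions for empty denominators: both sets empty => perfect (1);
  # otherwise an empty side scores 0
  if (tp + fp + fn == 0L) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  }
  list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
       precision = precision, recall = recall, f1 = f1)
}

#' Base-pair prediction metrics
#'
#' Per-sequence precision (how correct the predicted pairings are), recall
#' (how many reference pairings were found) and their harmonic mean F1,
#' computed over the off-diagonal base-pair sets only: unpaired (diagonal)
#' states never enter the counts. When both structures have no pairs the
#' score is 1 by convention; when only one side is empty, the undefined
#' ratio is 0.
#'
#' @param pred,ref `secondary_structure` objects of equal length.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' a <- secondary_structure(12, rbind(c(1, 5), c(2, 8)))
#' pair_metrics(a, a)$f1  # 1
#' @export
pair_metrics <- function(pred, ref) {
  if (pred$length != ref$length) {
    stop("predicted and reference structures have different lengths", call. = FALSE)
  }
  pk <- pair_key(pred$pairs)
  rk <- pair_key(ref$pairs)
  tp <- sum(pk %in% rk)
  metrics_from_counts(tp, length(pk) - tp, length(rk) - tp)
}

#' Metrics allowing one-position shifts
#'
#' Like [pair_metrics()], but a predicted pair `(i, j)` is also considered
#' correct if the reference contains one of the four one-position shifts
#' `(i+1, j)`, `(i-1, j)`, `(i, j+1)`, `(i, j-1)` (never the diagonal
#' shifts). Each reference pair can credit at most one prediction: exact
#' matches are credited first, then the remaining predictions greedily
#' claim the 5'-most available shifted reference pair, scanning
#' predictions in 5' order. This keeps `tp <= min(|pred|, |ref|)` and
#' guarantees the shifted scores never fall below the plain ones.
#'
#' @inheritParams pair_metrics
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
shifted_pair_metrics <- function(pred, ref) {
  if (pred$length != ref$length) {
    stop("predicted and reference structures have different lengths", call. = FALSE)
  }
  pp <- pred$pairs
  rp <- ref$pairs
  rk <- pair_key(rp)
  used <- logical(length(rk))
  tp <- 0L
  exact <- match(pair_key(pp), rk)
  hit <- !is.na(exact)
  used[exact[hit]] <- TRUE
  tp <- sum(hit)
  for (r in which(!hit)) {
    i <- pp[r, 1L]; j <- pp[r, 2L]
    cand <- c(paste(i + 1L, j, sep = ":"), paste(i - 1L, j, sep = ":"),
              paste(i, j + 1L, sep = ":"), paste(i, j - 1L, sep = ":"))
    avail <- match(cand, rk)
    avail <- avail[!is.na(avail)]
    avail <- avail[!used[avail]]
    if (length(avail)) {
      used[min(avail)] <- TRUE  # reference pairs are stored in 5' order
      tp <- tp + 1L
    }
  }
  metrics_from_counts(tp, nrow(pp) - tp, nrow(rp) - tp)
}

#' Aggregate per-record metrics
#'
#' Plain arithmetic means of precision/recall/F1 plus the length-weighted
#' F1 `sum_k w_k * F1_k` with `w_k = L_k / sum_k L_k`, which emphasizes
#' long sequences.
#'
#' @param metrics A list of per-record metric lists (from
#'   [pair_metrics()] or [shifted_pair_metrics()]).
#' @param lengths Integer vector of sequence lengths, parallel to
#'   `metrics`.
#' @return A list with `n`, `precision`, `recall`, `f1` (means) and
#'   `weighted_f1`.
#' @examples
#' m <- list(list(f1 = 1, precision = 1, recall = 1),
#'           list(f1 = 0.5, precision = 0.5, recall = 0.5))
#' aggregate_metrics(m, c(10, 30))$weighted_f1  # 0.625
#' @export
aggregate_metrics <- function(metrics, lengths) {
  if (!length(metrics)) stop("no records to aggregate", call. = FALSE)
  if (length(metrics) != length(lengths)) {
    stop("metrics and lengths must be parallel", call. = FALSE)
  }
  f1 <- vapply(metrics, function(m) m$f1, numeric(1))
  w <- lengths / sum(lengths)
  list(n = length(metrics),
       precision = mean(vapply(metrics, function(m) m$precision, numeric(1))),
       recall = mean(vapply(metrics, function(m) m$recall, numeric(1))),
       f1 = mean(f1),
       weighted_f1 = sum(w * f1))
}

#' Pseudoknot confusion counts
#'
#' Cross-tabulates whether the reference and the prediction are
#' pseudoknotted ([is_pseudoknotted()]), e.g. to count how many
#' pseudoknotted structures are predicted as pseudoknotted.
#'
#' @param preds,refs Parallel lists of `secondary_structure` objects.
#' @return A 2x2 integer matrix with rows `ref` (pk TRUE/FALSE) and
#'   columns `pred`.
#' @export
pseudoknot_confusion <- function(preds, refs) {
  if (length(preds) != length(refs)) {
    stop("preds and refs must have equal length", call. = FALSE)
  }
  rp <- vapply(refs, is_pseudoknotted, logical(1))
  pp <- vapply(preds, is_pseudoknotted, logical(1))
  out <- matrix(0L, 2L, 2L,
                dimnames = list(ref = c("pk", "nested"), pred = c("pk", "nested")))
  out[1L, 1L] <- sum(rp & pp)
  out[1L, 2L] <- sum(rp & !pp)
  out[2L, 1L] <- sum(!rp & pp)
  out[2L, 2L] <- sum(!rp & !pp)
  out
}

#' Evaluate predictions against references
#'
#' Computes plain and shifted per-record metrics, their aggregates, the
#' length-weighted F1 and the pseudoknot confusion counts.
#'
#' @param preds,refs Parallel lists of `secondary_structure` objects (or
#'   `structure_record` objects, whose structures are used).
#' @param ids Optional record identifiers.
#' @return A list of class `evaluation_report` with `per_record`
#'   (data.frame), `summary` (plain and shifted aggregates) and
#'   `pseudoknots` (2x2 counts).
#' @export
evaluate_structures <- function(preds, refs, ids = NULL) {
  get_s <- function(x) if (inherits(x, "structure_record")) x$structure else x
  preds <- lapply(preds, get_s)
  refs <- lapply(refs, get_s)
  if (length(preds) != length(refs)) {
    stop("preds and refs must have equal length", call. = FALSE)
  }
  if (!length(preds)) stop("no records to evaluate", call. = FALSE)
  if (is.null(ids)) ids <- sprintf("record_%04d", seq_along(preds))
  lengths <- vapply(refs, function(s) s$length, integer(1))
  plain <- Map(pair_metrics, preds, refs)
  shifted <- Map(shifted_pair_metrics, preds, refs)
  per_record <- data.frame(
    id = ids,
    L = lengths,
    precision = vapply(plain, `[[`, 1, "precision"),
    recall = vapply(plain, `[[`, 1, "recall"),
    f1 = vapply(plain, `[[`, 1, "f1"),
    precision_s = vapply(shifted, `[[`, 1, "precision"),
    recall_s = vapply(shifted, `[[`, 1, "recall"),
    f1_s = vapply(shifted, `[[`, 1, "f1"),
    pseudoknotted_ref = vapply(refs, is_pseudoknotted, logical(1)),
    pseudoknotted_pred = vapply(preds, is_pseudoknotted, logical(1)),
    stringsAsFactors = FALSE
  )
  structure(list(per_record = per_record,
                 summary = list(plain = aggregate_metrics(plain, lengths),
                                shifted = aggregate_metrics(shifted, lengths)),
                 pseudoknots = pseudoknot_confusion(preds, refs)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary$plain
  ss <- x$summary$shifted
  cat(sprintf("<evaluation_report> %d records\n", s$n))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  weighted F1 %.3f\n",
              s$precision, s$recall, s$f1, s$weighted_f1))
  cat(sprintf("  shifted:   %.3f         %.3f     %.3f             %.3f\n",
              ss$precision, ss$recall, ss$f1, ss$weighted_f1))
  pk <- x$pseudoknots
  cat(sprintf("  pseudoknots: %d/%d detected as pseudoknotted\n",
              pk[1L, 1L], pk[1L, 1L] + pk[1L, 2L]))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' One row per record (id, length, plain and shifted metrics, pseudoknot
#' flags) followed by commented summary lines.
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(format(report$per_record, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- report$summary$plain
  ss <- report$summary$shifted
  pk <- report$pseudoknots
  writeLines(c(
    sprintf("# n\t%d", s$n),
    sprintf("# precision\t%.6f\trecall\t%.6f\tf1\t%.6f\tweighted_f1\t%.6f",
            s$precision, s$recall, s$f1, s$weighted_f1),
    sprintf("# precision_s\t%.6f\trecall_s\t%.6f\tf1_s\t%.6f\tweighted_f1_s\t%.6f",
            ss$precision, ss$recall, ss$f1, ss$weighted_f1),
    sprintf("# pseudoknot_confusion\tref_pk_pred_pk\t%d\tref_pk_pred_nested\t%d\tref_nested_pred_pk\t%d\tref_nested_pred_nested\t%d",
            pk[1, 1], pk[1, 2], pk[2, 1], pk[2, 2])
  ), con)
  invisible(path)
}
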