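test_that("pair metrics follow the confusion-count definitions", {
  a <- secondary_structure(12, rbind(c(1, 5), c(2, 8)))
  expect_equal(pair_metrics(a, a)[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))

  pred <- secondary_structure(12, rbind(c(1, 5), c(2, 8), c(3, 9)), check = FALSE)
  ref <- secondary_structure(12, rbind(c(1, 5), c(2, 8), c(4, 9)), check = FALSE)
  m <- pair_metrics(pred, ref)
  expect_equal(m[c("tp", "fp", "fn")], list(tp = 2L, fp = 1L, fn = 1L))
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)

  expect_error(pair_metrics(a, secondary_structure(10)), "different lengths")
})

test_that("empty-set conventions are as documented", {
  none <- secondary_structure(10)
  some <- secondary_structure(10, rbind(c(1, 6)))
  both <- pair_metrics(none, none)
  expect_equal(both[c("precision", "recall", "f1")],
               list(precision = 1, recall = 1, f1 = 1))
  m1 <- pair_metrics(none, some)   # pred empty, ref nonempty
  expect_equal(m1[c("precision", "recall", "f1")],
               list(precision = 0, recall = 0, f1 = 0))
  m2 <- pair_metrics(some, none)   # ref empty, pred nonempty
  expect_equal(m2$recall, 0)
  expect_equal(m2$f1, 0)
})

test_that("shifted matching credits exactly the four listed shifts", {
  ref <- secondary_structure(15, rbind(c(3, 10)))
  hit <- secondary_structure(15, rbind(c(2, 10)))
  expect_equal(shifted_pair_metrics(hit, ref)$tp, 1L)
  for (p in list(c(4, 10), c(3, 9), c(3, 11))) {
    expect_equal(shifted_pair_metrics(secondary_structure(15, rbind(p)), ref)$tp, 1L)
  }
  # the diagonal shift (i+1, j+1) is never accepted
  diag_shift <- secondary_structure(15, rbind(c(2, 9)))
  expect_equal(shifted_pair_metrics(diag_shift, ref)$tp, 0L)
  far <- secondary_structure(15, rbind(c(2, 11)))
  expect_equal(shifted_pair_metrics(far, ref)$tp, 0L)
})

test_that("shifted metrics reduce to plain metrics on exact matches", {
  set.seed(61)
  for (rep in 1:10) {
    s <- random_pair_set(30L)
    expect_equal(shifted_pair_metrics(s, s), pair_metrics(s, s))
  }
})

test_that("each reference pair credits at most one prediction", {
  ref <- secondary_structure(20, rbind(c(5, 12)))
  pred <- secondary_structure(20, rbind(c(4, 12), c(6, 12)), check = FALSE)
  m <- shifted_pair_metrics(pred, ref)
  expect_equal(m$tp, 1L)
  expect_equal(m$fp, 1L)
})

test_that("shifted scores never fall below plain scores", {
  set.seed(62)
  for (rep in 1:50) {
    L <- sample(15:50, 1)
    pred <- random_pair_set(L)
    ref <- random_pair_set(L)
    p <- pair_metrics(pred, ref)
    s <- shifted_pair_metrics(pred, ref)
    expect_gte(s$tp, p$tp)
    expect_gte(s$f1, p$f1)
    # count identities of the plain variant
    expect_equal(p$tp + p$fn, nrow(ref$pairs))
    expect_equal(p$tp + p$fp, nrow(pred$pairs))
  }
})

test_that("aggregation computes length-weighted F1", {
  m <- list(list(precision = 1, recall = 1, f1 = 1),
            list(precision = 0.5, recall = 0.5, f1 = 0.5))
  agg <- aggregate_metrics(m, c(10L, 30L))
  expect_equal(agg$weighted_f1, 0.625)
  expect_equal(agg$f1, 0.75)
  # equal lengths: weighted equals plain mean
  agg2 <- aggregate_metrics(m, c(20L, 20L))
  expect_equal(agg2$weighted_f1, agg2$f1)
  # single record: its own F1
  expect_equal(aggregate_metrics(m[2], 40L)$weighted_f1, 0.5)
  # invariance under reordering
  agg3 <- aggregate_metrics(rev(m), c(30L, 10L))
  expect_equal(agg3$weighted_f1, agg$weighted_f1)
  expect_error(aggregate_metrics(list(), integer(0)), "no records")
})

test_that("pseudoknot confusion counts all four outcomes", {
  pk <- secondary_structure(15, rbind(c(1, 10), c(5, 15)))
  nested <- secondary_structure(15, rbind(c(1, 10), c(2, 9)))
  refs <- list(pk, pk, nested, nested)
  preds <- list(pk, nested, pk, nested)
  cm <- pseudoknot_confusion(preds, refs)
  expect_equal(as.vector(cm), c(1L, 1L, 1L, 1L))
  cm2 <- pseudoknot_confusion(list(nested, nested), list(nested, nested))
  expect_equal(sum(cm2["pk", ]), 0L)
  expect_equal(cm2["nested", "nested"], 2L)
})

test_that("a decoded pseudoknotted target is counted as pseudoknot-detected", {
  set.seed(63)
  rec <- make_dataset(1, synthetic_config(length_range = c(40, 60),
                                          pseudoknot_prob = 1))[[1]]
  pred <- blossom_decode(encode_target(rec$structure), valid_mask(rec$sequence),
                         decode_config(method = "blossom"))
  cm <- pseudoknot_confusion(list(pred), list(rec$structure))
  expect_equal(cm["pk", "pk"], 1L)
})

test_that("evaluation reports aggregate consistently and write as TSV", {
  set.seed(64)
  refs <- make_dataset(5, synthetic_config(length_range = c(25, 45)))
  preds <- lapply(refs, function(r) {
    argmax_decode(encode_target(r$structure), valid_mask(r$sequence))$structure
  })
  rep <- evaluate_structures(preds, refs)
  expect_equal(rep$summary$plain$f1, 1)
  expect_equal(rep$summary$plain$weighted_f1, 1)
  expect_equal(nrow(rep$per_record), 5L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, f)
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 5L)
  expect_true(all(c("id", "L", "f1", "f1_s", "pseudoknotted_ref") %in% names(tab)))
})
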