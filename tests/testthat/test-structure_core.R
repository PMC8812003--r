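test_that("canonical pair classification accepts exactly the six classes", {
  expect_equal(canonical_pair_type("G", "C"), "GC")
  expect_equal(canonical_pair_type("U", "G"), "UG")  # wobble
  expect_true(is.na(canonical_pair_type("A", "G")))
  accepted <- outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                    function(a, b) !is.na(canonical_pair_type(a, b)))
  expect_equal(sum(accepted), 6L)
  expect_error(canonical_pair_type("N", "A"), "must be one of")
})

test_that("sequence construction normalizes and validates residues", {
  q <- rna_sequence("acgt")
  expect_equal(q$residues, c("A", "C", "G", "U"))
  expect_error(rna_sequence(""), "at least one")
  expect_error(rna_sequence("ACGN"), "non-AUCG")
  qb <- rna_sequence("ACGN", ambiguous = "block")
  expect_equal(qb$residues[4], "N")
  expect_error(rna_sequence("AC!G", ambiguous = "block"), "non-letter")
})

test_that("structure construction enforces the single-partner invariant", {
  s <- secondary_structure(31, cbind(c(2:5, 10:12), c(27:24, 19:17)))
  expect_equal(nrow(s$pairs), 7L)
  expect_true(all(s$pairs[, 1] < s$pairs[, 2]))
  expect_error(secondary_structure(15, rbind(c(1, 10), c(1, 12))), "more than one pair")
  expect_error(secondary_structure(10, rbind(c(1, 12))), "out of range")
  expect_error(secondary_structure(10, rbind(c(3, 3))), "pair with itself")
  # unchecked construction is available for decoders that must report conflicts
  raw <- secondary_structure(15, rbind(c(1, 10), c(1, 12)), check = FALSE)
  expect_equal(nrow(raw$pairs), 2L)
})

test_that("partner vector uses the CT convention", {
  s <- secondary_structure(8, rbind(c(1, 5), c(2, 8)))
  expect_equal(partner_vector(s), c(5L, 8L, 0L, 0L, 1L, 0L, 0L, 2L))
})

test_that("pseudoknot detection is the crossing-pair criterion", {
  expect_true(is_pseudoknotted(secondary_structure(15, rbind(c(1, 10), c(5, 15)))))
  expect_false(is_pseudoknotted(secondary_structure(10, rbind(c(1, 10), c(2, 9)))))
  expect_false(is_pseudoknotted(secondary_structure(10)))
  # (11,14) sits inside the (5,15) loop: nested, not crossing
  flags <- crossing_pairs(secondary_structure(15, rbind(c(1, 10), c(5, 15), c(11, 14))))
  expect_equal(flags, c(TRUE, TRUE, FALSE))
})

test_that("nested generator output is never flagged as pseudoknotted", {
  set.seed(41)
  cfg <- synthetic_config(length_range = c(30, 70), pseudoknot_prob = 0)
  for (i in 1:50) expect_false(is_pseudoknotted(sample_structure(cfg)))
})

test_that("validation reports each constraint violation with its indices", {
  we <- worked_example()
  expect_equal(nrow(validate_structure(we$s, we$q)), 0L)

  q <- rna_sequence("GAC")
  v <- validate_structure(secondary_structure(3, rbind(c(1, 3)), check = FALSE), q)
  expect_equal(v$kind, "min_distance")

  q2 <- rna_sequence(strrep("A", 15))
  s2 <- secondary_structure(15, rbind(c(1, 10), c(1, 15)), check = FALSE)
  v2 <- validate_structure(s2, q2)
  expect_true(all(c("multi_pairing", "non_canonical") %in% v2$kind))

  expect_error(validate_structure(we$s, rna_sequence("ACGU")), "does not match")
})

test_that("a clean validation implies canonical pairs at legal distances", {
  set.seed(42)
  recs <- make_dataset(20, synthetic_config(length_range = c(30, 80)))
  for (r in recs) {
    expect_equal(nrow(validate_structure(r$structure, r$sequence)), 0L)
    p <- r$structure$pairs
    expect_true(all(p[, 2] - p[, 1] >= pair_min_distance()))
    cls <- canonical_pair_type(r$sequence$residues[p[, 1]],
                               r$sequence$residues[p[, 2]])
    expect_false(any(is.na(cls)))
  }
})

test_that("deliberate corruption triggers the matching violation kind", {
  set.seed(43)
  rec <- make_dataset(1, synthetic_config(length_range = c(40, 60)))[[1]]
  for (kind in c("non_canonical", "min_distance", "multi_pairing")) {
    bad <- corrupt_record(rec, kind)
    expect_true(kind %in% validate_structure(bad$structure, bad$sequence)$kind)
  }
})
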