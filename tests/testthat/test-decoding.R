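test_that("symmetrization averages a matrix with its transpose", {
  Y <- matrix(c(0, 0, 2, 0), 2, 2)
  S <- symmetrize_scores(Y)
  expect_equal(S[1, 2], 1)
  expect_equal(S[2, 1], 1)
  sym <- matrix(c(1, 3, 3, 2), 2, 2)
  expect_equal(symmetrize_scores(sym), sym)       # fixed point
  anti <- matrix(c(0, -4, 4, 0), 2, 2)
  expect_equal(symmetrize_scores(anti), matrix(0, 2, 2))
})

test_that("argmax decoding recovers exact targets without violations", {
  set.seed(51)
  recs <- make_dataset(20, synthetic_config(length_range = c(20, 60),
                                            pseudoknot_prob = 0.4))
  for (r in recs) {
    dec <- argmax_decode(encode_target(r$structure), valid_mask(r$sequence))
    expect_equal(dec$structure$pairs, r$structure$pairs)
    expect_equal(nrow(dec$violations), 0L)
  }
})

test_that("argmax picks row maxima, reports conflicts, breaks ties low", {
  # an 8-nt sequence whose mask admits (1,5) and (4,8)
  q <- rna_sequence("GAAGCAAC")
  V <- valid_mask(q)
  expect_true(V[1, 5] && V[4, 8])
  Y <- diag(8)
  Y[1, 5] <- Y[5, 1] <- 5
  Y[4, 8] <- Y[8, 4] <- 5
  dec <- argmax_decode(Y, V)
  expect_equal(dec$structure$pairs,
               matrix(c(1L, 4L, 5L, 8L), 2, dimnames = list(NULL, c("i", "j"))))
  expect_equal(nrow(dec$violations), 0L)

  # conflicting rows: 5 prefers 1, but 8 also points at 1 via asymmetry
  q2 <- rna_sequence("GAAACCCC")  # G can pair with any C at distance >= 3
  V2 <- valid_mask(q2)
  Y2 <- diag(8) * 0.1
  Y2[1, 5] <- Y2[5, 1] <- 3
  Y2[8, 1] <- 4   # row 8 points at 1; row 1 still prefers 5
  dec2 <- argmax_decode(Y2, V2)
  expect_true(nrow(dec2$violations) > 0)
  expect_equal(unique(dec2$violations$kind), "multi_pairing")

  # tie between two equal valid cells: lowest column index wins
  q3 <- rna_sequence("GAAACAAC")
  V3 <- valid_mask(q3)
  Y3 <- diag(8) * 0.1
  Y3[1, 5] <- Y3[1, 8] <- 2
  dec3 <- argmax_decode(Y3, V3)
  expect_true(any(dec3$structure$pairs[, 1] == 1 & dec3$structure$pairs[, 2] == 5))
})

test_that("argmax rejects rows with no admissible cell", {
  Y <- matrix(-Inf, 4, 4)
  V <- matrix(FALSE, 4, 4)
  expect_error(argmax_decode(Y, V), "no admissible cell")
})

test_that("blossom decoding recovers exact targets and matches argmax there", {
  set.seed(52)
  recs <- make_dataset(20, synthetic_config(length_range = c(20, 60),
                                            pseudoknot_prob = 0.4))
  for (r in recs) {
    T_ <- encode_target(r$structure)
    V <- valid_mask(r$sequence)
    sb <- blossom_decode(T_, V, decode_config(method = "blossom"))
    expect_equal(sb$pairs, r$structure$pairs)
    sa <- argmax_decode(T_, V)$structure
    expect_equal(sb$pairs, sa$pairs)
  }
})

test_that("blossom attains the exhaustive optimum on small instances", {
  set.seed(53)
  for (rep in 1:30) {
    L <- sample(4:9, 1)
    inst <- random_scored_instance(L)
    s <- blossom_decode(inst$Y, inst$V,
                        decode_config(method = "blossom", k = L))
    obj <- structure_objective(s, inst$Y)
    best <- brute_best_objective(inst$Y, inst$V)
    expect_equal(obj, best, tolerance = 1e-9)
  }
})

test_that("blossom output is always a valid structure", {
  set.seed(54)
  for (rep in 1:40) {
    L <- sample(20:120, 1)
    inst <- random_scored_instance(L)
    s <- blossom_decode(inst$Y, inst$V, decode_config(method = "blossom"))
    expect_equal(nrow(validate_structure(s, inst$q)), 0L)
  }
})

test_that("a dominant diagonal yields the all-unpaired structure", {
  q <- rna_sequence("GGGGAAAACCCC")
  V <- valid_mask(q)
  Y <- matrix(0.01, 12, 12)
  diag(Y) <- 10
  s <- blossom_decode(Y, V, decode_config(method = "blossom"))
  expect_equal(nrow(s$pairs), 0L)
  # an all-zero matrix is degenerate: nothing scores, nothing pairs
  s2 <- blossom_decode(matrix(0, 12, 12), V, decode_config(method = "blossom"))
  expect_equal(nrow(s2$pairs), 0L)
  # with negative scores everywhere, pairing can still be the optimum:
  # two bases paired cost 2*y_ij, unpaired they cost 2*(y_ii + y_jj)
  Yn <- matrix(-1, 12, 12) - diag(12)
  s3 <- blossom_decode(Yn, V, decode_config(method = "blossom"))
  expect_gte(structure_objective(s3, Yn),
             structure_objective(secondary_structure(12), Yn))
})

test_that("top-k pruning rarely loses objective relative to the full graph", {
  set.seed(55)
  worse <- 0L
  n <- 40L
  for (rep in seq_len(n)) {
    L <- sample(20:50, 1)
    inst <- random_scored_instance(L)
    s3 <- blossom_decode(inst$Y, inst$V, decode_config(method = "blossom", k = 3))
    sL <- blossom_decode(inst$Y, inst$V, decode_config(method = "blossom", k = L))
    o3 <- structure_objective(s3, inst$Y)
    oL <- structure_objective(sL, inst$Y)
    expect_lte(o3, oL + 1e-9)  # pruning can only reduce the objective
    if (o3 < oL - 1e-9) worse <- worse + 1L
  }
  # random matrices are harder for pruning than trained score matrices,
  # where scores are concentrated; still, k = 3 should usually suffice
  expect_lte(worse, n %/% 2)
})

test_that("the decode front door dispatches on the configured method", {
  we <- worked_example()
  T_ <- encode_target(we$s)
  V <- valid_mask(we$q)
  a <- decode_structure(T_, V, decode_config(method = "argmax"))
  b <- decode_structure(T_, V, decode_config(method = "blossom"))
  expect_equal(a$structure$pairs, we$s$pairs)
  expect_equal(b$structure$pairs, we$s$pairs)
  expect_equal(nrow(b$violations), 0L)
})
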