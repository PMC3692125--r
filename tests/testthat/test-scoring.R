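test_that("optimal parse scores match the pure-R parse-tree oracle", {
  strings <- all_rna_strings(4)
  for (seed in 1:8) {
    m <- build_toy_cm(random_toy_spec(seed, min_len = 1, max_len = 3,
                                      allow_bif = FALSE), name = "t")
    expect_lte(n_states(m), 25)
    for (s in strings)
      expect_equal(optimal_parse_score(m, s)$score, r_parse_score(m, s),
                   tolerance = 1e-9, label = paste("seed", seed, "seq", s))
  }
  # one bifurcated fixture, shorter string set
  mb <- build_toy_cm(toy_model_spec("GCACGUAC", "(.)((.))", seed = 1))
  for (s in c("", "A", "ACGCGU", "ACGU", "GGGGG"))
    expect_equal(optimal_parse_score(mb, s)$score, r_parse_score(mb, s),
                 tolerance = 1e-9)
})

test_that("state-path bits add up to the reported score", {
  for (seed in c(2, 5, 11)) {
    m <- build_toy_cm(random_toy_spec(seed, min_len = 3, max_len = 6,
                                      allow_bif = TRUE))
    p <- best_sequence(m)
    expect_equal(sum(p$state_path$trans_bits) + sum(p$state_path$emit_bits),
                 p$score, tolerance = 1e-9)
    expect_identical(nchar(p$structure), nchar(p$sequence))
  }
})

test_that("best_sequence equals exhaustive enumeration", {
  for (seed in 1:10) {
    m <- build_toy_cm(random_toy_spec(seed, min_len = 1, max_len = 5,
                                      allow_bif = FALSE))
    bs <- best_sequence(m)
    bf <- brute_force_best_sequence(m, max_len = 8)
    expect_equal(bs$score, bf$score, tolerance = 1e-9)
    expect_identical(bs$sequence, bf$sequence)
  }
})

test_that("no longer or different sequence beats the best sequence", {
  m <- build_toy_cm(random_toy_spec(3, min_len = 2, max_len = 4))
  best <- best_sequence(m)$score
  for (s in all_rna_strings(5))
    expect_lte(optimal_parse_score(m, s)$score, best + 1e-9)
})

test_that("the empty sequence is scored via pure deletion", {
  m <- tiny_model()
  p <- optimal_parse_score(m, "")
  expect_identical(p$sequence, "")
  expect_true(is.finite(p$score))
  expect_lt(p$score, 0)   # deletions are penalized
  expect_equal(p$score, r_parse_score(m, ""), tolerance = 1e-9)
})

test_that("structure brackets appear exactly at MP-emitted positions", {
  m <- build_toy_cm(toy_model_spec("GCGAAACGC", "(((...)))", boost = 2,
                                   seed = 4))
  p <- best_sequence(m)
  expect_identical(p$structure, "(((...)))")
  un <- optimal_parse_score(m, "AAAAAAAAA")
  pt <- cmlink:::structure_pairs(un$structure)   # pairing vector
  mp_rows <- un$state_path[un$state_path$type == "MP", ]
  expect_identical(as.integer(sum(pt != 0) / 2), nrow(mp_rows))
})

test_that("scoring guards refuse out-of-contract inputs", {
  m <- tiny_model()
  expect_error(brute_force_best_sequence(m, max_len = 9), "<= 8")
  expect_error(best_sequence(break_model("hazard")), "hazard")
})
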