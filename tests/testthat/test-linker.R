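test_that("a model linked with itself attains its best score", {
  for (seed in 1:8) {
    m <- build_toy_cm(random_toy_spec(seed, allow_bif = seed %% 2 == 0),
                      name = "self")
    r <- link_models(m, m)
    b <- best_sequence(m)
    expect_equal(r$link_score, b$score, tolerance = 1e-6)
    expect_equal(r$score_a, r$score_b, tolerance = 1e-9)
    expect_identical(r$structure_a, r$structure_b)
  }
})

test_that("the link sequence scores at least the link score in each model", {
  for (seed in 1:15) {
    p <- toy_pair(seed, min_len = 2, max_len = 6)
    r <- link_models(p$a, p$b)
    ra <- optimal_parse_score(p$a, r$link_sequence)
    rb <- optimal_parse_score(p$b, r$link_sequence)
    expect_gte(ra$score, r$link_score - 1e-9)
    expect_gte(rb$score, r$link_score - 1e-9)
    # reported per-model joint scores are also bounded by the re-parses
    expect_gte(ra$score, r$score_a - 1e-9)
    expect_gte(rb$score, r$score_b - 1e-9)
    expect_equal(r$link_score, min(r$score_a, r$score_b))
  }
})

test_that("link scores match exhaustive enumeration on bifurcation-free pairs", {
  for (seed in 1:10) {
    p <- toy_pair(seed, min_len = 2, max_len = 4)
    max_len <- max(nchar(p$spec_a$consensus), nchar(p$spec_b$consensus)) + 3L
    bf <- brute_force_link(p$a, p$b, max_len = max_len)
    r <- link_models(p$a, p$b)
    expect_equal(r$link_score, bf$link_score, tolerance = 1e-6,
                 label = paste("pair seed", seed))
  }
})

test_that("link scores never exceed the enumeration oracle", {
  for (seed in 1:5) {
    p <- toy_pair(seed + 50, min_len = 4, max_len = 5, allow_bif = TRUE)
    bf <- brute_force_link(p$a, p$b, max_len = 8)
    r <- link_models(p$a, p$b)
    expect_lte(r$link_score, bf$link_score + 1e-9)
  }
})

test_that("swapping the argument order only swaps the roles", {
  p <- toy_pair(7, min_len = 3, max_len = 6)
  f <- link_models(p$a, p$b)
  r <- link_models(p$b, p$a)
  expect_equal(f$link_score, r$link_score, tolerance = 0)
  expect_equal(f$score_a, r$score_b, tolerance = 0)
  expect_equal(f$score_b, r$score_a, tolerance = 0)
  expect_identical(f$link_sequence, r$link_sequence)
  expect_identical(f$structure_a, r$structure_b)
  expect_identical(f$structure_b, r$structure_a)
})

test_that("the link score is bounded by both models' best scores", {
  for (seed in 1:10) {
    p <- toy_pair(seed + 20, min_len = 2, max_len = 7)
    r <- link_models(p$a, p$b)
    expect_lte(r$link_score,
               min(best_sequence(p$a)$score, best_sequence(p$b)$score) + 1e-9)
  }
})

test_that("product structures mark pairs only where each model pairs", {
  a <- build_toy_cm(toy_model_spec("GCGAAC", "((..))", boost = 2, seed = 1),
                    name = "hairpin")
  b <- build_toy_cm(toy_model_spec("GCGAAC", "......", boost = 2, seed = 2),
                    name = "flat")
  r <- link_models(a, b)
  st <- product_structures(r)
  expect_identical(unname(st["b"]), strrep(".", nchar(r$link_sequence)))
  expect_identical(nchar(st[["a"]]), nchar(r$link_sequence))
  expect_true(cmlink:::is_balanced_structure(st[["a"]]))
})

test_that("a pair with no common sequence yields the sentinel", {
  # a model that must emit at least one character (no deletion path from
  # the root's ML) paired against one that only accepts the empty
  # sequence cannot happen with the generator; instead check the
  # sentinel plumbing directly on the brute-force side with max_len 0
  # against a model whose empty-sequence parse exists
  m <- tiny_model()
  bf <- brute_force_link(m, m, max_len = 0)
  expect_true(is.finite(bf$link_score))   # deletion parse exists
  expect_identical(bf$link_sequence, "")
})

test_that("link results are reproducible across repeated runs", {
  p <- toy_pair(13, min_len = 3, max_len = 6)
  r1 <- link_models(p$a, p$b)
  r2 <- link_models(p$a, p$b)
  expect_identical(r1[names(r1) != "diag"], r2[names(r2) != "diag"])
})
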