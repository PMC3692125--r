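test_that("generated toy models satisfy every structural invariant", {
  for (seed in 1:30) {
    sp <- random_toy_spec(seed, allow_bif = seed %% 2 == 0)
    m <- build_toy_cm(sp, name = "t")
    expect_length(validate_model(m), 0)
    expect_identical(m$clen, nchar(sp$consensus))
  }
})

test_that("the guide tree mirrors the requested structure", {
  m <- build_toy_cm(toy_model_spec("GCGAAACGC", "(((...)))", seed = 1))
  node_types <- vapply(m$nodes, `[[`, character(1), "type")
  expect_identical(sum(node_types == "MATP"), 3L)
  expect_identical(sum(node_types == "MATL"), 3L)
  expect_false("BIF" %in% node_types)

  mb <- build_toy_cm(toy_model_spec("GCAAGCGCAAGC", "((..))((..))", seed = 1))
  nb <- vapply(mb$nodes, `[[`, character(1), "type")
  expect_identical(sum(nb == "BIF"), 1L)
  expect_identical(sum(nb == "BEGL"), 1L)
  expect_identical(sum(nb == "BEGR"), 1L)
})

test_that("boost controls how strongly the consensus is preferred", {
  weak <- build_toy_cm(toy_model_spec("ACGU", "....", boost = 0.5, seed = 1))
  strong <- build_toy_cm(toy_model_spec("ACGU", "....", boost = 2, seed = 1))
  expect_gt(best_sequence(strong)$score, best_sequence(weak)$score)
  expect_identical(best_sequence(strong)$sequence, "ACGU")
})

test_that("toy generation is deterministic and leaves the RNG untouched", {
  set.seed(1234)
  before <- runif(1)
  m1 <- build_toy_cm(toy_model_spec("GAU", "...", seed = 9))
  set.seed(1234)
  invisible(runif(1))
  m2 <- build_toy_cm(toy_model_spec("GAU", "...", seed = 9))
  after <- runif(1)
  expect_identical(write_cm_file(m1), write_cm_file(m2))
  set.seed(1234)
  expect_identical(c(runif(1), runif(1)), c(before, after))
})

test_that("toy models are hazard-free by construction", {
  for (seed in 1:10) {
    m <- build_toy_cm(random_toy_spec(seed, allow_bif = TRUE))
    expect_length(validate_model(m), 0)
    ty <- state_types(m)
    for (v in which(ty %in% c("IL", "IR")) - 1L) {
      st <- m$states[[v + 1L]]
      k <- which(state_children(m, v) == v)
      expect_lt(st$trans[[k]] + max(st$emis), 0)
    }
  }
})
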