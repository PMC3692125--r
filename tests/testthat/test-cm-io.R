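test_that("round-trip write/parse preserves models in both dialects", {
  for (seed in 1:50) {
    sp <- random_toy_spec(seed, min_len = 1, max_len = 8,
                          allow_bif = seed %% 3 == 0)
    m <- build_toy_cm(sp, name = sprintf("toy%02d", seed))
    for (dialect in c("1.1", "1.0")) {
      txt <- write_cm_file(m, dialect = dialect)
      back <- parse_cm_file(txt)[[1]]
      expect_identical(back$name, m$name)
      expect_identical(length(back$states), length(m$states))
      expect_identical(vapply(back$states, `[[`, character(1), "type"),
                       vapply(m$states, `[[`, character(1), "type"))
      for (v in seq_along(m$states)) {
        expect_equal(back$states[[v]]$trans, m$states[[v]]$trans,
                     tolerance = 1e-4)
        expect_equal(back$states[[v]]$emis, m$states[[v]]$emis,
                     tolerance = 1e-4)
      }
      expect_length(validate_model(back), 0)
    }
  }
})

test_that("round-tripped models score sequences identically to printed precision", {
  m <- build_toy_cm(toy_model_spec("GCGAAACGC", "(((...)))", seed = 3),
                    name = "hairpin")
  back <- parse_cm_file(write_cm_file(m, dialect = "1.0"))[[1]]
  s <- best_sequence(m)$sequence
  expect_equal(optimal_parse_score(back, s)$score,
               optimal_parse_score(m, s)$score, tolerance = 1e-3)
})

test_that("multi-record files parse into one model per record", {
  m1 <- build_toy_cm(toy_model_spec("AC", "..", seed = 1), name = "one")
  m2 <- build_toy_cm(toy_model_spec("GU", "..", seed = 2), name = "two")
  txt <- write_cm_file(list(m1, m2))
  models <- parse_cm_file(txt)
  expect_length(models, 2)
  expect_identical(vapply(models, `[[`, character(1), "name"),
                   c("one", "two"))
})

test_that("a hand-written minimal record parses", {
  txt <- paste(
    "INFERNAL-1 [toy]",
    "NAME  mini",
    "STATES 7",
    "NODES 3",
    "ALPH  RNA",
    "NULL  0.00000 0.00000 0.00000 0.00000",
    "MODEL:",
    "    [ ROOT 0 ]",
    "     S 0 -1 0 1 3 -5.00000 -5.00000 -0.10000",
    "    IL 1 1 2 1 3 -6.00000 -6.00000 -6.00000 0.0 0.0 0.0 0.0",
    "    IR 2 2 1 2 2 -6.00000 -6.00000 0.0 0.0 0.0 0.0",
    "    [ MATL 1 ]",
    "    ML 3 2 3 5 2 -5.00000 -0.10000 2.00000 -3.0 -3.0 -3.0",
    "     D 4 2 3 5 2 -1.00000 -1.00000",
    "    IL 5 5 2 5 2 -6.00000 -6.00000 0.0 0.0 0.0 0.0",
    "    [ END 2 ]",
    "     E 6 5 2 -1 0",
    "//", sep = "\n")
  m <- parse_cm_file(txt)[[1]]
  expect_identical(m$name, "mini")
  expect_length(validate_model(m), 0)
  expect_identical(state_types(m),
                   c("S", "IL", "IR", "ML", "D", "IL", "E"))
  expect_gt(optimal_parse_score(m, "A")$score, 0)
})

test_that("parser reports malformed input with the offending line", {
  expect_error(parse_cm_file("INFERNAL-1 [x]\nNAME y\n//"),
               "MODEL|marker")
  expect_error(parse_cm_file("not a cm\n//"), "header")
  m <- tiny_model()
  txt <- gsub("(?m)^NAME.*\\n", "", write_cm_file(m), perl = TRUE)
  expect_error(parse_cm_file(txt), "NAME")
  txt2 <- sub("STATES +[0-9]+", "STATES 99", write_cm_file(m))
  expect_error(parse_cm_file(txt2), "STATES")
})

test_that("validate_model flags each violated invariant", {
  expect_length(validate_model(tiny_model()), 0)
  expect_gt(length(validate_model(break_model("root"))), 0)
  expect_gt(length(validate_model(break_model("null"))), 0)
  expect_gt(length(validate_model(break_model("arity"))), 0)
  expect_gt(length(validate_model(break_model("children"))), 0)
  hz <- validate_model(break_model("hazard"))
  expect_true(any(grepl("hazard|self-loop", hz)))
})

test_that("sequence encoding maps T to U and rejects IUPAC ambiguity codes", {
  m <- tiny_model()
  expect_identical(optimal_parse_score(m, "t")$sequence, "U")
  expect_equal(optimal_parse_score(m, "T")$score,
               optimal_parse_score(m, "U")$score)
  expect_error(optimal_parse_score(m, "N"), "IUPAC|unsupported")
  expect_error(optimal_parse_score(m, "R"), "IUPAC|unsupported")
})

test_that("read_cm_dir skips unreadable files with a warning", {
  dir <- tempfile("cmdir")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write_cm_file(tiny_model(), path = file.path(dir, "good.cm"))
  writeLines("not a CM at all", file.path(dir, "bad.cm"))
  expect_warning(models <- read_cm_dir(dir), "bad.cm")
  expect_length(models, 1)
  expect_identical(models[[1]]$name, "tiny")
})

test_that("stockholm_to_cm without Infernal explains the requirement", {
  old_path <- Sys.getenv("PATH")
  on.exit(Sys.setenv(PATH = old_path))
  Sys.setenv(PATH = tempfile("empty"))   # guarantee cmbuild is not found
  expect_error(stockholm_to_cm("whatever.sto"), "Infernal")
})
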