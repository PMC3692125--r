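report_toys <- function() {
  lapply(1:4, function(i)
    build_toy_cm(random_toy_spec(i + 70, min_len = 3, max_len = 5),
                 name = paste0("rep", i)))
}

test_that("TSV has the canonical schema and round-trips its numbers", {
  toys <- report_toys()
  tab <- compare_all_vs_all(toys)
  txt <- to_tsv(tab)
  df <- utils::read.delim(text = txt, check.names = FALSE,
                          colClasses = "character")
  expect_identical(names(df),
                   c("modelA", "modelB", "scoreA", "scoreB", "linkScore",
                     "linkSequence", "structureA", "structureB"))
  expect_identical(nrow(df), length(tab$entries))
  for (i in seq_along(tab$entries)) {
    e <- tab$entries[[i]]
    expect_identical(df$linkScore[i], sprintf("%.1f", e$link_score))
    expect_identical(df$scoreA[i], sprintf("%.1f", e$score_a))
    expect_identical(df$linkSequence[i], e$link_sequence)
    expect_identical(df$structureA[i], e$structure_a)
  }
  # byte determinism
  expect_identical(txt, to_tsv(compare_all_vs_all(toys)))
  # empty table renders header-only
  empty <- filter_results(tab, min_link_score = 1e6)
  expect_identical(to_tsv(empty),
                   paste0(strsplit(txt, "\n")[[1]][1], "\n"))
})

test_that("the score matrix is symmetric with best scores on the diagonal", {
  toys <- report_toys()
  tab <- compare_all_vs_all(toys)
  m <- to_matrix(tab, diagonal = "BEST_SCORE", models = toys)
  expect_identical(dim(m), c(4L, 4L))
  expect_equal(max(abs(m - t(m))), 0)
  for (i in 1:4)
    expect_equal(m[toys[[i]]$name, toys[[i]]$name],
                 best_sequence(toys[[i]])$score, tolerance = 1e-9)
  # every off-diagonal cell equals some TSV row's linkScore
  txt_scores <- vapply(tab$entries, function(e)
    sprintf("%.1f", e$link_score), character(1))
  off <- m[upper.tri(m)]
  expect_true(all(sprintf("%.1f", off) %in% txt_scores))

  bl <- to_matrix(tab, diagonal = "BLANK")
  expect_true(all(is.na(diag(bl))))
  expect_error(to_matrix(compare_one_vs_many(toys[1], toys[2:3])),
               "ALL_VS_ALL")
})

test_that("two identical models give a constant 2x2 matrix", {
  m1 <- build_toy_cm(random_toy_spec(80, min_len = 3, max_len = 4), "a")
  m2 <- m1; m2$name <- "b"
  tab <- compare_all_vs_all(list(m1, m2))
  mat <- to_matrix(tab, diagonal = "BEST_SCORE", models = list(m1, m2))
  expect_equal(max(mat) - min(mat), 0, tolerance = 1e-9)
})

test_that("DOT output follows the grammar and mirrors the graph", {
  toys <- report_toys()
  tab <- compare_all_vs_all(toys)
  g <- build_link_graph(tab, top_n = 3)
  dot <- to_dot(g)
  lines <- strsplit(dot, "\n")[[1]]
  expect_identical(lines[1], "graph cmlink {")
  expect_identical(lines[length(lines)], "}")
  body <- lines[-c(1, length(lines))]
  node_re <- '^  "[^"]+";$'
  edge_re <- '^  "[^"]+" -- "[^"]+" \\[label="-?[0-9]+\\.[0-9]"\\];$'
  expect_true(all(grepl(node_re, body) | grepl(edge_re, body)))
  expect_identical(sum(grepl(edge_re, body)), 3L)
  expect_identical(sum(grepl(node_re, body)), 4L)
  # empty graph still renders a valid document
  g0 <- build_link_graph(tab, min_link_score = 1e6)
  d0 <- strsplit(to_dot(g0), "\n")[[1]]
  expect_identical(d0[1], "graph cmlink {")
  expect_false(any(grepl(" -- ", d0)))
  # determinism
  expect_identical(dot, to_dot(build_link_graph(tab, top_n = 3)))
})

test_that("detail views align structures and re-optimized scores", {
  toys <- report_toys()
  r <- link_models(toys[[1]], toys[[2]])
  txt <- detail_view(r, toys[[1]], toys[[2]])
  lines <- strsplit(txt, "\n")[[1]]
  seq_line <- grep("^  [ACGU]+$", lines)[1]
  expect_false(is.na(seq_line))
  expect_identical(nchar(trimws(lines[seq_line + 1])) > 0, TRUE)
  expect_match(txt, sprintf("Link score: %.1f", r$link_score))
  expect_equal(r$link_score, min(r$score_a, r$score_b))
  expect_error(detail_view(r, toys[[2]], toys[[1]]), "match")

  # self comparison: identical structures
  rs <- link_models(toys[[1]], toys[[1]])
  ds <- detail_view(rs, toys[[1]], toys[[1]])
  expect_identical(rs$structure_a, rs$structure_b)

  # hairpin vs unstructured: second structure all dots
  a <- build_toy_cm(toy_model_spec("GGGAAACCC", "(((...)))", boost = 2,
                                   seed = 1), name = "hp")
  b <- build_toy_cm(toy_model_spec("GGGAAACCC", ".........", boost = 2,
                                   seed = 2), name = "flat")
  rh <- link_models(a, b)
  dv <- detail_view(rh, a, b)
  expect_match(dv, "\\.{9}  \\(flat\\)")
})

test_that("binned matrix discretizes against the given thresholds", {
  toys <- report_toys()
  tab <- compare_all_vs_all(toys)
  m <- to_matrix(tab, diagonal = "BEST_SCORE", models = toys)
  txt <- to_binned_tsv(m, thresholds = c(0, 5))
  df <- utils::read.delim(text = txt)
  expect_identical(nrow(df), 4L)
  vals <- as.matrix(df[, -1])
  expect_true(all(vals %in% 0:2))
})
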