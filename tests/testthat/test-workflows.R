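five_toys <- function() {
  lapply(1:5, function(i)
    build_toy_cm(random_toy_spec(i + 40, min_len = 3, max_len = 5),
                 name = paste0("toy", i)))
}

test_that("one-vs-many covers every query/database pair in order", {
  toys <- five_toys()
  t1 <- compare_one_vs_many(toys[1], toys[2:4])
  expect_identical(t1$mode, "ONE_VS_MANY")
  expect_length(t1$entries, 3)
  expect_identical(vapply(t1$entries, `[[`, character(1), "model_b"),
                   c("toy2", "toy3", "toy4"))

  # a query present in the database links against its own copy
  t2 <- compare_one_vs_many(toys[1], toys)
  expect_length(t2$entries, 5)
  self <- t2$entries[[1]]
  expect_identical(c(self$model_a, self$model_b), c("toy1", "toy1"))
  expect_equal(self$link_score, best_sequence(toys[[1]])$score,
               tolerance = 1e-6)
})

test_that("two queries against five toys give ten symmetric entries", {
  toys <- five_toys()
  queries <- lapply(toys[1:2], function(m) {
    m$name <- paste0("q_", m$name); m
  })
  tab <- compare_one_vs_many(queries, toys)
  expect_length(tab$entries, 10)
  for (e in tab$entries) {
    qi <- match(e$model_a, c("q_toy1", "q_toy2"))
    di <- match(e$model_b, paste0("toy", 1:5))
    sw <- link_models(toys[[di]], queries[[qi]])
    expect_equal(sw$link_score, e$link_score, tolerance = 0)
    expect_equal(c(sw$score_b, sw$score_a), c(e$score_a, e$score_b),
                 tolerance = 0)
  }
})

test_that("all-vs-all yields C(k,2) entries, invariant under permutation", {
  toys <- five_toys()
  tab <- compare_all_vs_all(toys)
  expect_identical(tab$mode, "ALL_VS_ALL")
  expect_length(tab$entries, choose(5, 2))
  perm <- compare_all_vs_all(toys[c(4, 2, 5, 1, 3)])
  expect_identical(to_tsv(tab), to_tsv(perm))
  expect_error(compare_all_vs_all(toys[1]), "at least 2")
})

test_that("two identical models give a single best-score entry", {
  m <- build_toy_cm(random_toy_spec(60, min_len = 3, max_len = 5), "m1")
  m2 <- m; m2$name <- "m2"
  tab <- compare_all_vs_all(list(m, m2))
  expect_length(tab$entries, 1)
  expect_equal(tab$entries[[1]]$link_score, best_sequence(m)$score,
               tolerance = 1e-6)
})

test_that("a failing model is isolated, the rest of the batch completes", {
  toys <- five_toys()
  toys[[3]] <- break_model("hazard")
  toys[[3]]$name <- "toy3"
  tab <- compare_all_vs_all(toys)
  expect_length(tab$entries, choose(5, 2) - 4)
  expect_length(tab$errors, 4)
  expect_true(all(grepl("toy3", names(tab$errors))))
})

test_that("filtering is pure, idempotent and matches a full-sort oracle", {
  toys <- five_toys()
  tab <- compare_all_vs_all(toys)
  expect_identical(to_tsv(filter_results(tab)), to_tsv(tab))

  sc <- vapply(tab$entries, `[[`, numeric(1), "link_score")
  thr <- stats::median(sc)
  ft <- filter_results(tab, min_link_score = thr)
  expect_true(all(vapply(ft$entries, `[[`, numeric(1), "link_score") >= thr))
  expect_identical(to_tsv(filter_results(ft, min_link_score = thr)),
                   to_tsv(ft))

  top <- filter_results(tab, top_n = 5)
  expect_length(top$entries, 5)
  expect_identical(sort(vapply(top$entries, `[[`, numeric(1), "link_score"),
                        decreasing = TRUE),
                   sort(sc, decreasing = TRUE)[1:5])

  hi <- filter_results(tab, min_link_score = max(sc) + 1)
  expect_length(hi$entries, 0)

  nm <- filter_results(tab, name_pattern = "TOY2")   # case-insensitive
  expect_true(all(vapply(nm$entries, function(e)
    grepl("toy2", paste(e$model_a, e$model_b)), logical(1))))
  expect_length(nm$entries, 4)
})

test_that("graphs keep isolated nodes and trace every edge to an entry", {
  toys <- five_toys()
  tab <- compare_all_vs_all(toys)
  sc <- vapply(tab$entries, `[[`, numeric(1), "link_score")
  g <- build_link_graph(tab, min_link_score = max(sc) + 1)
  expect_length(g$nodes, 5)
  expect_identical(nrow(g$edges), 0L)

  g2 <- build_link_graph(tab)
  expect_identical(nrow(g2$edges), length(tab$entries))
  for (i in seq_len(nrow(g2$edges))) {
    hits <- vapply(tab$entries, function(e)
      identical(sort(c(e$model_a, e$model_b)),
                sort(c(g2$edges$from[i], g2$edges$to[i]))) &&
        e$link_score == g2$edges$weight[i], logical(1))
    expect_identical(sum(hits), 1L)
  }
})

test_that("one-vs-many graphs only connect queries with database models", {
  toys <- five_toys()
  q <- toys[[1]]; q$name <- "query"
  tab <- compare_one_vs_many(list(q), toys[2:5])
  g <- build_link_graph(tab)
  expect_true(all(xor(g$edges$from == "query", g$edges$to == "query")))
})

test_that("the planted clan fixture thresholds into a 4-clique plus a satellite", {
  fix <- make_clan_fixture()
  tab <- compare_all_vs_all(fix)
  g <- build_link_graph(tab, min_link_score = 0)
  deg <- table(factor(c(g$edges$from, g$edges$to), levels = g$nodes))
  expect_identical(unname(deg[["lone"]]), 1L)
  clan <- c("clanA", "clanB", "clanC", "bridge")
  in_clan <- g$edges$from %in% clan & g$edges$to %in% clan
  expect_identical(sum(in_clan), 6L)   # C(4, 2): the clan is a clique
  # satellite attaches to the bridge model
  sat_edge <- g$edges[g$edges$from == "lone" | g$edges$to == "lone", ]
  expect_true("bridge" %in% c(sat_edge$from, sat_edge$to))
  # thresholded components recover the planted partition
  comp <- igraph::components(igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = FALSE,
    vertices = g$nodes))$membership
  expect_length(unique(comp), 1)   # satellite joins the clan via the bridge
  g2 <- build_link_graph(tab, min_link_score = 3)
  expect_false(any(g2$edges$from == "lone" | g2$edges$to == "lone"))
})
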