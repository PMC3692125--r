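# Renderers for comparison results: TSV result list, link-score matrix,
# DOT graph, and the per-pair detail view. All renderers are pure and
# byte-deterministic for a given input.

fmt_bits <- function(x) {
  ifelse(is.finite(x), sprintf("%.1f", x), "*")
}

#' Render a link table as TSV
#'
#' One header line plus one row per entry, columns `modelA`, `modelB`,
#' `scoreA`, `scoreB`, `linkScore`, `linkSequence`, `structureA`,
#' `structureB`. Scores are printed to one decimal (the sentinel prints
#' as `*`); rows keep the table's canonical entry order, so output is
#' byte-identical across runs for identical input. Sorting by any column
#' is left to downstream tools.
#'
#' @param table A `link_table`.
#' @return A single string (rows joined with `\n`, trailing newline).
#' @export
to_tsv <- function(table) {
  stopifnot(inherits(table, "link_table"))
  header <- paste(c("modelA", "modelB", "scoreA", "scoreB", "linkScore",
                    "linkSequence", "structureA", "structureB"),
                  collapse = "\t")
  rows <- vapply(table$entries, function(e)
    paste(c(e$model_a, e$model_b, fmt_bits(e$score_a), fmt_bits(e$score_b),
            fmt_bits(e$link_score), e$link_sequence,
            e$structure_a, e$structure_b), collapse = "\t"),
    character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Link-score matrix of an all-vs-all table
#'
#' Square symmetric matrix of link scores over the table's models.
#' Missing pairs (e.g. failed comparisons) get the sentinel. The
#' diagonal follows `diagonal`: `"BEST_SCORE"` fills in each model's
#' [best_sequence()] score — the score of a model "compared with
#' itself" — and requires the `models` list; `"BLANK"` leaves `NA`.
#'
#' @param table A `link_table` with mode `ALL_VS_ALL`.
#' @param diagonal `"BEST_SCORE"` or `"BLANK"`.
#' @param models List of `cm_model` objects (required for
#'   `"BEST_SCORE"`); matched to the table by name.
#' @return A numeric matrix with dimnames; class `link_matrix`.
#' @export
to_matrix <- function(table, diagonal = c("BEST_SCORE", "BLANK"),
                      models = NULL) {
  stopifnot(inherits(table, "link_table"))
  diagonal <- match.arg(diagonal)
  if (table$mode != "ALL_VS_ALL")
    stop("to_matrix requires an ALL_VS_ALL table", call. = FALSE)
  nms <- table$models
  k <- length(nms)
  m <- matrix(cm_sentinel(), k, k, dimnames = list(nms, nms))
  for (e in table$entries) {
    m[e$model_a, e$model_b] <- e$link_score
    m[e$model_b, e$model_a] <- e$link_score
  }
  if (diagonal == "BEST_SCORE") {
    if (is.null(models))
      stop("diagonal = \"BEST_SCORE\" needs the model objects",
           call. = FALSE)
    mod_names <- vapply(models, `[[`, character(1), "name")
    for (nm in nms) {
      i <- match(nm, mod_names)
      if (is.na(i))
        stop("no model object named '", nm, "' supplied", call. = FALSE)
      m[nm, nm] <- best_sequence(models[[i]])$score
    }
  } else {
    diag(m) <- NA_real_
  }
  class(m) <- c("link_matrix", class(m))
  m
}

#' Render a link graph in DOT
#'
#' Emits an undirected `graph` document: one node statement per model
#' (names quoted), one edge per filtered entry labelled with the link
#' score at one decimal. Node and edge order follow the graph object, so
#' output is deterministic; no layout coordinates are included (layout
#' is the renderer's job).
#'
#' @param graph A `link_graph` from [build_link_graph()].
#' @return A single string holding the DOT document.
#' @export
to_dot <- function(graph) {
  stopifnot(inherits(graph, "link_graph"))
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("graph cmlink {",
             paste0("  ", q(graph$nodes), ";"))
  if (nrow(graph$edges) > 0L)
    lines <- c(lines, sprintf("  %s -- %s [label=%s];",
                              q(graph$edges$from), q(graph$edges$to),
                              q(fmt_bits(graph$edges$weight))))
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

#' Detailed view of one comparison
#'
#' Human-readable block for a single pair: both names, the joint-parse
#' scores and link score, the link sequence with both consensus
#' structures aligned beneath it, and the re-optimized per-model scores
#' of the link sequence (each model's true optimum for that sequence,
#' which can only exceed the joint-parse score).
#'
#' @param result A `cm_link`.
#' @param model_a,model_b The `cm_model` objects the result was computed
#'   from; an error is raised when the names do not match.
#' @return A single string.
#' @export
detail_view <- function(result, model_a, model_b) {
  stopifnot(inherits(result, "cm_link"),
            inherits(model_a, "cm_model"), inherits(model_b, "cm_model"))
  if (!identical(result$model_a, model_a$name) ||
      !identical(result$model_b, model_b$name))
    stop("detail_view: models do not match the result (",
         result$model_a, " vs ", result$model_b, ")", call. = FALSE)
  ra <- optimal_parse_score(model_a, result$link_sequence)
  rb <- optimal_parse_score(model_b, result$link_sequence)
  paste0(
    sprintf("Comparison: %s vs %s\n", result$model_a, result$model_b),
    sprintf("Score in %s: %s bits\n", result$model_a,
            fmt_bits(result$score_a)),
    sprintf("Score in %s: %s bits\n", result$model_b,
            fmt_bits(result$score_b)),
    sprintf("Link score: %s bits\n", fmt_bits(result$link_score)),
    "Link sequence and structures:\n",
    sprintf("  %s\n", result$link_sequence),
    sprintf("  %s  (%s)\n", result$structure_a, result$model_a),
    sprintf("  %s  (%s)\n", result$structure_b, result$model_b),
    sprintf("Re-optimized: %s bits in %s, %s bits in %s\n",
            fmt_bits(ra$score), result$model_a,
            fmt_bits(rb$score), result$model_b))
}

#' Discretized (binned) matrix for color-style rendering
#'
#' Companion to [to_matrix()]: replaces each score with the index of its
#' bin given ascending `thresholds`, as a TSV string. Bin `0` is below
#' the first threshold; bin `length(thresholds)` at or above the last.
#' Rendering bins as colors is left to presentation tools.
#'
#' @param mat A `link_matrix`.
#' @param thresholds Ascending numeric cut points (bits).
#' @return A TSV string with a leading name column.
#' @export
to_binned_tsv <- function(mat, thresholds = c(0, 10, 20)) {
  stopifnot(inherits(mat, "link_matrix"), !is.unsorted(thresholds))
  bins <- matrix(findInterval(mat, thresholds), nrow(mat),
                 dimnames = dimnames(mat))
  bins[is.na(mat)] <- NA_integer_
  header <- paste(c("model", colnames(bins)), collapse = "\t")
  rows <- vapply(seq_len(nrow(bins)), function(i)
    paste(c(rownames(bins)[i], ifelse(is.na(bins[i, ]), "",
                                      bins[i, ])), collapse = "\t"),
    character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}
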