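# Batch comparison workflows: one-vs-many against a model database,
# all-vs-all among a model set, result filtering, and the weighted
# link graph used for clan-candidate inspection.

#' Link-comparison result table
#'
#' Container returned by [compare_one_vs_many()] and
#' [compare_all_vs_all()]: the ordered model names, one `cm_link` entry
#' per unordered pair (each pair at most once), the mode, and any
#' per-pair errors (comparisons that failed are recorded, never abort
#' the batch).
#'
#' @param models Character vector of model names, in canonical order.
#' @param entries List of `cm_link` objects.
#' @param mode `"ONE_VS_MANY"` or `"ALL_VS_ALL"`.
#' @param errors Named character vector of per-pair/per-model failures.
#' @param queries For one-vs-many tables, the query model names.
#' @return A `link_table` object.
#' @export
link_table <- function(models, entries, mode, errors = character(),
                       queries = character()) {
  mode <- match.arg(mode, c("ONE_VS_MANY", "ALL_VS_ALL"))
  pair_keys <- vapply(entries, function(e)
    paste(sort(c(e$model_a, e$model_b)), collapse = "\r"), character(1))
  if (anyDuplicated(pair_keys))
    stop("duplicate unordered model pair in link table", call. = FALSE)
  for (e in entries)
    if (!all(c(e$model_a, e$model_b) %in% models))
      stop("entry references a model name not in the table", call. = FALSE)
  structure(list(models = models, entries = entries, mode = mode,
                 errors = errors, queries = queries),
            class = "link_table")
}

#' @export
print.link_table <- function(x, ...) {
  cat(sprintf("<link_table> %s: %d models, %d entries",
              x$mode, length(x$models), length(x$entries)))
  if (length(x$errors)) cat(sprintf(", %d errors", length(x$errors)))
  cat("\n")
  invisible(x)
}

# One comparison with error isolation; with options(cmlink.log = TRUE) a
# structured per-pair timing line is emitted on stderr.
run_pair <- function(ma, mb, errors_env) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(link_models(ma, mb), error = function(e) {
    key <- paste(ma$name, mb$name, sep = " vs ")
    errors_env$errors[[key]] <- conditionMessage(e)
    NULL
  })
  if (isTRUE(getOption("cmlink.log")))
    message(sprintf("pair\t%s\t%s\t%s\t%.3fs", ma$name, mb$name,
                    if (is.null(res)) "error"
                    else sprintf("%.1f", res$link_score),
                    proc.time()[["elapsed"]] - t0))
  res
}

check_model_list <- function(models, what) {
  if (length(models) == 0L)
    stop(what, ": model list must be non-empty", call. = FALSE)
  for (m in models)
    if (!inherits(m, "cm_model"))
      stop(what, ": all inputs must be cm_model objects", call. = FALSE)
  nms <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop(what, ": duplicate model names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  nms
}

#' Compare query models against a model database
#'
#' Computes one link result per (query, database model) pair — including
#' a query against its own copy when present in the database. Order is
#' deterministic: query order, then database order. A failing pair is
#' recorded in `errors` and the remaining pairs are still computed.
#' Restricting the database to a subtype (e.g. only tRNA models) is done
#' by passing a pre-filtered list, e.g. via [read_cm_dir()] plus a name
#' predicate.
#'
#' @param queries,database Non-empty lists of `cm_model` objects.
#' @return A `link_table` with mode `ONE_VS_MANY`.
#' @export
compare_one_vs_many <- function(queries, database) {
  qn <- check_model_list(queries, "compare_one_vs_many (queries)")
  dn <- check_model_list(database, "compare_one_vs_many (database)")
  env <- new.env(); env$errors <- list()
  entries <- list()
  seen <- character()
  # query order, then database order; each unordered pair at most once
  # (a query present in the database links against its own copy)
  for (q in queries) for (d in database) {
    key <- paste(sort(c(q$name, d$name)), collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    r <- run_pair(q, d, env)
    if (!is.null(r)) entries[[length(entries) + 1L]] <- r
  }
  link_table(models = unique(c(qn, dn)), entries = entries,
             mode = "ONE_VS_MANY",
             errors = unlist(env$errors) %||% character(),
             queries = qn)
}

#' Compare every pair within a model set
#'
#' Computes the C(k, 2) link results among `k` models (self-pairs are
#' excluded from the table; the matrix view derives diagonal values from
#' [best_sequence()]). Entries are emitted in canonical order — models
#' sorted by name, then all pairs (i, j), i < j — so permuting the input
#' list never changes the result. Per-pair failures are isolated.
#'
#' @param models List of at least two `cm_model` objects with distinct
#'   names.
#' @return A `link_table` with mode `ALL_VS_ALL`.
#' @export
compare_all_vs_all <- function(models) {
  nms <- check_model_list(models, "compare_all_vs_all")
  if (length(models) < 2L)
    stop("compare_all_vs_all: need at least 2 models", call. = FALSE)
  ord <- order(nms)
  models <- models[ord]; nms <- nms[ord]
  env <- new.env(); env$errors <- list()
  entries <- list()
  k <- length(models)
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    r <- run_pair(models[[i]], models[[j]], env)
    if (!is.null(r)) entries[[length(entries) + 1L]] <- r
  }
  link_table(models = nms, entries = entries, mode = "ALL_VS_ALL",
             errors = unlist(env$errors) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter a link table
#'
#' Applies, in order: a case-insensitive substring match on either model
#' name (`name_pattern`), a lower bound on the link score
#' (`min_link_score`), then truncation to the `top_n` entries by
#' descending link score. Sorting is stable with ties broken by the
#' (modelA, modelB) name pair, so filtering is a pure, idempotent
#' function of the table.
#'
#' @param table A `link_table`.
#' @param name_pattern Optional substring (fixed, case-insensitive).
#' @param min_link_score Optional bits threshold.
#' @param top_n Optional positive integer.
#' @return A `link_table` with the surviving entries (model list
#'   unchanged, so isolated models remain known to the graph view).
#' @export
filter_results <- function(table, name_pattern = NULL,
                           min_link_score = NULL, top_n = NULL) {
  stopifnot(inherits(table, "link_table"))
  if (!is.null(top_n)) {
    top_n <- as.integer(top_n)
    if (is.na(top_n) || top_n < 1L)
      stop("top_n must be a positive integer", call. = FALSE)
  }
  entries <- table$entries
  if (!is.null(name_pattern) && nzchar(name_pattern)) {
    pat <- tolower(name_pattern)
    keep <- vapply(entries, function(e)
      grepl(pat, tolower(e$model_a), fixed = TRUE) ||
      grepl(pat, tolower(e$model_b), fixed = TRUE), logical(1))
    entries <- entries[keep]
  }
  if (!is.null(min_link_score)) {
    keep <- vapply(entries, function(e) e$link_score >= min_link_score,
                   logical(1))
    entries <- entries[keep]
  }
  if (!is.null(top_n) && length(entries) > 0L) {
    sc <- vapply(entries, `[[`, numeric(1), "link_score")
    nm <- vapply(entries, function(e) paste(e$model_a, e$model_b),
                 character(1))
    entries <- entries[order(-sc, nm)][seq_len(min(top_n,
                                                   length(entries)))]
  }
  link_table(models = table$models, entries = entries, mode = table$mode,
             errors = table$errors, queries = table$queries)
}

#' Weighted link graph of a (filtered) result table
#'
#' Nodes are all models of the table (isolated nodes are kept); edges are
#' the entries surviving the supplied filter, weighted by their link
#' scores. In `ONE_VS_MANY` mode edges exist only between a query and a
#' database model, mirroring a query-vs-database comparison where
#' database models are never compared among themselves. Thresholding the
#' scores before building the graph exposes clan candidates as connected
#' components.
#'
#' @param table A `link_table`.
#' @inheritParams filter_results
#' @return A `link_graph`: list with `nodes` (character) and `edges`
#'   (data frame with columns `from`, `to`, `weight`).
#' @export
build_link_graph <- function(table, name_pattern = NULL,
                             min_link_score = NULL, top_n = NULL) {
  ft <- filter_results(table, name_pattern = name_pattern,
                       min_link_score = min_link_score, top_n = top_n)
  entries <- ft$entries
  if (ft$mode == "ONE_VS_MANY" && length(ft$queries)) {
    keep <- vapply(entries, function(e)
      xor(e$model_a %in% ft$queries, e$model_b %in% ft$queries) ||
        (e$model_a == e$model_b), logical(1))
    entries <- entries[keep]
  }
  entries <- entries[vapply(entries, function(e)
    e$model_a != e$model_b, logical(1))]   # no self-edges
  edges <- data.frame(
    from = vapply(entries, `[[`, character(1), "model_a"),
    to = vapply(entries, `[[`, character(1), "model_b"),
    weight = vapply(entries, `[[`, numeric(1), "link_score"),
    stringsAsFactors = FALSE)
  structure(list(nodes = table$models, edges = edges),
            class = "link_graph")
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("<link_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}
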