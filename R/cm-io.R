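# Reading and writing Infernal-format covariance model files.
#
# Two ASCII dialects are supported: "1.0" (INFERNAL-1 header, bare node
# lines, no QDB columns) and "1.1" (INFERNAL1/a header, annotated node
# lines, four QDB bound columns per state line). Both store transition
# scores as log2 probabilities and emission scores as log2-odds against
# the record's null model, which is exactly the package's internal unit
# (bits), so reading is layout decoding plus null-line conversion. The
# NULL line holds log2-odds of the background against uniform 0.25.
# Unrecognized header lines (calibration statistics, COM/DATE provenance,
# checksums) are preserved verbatim and re-emitted on write.

fmt_score <- function(x) {
  ifelse(is.infinite(x) & x < 0, "*", sprintf("%.5f", x))
}

parse_score <- function(tok) {
  out <- suppressWarnings(as.numeric(tok))
  out[tok == "*"] <- -Inf
  out
}

HEADER_KEYS <- c("NAME", "ACC", "STATES", "NODES", "CLEN", "ALPH", "NULL", "W")

# ---- writing -------------------------------------------------------------

#' Write covariance models to Infernal CM text
#'
#' Serializes one or more models into a single CM-format document
#' (concatenated records separated by `//`), re-parsable by
#' [parse_cm_file()]. Scores are printed with five decimals; the
#' impossibility sentinel is written as `*`.
#'
#' @param models A `cm_model` or list of them. An empty list yields an
#'   empty document.
#' @param dialect `"1.0"` or `"1.1"`.
#' @param path Optional file path; when given the text is also written to
#'   disk.
#' @return The document as a single string (invisibly when `path` is set).
#' @export
write_cm_file <- function(models, dialect = "1.1", path = NULL) {
  if (inherits(models, "cm_model")) models <- list(models)
  stopifnot(dialect %in% c("1.0", "1.1"))
  txt <- paste0(vapply(models, write_one_cm, character(1), dialect = dialect),
                collapse = "")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

write_one_cm <- function(model, dialect) {
  stopifnot(inherits(model, "cm_model"))
  is11 <- dialect == "1.1"
  lines <- character()
  add <- function(...) lines[[length(lines) + 1L]] <<- sprintf(...)

  if (is11) add("INFERNAL1/a [1.1 | cmlink]") else add("INFERNAL-1 [1.0 | cmlink]")
  add("NAME     %s", model$name)
  if (!is.null(model$accession)) add("ACC      %s", model$accession)
  add("STATES   %d", length(model$states))
  add("NODES    %d", length(model$nodes))
  add("CLEN     %d", model$clen)
  add("ALPH     RNA")
  add("NULL     %s", paste(fmt_score(log2(model$null_model / 0.25)),
                           collapse = "  "))
  for (x in model$extra) add("%s", x)
  add(if (is11) "CM" else "MODEL:")

  # parent bookkeeping for the plast/pnum columns
  parents <- vector("list", length(model$states))
  for (st in model$states) {
    for (ch in state_children(model, st$index)) {
      if (ch != st$index)
        parents[[ch + 1L]] <- c(parents[[ch + 1L]], st$index)
    }
  }

  for (nd in model$nodes) {
    annot <- ""
    if (is11) {
      raw <- nd$annot$raw
      if (!is.null(raw)) {
        annot <- paste0(" ", paste(raw, collapse = " "))
      } else {
        cols <- nd$annot$cols
        res <- nd$annot$res
        lft <- if (length(cols) >= 1L) cols[[1L]] else "-"
        rgt <- if (length(cols) >= 2L) cols[[2L]] else "-"
        rl <- if (length(res) >= 1L) res[[1L]] else "-"
        rr <- if (length(res) >= 2L) res[[2L]] else "-"
        annot <- sprintf(" %6s %6s %6s %6s", lft, rgt, rl, rr)
      }
    }
    add("%34s[ %s %d ]%s", "", nd$type, nd$index, annot)
    for (sid in nd$state_indices) {
      st <- model$states[[sid + 1L]]
      par <- parents[[sid + 1L]]
      plast <- if (length(par)) max(par) else -1L
      pnum <- length(par)
      qdb <- if (is11) sprintf(" %5d %5d %5d %5d", 0L, 0L, 0L, 0L) else ""
      if (st$type == "B") {
        add("  %4s %5d %5d %d %5d %5d%s", "B", sid, plast, pnum,
            st$cfirst, st$cnum, qdb)
      } else if (st$type == "E") {
        add("  %4s %5d %5d %d %5d %5d%s", "E", sid, plast, pnum, -1L, 0L, qdb)
      } else {
        add("  %4s %5d %5d %d %5d %5d%s  %s%s", st$type, sid, plast, pnum,
            st$cfirst, st$cnum, qdb,
            paste(sprintf("%8s", fmt_score(st$trans)), collapse = " "),
            if (length(st$emis))
              paste0("  ", paste(sprintf("%8s", fmt_score(st$emis)),
                                 collapse = " "))
            else "")
      }
    }
  }
  add("//")
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- parsing -------------------------------------------------------------

#' Parse Infernal CM text into covariance models
#'
#' Accepts a document holding one or more concatenated CM records in the
#' 1.0 or 1.1 ASCII dialect (records end with `//`). Numeric fields are
#' interpreted as bits against the record's null model; the `*` marker
#' becomes the impossibility sentinel. The dialect is recorded per model.
#'
#' @param text A single string or a character vector of lines.
#' @return List of validated `cm_model` objects, in file order.
#' @export
parse_cm_file <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("\r$", "", text)

  models <- list()
  rec <- character()
  rec_start <- 1L
  flush <- function(end_line) {
    body <- rec[nzchar(trimws(rec))]
    if (length(body) > 0L)
      models[[length(models) + 1L]] <<- parse_one_cm(body, rec_start)
    rec <<- character()
  }
  for (ln in seq_along(text)) {
    if (trimws(text[[ln]]) == "//") {
      flush(ln)
      rec_start <- ln + 1L
    } else {
      if (length(rec) == 0L) rec_start <- ln
      rec[[length(rec) + 1L]] <- text[[ln]]
    }
  }
  flush(length(text))
  models
}

#' @rdname parse_cm_file
#' @param path Path to a CM file (may hold multiple concatenated records).
#' @export
read_cm_file <- function(path) {
  parse_cm_file(readLines(path, warn = FALSE))
}

parse_one_cm <- function(lines, offset) {
  ferr <- function(i, msg) {
    stop(sprintf("CM format error at line %d: %s (line: %s)",
                 offset + i - 1L, msg, trimws(lines[[i]])), call. = FALSE)
  }
  head_tok <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  dialect <- if (startsWith(head_tok[[1]], "INFERNAL1/a")) "1.1"
  else if (startsWith(head_tok[[1]], "INFERNAL-1")) "1.0"
  else ferr(1L, "malformed header, expected INFERNAL1/a or INFERNAL-1")

  name <- NULL; accession <- NULL; null_model <- NULL
  n_states_decl <- NA_integer_; n_nodes_decl <- NA_integer_
  clen_decl <- NA_integer_
  extra <- character()
  i <- 2L
  body_start <- NA_integer_
  while (i <= length(lines)) {
    tl <- trimws(lines[[i]])
    if (tl == "CM" || tl == "MODEL:") { body_start <- i + 1L; break }
    tok <- strsplit(tl, "\\s+")[[1]]
    key <- tok[[1]]
    if (key %in% HEADER_KEYS) {
      val <- tok[-1]
      switch(key,
        NAME = { name <- val[[1]] },
        ACC = { accession <- val[[1]] },
        STATES = { n_states_decl <- as.integer(val[[1]]) },
        NODES = { n_nodes_decl <- as.integer(val[[1]]) },
        CLEN = { clen_decl <- as.integer(val[[1]]) },
        ALPH = {
          if (!toupper(val[[1]]) %in% c("RNA", "DNA"))
            ferr(i, paste("unsupported alphabet", val[[1]]))
        },
        "NULL" = {
          if (length(val) != 4L) ferr(i, "NULL line must have 4 values")
          null_model <- 0.25 * 2^parse_score(val)
          null_model <- null_model / sum(null_model)
        },
        W = { extra <- c(extra, lines[[i]]) }
      )
    } else {
      extra <- c(extra, lines[[i]])
    }
    i <- i + 1L
  }
  if (is.na(body_start)) ferr(length(lines), "missing CM/MODEL: section marker")
  if (is.null(name)) ferr(1L, "missing NAME header line")
  if (is.null(null_model)) null_model <- rep(0.25, 4)

  states <- list()
  nodes <- list()
  cur_node <- NA_integer_
  for (j in seq(body_start, length(lines))) {
    tl <- trimws(lines[[j]])
    if (!nzchar(tl)) next
    if (startsWith(tl, "[")) {
      tok <- strsplit(gsub("[][]", " ", tl), "\\s+")[[1]]
      tok <- tok[nzchar(tok)]
      if (length(tok) < 2L || !tok[[1]] %in% NODE_TYPES)
        ferr(j, "malformed node line")
      cur_node <- as.integer(tok[[2]])
      raw <- if (length(tok) > 2L) tok[-(1:2)] else NULL
      nodes[[cur_node + 1L]] <- cm_node(cur_node, tok[[1]], integer(),
                                        annot = if (!is.null(raw))
                                          list(raw = raw) else NULL)
      next
    }
    tok <- strsplit(tl, "\\s+")[[1]]
    sty <- tok[[1]]
    if (!sty %in% STATE_TYPES) ferr(j, paste("unknown state type", sty))
    if (is.na(cur_node)) ferr(j, "state line before any node line")
    ints <- suppressWarnings(as.integer(tok[2:6]))
    if (anyNA(ints)) ferr(j, "malformed state line (index/children fields)")
    sid <- ints[[1]]; cfirst <- ints[[4]]; cnum <- ints[[5]]
    rest <- if (length(tok) > 6L) tok[-(1:6)] else character()
    if (dialect == "1.1" && !sty %in% c("B", "E")) {
      if (length(rest) < 4L) ferr(j, "missing QDB columns")
      rest <- rest[-(1:4)]
    } else if (dialect == "1.1") {
      rest <- rest[-seq_len(min(4L, length(rest)))]
    }
    trans <- NULL
    emis <- numeric()
    if (!sty %in% c("B", "E")) {
      if (length(rest) < cnum) ferr(j, "missing transition scores")
      trans <- parse_score(rest[seq_len(cnum)])
      rest <- rest[-seq_len(cnum)]
      ar <- emission_arity(sty)
      if (ar > 0L) {
        if (length(rest) < ar) ferr(j, "missing emission scores")
        emis <- parse_score(rest[seq_len(ar)])
      }
    }
    states[[sid + 1L]] <- cm_state(sid, sty, cur_node, cfirst = cfirst,
                                   cnum = cnum, trans = trans, emis = emis)
    nodes[[cur_node + 1L]]$state_indices <-
      c(nodes[[cur_node + 1L]]$state_indices, sid)
  }

  if (any(vapply(states, is.null, logical(1))))
    ferr(body_start, "state indices are not contiguous from 0")
  if (!is.na(n_states_decl) && n_states_decl != length(states))
    ferr(1L, sprintf("STATES header says %d, found %d", n_states_decl,
                     length(states)))
  if (!is.na(n_nodes_decl) && n_nodes_decl != length(nodes))
    ferr(1L, sprintf("NODES header says %d, found %d", n_nodes_decl,
                     length(nodes)))

  cm_model(name, states, nodes, null_model = null_model, dialect = dialect,
           clen = if (is.na(clen_decl)) NULL else clen_decl,
           accession = accession, extra = extra, validate = TRUE)
}

# ---- directories and external conversion hook ----------------------------

#' Read every CM file in a directory
#'
#' A local directory of CM files stands in for a model database (for
#' example an Rfam flatfile split, or `Rfam.cm` itself since files may hold
#' many records). Unreadable files are skipped with a warning so one bad
#' model never aborts a batch.
#'
#' @param dir Directory path.
#' @param pattern Filename regular expression, default `\\.cm$`.
#' @return Named list of `cm_model` objects.
#' @export
read_cm_dir <- function(dir, pattern = "\\.cm$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  out <- list()
  for (f in files) {
    ms <- tryCatch(read_cm_file(f), error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      list()
    })
    out <- c(out, ms)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "name"))
}

#' Convert a Stockholm alignment to a CM with an external cmbuild
#'
#' Stockholm parsing is deliberately not implemented here; building a CM
#' from an alignment is Infernal's job. This hook shells out to a `cmbuild`
#' executable when one is on the PATH and fails with a clear message
#' otherwise.
#'
#' @param stockholm_path Path to a Stockholm alignment.
#' @param cmbuild Name or path of the cmbuild executable.
#' @return List of `cm_model` objects built from the alignment.
#' @export
stockholm_to_cm <- function(stockholm_path, cmbuild = "cmbuild") {
  exe <- Sys.which(cmbuild)
  if (!nzchar(exe))
    stop("Stockholm input requires Infernal: no '", cmbuild,
         "' executable found on the PATH", call. = FALSE)
  out <- tempfile(fileext = ".cm")
  status <- system2(exe, c("-F", shQuote(out), shQuote(stockholm_path)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("cmbuild failed with status ", status, call. = FALSE)
  read_cm_file(out)
}
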