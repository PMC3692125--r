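#' @useDynLib cmlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- alphabet and state-machine vocabulary -------------------------------

RNA_ALPHABET <- c("A", "C", "G", "U")

STATE_TYPES <- c("S", "D", "IL", "IR", "ML", "MR", "MP", "B", "E")
NODE_TYPES  <- c("ROOT", "MATL", "MATR", "MATP", "BIF", "BEGL", "BEGR", "END")

# integer codes shared with the C++ kernels (src/cm_kernels.cpp)
STATE_CODE <- stats::setNames(0:8, STATE_TYPES)

SINGLET_EMITTERS <- c("ML", "MR", "IL", "IR")
LEFT_EMITTERS    <- c("ML", "IL")
RIGHT_EMITTERS   <- c("MR", "IR")

#' Score sentinel for impossible transitions, emissions and parses
#'
#' A single global sentinel, strictly below every finite bit score and
#' absorbing under addition, marks impossibility throughout the package
#' (written as `*` in CM files).
#'
#' @return `-Inf`.
#' @export
cm_sentinel <- function() -Inf

emission_arity <- function(type) {
  switch(type,
    ML = 4L, MR = 4L, IL = 4L, IR = 4L,
    MP = 16L,
    0L
  )
}

# ---- constructors --------------------------------------------------------

#' Construct a covariance model object
#'
#' Low-level constructor for the in-memory representation of a profile SCFG.
#' Most users will obtain models from [parse_cm_file()] or [build_toy_cm()].
#'
#' States are kept in Infernal order: node by node, split-set states first,
#' then that node's insert states. All indices are 0-based as in CM files.
#'
#' @param name Model name.
#' @param states List of states as created by [cm_state()].
#' @param nodes List of nodes as created by [cm_node()].
#' @param null_model Numeric(4), background probabilities over A,C,G,U.
#' @param dialect `"1.0"` or `"1.1"`.
#' @param clen Consensus length (number of match columns).
#' @param accession Optional accession string.
#' @param extra Character vector of opaque header lines preserved verbatim
#'   on round-trip (calibration statistics, provenance, checksums).
#' @param validate Run [validate_model()] and stop on diagnostics?
#' @return An object of class `cm_model`.
#' @export
cm_model <- function(name, states, nodes, null_model, dialect = "1.1",
                     clen = NULL, accession = NULL, extra = character(),
                     validate = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.null(clen)) {
    clen <- sum(vapply(nodes, function(nd) {
      switch(nd$type, MATL = 1L, MATR = 1L, MATP = 2L, 0L)
    }, integer(1)))
  }
  m <- structure(
    list(
      name = name,
      accession = accession,
      dialect = dialect,
      clen = as.integer(clen),
      null_model = as.numeric(null_model),
      states = states,
      nodes = nodes,
      extra = extra
    ),
    class = "cm_model"
  )
  if (validate) {
    diag <- validate_model(m)
    if (length(diag) > 0L) {
      stop("invalid covariance model '", name, "':\n  ",
           paste(diag, collapse = "\n  "), call. = FALSE)
    }
  }
  m
}

#' @rdname cm_model
#' @param index 0-based state index.
#' @param type State type, one of S, D, IL, IR, ML, MR, MP, B, E.
#' @param node 0-based owning node index.
#' @param cfirst 0-based index of first child (-1 for E; left child for B).
#' @param cnum Number of children (right-child index for B, 0 for E).
#' @param trans Numeric transition scores in bits (log2 probabilities),
#'   length `cnum`; `NULL` for B and E states.
#' @param emis Numeric emission log-odds in bits: length 4 (A,C,G,U) for
#'   singlet emitters, 16 (row-major AA..UU) for MP, length 0 otherwise.
#' @export
cm_state <- function(index, type, node, cfirst = -1L, cnum = 0L,
                     trans = NULL, emis = numeric()) {
  list(index = as.integer(index), type = type, node = as.integer(node),
       cfirst = as.integer(cfirst), cnum = as.integer(cnum),
       trans = if (is.null(trans)) NULL else as.numeric(trans),
       emis = as.numeric(emis))
}

#' @rdname cm_model
#' @param node_type Node type, one of ROOT, MATL, MATR, MATP, BIF, BEGL,
#'   BEGR, END.
#' @param state_indices 0-based indices of the member states.
#' @param annot Optional named list of per-node annotation (consensus
#'   column map / residues) carried through to 1.1 output.
#' @export
cm_node <- function(index, node_type, state_indices, annot = NULL) {
  list(index = as.integer(index), type = node_type,
       state_indices = as.integer(state_indices), annot = annot)
}

# ---- basic accessors -----------------------------------------------------

#' @export
print.cm_model <- function(x, ...) {
  cat(sprintf("<cm_model> %s%s  dialect %s\n", x$name,
              if (!is.null(x$accession)) paste0(" (", x$accession, ")") else "",
              x$dialect))
  cat(sprintf("  states: %d  nodes: %d  consensus length: %d\n",
              length(x$states), length(x$nodes), x$clen))
  invisible(x)
}

#' Model accessors
#'
#' `n_states()` returns the number of states, `state_types()` the
#' character vector of state types in model order, and
#' `state_children()` the 0-based child state indices of 0-based state
#' `i` (for a `B` state, its two begin states).
#'
#' @param model A `cm_model`.
#' @param i 0-based state index.
#' @return See description.
#' @export
n_states <- function(model) length(model$states)

#' @rdname n_states
#' @export
state_types <- function(model) {
  vapply(model$states, `[[`, character(1), "type")
}

#' @rdname n_states
#' @export
state_children <- function(model, i) {
  st <- model$states[[i + 1L]]
  if (st$type == "E") return(integer())
  if (st$type == "B") return(c(st$cfirst, st$cnum))
  if (st$cnum == 0L) return(integer())
  seq.int(st$cfirst, st$cfirst + st$cnum - 1L)
}

# transition score from state i to 0-based child index j (bits)
transition_score <- function(model, i, j) {
  st <- model$states[[i + 1L]]
  if (st$type == "B") return(0)
  k <- j - st$cfirst + 1L
  if (k < 1L || k > st$cnum) return(cm_sentinel())
  st$trans[[k]]
}

# ---- validation ----------------------------------------------------------

#' Validate a covariance model
#'
#' Checks every structural invariant of the in-memory model and flags
#' hazards that would break downstream dynamic programs. Returns
#' diagnostics rather than raising, so callers can report all problems at
#' once.
#'
#' Checked: a single root S state at index 0; at least one E state; child
#' indices in range and strictly increasing except insert self-loops;
#' B states with exactly two S children; null model summing to 1; emission
#' vector arity per state type; BIF/MATP node composition; and the
#' non-termination hazard - an insert self-loop whose transition score plus
#' maximal emission score is >= 0 bits, which would let an optimal parse
#' grow without bound.
#'
#' @param model A `cm_model` (possibly malformed).
#' @return Character vector of diagnostics; empty if the model is valid.
#' @export
validate_model <- function(model) {
  bad <- character()
  say <- function(...) bad[[length(bad) + 1L]] <<- sprintf(...)

  sts <- model$states
  n <- length(sts)
  if (n == 0L) return("model has no states")

  types <- vapply(sts, `[[`, character(1), "type")
  if (types[[1]] != "S") say("state 0: root must be type S, found %s", types[[1]])
  if (sum(types == "S" & seq_along(types) == 1L) != 1L && types[[1]] == "S") {
    # additional S states are legal (BEGL/BEGR); only index 0 must be S
  }
  if (!any(types == "E")) say("model has no E state")

  if (abs(sum(model$null_model) - 1) > 1e-6)
    say("null model probabilities sum to %.6f, not 1", sum(model$null_model))
  if (length(model$null_model) != 4L)
    say("null model must have 4 probabilities, found %d", length(model$null_model))

  for (st in sts) {
    i <- st$index
    if (!st$type %in% STATE_TYPES) {
      say("state %d: unknown type %s", i, st$type)
      next
    }
    ar <- emission_arity(st$type)
    if (length(st$emis) != ar)
      say("state %d (%s): emission vector length %d, expected %d",
          i, st$type, length(st$emis), ar)

    if (st$type == "E") {
      next
    } else if (st$type == "B") {
      ch <- c(st$cfirst, st$cnum)
      if (any(ch < 0L) || any(ch >= n)) {
        say("state %d (B): child index out of range (%d, %d)", i, ch[1], ch[2])
      } else {
        chtypes <- types[ch + 1L]
        if (!all(chtypes == "S"))
          say("state %d (B): children must both be S states, found %s",
              i, paste(chtypes, collapse = ","))
        if (any(ch <= i))
          say("state %d (B): child indices must exceed own index", i)
      }
    } else {
      ch <- state_children(model, i)
      if (length(ch) == 0L) {
        say("state %d (%s): no transitions", i, st$type)
        next
      }
      if (length(st$trans) != length(ch))
        say("state %d (%s): %d transition scores for %d children",
            i, st$type, length(st$trans), length(ch))
      if (any(ch >= n) || any(ch < 0L))
        say("state %d (%s): transition target out of range", i, st$type)
      self_ok <- st$type %in% c("IL", "IR")
      bad_targets <- if (self_ok) ch[ch < i] else ch[ch <= i]
      if (length(bad_targets) > 0L)
        say("state %d (%s): transition to non-increasing index %s",
            i, st$type, paste(bad_targets, collapse = ","))
      # non-termination hazard: self-loop gain >= 0
      if (self_ok && i %in% ch) {
        tself <- st$trans[[match(i, ch)]]
        gain <- tself + max(st$emis)
        if (is.finite(tself) && gain >= 0)
          say("state %d (%s): non-termination hazard, self-loop gain %+.3f bits >= 0",
              i, st$type, gain)
      }
    }
  }

  for (nd in model$nodes) {
    ntypes <- types[nd$state_indices + 1L]
    if (nd$type == "BIF" && sum(ntypes == "B") != 1L)
      say("node %d (BIF): must own exactly one B state", nd$index)
    if (nd$type == "MATP" && sum(ntypes == "MP") != 1L)
      say("node %d (MATP): must own exactly one MP state", nd$index)
  }

  bad
}

has_hazard <- function(model) {
  any(grepl("non-termination hazard", validate_model(model), fixed = TRUE))
}

# refuse models unfit for the state-only dynamic programs
assert_no_hazard <- function(model, caller) {
  diag <- validate_model(model)
  hz <- grep("non-termination hazard", diag, value = TRUE, fixed = TRUE)
  if (length(hz) > 0L)
    stop(caller, ": refusing model '", model$name, "': ", hz[[1]], call. = FALSE)
  if (length(diag) > 0L)
    stop(caller, ": model '", model$name, "' is invalid: ", diag[[1]], call. = FALSE)
  invisible(model)
}

# ---- flattening for the C++ kernels --------------------------------------

# Flatten a validated model into parallel vectors. Transition and emission
# scores are concatenated with 0-based offset vectors; B states carry their
# two children in cfirst/cnum.
cm_flatten <- function(model) {
  sts <- model$states
  n <- length(sts)
  type_code <- vapply(sts, function(s) STATE_CODE[[s$type]], integer(1))
  cfirst <- vapply(sts, `[[`, integer(1), "cfirst")
  cnum <- vapply(sts, `[[`, integer(1), "cnum")
  trans <- lapply(sts, function(s) if (is.null(s$trans)) numeric() else s$trans)
  emis <- lapply(sts, `[[`, "emis")
  toff <- c(0L, cumsum(lengths(trans)))
  eoff <- c(0L, cumsum(lengths(emis)))
  list(
    n = n,
    type = type_code,
    cfirst = cfirst,
    cnum = cnum,
    trans = unlist(trans, use.names = FALSE),
    toff = toff,
    emis = unlist(emis, use.names = FALSE),
    eoff = eoff
  )
}

# ---- sequence utilities --------------------------------------------------

#' Encode an RNA sequence for scoring
#'
#' Maps DNA thymine to uracil and rejects anything outside `{A,C,G,U}`
#' (IUPAC ambiguity codes included).
#'
#' @param sequence Single string.
#' @return Integer vector, 0-based codes over A=0, C=1, G=2, U=3.
#' @keywords internal
encode_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(integer())
  chars <- toupper(strsplit(sequence, "", fixed = TRUE)[[1]])
  chars[chars == "T"] <- "U"
  codes <- match(chars, RNA_ALPHABET) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid RNA sequence: character(s) ",
         paste(sQuote(bad), collapse = ", "),
         " not in {A,C,G,U} (IUPAC ambiguity codes are not supported)",
         call. = FALSE)
  }
  codes
}

decode_rna <- function(codes) {
  if (length(codes) == 0L) return("")
  paste(RNA_ALPHABET[codes + 1L], collapse = "")
}

# balanced dot-bracket check used by validation and tests
is_balanced_structure <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    } else if (ch != ".") return(FALSE)
  }
  depth == 0L
}

# pair table: 0 for unpaired, else 1-based partner position
structure_pairs <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure", call. = FALSE)
      j <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced structure", call. = FALSE)
  pt
}
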