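# Single-model scoring: optimal (CYK) parses of a given sequence, the
# model's best achievable sequence, and a brute-force enumeration oracle.

#' Optimal parse of a sequence by a covariance model
#'
#' Computes the maximum-bit-score global parse of the full sequence by the
#' full model (CYK over subsequences x states; no local begins/ends, no
#' truncation). Ties are broken deterministically: lowest child state
#' index, then leftmost bifurcation split.
#'
#' @param model A `cm_model`.
#' @param sequence RNA string over A,C,G,U (T mapped to U; the empty
#'   string is legal and scored via pure-deletion parses).
#' @return A `cm_parse` object: `score` (bits; `-Inf` when no parse
#'   exists), `sequence`, `structure` (dot-bracket with brackets exactly at
#'   positions emitted by MP states on the optimal path), and `state_path`,
#'   a data frame whose transition and emission bit columns sum to `score`.
#' @export
optimal_parse_score <- function(model, sequence) {
  stopifnot(inherits(model, "cm_model"))
  codes <- encode_rna(sequence)
  fl <- cm_flatten(model)
  res <- cpp_cyk(fl$type, fl$cfirst, fl$cnum, fl$trans, fl$toff,
                 fl$emis, fl$eoff, as.integer(codes), TRUE)
  build_parse_result(model, codes, res$score, res$trace)
}

build_parse_result <- function(model, codes, score, trace) {
  L <- length(codes)
  seq_str <- decode_rna(codes)
  if (!is.finite(score) || nrow(trace) == 0L) {
    return(new_cm_parse(score = cm_sentinel(), sequence = seq_str,
                        structure = strrep(".", L),
                        state_path = empty_state_path()))
  }
  n <- nrow(trace)
  st_idx <- trace[, "state"]
  types <- vapply(st_idx, function(v) model$states[[v + 1L]]$type,
                  character(1))
  emit_left <- rep(NA_integer_, n)
  emit_right <- rep(NA_integer_, n)
  emit_bits <- numeric(n)
  trans_bits <- numeric(n)
  struct <- rep(".", L)
  for (r in seq_len(n)) {
    v <- st_idx[[r]]
    ty <- types[[r]]
    i <- trace[r, "i"]; j <- trace[r, "j"]
    st <- model$states[[v + 1L]]
    if (ty %in% LEFT_EMITTERS) {
      emit_left[[r]] <- i + 1L
      emit_bits[[r]] <- st$emis[[codes[[i + 1L]] + 1L]]
    } else if (ty %in% RIGHT_EMITTERS) {
      emit_right[[r]] <- j
      emit_bits[[r]] <- st$emis[[codes[[j]] + 1L]]
    } else if (ty == "MP") {
      emit_left[[r]] <- i + 1L
      emit_right[[r]] <- j
      emit_bits[[r]] <- st$emis[[codes[[i + 1L]] * 4L + codes[[j]] + 1L]]
      struct[[i + 1L]] <- "("
      struct[[j]] <- ")"
    }
    # in pre-order the child of a non-branching state is the next row
    if (!ty %in% c("B", "E") && r < n)
      trans_bits[[r]] <- transition_score(model, v, st_idx[[r + 1L]])
  }
  path <- data.frame(state = st_idx, type = types,
                     i = trace[, "i"], j = trace[, "j"],
                     emit_left = emit_left, emit_right = emit_right,
                     trans_bits = trans_bits, emit_bits = emit_bits)
  new_cm_parse(score = score, sequence = seq_str,
               structure = paste(struct, collapse = ""), state_path = path)
}

empty_state_path <- function() {
  data.frame(state = integer(), type = character(), i = integer(),
             j = integer(), emit_left = integer(), emit_right = integer(),
             trans_bits = numeric(), emit_bits = numeric())
}

new_cm_parse <- function(score, sequence, structure, state_path) {
  structure(list(score = score, sequence = sequence,
                 structure = structure, state_path = state_path),
            class = "cm_parse")
}

#' @export
print.cm_parse <- function(x, ...) {
  cat(sprintf("<cm_parse> score %.1f bits\n", x$score))
  if (nzchar(x$sequence)) {
    cat(" ", x$sequence, "\n ", x$structure, "\n", sep = "")
  } else {
    cat("  (empty sequence)\n")
  }
  invisible(x)
}

#' Best achievable sequence of a covariance model
#'
#' Finds the RNA sequence maximizing [optimal_parse_score()] over all
#' finite sequences, by dynamic programming over states only: each
#' emitting state contributes its maximal emission, bifurcations sum both
#' children. Insert self-loops are never taken because their gain is
#' strictly negative in a valid model; models carrying a non-termination
#' hazard are refused. Emission ties break in alphabetical nucleotide
#' order.
#'
#' A model's best score is the value a model gives itself under pairwise
#' comparison ("compared with itself"), so it anchors the self-link
#' identity and the diagonal of the all-vs-all score matrix.
#'
#' @param model A valid, hazard-free `cm_model`.
#' @return A `cm_parse` for the best sequence.
#' @export
best_sequence <- function(model) {
  assert_no_hazard(model, "best_sequence")
  n <- n_states(model)
  best <- rep(cm_sentinel(), n)
  ch_pick <- rep(NA_integer_, n)
  em_pick <- vector("list", n)

  for (v in seq.int(n - 1L, 0L)) {
    st <- model$states[[v + 1L]]
    ty <- st$type
    if (ty == "E") { best[[v + 1L]] <- 0; next }
    if (ty == "B") {
      best[[v + 1L]] <- best[[st$cfirst + 1L]] + best[[st$cnum + 1L]]
      next
    }
    children <- state_children(model, v)
    b <- cm_sentinel(); bc <- NA_integer_; be <- integer()
    for (k in seq_along(children)) {
      y <- children[[k]]
      if (y == v) next   # insert self-loop: negative gain, never optimal
      base <- st$trans[[k]] + best[[y + 1L]]
      if (ty %in% c("S", "D")) {
        if (base > b) { b <- base; bc <- y; be <- integer() }
      } else if (ty == "MP") {
        for (c1 in 0:3) for (c2 in 0:3) {
          s <- base + st$emis[[c1 * 4L + c2 + 1L]]
          if (s > b) { b <- s; bc <- y; be <- c(c1, c2) }
        }
      } else {
        for (c1 in 0:3) {
          s <- base + st$emis[[c1 + 1L]]
          if (s > b) { b <- s; bc <- y; be <- c1 }
        }
      }
    }
    best[[v + 1L]] <- b
    ch_pick[[v + 1L]] <- bc
    em_pick[[v + 1L]] <- be
  }

  if (!is.finite(best[[1L]])) {
    return(new_cm_parse(cm_sentinel(), "", "", empty_state_path()))
  }

  # traceback assembling the sequence outside-in
  assemble <- function(v) {
    st <- model$states[[v + 1L]]
    ty <- st$type
    if (ty == "E") return(character())
    if (ty == "B")
      return(c(assemble(st$cfirst), assemble(st$cnum)))
    inner <- assemble(ch_pick[[v + 1L]])
    em <- em_pick[[v + 1L]]
    if (ty %in% LEFT_EMITTERS) c(RNA_ALPHABET[em + 1L], inner)
    else if (ty %in% RIGHT_EMITTERS) c(inner, RNA_ALPHABET[em + 1L])
    else if (ty == "MP") c(RNA_ALPHABET[em[1L] + 1L], inner,
                           RNA_ALPHABET[em[2L] + 1L])
    else inner
  }
  seq_str <- paste(assemble(0L), collapse = "")
  # re-parse for the canonical ParseResult; CYK recovers the same score
  optimal_parse_score(model, seq_str)
}

#' Brute-force best sequence by exhaustive enumeration
#'
#' Test oracle: scores every RNA sequence of length up to `max_len`
#' (canonical order: shorter first, then alphabetical) and returns the
#' exact maximum of [optimal_parse_score()]. Guarded to `max_len <= 8`.
#'
#' @param model A `cm_model`.
#' @param max_len Maximum sequence length (<= 8).
#' @return A `cm_parse` for the best enumerated sequence (sentinel score
#'   and empty sequence if no sequence up to `max_len` parses).
#' @export
brute_force_best_sequence <- function(model, max_len) {
  stopifnot(inherits(model, "cm_model"))
  if (max_len > 8L) stop("brute-force guard: max_len must be <= 8",
                         call. = FALSE)
  fl <- cm_flatten(model)
  res <- cpp_enum_best_single(fl$type, fl$cfirst, fl$cnum, fl$trans,
                              fl$toff, fl$emis, fl$eoff, as.integer(max_len))
  if (!is.finite(res$score))
    return(new_cm_parse(cm_sentinel(), "", "", empty_state_path()))
  optimal_parse_score(model, decode_rna(res$seq))
}
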