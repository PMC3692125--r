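# Synthetic covariance models for testing and benchmarking.
#
# A ToyModelSpec is a consensus RNA string plus a dot-bracket structure;
# build_toy_cm() turns it into a fully valid CM using the standard guide
# tree construction (unpaired column -> MATL, base pair -> MATP, branch
# point -> BIF/BEGL/BEGR), so the toys exercise the same state machinery
# as Rfam models, just at desk scale.

#' Specify a synthetic toy covariance model
#'
#' @param consensus RNA string over A,C,G,U (T is accepted and mapped to U).
#' @param structure Dot-bracket string of the same length, balanced, no
#'   pseudoknots.
#' @param boost Emission strength: the log-odds in bits (vs the uniform
#'   background) given to the consensus nucleotide (singlet columns) or
#'   consensus pair (MATP columns). Values above 2 bits (4 bits for pairs)
#'   concentrate all probability on the consensus and send the alternatives
#'   to the sentinel.
#' @param spread Probability mass in `[0,1)` placed on non-main transitions
#'   (deletes, inserts); 0 gives a rigid consensus-only model.
#' @param seed Integer seed controlling the deterministic jitter on
#'   non-consensus emission and transition weights.
#' @return A `toy_model_spec` object.
#' @export
toy_model_spec <- function(consensus, structure, boost = 1.5,
                           spread = 0.1, seed = 1L) {
  codes <- encode_rna(consensus)   # validates the alphabet, maps T->U
  if (length(codes) < 1L) stop("consensus must have length >= 1", call. = FALSE)
  if (nchar(structure) != length(codes))
    stop("consensus and structure lengths differ", call. = FALSE)
  if (!is_balanced_structure(structure))
    stop("structure is not a balanced dot-bracket string", call. = FALSE)
  if (spread < 0 || spread >= 1)
    stop("spread must be in [0, 1)", call. = FALSE)
  structure(
    list(consensus = decode_rna(codes), structure = structure,
         boost = as.numeric(boost), spread = as.numeric(spread),
         seed = as.integer(seed)),
    class = "toy_model_spec"
  )
}

# run code with its own RNG stream, leaving the caller's stream untouched
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- guide tree ----------------------------------------------------------

# Plan the guide tree for columns i..j of the pair table. Returns a list of
# node plans (type, cols, next/left/right links filled in by the caller's
# accumulator).
plan_guide_nodes <- function(pt, i, j, acc, prev = NA_integer_) {
  emit <- function(type, cols = integer()) {
    acc$nodes[[length(acc$nodes) + 1L]] <- list(type = type, cols = cols,
                                                next_node = NA_integer_,
                                                left = NA_integer_,
                                                right = NA_integer_)
    length(acc$nodes)
  }
  link <- function(id) {
    if (!is.na(prev)) acc$nodes[[prev]]$next_node <- id
    prev <<- id
  }
  repeat {
    if (i > j) { link(emit("END")); return(invisible(NULL)) }
    if (pt[i] == 0L) { link(emit("MATL", i)); i <- i + 1L; next }
    if (pt[i] == j)  { link(emit("MATP", c(i, j))); i <- i + 1L; j <- j - 1L; next }
    if (pt[j] == 0L) { link(emit("MATR", j)); j <- j - 1L; next }
    # i pairs k < j: bifurcate into [i..k] and [k+1..j]
    k <- pt[i]
    bif <- emit("BIF"); link(bif)
    begl <- emit("BEGL")
    acc$nodes[[bif]]$left <- begl
    plan_guide_nodes(pt, i, k, acc, prev = begl)
    begr <- emit("BEGR")
    acc$nodes[[bif]]$right <- begr
    plan_guide_nodes(pt, k + 1L, j, acc, prev = begr)
    return(invisible(NULL))
  }
}

NODE_SPLIT_SET <- list(
  ROOT = "S", MATL = c("ML", "D"), MATR = c("MR", "D"),
  MATP = c("MP", "ML", "MR", "D"), BIF = "B", BEGL = "S", BEGR = "S",
  END = "E"
)
NODE_INSERTS <- list(
  ROOT = c("IL", "IR"), MATL = "IL", MATR = "IR",
  MATP = c("IL", "IR"), BIF = character(), BEGL = character(),
  BEGR = "IL", END = character()
)
NODE_PRIMARY <- c(ROOT = "S", MATL = "ML", MATR = "MR", MATP = "MP",
                  BIF = "B", BEGL = "S", BEGR = "S", END = "E")

# ---- toy model construction ---------------------------------------------

#' Build a covariance model from a toy specification
#'
#' Deterministic given the spec's seed. Unpaired consensus columns become
#' MATL nodes, base-paired columns MATP nodes, and branch points in the
#' structure BIF/BEGL/BEGR nodes, each with the full Infernal state
#' complement (match, delete, insert states). Transition probabilities put
#' `1 - spread` on the main consensus path; emissions give the consensus
#' nucleotide (pair) a log-odds of `boost` bits. Insert states emit
#' uniformly, so every insert self-loop has strictly negative gain and the
#' model is free of non-termination hazards by construction.
#'
#' @param spec A [toy_model_spec()].
#' @param name Model name (defaults to a name derived from the seed).
#' @param dialect CM dialect tag recorded on the model.
#' @return A validated `cm_model`.
#' @export
build_toy_cm <- function(spec, name = NULL, dialect = "1.1") {
  stopifnot(inherits(spec, "toy_model_spec"))
  if (is.null(name)) name <- sprintf("toy-%d", spec$seed)
  with_local_seed(spec$seed, build_toy_cm_impl(spec, name, dialect))
}

build_toy_cm_impl <- function(spec, name, dialect) {
  codes <- encode_rna(spec$consensus)
  pt <- structure_pairs(spec$structure)

  acc <- new.env(parent = emptyenv())
  acc$nodes <- list(list(type = "ROOT", cols = integer(),
                         next_node = NA_integer_, left = NA_integer_,
                         right = NA_integer_))
  plan_guide_nodes(pt, 1L, length(codes), acc, prev = 1L)
  plans <- acc$nodes

  # allocate state indices node by node: split set first, then inserts
  n_nodes <- length(plans)
  node_states <- vector("list", n_nodes)   # named index vectors per node
  idx <- 0L
  for (k in seq_len(n_nodes)) {
    tys <- c(NODE_SPLIT_SET[[plans[[k]]$type]], NODE_INSERTS[[plans[[k]]$type]])
    ids <- seq.int(idx, idx + length(tys) - 1L)
    names(ids) <- tys
    node_states[[k]] <- ids
    idx <- idx + length(tys)
  }

  boost <- spec$boost
  spread <- spec$spread

  singlet_emis <- function(cons_code) {
    p_cons <- min(0.25 * 2^boost, 1)
    rest <- 1 - p_cons
    p <- rep(0, 4)
    if (rest > 0) {
      w <- 1 + 0.5 * stats::runif(3)
      p[-(cons_code + 1L)] <- rest * w / sum(w)
    }
    p[cons_code + 1L] <- p_cons
    log2(p / 0.25)
  }
  pair_emis <- function(cl, cr) {
    p_cons <- min(0.0625 * 2^boost, 1)
    rest <- 1 - p_cons
    p <- rep(0, 16)
    ci <- cl * 4L + cr + 1L
    if (rest > 0) {
      w <- 1 + 0.5 * stats::runif(15)
      p[-ci] <- rest * w / sum(w)
    }
    p[ci] <- p_cons
    log2(p / 0.0625)
  }

  emis_for <- function(state_type, plan) {
    cols <- plan$cols
    switch(state_type,
      ML = singlet_emis(codes[[cols[[1L]]]]),
      MR = singlet_emis(codes[[cols[[length(cols)]]]]),
      MP = pair_emis(codes[[cols[[1L]]]], codes[[cols[[2L]]]]),
      IL = rep(0, 4),
      IR = rep(0, 4),
      numeric()
    )
  }

  # transition probabilities over an ordered child set: the main child gets
  # 1 - spread, the rest share spread with seeded jitter
  trans_scores <- function(children_types, main_pos) {
    k <- length(children_types)
    p <- rep(0, k)
    if (k == 1L) { p[1L] <- 1 } else if (spread == 0) {
      p[main_pos] <- 1
    } else {
      p[main_pos] <- 1 - spread
      w <- 1 + 0.5 * stats::runif(k - 1L)
      p[-main_pos] <- spread * w / sum(w)
    }
    log2(p)
  }

  states <- list()
  nodes <- list()
  for (k in seq_len(n_nodes)) {
    plan <- plans[[k]]
    ids <- node_states[[k]]
    nxt <- plan$next_node
    split_next <- if (!is.na(nxt)) node_states[[nxt]][NODE_SPLIT_SET[[plans[[nxt]]$type]]] else integer()
    primary_next <- if (!is.na(nxt)) node_states[[nxt]][[NODE_PRIMARY[[plans[[nxt]]$type]]]] else NA_integer_

    for (pos in seq_along(ids)) {
      sty <- names(ids)[[pos]]
      sid <- ids[[pos]]
      if (sty == "E") {
        states[[sid + 1L]] <- cm_state(sid, "E", k - 1L)
      } else if (sty == "B") {
        lft <- node_states[[plan$left]][["S"]]
        rgt <- node_states[[plan$right]][["S"]]
        states[[sid + 1L]] <- cm_state(sid, "B", k - 1L,
                                       cfirst = lft, cnum = rgt)
      } else {
        inserts <- ids[names(ids) %in% c("IL", "IR")]
        own_ins <- switch(sty,
          IL = inserts,                       # self + IR if present
          IR = inserts[names(inserts) == "IR"],
          inserts
        )
        children <- c(own_ins, split_next)
        ctypes <- names(children)
        main_pos <- match(TRUE, children == primary_next)
        if (is.na(main_pos)) main_pos <- length(children)
        tr <- trans_scores(ctypes, main_pos)
        states[[sid + 1L]] <- cm_state(
          sid, sty, k - 1L,
          cfirst = unname(children[[1L]]), cnum = length(children),
          trans = tr, emis = emis_for(sty, plan)
        )
      }
    }
    nodes[[k]] <- cm_node(k - 1L, plan$type, unname(ids),
                          annot = list(cols = plan$cols,
                                       res = if (length(plan$cols))
                                         RNA_ALPHABET[codes[plan$cols] + 1L]
                                       else character()))
  }

  cm_model(name, states, nodes, null_model = rep(0.25, 4),
           dialect = dialect)
}

# ---- random specs for property tests and benchmarks ----------------------

#' Draw a random toy model specification
#'
#' Deterministic given the seed. Structures are sampled from simple
#' pseudoknot-free shapes: unstructured runs, hairpins with loops, and
#' (optionally) two-stem branched layouts that introduce a bifurcation.
#'
#' @param seed Integer seed.
#' @param min_len,max_len Consensus length range.
#' @param allow_bif Allow branched structures (B states)?
#' @param spread,boost Passed through to [toy_model_spec()].
#' @return A `toy_model_spec`.
#' @export
random_toy_spec <- function(seed, min_len = 1L, max_len = 8L,
                            allow_bif = FALSE, spread = 0.1, boost = 1.5) {
  with_local_seed(seed, {
    len <- sample(min_len:max_len, 1L)
    consensus <- paste(sample(RNA_ALPHABET, len, replace = TRUE),
                       collapse = "")
    structure <- random_structure(len, allow_bif)
    toy_model_spec(consensus, structure, boost = boost, spread = spread,
                   seed = seed)
  })
}

# sample a balanced dot-bracket string; branched shapes need >= 6 columns
random_structure <- function(len, allow_bif) {
  shapes <- "open"
  if (len >= 3L) shapes <- c(shapes, "hairpin")
  if (allow_bif && len >= 6L) shapes <- c(shapes, "branched")
  shape <- sample(shapes, 1L)
  if (shape == "open") return(strrep(".", len))
  if (shape == "hairpin") {
    # one stem of depth d enclosing an unpaired loop
    d <- sample(seq_len(max(1L, (len - 1L) %/% 2L)), 1L)
    loop <- len - 2L * d
    return(paste0(strrep("(", d), strrep(".", loop), strrep(")", d)))
  }
  # branched: two adjacent hairpins, leftover columns unpaired at the ends
  d1 <- sample(1:((len - 4L) %/% 2L), 1L)
  rem <- len - (2L * d1 + 1L)
  d2 <- sample(1:((rem - 1L) %/% 2L), 1L)
  tail_dots <- len - (2L * d1 + 1L) - (2L * d2 + 1L)
  paste0(strrep("(", d1), ".", strrep(")", d1),
         strrep("(", d2), ".", strrep(")", d2),
         strrep(".", tail_dots))
}
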