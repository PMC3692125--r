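# Link score and Link sequence for a pair of covariance models.
#
# The Link sequence of two models is the single sequence scoring highest
# in both models simultaneously; its Link score is the lower of the two
# model bit scores ("a sequence with a Link score of 20 bits scores at
# least 20 bits in each model"). The search is a max-min dynamic program
# over pairs of states, one from each model: a DP cell holds the Pareto
# frontier of (score-in-A, score-in-B) pairs achievable by joint
# derivations from its two states that emit one common subsequence.
# Emitting states pair when their emission footprint matches (left with
# left, right with right, pair with pair), silent states advance one
# model while the other waits, and bifurcations synchronize.
#
# Joint derivations of real model pairs are rarely perfectly synchronized,
# so three asymmetric mechanisms widen coverage while staying sound (every
# candidate corresponds to an actual pair of parses of one common
# sequence):
#
# * MP-split: an MP pair emission in one model is consumed by one left-
#   and one right-emitter of the other. When the left-emitter comes first
#   the right nucleotide becomes an "owed" emission (below); when the
#   right-emitter comes first (e.g. the ROOT IR of an unstructured model)
#   the partner left-emitter is reached through a precomputed best path of
#   silent states.
# * Owed right emissions: a model may emit the rightmost character of the
#   current span before the other model does. The DP then moves into a
#   pending plane keyed by the owed nucleotide; while pending, paired left
#   emissions and silent advances continue, and the owing model settles
#   the debt at its next right-emitter, at a final left-emitter (when the
#   owed character is the last of the span), or with an MP emission whose
#   right half is the owed character. One debt at a time is tracked, so
#   cells number at most 9 x |statesA| x |statesB| (1 + 2 models x 4
#   nucleotides), preserving the quadratic complexity contract.
# * Subtree deletion: a bifurcation facing a linear model may derive one
#   subtree as all-deletions while the other subtree pairs on.
#
# Keeping whole Pareto frontiers (instead of a single greedy (a,b) pair
# per cell) makes the max-min selection exact over everything the product
# rules express; the frontier is capped (default 64 entries). Joint
# parses are a subset of all parse pairs, so the link score is a lower
# bound on the exhaustive sequence-enumeration optimum (brute_force_link)
# and attains it whenever the optimal common sequence is jointly
# derivable - in particular for self comparisons, where mirroring the
# model's own best parse is always available.

LINK_KINDS <- c(
  A_SILENT = 1L, B_SILENT = 2L, LL = 3L, RR = 4L, PP = 5L,
  SPLIT_A_RFIRST = 7L, SPLIT_B_RFIRST = 9L,
  BIF_SYNC = 10L,
  DEL_A_LEFT = 11L, DEL_A_RIGHT = 12L, DEL_B_LEFT = 13L,
  DEL_B_RIGHT = 14L,
  CROSS = 15L, BASE = 16L,
  ORIG_SPLIT_A = 17L, ORIG_SPLIT_B = 18L,
  ORIG_RIGHT_A = 19L, ORIG_RIGHT_B = 20L,
  RES_RIGHT_B = 21L, RES_LEFT_CLOSED_B = 22L, RES_MP_B = 23L,
  PEND_LL = 24L, PEND_A_SILENT = 25L, PEND_B_SILENT = 26L,
  RES_RIGHT_A = 27L, RES_LEFT_CLOSED_A = 28L, RES_MP_A = 29L
)

# plane 1: no pending debt; planes 2-5: A owes right emission of A,C,G,U;
# planes 6-9: B owes right emission of A,C,G,U
PLANE_NONE <- 1L
plane_a_owes <- function(c) 2L + c
plane_b_owes <- function(c) 6L + c

# ---- per-model preprocessing ---------------------------------------------

linker_prep <- function(model) {
  n <- n_states(model)
  types <- state_types(model)
  children <- lapply(seq_len(n) - 1L, function(v) state_children(model, v))
  trans <- lapply(model$states, function(s)
    if (is.null(s$trans)) numeric() else s$trans)
  emis <- lapply(model$states, `[[`, "emis")

  # eps[v]: best all-silent (pure deletion) completion score from v
  eps <- rep(cm_sentinel(), n)
  for (v in seq.int(n, 1L)) {
    ty <- types[[v]]
    if (ty == "E") eps[[v]] <- 0
    else if (ty == "B") {
      st <- model$states[[v]]
      eps[[v]] <- eps[[st$cfirst + 1L]] + eps[[st$cnum + 1L]]
    } else if (ty %in% c("S", "D")) {
      ch <- children[[v]]
      vals <- trans[[v]] + eps[ch + 1L]
      if (length(vals)) eps[[v]] <- max(vals)
    } # emitters stay at the sentinel: they cannot be silent
  }

  # close[v] for singlet emitters: best transition into a silent completion
  close <- rep(cm_sentinel(), n)
  for (v in seq_len(n)) {
    if (types[[v]] %in% SINGLET_EMITTERS) {
      ch <- children[[v]]
      keep <- ch != (v - 1L)
      if (any(keep))
        close[[v]] <- max(trans[[v]][keep] + eps[ch[keep] + 1L])
    }
  }

  # reach[[v]] for right-emitters: left-emitters reachable from v's
  # children through silent-interior (S/D) paths; score includes the
  # transition out of v and the silent path, not the target's own scores.
  # Used by the right-emitter-first MP-split rule.
  reach <- vector("list", n)
  for (v in seq_len(n)) {
    if (!types[[v]] %in% RIGHT_EMITTERS) next
    best_to <- rep(cm_sentinel(), n)
    ch <- children[[v]]
    for (k in seq_along(ch)) {
      y <- ch[[k]]
      if (y == v - 1L) next
      best_to[[y + 1L]] <- max(best_to[[y + 1L]], trans[[v]][[k]])
    }
    for (x in seq_len(n)) {
      if (!is.finite(best_to[[x]]) || !types[[x]] %in% c("S", "D")) next
      chx <- children[[x]]
      for (k in seq_along(chx)) {
        y <- chx[[k]] + 1L
        s <- best_to[[x]] + trans[[x]][[k]]
        if (s > best_to[[y]]) best_to[[y]] <- s
      }
    }
    hit <- which(is.finite(best_to) & types %in% LEFT_EMITTERS)
    if (length(hit))
      reach[[v]] <- list(target = hit - 1L, score = best_to[hit])
  }

  list(model = model, n = n, types = types, children = children,
       trans = trans, emis = emis, eps = eps, close = close, reach = reach)
}

# ---- the product DP ------------------------------------------------------

link_dp <- function(pa, pb, max_pareto = 64L) {
  nA <- pa$n; nB <- pb$n
  cells <- vector("list", 9L * nA * nB)
  cid <- function(v, w, p) (((p - 1L) * nA + v) * nB) + w + 1L

  for (s in seq.int(nA + nB - 2L, 0L)) {
    v_lo <- max(0L, s - (nB - 1L))
    v_hi <- min(nA - 1L, s)
    for (v in seq.int(v_hi, v_lo)) {
      w <- s - v
      # the debt-free plane first: pending planes at (v, w) may resolve
      # into it through an insert self-loop
      cc <- link_cell(pa, pb, v, w, PLANE_NONE, cells, cid, max_pareto)
      if (!is.null(cc)) cells[[cid(v, w, PLANE_NONE)]] <- cc
      for (p in 2:9) {
        cc <- link_cell(pa, pb, v, w, p, cells, cid, max_pareto)
        if (!is.null(cc)) cells[[cid(v, w, p)]] <- cc
      }
    }
  }
  cells
}

link_cell <- function(pa, pb, v, w, plane, cells, cid, max_pareto) {
  tyA <- pa$types[[v + 1L]]
  tyB <- pb$types[[w + 1L]]
  K <- LINK_KINDS

  ca <- numeric(); cb <- numeric()
  kind <- integer(); cell1 <- integer(); elem1 <- integer()
  cell2 <- integer(); elem2 <- integer()
  emitL <- integer(); emitR <- integer()

  push <- function(kd, a, b, c1 = NA_integer_, e1 = NA_integer_,
                   c2 = NA_integer_, e2 = NA_integer_,
                   eL = NA_integer_, eR = NA_integer_) {
    k <- length(a)
    if (k == 0L) return(invisible())
    ca <<- c(ca, a); cb <<- c(cb, b)
    kind <<- c(kind, rep(kd, k))
    cell1 <<- c(cell1, rep_len(c1, k)); elem1 <<- c(elem1, rep_len(e1, k))
    cell2 <<- c(cell2, rep_len(c2, k)); elem2 <<- c(elem2, rep_len(e2, k))
    emitL <<- c(emitL, rep_len(eL, k)); emitR <<- c(emitR, rep_len(eR, k))
  }
  from_cell <- function(kd, sub, da, db, eL = NA_integer_,
                        eR = NA_integer_) {
    cc <- cells[[sub]]
    if (is.null(cc)) return(invisible())
    push(kd, cc$a + da, cc$b + db, c1 = sub, e1 = seq_along(cc$a),
         eL = eL, eR = eR)
  }

  a_left <- tyA %in% LEFT_EMITTERS; b_left <- tyB %in% LEFT_EMITTERS
  a_right <- tyA %in% RIGHT_EMITTERS; b_right <- tyB %in% RIGHT_EMITTERS
  chA <- pa$children[[v + 1L]]; chB <- pb$children[[w + 1L]]
  trA <- pa$trans[[v + 1L]]; trB <- pb$trans[[w + 1L]]
  eA <- pa$emis[[v + 1L]]; eB <- pb$emis[[w + 1L]]

  if (plane == PLANE_NONE) {
    if (tyA == "E" && tyB == "E") push(K[["BASE"]], 0, 0)

    if (tyA %in% c("S", "D"))
      for (k in seq_along(chA))
        from_cell(K[["A_SILENT"]], cid(chA[[k]], w, PLANE_NONE),
                  trA[[k]], 0)
    if (tyB %in% c("S", "D"))
      for (k in seq_along(chB))
        from_cell(K[["B_SILENT"]], cid(v, chB[[k]], PLANE_NONE),
                  0, trB[[k]])

    if ((a_left && b_left) || (a_right && b_right)) {
      kd <- if (a_left) K[["LL"]] else K[["RR"]]
      for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
        y <- chA[[ka]]; z <- chB[[kb]]
        if (y == v && z == w) next   # simultaneous self-loop: dominated
        for (c1 in 0:3)
          from_cell(kd, cid(y, z, PLANE_NONE),
                    trA[[ka]] + eA[[c1 + 1L]], trB[[kb]] + eB[[c1 + 1L]],
                    eL = if (a_left) c1 else NA_integer_,
                    eR = if (a_left) NA_integer_ else c1)
      }
    }

    if (tyA == "MP" && tyB == "MP") {
      for (ka in seq_along(chA)) for (kb in seq_along(chB))
        for (c1 in 0:3) for (c2 in 0:3) {
          pi <- c1 * 4L + c2 + 1L
          from_cell(K[["PP"]], cid(chA[[ka]], chB[[kb]], PLANE_NONE),
                    trA[[ka]] + eA[[pi]], trB[[kb]] + eB[[pi]],
                    eL = c1, eR = c2)
        }
    }

    # MP-split, left-emitter-first: the pair's right nucleotide becomes an
    # owed emission of the singlet model
    if (tyA == "MP" && b_left) {
      for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
        y <- chA[[ka]]; z <- chB[[kb]]
        for (c1 in 0:3) for (c2 in 0:3)
          from_cell(K[["ORIG_SPLIT_A"]], cid(y, z, plane_b_owes(c2)),
                    trA[[ka]] + eA[[c1 * 4L + c2 + 1L]],
                    trB[[kb]] + eB[[c1 + 1L]], eL = c1, eR = c2)
      }
    }
    if (tyB == "MP" && a_left) {
      for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
        y <- chA[[ka]]; z <- chB[[kb]]
        for (c1 in 0:3) for (c2 in 0:3)
          from_cell(K[["ORIG_SPLIT_B"]], cid(y, z, plane_a_owes(c2)),
                    trA[[ka]] + eA[[c1 + 1L]],
                    trB[[kb]] + eB[[c1 * 4L + c2 + 1L]], eL = c1, eR = c2)
      }
    }

    # MP-split, right-emitter-first (e.g. a ROOT IR upstream of all left
    # emitters): partner left-emitter reached through silent states
    if (tyA == "MP" && b_right) closure_split(pa, pb, v, w, TRUE,
                                              cells, cid, from_cell)
    if (tyB == "MP" && a_right) closure_split(pb, pa, w, v, FALSE,
                                              cells, cid, from_cell)

    # lone right emission: this model runs ahead on the right edge and the
    # other inherits the debt
    if (a_right) {
      for (ka in seq_along(chA)) {
        y <- chA[[ka]]
        if (y == v) next
        for (c1 in 0:3)
          from_cell(K[["ORIG_RIGHT_A"]], cid(y, w, plane_b_owes(c1)),
                    trA[[ka]] + eA[[c1 + 1L]], 0, eR = c1)
      }
    }
    if (b_right) {
      for (kb in seq_along(chB)) {
        z <- chB[[kb]]
        if (z == w) next
        for (c1 in 0:3)
          from_cell(K[["ORIG_RIGHT_B"]], cid(v, z, plane_a_owes(c1)),
                    0, trB[[kb]] + eB[[c1 + 1L]], eR = c1)
      }
    }

    if (tyA == "B" && tyB == "B") {
      stA <- pa$model$states[[v + 1L]]; stB <- pb$model$states[[w + 1L]]
      subL <- cells[[cid(stA$cfirst, stB$cfirst, PLANE_NONE)]]
      subR <- cells[[cid(stA$cnum, stB$cnum, PLANE_NONE)]]
      if (!is.null(subL) && !is.null(subR)) {
        nl <- length(subL$a); nr <- length(subR$a)
        i <- rep(seq_len(nl), each = nr); j <- rep(seq_len(nr), nl)
        push(K[["BIF_SYNC"]], subL$a[i] + subR$a[j], subL$b[i] + subR$b[j],
             c1 = cid(stA$cfirst, stB$cfirst, PLANE_NONE), e1 = i,
             c2 = cid(stA$cnum, stB$cnum, PLANE_NONE), e2 = j)
      }
    }
    if (tyA == "B") {
      stA <- pa$model$states[[v + 1L]]
      from_cell(K[["DEL_A_LEFT"]], cid(stA$cnum, w, PLANE_NONE),
                pa$eps[[stA$cfirst + 1L]], 0)
      from_cell(K[["DEL_A_RIGHT"]], cid(stA$cfirst, w, PLANE_NONE),
                pa$eps[[stA$cnum + 1L]], 0)
    }
    if (tyB == "B") {
      stB <- pb$model$states[[w + 1L]]
      from_cell(K[["DEL_B_LEFT"]], cid(v, stB$cnum, PLANE_NONE),
                0, pb$eps[[stB$cfirst + 1L]])
      from_cell(K[["DEL_B_RIGHT"]], cid(v, stB$cfirst, PLANE_NONE),
                0, pb$eps[[stB$cnum + 1L]])
    }

    # opposite-handed singlet emitters sharing the final character of both
    # spans; both models then complete silently
    if ((a_left && b_right) || (a_right && b_left)) {
      clA <- pa$close[[v + 1L]]; clB <- pb$close[[w + 1L]]
      if (is.finite(clA) && is.finite(clB)) {
        for (c1 in 0:3)
          push(K[["CROSS"]], eA[[c1 + 1L]] + clA, eB[[c1 + 1L]] + clB,
               eL = c1)
      }
    }
  } else {
    # pending planes: one owed right emission is outstanding
    b_owes <- plane >= 6L
    owed <- if (b_owes) plane - 6L else plane - 2L

    if (tyA %in% c("S", "D"))
      for (k in seq_along(chA))
        from_cell(K[["PEND_A_SILENT"]], cid(chA[[k]], w, plane),
                  trA[[k]], 0)
    if (tyB %in% c("S", "D"))
      for (k in seq_along(chB))
        from_cell(K[["PEND_B_SILENT"]], cid(v, chB[[k]], plane),
                  0, trB[[k]])

    if (a_left && b_left) {
      for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
        y <- chA[[ka]]; z <- chB[[kb]]
        if (y == v && z == w) next
        for (c1 in 0:3)
          from_cell(K[["PEND_LL"]], cid(y, z, plane),
                    trA[[ka]] + eA[[c1 + 1L]], trB[[kb]] + eB[[c1 + 1L]],
                    eL = c1)
      }
    }

    if (b_owes) {
      if (b_right)   # settle at the next right-emitter (forced character)
        for (kb in seq_along(chB))
          from_cell(K[["RES_RIGHT_B"]], cid(v, chB[[kb]], PLANE_NONE),
                    0, eB[[owed + 1L]] + trB[[kb]])
      if (b_left) {  # owed character is the last of the span
        clB <- pb$close[[w + 1L]]
        if (is.finite(pa$eps[[v + 1L]]) && is.finite(clB))
          push(K[["RES_LEFT_CLOSED_B"]], pa$eps[[v + 1L]],
               eB[[owed + 1L]] + clB)
      }
      if (tyB == "MP" && a_left) {   # MP whose right half is the debt
        for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
          y <- chA[[ka]]; z <- chB[[kb]]
          for (c1 in 0:3)
            from_cell(K[["RES_MP_B"]], cid(y, z, PLANE_NONE),
                      trA[[ka]] + eA[[c1 + 1L]],
                      trB[[kb]] + eB[[c1 * 4L + owed + 1L]], eL = c1)
        }
      }
    } else {
      if (a_right)
        for (ka in seq_along(chA))
          from_cell(K[["RES_RIGHT_A"]], cid(chA[[ka]], w, PLANE_NONE),
                    eA[[owed + 1L]] + trA[[ka]], 0)
      if (a_left) {
        clA <- pa$close[[v + 1L]]
        if (is.finite(clA) && is.finite(pb$eps[[w + 1L]]))
          push(K[["RES_LEFT_CLOSED_A"]], eA[[owed + 1L]] + clA,
               pb$eps[[w + 1L]])
      }
      if (tyA == "MP" && b_left) {
        for (ka in seq_along(chA)) for (kb in seq_along(chB)) {
          y <- chA[[ka]]; z <- chB[[kb]]
          for (c1 in 0:3)
            from_cell(K[["RES_MP_A"]], cid(y, z, PLANE_NONE),
                      trA[[ka]] + eA[[c1 * 4L + owed + 1L]],
                      trB[[kb]] + eB[[c1 + 1L]], eL = c1)
        }
      }
    }
  }

  if (length(ca) == 0L) return(NULL)
  ok <- is.finite(ca) & is.finite(cb)
  if (!any(ok)) return(NULL)
  sel <- pareto_select(ca[ok], cb[ok], max_pareto)
  ix <- which(ok)[sel]
  list(a = ca[ix], b = cb[ix], kind = kind[ix],
       cell1 = cell1[ix], elem1 = elem1[ix],
       cell2 = cell2[ix], elem2 = elem2[ix],
       emitL = emitL[ix], emitR = emitR[ix])
}

# MP (in model p1, state v1) vs a right-emitter of p2 (state w1) that
# right-emits the pair's right nucleotide before a left-emitter - reached
# through silent states only - emits the left one.
closure_split <- function(p1, p2, v1, w1, a_is_mp, cells, cid, from_cell) {
  rc <- p2$reach[[w1 + 1L]]
  if (is.null(rc)) return(invisible())
  ch1 <- p1$children[[v1 + 1L]]
  eMP <- p1$emis[[v1 + 1L]]
  eW <- p2$emis[[w1 + 1L]]
  kd <- if (a_is_mp) LINK_KINDS[["SPLIT_A_RFIRST"]]
        else LINK_KINDS[["SPLIT_B_RFIRST"]]
  for (ti in seq_along(rc$target)) {
    u <- rc$target[[ti]]            # the left-emitter on p2's side
    psc <- rc$score[[ti]]
    eU <- p2$emis[[u + 1L]]
    chU <- p2$children[[u + 1L]]
    for (ku in seq_along(chU)) {
      z <- chU[[ku]]
      tz <- p2$trans[[u + 1L]][[ku]]
      for (k1 in seq_along(ch1)) {
        y <- ch1[[k1]]
        t1 <- p1$trans[[v1 + 1L]][[k1]]
        for (c1 in 0:3) for (c2 in 0:3) {
          d1 <- t1 + eMP[[c1 * 4L + c2 + 1L]]
          d2 <- eW[[c2 + 1L]] + psc + eU[[c1 + 1L]] + tz
          if (a_is_mp)
            from_cell(kd, cid(y, z, PLANE_NONE), d1, d2, eL = c1, eR = c2)
          else
            from_cell(kd, cid(z, y, PLANE_NONE), d2, d1, eL = c1, eR = c2)
        }
      }
    }
  }
  invisible()
}

# Keep the Pareto frontier of (a, b) pairs, ordered by descending
# min(a,b), then descending max(a,b), then first occurrence; capped.
pareto_select <- function(a, b, cap) {
  o <- order(-a, -b, seq_along(a))
  keep <- logical(length(a))
  best_b <- -Inf
  for (i in o) {
    if (b[[i]] > best_b) { keep[[i]] <- TRUE; best_b <- b[[i]] }
  }
  idx <- which(keep)
  lo <- pmin(a[idx], b[idx]); hi <- pmax(a[idx], b[idx])
  idx <- idx[order(-lo, -hi, idx)]
  idx[seq_len(min(length(idx), cap))]
}

# ---- traceback -----------------------------------------------------------

# Reassembles the link sequence and both dot-bracket structures from the
# backpointers, outside-in. Results carry `owed`: the structure symbol of
# the owing model for a pending right emission, bubbled up from the
# resolving rule to the originating one (which knows the character's
# position but not yet whether the other model emitted it via a singlet
# or an MP).
link_traceback <- function(cells, id, elem) {
  cc <- cells[[id]]
  kd <- cc$kind[[elem]]
  eL <- cc$emitL[[elem]]; eR <- cc$emitR[[elem]]
  sub <- function() link_traceback(cells, cc$cell1[[elem]], cc$elem1[[elem]])
  res <- function(seq, sa, sb, owed = NULL)
    list(seq = seq, sa = sa, sb = sb, owed = owed)
  chL <- if (!is.na(eL)) RNA_ALPHABET[[eL + 1L]]
  chR <- if (!is.na(eR)) RNA_ALPHABET[[eR + 1L]]
  K <- LINK_KINDS

  if (kd == K[["BASE"]])
    return(res(character(), character(), character()))
  if (kd == K[["CROSS"]])
    return(res(chL, ".", "."))
  if (kd %in% K[c("RES_LEFT_CLOSED_B", "RES_LEFT_CLOSED_A")])
    return(res(character(), character(), character(), owed = "."))

  if (kd == K[["BIF_SYNC"]]) {
    lft <- link_traceback(cells, cc$cell1[[elem]], cc$elem1[[elem]])
    rgt <- link_traceback(cells, cc$cell2[[elem]], cc$elem2[[elem]])
    return(res(c(lft$seq, rgt$seq), c(lft$sa, rgt$sa), c(lft$sb, rgt$sb)))
  }

  r <- sub()
  if (kd %in% K[c("A_SILENT", "B_SILENT", "DEL_A_LEFT", "DEL_A_RIGHT",
                  "DEL_B_LEFT", "DEL_B_RIGHT")])
    return(r)
  if (kd %in% K[c("PEND_A_SILENT", "PEND_B_SILENT")])
    return(r)
  if (kd == K[["LL"]] || kd == K[["PEND_LL"]])
    return(res(c(chL, r$seq), c(".", r$sa), c(".", r$sb), owed = r$owed))
  if (kd == K[["RR"]])
    return(res(c(r$seq, chR), c(r$sa, "."), c(r$sb, ".")))
  if (kd == K[["PP"]])
    return(res(c(chL, r$seq, chR), c("(", r$sa, ")"), c("(", r$sb, ")")))
  if (kd == K[["SPLIT_A_RFIRST"]])
    return(res(c(chL, r$seq, chR), c("(", r$sa, ")"), c(".", r$sb, ".")))
  if (kd == K[["SPLIT_B_RFIRST"]])
    return(res(c(chL, r$seq, chR), c(".", r$sa, "."), c("(", r$sb, ")")))
  if (kd == K[["ORIG_SPLIT_A"]])
    return(res(c(chL, r$seq, chR), c("(", r$sa, ")"),
               c(".", r$sb, r$owed)))
  if (kd == K[["ORIG_SPLIT_B"]])
    return(res(c(chL, r$seq, chR), c(".", r$sa, r$owed),
               c("(", r$sb, ")")))
  if (kd == K[["ORIG_RIGHT_A"]])
    return(res(c(r$seq, chR), c(r$sa, "."), c(r$sb, r$owed)))
  if (kd == K[["ORIG_RIGHT_B"]])
    return(res(c(r$seq, chR), c(r$sa, r$owed), c(r$sb, ".")))
  if (kd %in% K[c("RES_RIGHT_B", "RES_RIGHT_A")]) {
    r$owed <- "."
    return(r)
  }
  if (kd == K[["RES_MP_B"]])
    return(res(c(chL, r$seq), c(".", r$sa), c("(", r$sb), owed = ")"))
  if (kd == K[["RES_MP_A"]])
    return(res(c(chL, r$seq), c("(", r$sa), c(".", r$sb), owed = ")"))
  stop("internal error: unknown traceback kind ", kd)
}

# ---- public API ----------------------------------------------------------

#' Link score and Link sequence of a model pair
#'
#' Runs the max-min product dynamic program over state pairs (see the
#' package vignette for the recursion) and returns the jointly emitted
#' sequence maximizing the minimum of the two accumulated model scores.
#' The reported `score_a`/`score_b` are the joint parse's per-model sums;
#' the single-model optimum for the link sequence can only be larger and
#' is reported by [detail_view()]. Results are bit-reproducible: the pair
#' is canonically ordered internally, so swapping the arguments swaps the
#' roles but never changes any score or the sequence.
#'
#' @param model_a,model_b Valid, hazard-free `cm_model` objects.
#' @param max_pareto Cap on the per-cell Pareto frontier (default 64).
#' @return A `cm_link` object with fields `model_a`, `model_b`, `score_a`,
#'   `score_b`, `link_score` (the exact minimum of the two), the
#'   `link_sequence`, per-model dot-bracket structures `structure_a` and
#'   `structure_b`, and a `diag` list with DP cell statistics. When no
#'   joint parse exists all scores are the sentinel and the sequence is
#'   empty.
#' @export
link_models <- function(model_a, model_b, max_pareto = 64L) {
  assert_no_hazard(model_a, "link_models")
  assert_no_hazard(model_b, "link_models")

  keyA <- paste0(model_a$name, "\n", write_cm_file(model_a))
  keyB <- paste0(model_b$name, "\n", write_cm_file(model_b))
  swapped <- keyB < keyA
  m1 <- if (swapped) model_b else model_a
  m2 <- if (swapped) model_a else model_b

  p1 <- linker_prep(m1)
  p2 <- linker_prep(m2)
  cells <- link_dp(p1, p2, max_pareto = as.integer(max_pareto))
  root <- cells[[1L]]   # cell (0, 0) in the debt-free plane

  diag <- list(
    n_cells = 9L * p1$n * p2$n,
    n_states_a = if (swapped) p2$n else p1$n,
    n_states_b = if (swapped) p1$n else p2$n,
    cells_materialized = sum(!vapply(cells, is.null, logical(1))),
    pareto_elements = sum(vapply(cells, function(x)
      if (is.null(x)) 0L else length(x$a), integer(1)))
  )

  if (is.null(root)) {
    res <- list(s1 = cm_sentinel(), s2 = cm_sentinel(), seq = "",
                st1 = "", st2 = "")
  } else {
    tb <- link_traceback(cells, 1L, 1L)
    res <- list(s1 = root$a[[1L]], s2 = root$b[[1L]],
                seq = paste(tb$seq, collapse = ""),
                st1 = paste(tb$sa, collapse = ""),
                st2 = paste(tb$sb, collapse = ""))
  }

  if (swapped) res <- list(s1 = res$s2, s2 = res$s1, seq = res$seq,
                           st1 = res$st2, st2 = res$st1)
  new_cm_link(model_a$name, model_b$name, res$s1, res$s2, res$seq,
              res$st1, res$st2, diag)
}

new_cm_link <- function(name_a, name_b, score_a, score_b, link_sequence,
                        structure_a, structure_b, diag = NULL) {
  structure(
    list(model_a = name_a, model_b = name_b,
         score_a = score_a, score_b = score_b,
         link_score = min(score_a, score_b),
         link_sequence = link_sequence,
         structure_a = structure_a, structure_b = structure_b,
         diag = diag),
    class = "cm_link"
  )
}

#' @export
print.cm_link <- function(x, ...) {
  cat(sprintf("<cm_link> %s vs %s\n", x$model_a, x$model_b))
  cat(sprintf("  scores: %.1f / %.1f bits   link score: %.1f bits\n",
              x$score_a, x$score_b, x$link_score))
  if (nzchar(x$link_sequence)) {
    cat("  ", x$link_sequence, "\n  ", x$structure_a, "\n  ",
        x$structure_b, "\n", sep = "")
  } else {
    cat("  (no joint parse)\n")
  }
  invisible(x)
}

#' Per-model consensus structures of a link result
#'
#' The product parse proposes a consensus secondary structure of both RNA
#' families for the link sequence: each model's dot-bracket has brackets
#' exactly where that model's MP states emitted on the joint parse, so a
#' position paired in one structure may be unpaired in the other (a stem
#' present in only one family appears deleted in the other's consensus).
#'
#' @param link_result A `cm_link` from [link_models()].
#' @return Named character vector with elements `a` and `b`.
#' @export
product_structures <- function(link_result) {
  stopifnot(inherits(link_result, "cm_link"))
  c(a = link_result$structure_a, b = link_result$structure_b)
}

#' Brute-force link by exhaustive sequence enumeration
#'
#' Test oracle: enumerates every RNA sequence up to `max_len` (canonical
#' order) and maximizes the minimum of the two models' optimal parse
#' scores. Unlike [link_models()], the reported per-model scores are the
#' true single-model optima of the winning sequence.
#'
#' @param model_a,model_b `cm_model` objects.
#' @param max_len Maximum sequence length (<= 8).
#' @return A `cm_link`.
#' @export
brute_force_link <- function(model_a, model_b, max_len) {
  if (max_len > 8L) stop("brute-force guard: max_len must be <= 8",
                         call. = FALSE)
  fa <- cm_flatten(model_a); fb <- cm_flatten(model_b)
  res <- cpp_enum_best_pair(fa$type, fa$cfirst, fa$cnum, fa$trans, fa$toff,
                            fa$emis, fa$eoff,
                            fb$type, fb$cfirst, fb$cnum, fb$trans, fb$toff,
                            fb$emis, fb$eoff, as.integer(max_len))
  if (!is.finite(res$score))
    return(new_cm_link(model_a$name, model_b$name, cm_sentinel(),
                       cm_sentinel(), "", "", ""))
  s <- decode_rna(res$seq)
  pa <- optimal_parse_score(model_a, s)
  pb <- optimal_parse_score(model_b, s)
  new_cm_link(model_a$name, model_b$name, pa$score, pb$score, s,
              pa$structure, pb$structure)
}
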