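# Independent pure-R scoring oracle: recursive maximization over all
# parse trees of (state, span), written without reference to the C++
# kernel. Memoized; intended for small fixtures only (<= 25 states,
# sequences of length <= 5).

r_parse_score <- function(model, sequence) {
  codes <- cmlink:::encode_rna(sequence)
  L <- length(codes)
  memo <- new.env(parent = emptyenv())
  rec <- function(v, i, j) {
    key <- paste(v, i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    st <- model$states[[v + 1L]]
    ty <- st$type
    best <- -Inf
    if (ty == "E") {
      if (i == j) best <- 0
    } else if (ty == "B") {
      for (k in i:j)
        best <- max(best, rec(st$cfirst, i, k) + rec(st$cnum, k, j))
    } else {
      kids <- state_children(model, v)
      for (kk in seq_along(kids)) {
        y <- kids[[kk]]
        tr <- st$trans[[kk]]
        val <- -Inf
        if (ty %in% c("S", "D")) {
          val <- tr + rec(y, i, j)
        } else if (ty %in% c("IL", "ML")) {
          if (j > i)
            val <- tr + st$emis[[codes[[i + 1L]] + 1L]] + rec(y, i + 1L, j)
        } else if (ty %in% c("IR", "MR")) {
          if (j > i)
            val <- tr + st$emis[[codes[[j]] + 1L]] + rec(y, i, j - 1L)
        } else if (ty == "MP") {
          if (j - i >= 2L)
            val <- tr +
              st$emis[[codes[[i + 1L]] * 4L + codes[[j]] + 1L]] +
              rec(y, i + 1L, j - 1L)
        }
        best <- max(best, val)
      }
    }
    memo[[key]] <- best
    best
  }
  rec(0L, 0L, L)
}

# All RNA strings of length 0..max_len in canonical order.
all_rna_strings <- function(max_len) {
  alphabet <- c("A", "C", "G", "U")
  out <- ""
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), L), stringsAsFactors = FALSE))
    # expand.grid varies the first column fastest; reorder for
    # lexicographic order with the leftmost character most significant
    s <- do.call(paste0, rev(grid))
    out <- c(out, sort(s))
  }
  out
}
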