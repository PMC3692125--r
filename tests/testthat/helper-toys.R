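# Shared fixtures: seeded toy models, deliberately broken models for the
# validator, and the planted clan fixture.

toy_pair <- function(seed, min_len = 2, max_len = 4, allow_bif = FALSE) {
  spA <- random_toy_spec(seed * 2 - 1, min_len = min_len,
                         max_len = max_len, allow_bif = allow_bif)
  spB <- random_toy_spec(seed * 2, min_len = min_len, max_len = max_len,
                         allow_bif = allow_bif)
  list(a = build_toy_cm(spA, name = "A"), b = build_toy_cm(spB, name = "B"),
       spec_a = spA, spec_b = spB)
}

# A minimal hand-written valid model: ROOT(S,IL,IR) MATL(ML,D,IL) END(E),
# consensus a single A-preferring column. Useful as a known-good baseline
# and as the starting point for broken variants.
tiny_model <- function(name = "tiny") {
  build_toy_cm(toy_model_spec("A", ".", boost = 1, seed = 1), name = name)
}

# Broken variants, one per validator invariant.
break_model <- function(how) {
  m <- tiny_model()
  if (how == "root") {
    m$states[[1]]$type <- "D"
  } else if (how == "null") {
    m$null_model <- c(0.5, 0.5, 0.5, 0.5)
  } else if (how == "arity") {
    m$states[[4]]$emis <- numeric(16)   # ML with pair-sized table
  } else if (how == "children") {
    m$states[[1]]$cnum <- 99L
  } else if (how == "hazard") {
    # insert self-loop with non-negative gain: guaranteed mass leak
    il <- which(vapply(m$states, `[[`, character(1), "type") == "IL")[1]
    k <- which(state_children(m, il - 1L) == il - 1L)
    m$states[[il]]$trans[k] <- 0.5
    m$states[[il]]$emis <- rep(0.5, 4)
  } else stop("unknown breakage: ", how)
  m
}

# Planted clan fixture: three models sharing an AAAA consensus, a bridge
# model scoring A- and U-sequences equally, and a loner preferring UUUU.
# Designed margins (boost 1.766 bits/column vs 0.848 for the bridge) put
# clan and bridge-satellite links clearly above 0 bits and
# loner-vs-clan links clearly below, so 0 bits is a safe a-priori
# threshold.
make_clan_fixture <- function() {
  b <- log2(0.85 / 0.25)
  clan <- lapply(1:3, function(i)
    build_toy_cm(toy_model_spec("AAAA", "....", boost = b, seed = i),
                 name = paste0("clan", LETTERS[i])))
  bridge <- build_toy_cm(toy_model_spec("AAAA", "....", boost = b,
                                        seed = 4), name = "bridge")
  amb <- log2(c(0.45, 0.05, 0.05, 0.45) / 0.25)   # A and U both favored
  for (i in seq_along(bridge$states)) {
    st <- bridge$states[[i]]
    if (st$type == "ML") bridge$states[[i]]$emis <- amb
  }
  stopifnot(length(validate_model(bridge)) == 0)
  lone <- build_toy_cm(toy_model_spec("UUUU", "....", boost = b,
                                      seed = 5), name = "lone")
  c(clan, list(bridge, lone))
}
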