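---
title: "Comparing covariance models with link scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing covariance models with link scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(cmlink)
```

## The problem

A covariance model (CM) is a profile stochastic context-free grammar
describing an RNA family: a tree of states that emit nucleotides singly
(`ML`, `MR`, `IL`, `IR`), in base pairs (`MP`), or not at all (`S`, `D`,
`B`, `E`). A sequence's bit score under a model is the log-odds of its
best parse relative to a uniform null. When two models assign high
scores to the same sequences, database searches with them will return
overlapping hits — either a genuine evolutionary relationship (Rfam
groups such families into clans) or an overly permissive model.

`cmlink` quantifies this overlap with the **link score** of a model
pair: the score of the single sequence that does best in *both* models
simultaneously, measured as the *lower* of its two bit scores. A link
score of 20 bits means one concrete sequence — the **link sequence** —
scores at least 20 bits in each model. A model linked with itself simply
recovers its best achievable sequence, so the self-link score is the
natural ceiling: `link_models(M, M)$link_score ==
best_sequence(M)$score`.

## Toy models

Real CMs are built from curated alignments; for experimentation and
testing the package generates small, fully controlled models from a
consensus sequence and a dot-bracket structure:

```{r}
hairpin <- build_toy_cm(
  toy_model_spec("GGGAAACCC", "(((...)))", boost = 2, seed = 1),
  name = "hairpin")
hairpin
flat <- build_toy_cm(
  toy_model_spec("GGGAAACCC", ".........", boost = 2, seed = 2),
  name = "flat")
```

Two parameters shape the emission and transition tables:

* `boost` (default 1.5 bits) is the log-odds of the consensus nucleotide
  (or pair) over the uniform null — it plays the role that alignment
  conservation plays in a real model. The consensus probability is
  `0.25 * 2^boost` per singlet and `0.0625 * 2^boost` per pair, capped
  at 1.
* `spread` (default 0.1) is the probability mass on non-consensus
  transitions, split with seeded jitter so that no two toy models are
  numerically identical.

Insert emissions are uniform (0 log-odds), which makes every insert
self-loop strictly score-decreasing: toy models are *hazard-free* by
construction, and `validate_model()` rejects any model where a self-loop
could gain score without bound. These toys emulate the aspects of real
CMs that matter for comparison — consensus preference, structure via
`MP` states, deletions, inserts, bifurcation — at sizes where exhaustive
enumeration is still possible, which is how the implementation is
validated.

## Scoring and the link computation

Single-model scoring is a standard CYK maximization over (state,
subsequence) cells, implemented in C++ (the textbook choice for these
cubic kernels):

```{r}
best_sequence(hairpin)
optimal_parse_score(flat, "GGGAAACCC")
```

The link computation is a max-min dynamic program over *pairs of
states*, one from each model. A cell holds the candidate score pairs
`(score in A, score in B)` of joint derivations that emit one common
subsequence. Emitters pair when their footprints match (left-left,
right-right, pair-pair), silent states advance one model while the
other waits, and bifurcations synchronize. Three asymmetric mechanisms
cover desynchronized derivations, each corresponding to a literal pair
of parses of one common sequence:

* **MP-splits**: a pair emission in one model consumed by one left- and
  one right-emitter of the other;
* **owed right emissions**: one model may emit the rightmost character
  of the current span before the other; the debt (at most one, a single
  nucleotide) is carried in the DP state and settled at the other
  model's next right-emitter, final left-emitter, or matching `MP`;
* **subtree deletion**: a bifurcation facing a linear model may derive
  one of its subtrees entirely by deletions.

With the single-debt bound, cells number at most `9 * nA * nB`, keeping
the computation quadratic in the model sizes. Two further design
choices are worth naming:

* Each cell keeps a **Pareto frontier** of score pairs rather than one
  greedy pair — maximizing the *minimum* of two objectives is not
  decomposable, so a pair dominated in one model can still win the
  final min. The frontier is capped (`max_pareto`, default 64); in all
  enumeration checks run during development the cap was never the
  binding constraint on correctness.
* The pair is put into a canonical internal order before the DP and
  swapped back afterwards, so swapping the arguments swaps the roles
  but never changes a digit.

Joint derivations are a subset of all parse pairs, so the link score is
a lower bound on the true optimum over all sequences; it attains it in
every exhaustive cross-check the package ships (see the test suite and
`scripts/acceptance.R`), and the self-link identity holds exactly
because mirroring a model's own best parse is always expressible.

```{r}
r <- link_models(hairpin, flat)
r
```

The two structure lines are the models' respective consensus structures
for the link sequence — a stem present in one family and absent in the
other shows up exactly here:

```{r}
product_structures(r)
```

`brute_force_link()` is the enumeration oracle (every sequence up to
length 8) used to validate the DP on small models:

```{r}
brute_force_link(hairpin, flat, max_len = 8)$link_score
```

## Workflows and reports

`compare_all_vs_all()` computes the `C(k, 2)` pairwise results in a
deterministic canonical order (and isolates per-pair failures);
`compare_one_vs_many()` compares queries against a model database, e.g.
a directory read with `read_cm_dir()`. Results filter by name
substring, score threshold, and top-N, and render as TSV, score matrix,
DOT graph, or a per-pair detail view:

```{r}
models <- list(
  hairpin, flat,
  build_toy_cm(toy_model_spec("ACGUA", ".....", seed = 3), name = "short"))
tab <- compare_all_vs_all(models)
cat(to_tsv(tab))
to_matrix(tab, diagonal = "BEST_SCORE", models = models)
cat(to_dot(build_link_graph(tab, min_link_score = 0)))
```

Thresholding the graph exposes clan candidates as connected components:
mutually high-linking models form cliques, and a model that cross-hits
only one family appears as a degree-1 satellite. The package's
acceptance checks plant exactly such a fixture and recover it.

## Numerical conventions

* All scores are bits; `-Inf` is the impossibility sentinel, written as
  `*` in CM files.
* CM files (both the 1.0 and 1.1 ASCII dialects) store five-decimal
  scores; round-trips are exact to 1e-4 bits.
* Ties break deterministically everywhere (lowest child index, leftmost
  bifurcation split, alphabetical nucleotide), so every result is
  bit-reproducible.

## Limitations

* Global alignment only: no local begins/ends, no truncated parses, and
  no HMM filter sections of 1.1 files.
* The link DP's asymmetric rules carry at most one pending emission;
  configurations needing a deeper queue (several right emissions owed
  at once) fall back to a sound lower bound. None of the seeded
  enumeration cross-checks hit such a configuration.
* `brute_force_*` oracles are capped at sequence length 8 by design.
* Stockholm alignments are not parsed; `stockholm_to_cm()` shells out
  to Infernal's `cmbuild` when available and explains the requirement
  otherwise.
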