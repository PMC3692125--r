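# cmlink

Pairwise comparison of RNA covariance models via link scores.

Covariance models (CMs, profile stochastic context-free grammars in the
Infernal file format) describe RNA families by conserved sequence *and*
secondary structure. Two models that assign high bit scores to the same
sequences will cross-match in database searches — either because the
families are genuinely related (Rfam clans) or because a model is too
permissive. `cmlink` measures this overlap directly: for a pair of
models it computes the **link sequence**, the single sequence scoring
highest in both models simultaneously, and the **link score**, the
lower of its two bit scores. A link score of 20 bits certifies one
concrete sequence scoring at least 20 bits in each model. A model
compared with itself recovers its best achievable sequence, so the
self-link score equals `best_sequence(M)$score`.

The package provides:

* **cm_io** — read/write Infernal 1.0 and 1.1 ASCII CM files
  (multi-record), model validation, and a seeded toy-model generator
  (`build_toy_cm()`) for controlled experiments;
* **scoring** — optimal (CYK) parse scores, best achievable sequence,
  and brute-force enumeration oracles (C++ kernels via Rcpp);
* **linker** — `link_models()`, a quadratic max-min dynamic program
  over state pairs with Pareto-frontier cells, plus the
  `brute_force_link()` oracle;
* **workflows** — `compare_one_vs_many()`, `compare_all_vs_all()`,
  filtering, and thresholded link graphs for clan-candidate screening;
* **reports & CLI** — TSV tables, score matrices, DOT graphs, per-pair
  detail views, and a `cmlink` command-line tool.

## Worked example

```r
library(cmlink)

hairpin <- build_toy_cm(
  toy_model_spec("GGGAAACCC", "(((...)))", boost = 2, seed = 1),
  name = "hairpin")
flat <- build_toy_cm(
  toy_model_spec("GGGAAACCC", ".........", boost = 2, seed = 2),
  name = "flat")
short <- build_toy_cm(
  toy_model_spec("ACGUA", ".....", seed = 3), name = "short")

best_sequence(hairpin)
#> <cm_parse> score 10.9 bits
#>  GGGAAACCC
#>  (((...)))

link_models(hairpin, flat)
#> <cm_link> hairpin vs flat
#>   scores: 2.3 / 5.5 bits   link score: 2.3 bits
#>   GGGAAACCC
#>   ((.....))
#>   .........
```

The two models share their consensus letters, so they link on
`GGGAAACCC`; the structure lines show each model's consensus structure
for that sequence (the stem exists only in `hairpin`'s view).

```r
tab <- compare_all_vs_all(list(hairpin, flat, short))
cat(to_tsv(tab))
#> modelA	modelB	scoreA	scoreB	linkScore	linkSequence	structureA	structureB
#> flat	hairpin	5.5	2.3	2.3	GGGAAACCC	.........	((.....))
#> flat	short	-1.9	-5.4	-5.4	GGGAAC	......	......
#> hairpin	short	-4.8	-4.4	-4.8	ACGAAGC	((...))	.......

round(to_matrix(tab, "BEST_SCORE", list(hairpin, flat, short)), 1)
#>         flat hairpin short
#> flat    16.5     2.3  -5.4
#> hairpin  2.3    10.9  -4.8
#> short   -5.4    -4.8   6.6

cat(to_dot(build_link_graph(tab, min_link_score = 0)))
#> graph cmlink {
#>   "flat";
#>   "hairpin";
#>   "short";
#>   "flat" -- "hairpin" [label="2.3"];
#> }
```

Thresholding at 0 bits keeps only the genuinely overlapping pair:
`short` has no sequence scoring well in either other model, so it stays
an isolated node — exactly how clan candidates versus unrelated models
separate at scale.

The command-line interface wraps the same operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cmlink", package = "cmlink"))')
$CLI link hairpin.cm flat.cm
$CLI vs-db --query hairpin.cm --db models/ --min-link 10 --top 20
$CLI report dot --models a.cm b.cm c.cm --min-link 0 --out clan.dot
```

See the vignette (`vignettes/link-scores.Rmd`) for the model of the
link computation, the design of the max-min product DP (pending
emissions, Pareto-frontier cells, subtree deletion), and its documented
limitations.

## License

GPL-3.
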