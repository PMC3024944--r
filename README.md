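# taxq

Penalty-score taxonomic assignment of ambiguous sequencing reads.

## The problem

In amplicon-based surveys of microbial communities, short 16S rRNA reads
are classified against a reference taxonomy whose leaves carry known
sequences. A large fraction of reads match several reference species
equally well. Assigning such an *ambiguous* read to the lowest common
ancestor (LCA) of its matches — the standard practice — never misses the
right organism but implicitly claims every species under that ancestor,
inflating false positives; committing to one matched leaf has the opposite
failure. `taxq` is for microbiome researchers who want explicit control
over that trade-off.

## The method

For a read with hit set $M_i$ (the matched leaves), let $T_i$ be the
subtree rooted at the LCA of $M_i$. Assigning the read to a node $j$ of
$T_i$ partitions the leaves of $T_i$ into $TP$ (hits under $j$), $FP$
(non-hits under $j$), $FN$ (hits outside) and $TN$ (non-hits outside), and
the read goes to the node minimizing the penalty score

$$PS_{i,j} = q\,\frac{|FN_{i,j}|}{|TP_{i,j}|} +
            (1-q)\,\frac{|FP_{i,j}|}{|TP_{i,j}|},
  \qquad PS_{i,j}=\infty \text{ when } |TP_{i,j}| = 0 .$$

* `q = 1` recovers the LCA assignment (score 0 at the LCA),
* `q = 0` places the read at a matched leaf (score 0),
* `q = 0.5` is equivalent to maximizing the F-measure,
* intermediate `q` interpolates between recall- and precision-favouring
  assignments.

The optimum is found in `O(|M_i|)` time per read: after a one-off
linear-time preprocessing of the taxonomy (postorder numbering, constant
time LCA queries, subtree leaf counts), only the *relevant* nodes — the hit
leaves and LCAs of pairs of hits, which form the topological restriction
`T_i || M_i` with at most `2|M_i| − 1` nodes — need to be scored.

For validation on data with known source leaves, each assignment becomes a
point in ROC space (with singleton truth sets) and its signed distance to
the diagonal is summed into the per-`q` goodness `G_q`; a truth-free
expected distance `E(D)` (weighting by the fraction of hits under the
candidate node) drives a per-read best-`q` selection rule. A simulator of
ranked taxonomies, tree-correlated reference sequences and error-bearing
reads makes everything testable end to end.

## Worked example

The classic 8-leaf instance: hits `{s1, s5, s6, s7}`, true source `s5`.

```r
library(taxq)

idx <- preprocessTaxonomy(parseTaxonomy(
    "((s1,s2,s3,s4)a,(s5,s6,s7,s8)j)root;"))
m <- HitSet("r1", c("s1","s5","s6","s7"), trueHit = "s5", idx = idx)

assignFast(idx, m, q = 0.5)
#> Assignment of read r1 at q = 0.5
#>   node 11 ( level-1 ), score 0.3333333 , 1 tie(s)
#>   counts: tp 3 fp 1 tn 3 fn 1
```

At `q = 0.5` the read lands on node `j`: its subtree holds three of the
four hits (`tp = 3`) at the cost of one unmatched leaf (`fp = 1`), leaving
one hit outside (`fn = 1`); the score is `(0.5·1 + 0.5·1)/3 = 1/3` — and
for this particular partition the score is 1/3 at *every* `q`. Sweeping the
grid shows the two extremes:

```r
sweepQ(idx, list(m), c(0, 0.5, 1))[, c("q","node","rank","score","n_ties")]
#>     q node    rank     score n_ties
#> 1 0.0   s1 level-2 0.0000000      4
#> 2 0.5    j level-1 0.3333333      1
#> 3 1.0 root    root 0.0000000      1
```

`q = 0` ties all four hit leaves (score 0; the canonical pick is the most
specific node, then smallest postorder), `q = 1` is the LCA. Against the
known truth, the `q = 0.5` choice is a strong ROC point, and the best-`q`
rule picks node `j` via the truth-free expected distance:

```r
truthConfusion(idx, m, "j")[, c("tpr_h","fpr_h","d")]
#>   tpr_h     fpr_h        d
#> 1     1 0.4285714 0.404061

bestQPerRead(idx, m)
#> $node: 11      # node j
#> $q:    0.2
#> $e_d:  0.2272843
```

An end-to-end run on simulated data (taxonomy, reads, matching,
assignment sweep, validation, all written as TSV/FASTA plus a manifest):

```r
res <- runPipeline("out/", simConfig(seed = 17), k = 2)
res$validation    # per-q G_q, mean truth precision / recall
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/taxq` (subcommands `simulate`, `match`, `assign`,
`summarize`, `validate`, `pipeline`).

## Acceptance script

`scripts/acceptance.R` regenerates the package's analytic acceptance
quantities from scratch — it simulates 100 random ranked taxonomies with
random hit sets, runs the assignment machinery on each, and reports the
penalty score of the `q = 1` (LCA) assignment and the expected distance of
the LCA assignment, each asserted constant across instances:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## File formats

* taxonomy: Newick with named internal nodes, or a lineage table
  (`leaf<TAB>domain…species`, or generic `level1..levelK`);
* hits: `read_id<TAB>comma-separated leaf names[<TAB>true_hit]`, or
  12-column BLAST tabular (outfmt 6) with e-value tie grouping;
* reads/references: FASTA;
* all tabular output: UTF-8, LF, tab-separated with a header row.

See the vignette (`vignettes/penalty-score-assignment.Rmd`) for the model,
numerical policy, simulator assumptions and known limitations.
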