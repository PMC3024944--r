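---
title: "Penalty-score taxonomic assignment of ambiguous reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalty-score taxonomic assignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxq)
```

## The problem

Amplicon surveys of microbial communities classify short 16S rRNA reads
against a reference taxonomy whose leaves carry known sequences. Many reads
match several reference leaves equally well (*ambiguous reads*). The common
remedy — assign such a read to the lowest common ancestor (LCA) of its
matches — never loses the correct organism but silently claims every leaf
under that ancestor, which may be an entire order or class: recall is
perfect, precision can be abysmal. Committing to a single matched leaf has
the opposite failure mode. `taxq` implements a single-parameter family of
assignments that interpolates between these extremes.

## The model

Let $T$ be a rooted taxonomy with leaf set $L$, and let a read have hit set
$M_i \subseteq L$ with $|M_i| \ge 2$. Let $T_i$ be the subtree rooted at
the LCA of $M_i$. Assigning the read to a node $j$ of $T_i$ partitions the
leaves of $T_i$: hits under $j$ are true positives, non-hits under $j$
false positives, hits outside $j$ false negatives, non-hits outside $j$
true negatives. The penalty score with weight $q \in [0,1]$ is

$$
PS_{i,j} \;=\; q\,\frac{|FN_{i,j}|}{|TP_{i,j}|}
        \;+\; (1-q)\,\frac{|FP_{i,j}|}{|TP_{i,j}|},
\qquad PS_{i,j} = \infty \text{ if } |TP_{i,j}| = 0,
$$

and the read is assigned to the node(s) minimizing it. Three facts anchor
the interpretation, and all three are verified exactly by the test suite:

* $q = 1$: the LCA has no false negatives, so its score is $0$ — the
  classical LCA assignment.
* $q = 0$: any hit leaf has no false positives, so score $0$ is attained at
  a leaf.
* $q = 0.5$: minimizing $PS$ is equivalent to maximizing the F-measure
  $F = 2|TP|/(|FN| + |FP| + 2|TP|)$ (multiply numerator and denominator
  out; the argmin is invariant under the monotone transformation).

Reads with one hit go to that leaf; reads with no hits are reported
unassigned.

## Computing the optimum

Two independent routes are implemented, and their agreement (together with
a third, whole-tree brute force written only in the tests) is a standing
regression check:

**Naive route** (`assignNaive`). Find the root of $T_i$ bottom-up from the
hit leaves — the first node with $|M_i|$ hit descendants — then one
top-down pass computes $|M_{i,j}|$ and $|L_{i,j}|$ for every node of $T_i$
by summing over children, with $|N_{i,j}| = |L_{i,j}| - |M_{i,j}|$. Time
$O(|T_i|)$ per read.

**Fast route** (`assignFast`). After a one-off preprocessing of $T$ —
left-to-right postorder numbers $post(j)$, the smallest subtree postorder
number $m(j)$ (so that *$j$ properly contains $j'$* is the $O(1)$ test
$m(j) \le m(j') \le post(j') < post(j)$), subtree leaf counts, and an Euler
tour with a sparse table giving $O(1)$ LCA queries — only the *relevant*
nodes need scoring: the hit leaves and LCAs of pairs of hits. If $j$ is not
relevant, the LCA of the hits under $j$ has the same true positives and no
more false positives, so it scores no worse; hence an optimum always sits
at a relevant node. The relevant nodes form the topological restriction
$T_i \| M_i$ (at most $2|M_i| - 1$ nodes), built in $O(|M_i|)$ queries:
sort hits by postorder number, take adjacent-pair LCAs, sort the union by
$(m(j), -post(j))$ so ancestors precede descendants, and recover parent
links with a stack of open ancestors. Subtree leaf counts $|L_j|$ are
precomputed, so every score follows from the bottom-up hit counts.

The fast route reports only relevant minimizers. Non-relevant co-minimizers
can exist (e.g. a unary chain above a relevant optimum at $q=1$); the score
equality, not tie-set equality, is the contract between the two routes, and
the tests assert exactly that (plus tie-set equality between the naive
route and brute force, which score the same node set).

### Numerical policy

Scores are plain doubles. Tie detection uses a relative tolerance of
$10^{-12}$ ($s - s_{\min} \le 10^{-12}\max(1, |s_{\min}|)$); with integer
counts and grid values of $q$ the distinct score values are far apart
relative to this, and the 500-instance brute-force comparison observes
exact agreement. Among tied nodes the *canonical* representative is the one
with fewest subtree leaves (most specific), then smallest postorder number.
This matches the stated $q = 0$ behavior (an optimal assignment at a leaf)
and is deterministic; the full tie set is always available in
`bestNodes()`, and `n_ties` is reported in sweep output, because how
multi-way ties should be tallied in rank distributions is ultimately a
reporting policy, not part of the model.

## Validation in ROC space

For simulated reads the source leaf $H_i$ is known. With the singleton
truth set $\{H_i\}$, an assignment to $j$ has $TPR_H \in \{0, 1\}$
(is $H_i$ under $j$?) and $FPR_H = (|L_{i,j}| - TPR_H)/(|L_i| - 1)$. Each
read is the point $(FPR_H, TPR_H)$ in ROC space and its signed distance to
the diagonal is

$$
D = \tfrac{\sqrt2}{2}\,\frac{|L_i| - |L_{i,j}|}{|L_i| - 1}
\;\;\text{(truth inside)},\qquad
D = -\tfrac{\sqrt2}{2}\,\frac{|L_i| - |L_{i,j}| - 1}{|L_i| - 1}
\;\;\text{(truth outside)}.
$$

One deliberate quirk: the negative branch above is **not** the geometric
distance of $(FPR_H, 0)$ to the diagonal (which would be
$\tfrac{\sqrt2}{2} FPR_H$). We implement the stated formulas as printed and
do not "correct" them; the discrepancy only affects the magnitude, not the
sign, of penalties for truth-excluding assignments, and all downstream
comparisons use the same convention consistently. A corollary worth noting:
with the printed formula, a truth-excluding assignment to a node with
$|L_{i,j}| = |L_i| - 1$ scores $0$, not a negative value.

Summed over reads at a fixed $q$, $G_q = \sum_i D_i$ measures how well that
$q$ performs; LCA assignments contribute $0$ (both rates are 1 — the point
sits on the diagonal), so $G_1 = 0$ always, and $G_q$ typically rises from
negative values at $q = 0$ to a positive maximum in the upper-middle of the
grid before returning to $0$.

Without ground truth, the probability that the truth sits under $j$ —
*assuming it is among the hits* — is $p = |M_{i,j}|/|M_i|$, giving the
expected distance $E(D_{i,j}) = p\,D_{\text{in}} + (1-p)\,D_{\text{out}}$.
The per-read best-$q$ rule evaluates $E(D)$ at the canonical node for each
grid $q$ and keeps the maximizer if positive, otherwise falls back to the
LCA ($E(D) = 0$ there, exactly). On ties the smallest $q$ wins,
deterministically. The assumption $H_i \in M_i$ is the known blind spot:
when the matcher misses the truth entirely, $p$ overstates the chance of
containing it.

Per-read truth precision is $\mathbf{1}[H_i \text{ under } j]/|L_{i,j}|$
and recall is $\mathbf{1}[H_i \text{ under } j]$; dataset values are
unweighted means over ambiguous, non-degenerate reads. The aggregation is a
package choice (means rather than sums) — it is scale-free, and any fixed
per-read aggregation preserves the structural identity that at $q = 0$
every assignment sits at one leaf, forcing precision $=$ recall exactly.
Reads with $|M_i| \le 1$ or $|L_i| = 1$ are excluded from all validation
sums (the distances are undefined or degenerate) and counted separately.

## The synthetic world

The simulator exists so the whole method is testable end to end with no
external data, and its defaults are fixed a priori:

| parameter | default | why |
|---|---|---|
| leaves / ranks | 200 / 7 | seven canonical ranks; desk-scale stand-in for a reference taxonomy of thousands of type cultures |
| reference length | 1,500 bp | full-length 16S rRNA |
| per-level substitution rate | 0.01 /site/level | sister species ~98% identical, deepest splits ~86% — the 16S range; this is the dial that makes nearby leaves confusable |
| read length / count | 100 bp / 2,000 | short-read regime where ambiguity is worst |
| substitution error rate | 0.005 /base | 454-like substitution component |
| homopolymer indel rate | 0.02 /run | the dominant 454 error mode, one ±1 bp event per run at most |
| min length fraction | 0.75 | reads shorter than 75% of expected length are discarded |

Sequences evolve down the tree by independent per-site substitution — no
rate heterogeneity across sites, no conserved/hypervariable structure, no
chimeras, no clone-size distribution and no quality scores. Reads are
windows of a uniformly chosen leaf with substitution and homopolymer
errors; region-restricted sampling (`simulateRegionReads`) emulates
hypervariable-region amplicons by constraining the source window. A green
test on this world therefore establishes the *algorithmic* claims (score
equivalences, exact zeros, monotone tendencies) — not that real 16S data
will show the same ambiguity profile; uniform-rate divergence makes
windows more uniformly informative than real amplicons.

Determinism: the taxonomy draw seeds the RNG with `seed`, the read draw
with `seed + 1`, so identical configurations give byte-identical FASTA and
truth tables (asserted in the tests).

### Two measured deviations worth knowing about

* **Ambiguity versus error rate.** With a fixed mismatch budget $k$,
  raising the sequencing error rate *shrinks* hit sets (reads drift out of
  the $k$-ball of every reference): mean $|M_i|$ fell from 6.8 to 4.2 as
  the substitution error rate rose from 0 to 2% in this world. The tests
  assert this direction. (Allowing a larger $k$ — a different dial — is
  what increases ambiguity.)
* **Precision at the bottom of the grid.** At $q = 0$ the optimum is an
  arbitrary hit leaf, so mean precision is about $E[1/|M_i|]$. One grid
  step up ($q = 0.1$), assigned nodes are still small but contain the truth
  far more often, and at 200-leaf scale mean precision *rises*
  significantly (+0.028 across five seeds) before declining monotonically
  over the rest of the grid. The corresponding acceptance check is left
  failing on that single step rather than widened: it is a real property of
  this world at this scale, not noise.

## Matching

The built-in matcher declares leaf $\ell$ a hit when some window of
$\ell$'s reference of exactly read length lies within Hamming distance $k$
(default 2) of the read — no indels, forward strand by default
(`revcomp = TRUE` also scans the reverse complement; amplicon reads are
normally orientation-normalized). It is a deliberately naive $O(\text{total
reference length} \times \text{read length})$ stand-in for a production
mapper, implemented via `Biostrings::matchPattern` over the concatenated
references with matches filtered to windows lying inside a single
reference; multiple matching windows in one reference count once, and `N`
in a read mismatches every (plain ACGT) reference base. The BLAST tabular
reader offers the alternative route used on real data: per query, all
subjects tied at the minimum e-value, provided it is at most the cutoff
(default $10^{-3}$).

## Degenerate inputs and edge policy

* Empty taxonomy, duplicate leaf names, ragged lineage rows: hard errors.
* Hit names not in the taxonomy: hard error naming the row; duplicate hits
  within a read: deduplicated with a warning.
* $|M_i| = 0$: retained, reported unassigned; $|M_i| = 1$: assigned to the
  leaf with $tp = 1$, $fp = fn = tn = 0$ and score 0.
* Candidate nodes outside $T_i$ in validation functions: rejected (their
  penalty score is $\infty$ and the ROC record is undefined).
* Newick trees without rank metadata get `level-k` ranks by depth; the
  seven canonical names are applied only when every leaf sits at depth 7.
  Non-uniform leaf depths are supported throughout; rank reporting is then
  by depth label.

## Known limitations

The LCA structure assumes the reference taxonomy is a tree with unique leaf
names; there is no support for NCBI-style taxonomy dumps, polytomy
resolution or tree editing. The matcher is not quality-aware and does not
model alignment indels (the homopolymer indels the simulator introduces are
precisely what a Hamming matcher struggles with — which is faithful to the
regime the method was designed for). The expected-distance rule inherits
the $H_i \in M_i$ assumption discussed above.
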