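---
title: "Estimating species trees by maximizing triplet consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating species trees by maximizing triplet consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletree)
```

## The model and the optimization criterion

Gene trees evolve *within* the species tree. Under the multi-species
coalescent (MSC), lineages entering an ancestral population may fail to
coalesce before the next speciation event further rootward; when they do,
the gene tree can differ topologically from the species tree (incomplete
lineage sorting, ILS). The shorter an internal branch of the species tree
— measured in coalescent units, generations divided by effective
population size — the more ILS it generates.

For any three species \(\{a,b,c\}\), a rooted tree induces one of three
rooted triplets; we write \(a|bc\) when \(b\) and \(c\) are siblings. If
the species tree separates \(a\) from the cherry \(\{b,c\}\) by an
internal branch of length \(t\), the probability a true gene tree shows
the matching triplet is \(1-\tfrac23 e^{-t}\), and each of the two
alternatives has probability \(\tfrac13 e^{-t}\). Two consequences drive
this package:

* the species-tree triplet is always the strictly most probable gene-tree
  triplet (there is no rooted three-taxon anomaly zone), and
* the two minority topologies are exchangeable.

Hence the estimator: given \(k\) rooted binary gene trees \(\mathcal G\)
on \(n\) taxa, return the rooted binary tree \(S\) maximizing the
triplet-consistency score
\[
TC(S,\mathcal G)=\sum_{gt\in\mathcal G}\ \sum_{|r|=3}
\mathbf 1\left[S|r = gt|r\right].
\]
By the law of large numbers the empirical triplet frequencies converge to
their MSC probabilities, the dominant triplet of every 3-subset
eventually matches the species tree, and the maximizer converges to the
true species tree: the estimator is statistically consistent. The test
suite verifies this empirically (1000 simulated true gene trees from a
15-taxon caterpillar with 0.5-coalescent-unit internal branches are
enough for exact recovery).

## Counting triplets without enumerating them

Every internal node \(u\) of a rooted binary tree splits the taxa below
it into the leaf sets of its two children — the *subtree-bipartition*
(SBP) \(X_1|X_2\). A triplet maps to exactly one SBP: the one at the LCA
of its three taxa, cherry on one side, outlier on the other. Three facts
make the score computable in closed form:

1. an SBP with side sizes \(n_1,n_2\) carries
   \(\binom{n_1}{2}n_2+\binom{n_2}{2}n_1 = n_1n_2(n_1+n_2-2)/2\)
   triplets (`triplet_count()`);
2. the triplets shared by SBPs \(x=X_1|X_2\) and \(y=Y_1|Y_2\) are those
   carried by the two intersection bipartitions
   \((X_1\cap Y_1\,|\,X_2\cap Y_2)\) and \((X_1\cap Y_2\,|\,X_2\cap Y_1)\),
   each shared triplet counted exactly once (`shared_triplets()`);
3. summing (2) against the multiset of gene-tree SBPs, with
   multiplicities, gives the number of gene-tree triplets agreeing with
   any candidate SBP (`tc_score_sbp()`), and summing that over the
   \(n-1\) SBPs of a species tree gives \(TC\) (`tc_score()`).

The root's SBP is included everywhere: triplets whose LCA is the root map
there, and without it the conservation law — the per-SBP counts of any
tree sum to \(\binom n3\) — would fail. That conservation law, and exact
agreement between `tc_score()` and a brute-force LCA-based oracle
(`triplet_oracle()`), are property-tested over random instances.

Scoring keeps the full multiset (the score definition sums over every
gene tree); only the search space uses the distinct set. Deduplicating
identical gene trees first would be mathematically identical — we keep
the straightforward multiset accounting.

## The dynamic program

\(V(A)\), the best score achievable by a rooted subtree on clade
\(A\subseteq\mathcal X\), satisfies \(V(A)=0\) for singletons and
\[
V(A)=\max_{A'|A\setminus A'}\
V(A')+V(A\setminus A')+TC_{\mathcal G}(A'\,|\,A\setminus A').
\]
Clusters are processed in increasing size, so every value on the right is
final when read; backtracking from \(\mathcal X\) assembles the tree.

* **Constrained mode** (default): candidate splits are exactly the
  distinct SBPs observed in the gene trees, indexed by their union
  clade. Both sides of a gene-tree SBP are themselves SBP unions or
  singletons within the same tree, so the recursion never reaches a
  cluster without candidates as long as the gene trees are complete;
  incomplete gene trees are rejected at input. No ASTRAL-II-style
  search-space augmentation is performed — the constrained space is
  strictly the gene-tree SBPs.
* **Exact mode**: all \(2^{|A|-1}-1\) splits of every cluster, generated
  lazily from integer masks. This evaluates \(\Theta(3^n)\) splits and is
  refused above `exact_cap` (default 15 taxa, raisable to a hard ceiling
  of 22 where the \(2^n\) table still fits comfortably in memory). In
  this pure-R implementation exact mode is comfortable to about 10–12
  taxa; the cap is a guard against accidental exponential runs, not a
  throughput promise. Exact-mode optimality is verified in the tests
  against explicit enumeration of all rooted binary topologies up to
  \(n=7\) (10,395 topologies).

Per-SBP scores are computed once and cached (constrained mode), keeping
the overall work at \(O(n^2 k\,|\mathcal{SBP}|^2)\)-flavoured scaling;
clades are fixed-width bitsets of 16-bit words, so the pairwise
intersection counts vectorize across the whole pool.

**Tie-breaking.** The argmax over splits can tie. Candidates are ordered
canonically — by the bitset of the split's left clade, the side holding
the lowest-indexed taxon — and the first strict maximum wins. Taxon
indices themselves come from sorting labels lexicographically, never from
input order. Identical input therefore yields byte-identical output, at
the cost that the choice among exactly tied optima is an arbitrary (but
documented and stable) convention.

## The simulator: what it emulates and what it does not

`simulate_gene_trees()` draws true gene-tree topologies under the plain
MSC: one haploid lineage per species enters at each leaf; within a branch
of length \(t\) carrying \(j\) lineages, waiting times are exponential
with rate \(j(j-1)/2\) and a uniformly random pair merges at each event;
survivors pass rootward; above the root coalescence runs to completion.
Branch lengths are already in coalescent units, so there is no separate
population-size dial. Calibration against the closed-form three-taxon
probabilities above is part of the acceptance suite (50,000 genes per
branch length, 3 binomial standard errors; minority-topology
exchangeability is checked with a pooled chi-square test at
\(\alpha=0.001\) across the four branch lengths, a band chosen once to
keep the aggregate false-alarm rate of four Monte-Carlo comparisons
around a tenth of a percent).

`make_model_tree()` supplies caterpillar, balanced, and random
equal-rates (Yule) topologies with every internal branch set to
`internal_bl * rescale`; halving/doubling `rescale` is the conventional
way to sweep ILS levels. Terminal branches are fixed at 1 coalescent unit
— with one sampled lineage per species they cannot host coalescences, so
their length is immaterial. Defaults used in the acceptance experiment
(15-taxon caterpillar, 0.5 coalescent units, 1000 genes) mirror the
published true-gene-tree condition at which triplet-based estimation
attains RF = 0; the original generator's full parameterization is
unpublished, so this is a surrogate at a stated, fixed operating point.

What a green simulation test does **not** establish: robustness to
gene-tree estimation error (sequences are never simulated), missing
taxa, gene duplication/loss or horizontal transfer, or behaviour on
unrooted/multifurcating inputs — all are rejected or out of scope by
design.

## Numerical and degenerate-input choices

* Scores are exact integer counts held in doubles (exact far beyond any
  realistic \(k\binom n3\)); no floating-point tolerance is ever applied
  to a score comparison.
* Clade bitsets use 16-bit words: every `bitwAnd` stays within positive
  `int` range and popcounts are one table lookup; nothing limits \(n\)
  except exact-mode's cap.
* A trifurcating root (or any multifurcation) is a hard error — treating
  it as unrooted would silently change the criterion, since triplets are
  root-dependent.
* Duplicate labels, taxon-set mismatches between gene trees, and empty
  inputs fail fast with the offending line number or the symmetric
  difference of the label sets.
* Unrooted RF is undefined at \(n=3\); the error points to the rooted
  clade-based variant (`rooted = TRUE`, normalized by \(2(n-2)\)), which
  exists because the estimator's output is rooted while most comparison
  methods print unrooted trees. The acceptance experiment reports the
  unrooted convention, where perfect recovery is 0 under both.

## Known limitations

Constrained mode only guarantees the optimum *within* the gene-tree SBP
space; when the true root bipartition never appears in any gene tree the
constrained optimum can differ from the global one (the fitted object
records `mode` so users know which guarantee applies). Branch lengths are
not estimated on the output tree. The pure-R exact mode is exponential
and practical only for small \(n\); the constrained DP handles hundreds
of genes and tens of taxa in seconds but has not been tuned for
thousand-taxon inputs.
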