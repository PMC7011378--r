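# tripletree

Species-tree estimation from gene trees by maximizing rooted-triplet
consistency, with a multi-species coalescent (MSC) gene-tree simulator and
tree-comparison metrics.

## The problem

Different loci sampled across a genome routinely disagree about the
species phylogeny: under the multi-species coalescent, incomplete lineage
sorting (ILS) makes individual gene trees differ from the species tree,
and the most probable gene tree can even differ from the species tree
topology (the anomaly zone). Rooted three-taxon trees have no anomaly
zone — for every set of three species, the triplet topology induced by
the species tree is the single most probable gene-tree triplet. Summary
methods that maximize triplet agreement therefore converge on the true
species tree as the number of true gene trees grows.

`tripletree` estimates the rooted species tree *S* on taxa 𝒳 from k
rooted, binary, single-copy gene trees 𝒢 by maximizing the
triplet-consistency score

TC(S, 𝒢) = Σ_{gt ∈ 𝒢} Σ_{r ∈ 3-subsets of 𝒳} 1[ S|r = gt|r ],

the number of (gene tree, 3-subset) pairs on which the induced rooted
triplets agree. Enumerating the 3·C(n,3) triplets is avoided entirely:
every triplet maps to exactly one *subtree-bipartition* (SBP) — the split
X₁|X₂ that an internal node induces between the leaf sets of its two
child subtrees — and the number of triplets an SBP carries has the closed
form n₁n₂(n₁+n₂−2)/2. Triplets shared by two SBPs x = X₁|X₂ and
y = Y₁|Y₂ are counted by applying that formula to the intersections
(X₁∩Y₁ | X₂∩Y₂) and (X₁∩Y₂ | X₂∩Y₁). The optimal tree is found by a
dynamic program over clades,

V(A) = max over splits A′|A−A′ of { V(A′) + V(A−A′) + TC_𝒢(A′|A−A′) },

run either over the splits observed in the gene trees (**constrained**
mode, polynomial time, the default) or over all 2^(|A|−1)−1 splits of
every clade (**exact** mode, exponential, guarded by a taxon cap).
Both modes are statistically consistent estimators under the MSC when
given true gene trees.

## Worked example

```r
library(tripletree)

# three gene trees, two supporting bc|a and one supporting ac|b
g <- gene_trees(c("((b,c),a);", "((b,c),a);", "((a,c),b);"))
fit <- tripletree(g)
fit
#> Maximum triplet consistency species tree (constrained mode)
#>   taxa: n = 3   gene trees: k = 3   distinct SBPs: 4
#>   TC_SCORE=2 of 3 (0.6667 of triplets)
#>   (a,(b,c));
```

The majority triplet bc|a wins; it agrees with 2 of the 3 gene trees, so
the score is 2 out of the maximum possible k·C(n,3) = 3.

End-to-end consistency check by simulation — 1000 true gene trees from a
15-taxon caterpillar species tree whose internal branches are all 0.5
coalescent units (substantial ILS: only ~60% of genes recover any given
species-tree triplet around a short branch):

```r
sp    <- make_model_tree("caterpillar", n = 15, internal_bl = 0.5)
genes <- simulate_gene_trees(sp, n_genes = 1000, seed = 15)
fit   <- tripletree(genes)
fit
#> Maximum triplet consistency species tree (constrained mode)
#>   taxa: n = 15   gene trees: k = 1000   distinct SBPs: 1753
#>   TC_SCORE=380136 of 455000 (0.8355 of triplets)
#>   ((((((((((((((t01,t02),t03),t04),t05),t06),t07),t08),t09),t10),t11),t12),t13),t14),t15);
rf_rate(fit$tree, sp)
#> [1] 0
```

Despite 1753 distinct subtree-bipartitions circulating in the discordant
gene trees, the estimator recovers the model tree exactly (normalized
Robinson-Foulds distance 0); only ~84% of gene-tree triplets agree with
it, which is what the coalescent predicts, not an error.

## Command line

A thin Rscript front end ships at `inst/cli/tripletree.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","tripletree.R",package="tripletree"))')
Rscript $CLI simulate --shape caterpillar --n 15 --internal-bl 0.5 \
                      --n-genes 1000 --seed 15 --out genes.nwk
Rscript $CLI infer    --genes genes.nwk --out species.nwk   # logs TC_SCORE=...
Rscript $CLI score    --species species.nwk --genes genes.nwk
Rscript $CLI rf       --tree1 species.nwk --tree2 genes.nwk.species.nwk
```

Exit codes: 0 success, 2 validation error, 3 capability refusal (exact
mode above the taxon cap), 1 unexpected.

## Acceptance script

`scripts/acceptance.R` re-runs the simulation experiment above from
scratch — builds the 15-taxon caterpillar model tree (internal branches
0.5 coalescent units), simulates 1000 true gene trees under the MSC with
the given seed, infers the species tree in constrained mode, and measures
the normalized RF distance to the model tree — and writes the result as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Gene trees must be rooted, binary, and complete (same taxon set in every
tree); unrooted or multifurcating inputs are rejected, not silently
re-interpreted, because the triplet criterion is root-dependent. Branch
lengths on input gene trees are ignored (the estimator is topology-only);
only the simulator consumes branch lengths, which are in coalescent
units. The output tree is a rooted topology without branch-length
estimates.
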