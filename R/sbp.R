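# Subtree-bipartitions (SBPs) and the triplet-counting formulas.
#
# Every internal node u of a rooted binary tree splits the taxa of its
# subtree into the leaf sets of its two children: the subtree-bipartition
# X1|X2 at u. A rooted triplet maps to exactly one SBP — the one at the
# LCA of its three taxa, with the cherry pair on one side and the outlier
# on the other — which is what lets triplet agreement be counted without
# ever enumerating the 3*C(n,3) triplets.
#
# SBPs are stored canonically: `left` is the side containing the lowest
# taxon bit of the union, so equality and ordering are well defined.

# tip bitset for every node of a phylo; rows 1..(n+Nnode), nw columns
node_masks <- function(phy, taxa) {
  n <- length(phy$tip.label)
  nw <- n_words(length(taxa))
  M <- matrix(0L, n + phy$Nnode, nw)
  pos <- match(phy$tip.label, taxa) - 1L
  for (i in seq_len(n)) M[i, ] <- bits_from_positions(pos[i], nw)
  e <- reorder_postorder(phy)$edge
  for (i in seq_len(nrow(e))) {
    M[e[i, 1L], ] <- bitwOr(M[e[i, 1L], ], M[e[i, 2L], ])
  }
  M
}

#' Extract subtree-bipartitions from a rooted binary tree
#'
#' Returns one SBP per internal node (the root included: triplets whose
#' LCA is the root map there, and dropping it would break the
#' every-triplet-maps-once conservation law). Clades are bitsets over the
#' canonical (sorted) taxon index.
#'
#' @param tree A rooted binary `phylo`.
#' @param taxa Character vector of taxon labels defining bit positions;
#'   defaults to the tree's own sorted labels.
#' @return A list with integer matrices `left` and `right` (one SBP per
#'   row, 16-bit words per column), `n`, `nw` and `taxa`.
#' @examples
#' s <- extract_sbps(parse_newick("((a,b),c);"))
#' nrow(s$left)  # n - 1 = 2
#' @export
extract_sbps <- function(tree, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  validate_rooted_binary(tree, taxa)
  n <- length(taxa)
  nw <- n_words(n)
  M <- node_masks(tree, taxa)
  kids <- vector("list", n + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  ints <- (n + 1L):(n + tree$Nnode)
  L <- matrix(0L, length(ints), nw)
  R <- matrix(0L, length(ints), nw)
  for (j in seq_along(ints)) {
    ch <- kids[[ints[j]]]
    a <- M[ch[1L], ]
    b <- M[ch[2L], ]
    if (bits_has_lowest_of(a, bitwOr(a, b))) {
      L[j, ] <- a; R[j, ] <- b
    } else {
      L[j, ] <- b; R[j, ] <- a
    }
  }
  list(left = L, right = R, n = n, nw = nw, taxa = taxa)
}

#' Pool subtree-bipartitions over a gene-tree set
#'
#' Multiset union of [extract_sbps()] over all gene trees. Multiplicities
#' are kept because the triplet-consistency score sums over every gene
#' tree; the distinct SBPs double as the constrained search space of the
#' dynamic program.
#'
#' @param genes A [gene_trees()] object.
#' @return A list of class `sbp_pool`: matrices `left`, `right` (distinct
#'   SBPs, canonical order), integer `count` (multiplicities), `n`, `nw`,
#'   `k`, `taxa`, and `total` (sum of counts, `k * (n - 1)` for complete
#'   binary gene trees).
#' @export
pool_sbps <- function(genes) {
  stopifnot(inherits(genes, "gene_trees"))
  per <- lapply(genes$trees, extract_sbps, taxa = genes$taxa)
  L <- do.call(rbind, lapply(per, `[[`, "left"))
  R <- do.call(rbind, lapply(per, `[[`, "right"))
  key <- paste(apply(L, 1L, bits_key), apply(R, 1L, bits_key))
  f <- factor(key)
  first <- match(levels(f), key)
  structure(
    list(left = L[first, , drop = FALSE], right = R[first, , drop = FALSE],
         count = tabulate(f), n = genes$n, nw = n_words(genes$n),
         k = genes$k, taxa = genes$taxa, total = nrow(L)),
    class = "sbp_pool"
  )
}

#' Number of triplets mapped to a subtree-bipartition
#'
#' A triplet maps to the SBP X1|X2 when its cherry lies entirely in one
#' side and its outlier in the other, so with side sizes `n1` and `n2`
#' the count is `C(n1,2)*n2 + C(n2,2)*n1 = n1*n2*(n1+n2-2)/2`.
#'
#' @param n1,n2 Non-negative side sizes (vectorized).
#' @return Integer-valued count(s).
#' @examples
#' triplet_count(3, 2)  # 9
#' @export
triplet_count <- function(n1, n2) {
  if (any(n1 < 0) || any(n2 < 0)) stop("side sizes must be non-negative")
  n1 * n2 * (n1 + n2 - 2) / 2
}

#' Triplets mapped to both of two subtree-bipartitions
#'
#' For x = X1|X2 and y = Y1|Y2 (over one taxon index; unions need not be
#' equal or nested) the shared triplets are those mapped to one of the
#' two intersection bipartitions (X1&Y1 | X2&Y2) and (X1&Y2 | X2&Y1);
#' each shared triplet is counted by exactly one of the two, so the count
#' is triplet_count on both, summed. Symmetric in x and y.
#'
#' @param x,y SBPs as lists with bitset vectors `left` and `right`
#'   (e.g. one row of an [extract_sbps()] result).
#' @return Integer-valued count.
#' @export
shared_triplets <- function(x, y) {
  triplet_count(bits_popcount(bitwAnd(x$left, y$left)),
                bits_popcount(bitwAnd(x$right, y$right))) +
  triplet_count(bits_popcount(bitwAnd(x$left, y$right)),
                bits_popcount(bitwAnd(x$right, y$left)))
}

# score of one candidate SBP (word vectors xl, xr) against the pool:
# sum over gene SBPs y of count(y) * shared_triplets(x, y), vectorized
# across the pool's rows
sbp_pool_score <- function(xl, xr, pool) {
  a11 <- rows_and_popcount(pool$left,  xl)
  a22 <- rows_and_popcount(pool$right, xr)
  a12 <- rows_and_popcount(pool$left,  xr)
  a21 <- rows_and_popcount(pool$right, xl)
  sum(pool$count * (triplet_count(a11, a22) + triplet_count(a12, a21)))
}

#' Triplet-consistency score of a subtree-bipartition against gene trees
#'
#' Total number of (gene tree, triplet) pairs in which the triplet maps
#' to `x` and agrees with that gene tree: the multiplicity-weighted sum
#' of [shared_triplets()] between `x` and every gene-tree SBP.
#'
#' @param x An SBP: list with bitset vectors `left`, `right`.
#' @param pool An [pool_sbps()] result on the same taxon index.
#' @return Integer-valued score.
#' @export
tc_score_sbp <- function(x, pool) {
  stopifnot(inherits(pool, "sbp_pool"))
  sbp_pool_score(x$left, x$right, pool)
}

#' Triplet-consistency score of a species tree
#'
#' The count, over gene trees and 3-taxon subsets, of induced rooted
#' triplets shared between `species` and the gene trees. Computed by
#' summing [tc_score_sbp()] over the n-1 SBPs of the species tree —
#' never by enumerating triplets. Bounded by `k * choose(n, 3)`, attained
#' when every gene tree equals the species tree.
#'
#' @param species A rooted binary `phylo` on the gene trees' taxon set.
#' @param genes A [gene_trees()] object, or an `sbp_pool` already built
#'   from one.
#' @return Integer-valued score.
#' @examples
#' g <- gene_trees(c("((b,c),a);", "((b,c),a);", "((a,c),b);"))
#' tc_score(parse_newick("((b,c),a);"), g)  # 2
#' @export
tc_score <- function(species, genes) {
  pool <- if (inherits(genes, "sbp_pool")) genes else pool_sbps(genes)
  validate_rooted_binary(species, pool$taxa)
  s <- extract_sbps(species, pool$taxa)
  tot <- 0
  for (j in seq_len(nrow(s$left))) {
    tot <- tot + sbp_pool_score(s$left[j, ], s$right[j, ], pool)
  }
  tot
}
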