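# Tree-comparison metrics and the brute-force triplet oracle.
#
# The oracle restricts a tree to three leaves by comparing LCA depths
# (never via bitsets or SBP counting), so it is an independent ground
# truth for the closed-form triplet-consistency score.

# root-to-leaf node paths for every tip label; list keyed by label
tip_paths <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  parent <- integer(nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  paths <- vector("list", n)
  for (i in seq_len(n)) {
    p <- i
    v <- i
    while (v != root) {
      v <- parent[v]
      p <- c(p, v)
    }
    paths[[i]] <- rev(p)        # root first; LCA depth = common prefix length
  }
  names(paths) <- phy$tip.label
  paths
}

lca_depth <- function(pa, pb) {
  m <- min(length(pa), length(pb))
  eq <- pa[seq_len(m)] == pb[seq_len(m)]
  if (all(eq)) m else which.min(eq) - 1L
}

#' Rooted triplet induced on three taxa
#'
#' Restricting a rooted binary tree to three leaves gives one of the
#' three rooted triplet topologies. The cherry is the pair whose LCA is
#' strictly deeper than the LCA of all three; the remaining taxon is the
#' outlier.
#'
#' @param tree A rooted binary `phylo`.
#' @param taxa Character vector of exactly three leaf labels.
#' @return The outlier label (so `a` means the triplet `a|bc`).
#' @examples
#' induced_triplet(parse_newick("(((a,b),c),d);"), c("a", "c", "d"))  # "d"
#' @export
induced_triplet <- function(tree, taxa) {
  stopifnot(length(taxa) == 3L)
  if (!all(taxa %in% tree$tip.label)) {
    stop("taxon not in tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "), call. = FALSE)
  }
  p <- tip_paths(tree)[taxa]
  d12 <- lca_depth(p[[1L]], p[[2L]])
  d13 <- lca_depth(p[[1L]], p[[3L]])
  d23 <- lca_depth(p[[2L]], p[[3L]])
  taxa[which.max(c(d23, d13, d12))]  # deepest pair's LCA -> other taxon is outlier
}

#' Brute-force triplet-consistency score
#'
#' For every 3-taxon subset and every gene tree, counts 1 when the
#' induced triplets of the species tree and the gene tree match. This is
#' the O(k n^3) definition of the triplet-consistency score, used as the
#' independent oracle for [tc_score()].
#'
#' @param species A rooted binary `phylo`.
#' @param genes A [gene_trees()] object on the same taxon set.
#' @return Integer-valued score.
#' @export
triplet_oracle <- function(species, genes) {
  stopifnot(inherits(genes, "gene_trees"))
  validate_rooted_binary(species, genes$taxa)
  taxa <- genes$taxa
  subsets <- utils::combn(taxa, 3L)
  sp_paths <- tip_paths(species)
  outlier_of <- function(paths, tri) {
    p <- paths[tri]
    d12 <- lca_depth(p[[1L]], p[[2L]])
    d13 <- lca_depth(p[[1L]], p[[3L]])
    d23 <- lca_depth(p[[2L]], p[[3L]])
    tri[which.max(c(d23, d13, d12))]
  }
  sp_out <- apply(subsets, 2L, outlier_of, paths = sp_paths)
  total <- 0L
  for (gt in genes$trees) {
    gp <- tip_paths(gt)
    g_out <- apply(subsets, 2L, outlier_of, paths = gp)
    total <- total + sum(g_out == sp_out)
  }
  total
}

# clade label-sets of a rooted tree, as sorted keys; non-trivial only
# (size in [2, n-1])
rooted_clade_keys <- function(phy) {
  n <- length(phy$tip.label)
  taxa <- sort(phy$tip.label)
  M <- node_masks(phy, taxa)
  ints <- (n + 1L):(n + phy$Nnode)
  keys <- apply(M[ints, , drop = FALSE], 1L, bits_key)
  sizes <- vapply(ints, function(i) bits_popcount(M[i, ]), 0)
  keys[sizes >= 2 & sizes <= n - 1]
}

#' Normalized Robinson-Foulds distance
#'
#' Default convention treats both trees as unrooted: the symmetric
#' difference of their non-trivial bipartitions, normalized by
#' `2 * (n - 3)`, so identical topologies score 0 and trees sharing no
#' non-trivial split score 1. With `rooted = TRUE` the comparison is over
#' rooted clades instead, normalized by `2 * (n - 2)` — appropriate when
#' root placement is part of the hypothesis being compared.
#'
#' @param t1,t2 Binary `phylo` trees on the same taxon set.
#' @param rooted Use the clade-based rooted convention.
#' @return A fraction in `[0, 1]`.
#' @examples
#' rf_rate(parse_newick("((a,b),(c,d));"), parse_newick("((a,c),(b,d));"))
#' @export
rf_rate <- function(t1, t2, rooted = FALSE) {
  validate_rooted_binary(t1)
  validate_rooted_binary(t2, sort(t1$tip.label))
  n <- length(t1$tip.label)
  if (rooted) {
    k1 <- rooted_clade_keys(t1)
    k2 <- rooted_clade_keys(t2)
    d <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
    return(d / (2 * (n - 2)))
  }
  if (n < 4L) {
    stop("unrooted RF undefined for n < 4; use rooted = TRUE", call. = FALSE)
  }
  d <- as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)))
  d / (2 * (n - 3))
}
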