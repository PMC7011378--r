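# Multi-species coalescent gene-tree simulator.
#
# One haploid lineage enters at each species-tree leaf. Inside a branch
# of length t (coalescent units) carrying j lineages, waiting times to
# the next coalescence are Exp(j*(j-1)/2); an event within the remaining
# branch length merges a uniformly random pair. Surviving lineages pass
# to the parent branch; above the root coalescence continues unbounded
# until a single lineage remains. Branch lengths are already in
# coalescent units, so there is no separate population-size parameter;
# gene trees are returned topology-only (the estimator ignores lengths).

# species tree preprocessing shared by all genes of a run
msc_prep <- function(species_tree) {
  phy <- species_tree
  validate_rooted_binary(phy)
  n <- length(phy$tip.label)
  if (n < 3L) stop("species tree must have n >= 3 taxa", call. = FALSE)
  if (is.null(phy$edge.length)) {
    stop("species tree must carry branch lengths in coalescent units",
         call. = FALSE)
  }
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length <= 0)) {
    stop("all branch lengths must be positive and finite", call. = FALSE)
  }
  e <- reorder_postorder(phy)
  elen <- numeric(n + phy$Nnode)           # length of branch above each node
  elen[e$edge[, 2L]] <- e$edge.length
  kids <- vector("list", n + phy$Nnode)
  for (i in seq_len(nrow(e$edge))) {
    p <- e$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], e$edge[i, 2L])
  }
  root <- setdiff(e$edge[, 1L], e$edge[, 2L])
  list(n = n, order = unique(e$edge[, 1L]), kids = kids, elen = elen,
       root = root, labels = phy$tip.label)
}

# one gene tree; returns a phylo on prep$labels
msc_one <- function(prep) {
  n <- prep$n
  merges <- matrix(0L, n - 1L, 2L)
  mcount <- 0L
  lineages <- vector("list", length(prep$elen))
  for (i in seq_len(n)) lineages[[i]] <- i
  coalesce <- function(set, tlim) {
    j <- length(set)
    tacc <- 0
    while (j >= 2L) {
      tacc <- tacc + stats::rexp(1L, j * (j - 1L) / 2)
      if (tacc > tlim) break
      pair <- sample.int(j, 2L)
      mcount <<- mcount + 1L
      merges[mcount, ] <<- set[pair]
      set <- c(set[-pair], n + mcount)
      j <- j - 1L
    }
    set
  }
  # leaf branches first (a single lineage cannot coalesce, but keep general)
  for (i in seq_len(n)) {
    lineages[[i]] <- coalesce(lineages[[i]], prep$elen[i])
  }
  for (v in prep$order) {
    set <- unlist(lineages[prep$kids[[v]]])
    tlim <- if (v == prep$root) Inf else prep$elen[v]
    lineages[[v]] <- coalesce(set, tlim)
  }
  # merge record -> phylo; root must get node number n+1, so internal
  # ids are reversed (last merge made the root)
  relab <- function(x) ifelse(x <= n, x, 3L * n - x)
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  for (j in seq_len(n - 1L)) {
    p <- relab(n + j)
    edge[2L * j - 1L, ] <- c(p, relab(merges[j, 1L]))
    edge[2L * j, ] <- c(p, relab(merges[j, 2L]))
  }
  phy <- structure(list(edge = edge, tip.label = prep$labels,
                        Nnode = n - 1L), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate one gene tree under the multi-species coalescent
#'
#' @param species_tree A rooted binary `phylo` with all branch lengths in
#'   coalescent units (the root has no branch; lineages reaching it
#'   coalesce without a time limit).
#' @return A rooted binary `phylo` on the species taxon set, topology only.
#' @seealso [simulate_gene_trees()] for seeded multi-gene runs.
#' @export
simulate_gene_tree <- function(species_tree) {
  msc_one(msc_prep(species_tree))
}

#' Simulate a set of gene trees under the multi-species coalescent
#'
#' `n_genes` independent draws from the gene-tree distribution the
#' species tree defines. With a fixed `seed` the output is fully
#' reproducible.
#'
#' @inheritParams simulate_gene_tree
#' @param n_genes Number of gene trees to simulate.
#' @param seed Optional integer seed.
#' @return A [gene_trees()] object with `k = n_genes` trees.
#' @examples
#' sp <- make_model_tree("balanced", n = 4, internal_bl = 1)
#' g <- simulate_gene_trees(sp, n_genes = 10, seed = 1)
#' @export
simulate_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  stopifnot(n_genes >= 1L)
  if (!is.null(seed)) set.seed(seed)
  prep <- msc_prep(species_tree)
  trees <- vector("list", n_genes)
  for (g in seq_len(n_genes)) trees[[g]] <- msc_one(prep)
  structure(
    list(trees = trees, taxa = sort(prep$labels), n = prep$n, k = n_genes),
    class = "gene_trees"
  )
}

#' Build a model species tree with coalescent-unit branch lengths
#'
#' Deterministic caterpillar and balanced shapes, or a seeded random
#' Yule (equal-rates) topology. All internal branches get length
#' `internal_bl * rescale`: halving the internal branches (rescale 0.5)
#' increases incomplete lineage sorting, doubling them (rescale 2)
#' suppresses it. Terminal branches are set to 1 coalescent unit; with
#' one sampled lineage per species they cannot host coalescences, so
#' their length never affects the gene-tree distribution.
#'
#' @param shape `"caterpillar"`, `"balanced"`, or `"yule"`.
#' @param n Number of taxa (>= 3). Labels are `t01`, `t02`, ...
#' @param internal_bl Base internal branch length, coalescent units.
#' @param rescale Multiplier applied to all internal branch lengths.
#' @param seed Optional seed (only the Yule shape is random).
#' @return A rooted binary `phylo` with branch lengths.
#' @examples
#' make_model_tree("caterpillar", n = 15, internal_bl = 0.5)
#' @export
make_model_tree <- function(shape = c("caterpillar", "balanced", "yule"),
                            n, internal_bl = 1, rescale = 1, seed = NULL) {
  shape <- match.arg(shape)
  if (n < 3L) stop("n must be >= 3", call. = FALSE)
  if (internal_bl <= 0 || rescale <= 0) {
    stop("internal_bl and rescale must be positive", call. = FALSE)
  }
  labs <- sprintf("t%02d", seq_len(n))
  nwk <- switch(shape,
    caterpillar = {
      s <- paste0("(", labs[1L], ",", labs[2L], ")")
      for (i in 3:n) s <- paste0("(", s, ",", labs[i], ")")
      paste0(s, ";")
    },
    balanced = {
      rec <- function(v) {
        if (length(v) == 1L) return(v)
        h <- ceiling(length(v) / 2)
        paste0("(", rec(v[seq_len(h)]), ",", rec(v[-seq_len(h)]), ")")
      }
      paste0(rec(labs), ";")
    },
    yule = {
      if (!is.null(seed)) set.seed(seed)
      # equal-rates topology: merge uniformly chosen pairs until one tree
      # remains (the labelled-shape distribution matches the Yule process)
      frags <- as.list(labs)
      while (length(frags) > 1L) {
        pair <- sample.int(length(frags), 2L)
        merged <- paste0("(", frags[[pair[1L]]], ",", frags[[pair[2L]]], ")")
        frags <- c(frags[-pair], list(merged))
      }
      paste0(frags[[1L]], ";")
    }
  )
  phy <- parse_newick(nwk)
  nt <- length(phy$tip.label)
  bl <- numeric(nrow(phy$edge))
  is_tip <- phy$edge[, 2L] <= nt
  bl[is_tip] <- 1
  bl[!is_tip] <- internal_bl * rescale
  phy$edge.length <- bl
  phy
}
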