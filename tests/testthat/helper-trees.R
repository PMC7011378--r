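# Shared fixtures and independent oracles for the test suite.

# random rooted binary topology on labels a, b, c, ... (or t01.. for n > 26)
rand_tree <- function(n) {
  labs <- if (n <= 26) letters[seq_len(n)] else sprintf("t%02d", seq_len(n))
  phy <- ape::rtree(n, rooted = TRUE, tip.label = sample(labs))
  phy$edge.length <- NULL
  phy
}

rand_gene_set <- function(n, k) gene_trees(replicate(k, rand_tree(n), simplify = FALSE))

# 6-taxon caterpillar on the given label order
caterpillar6 <- function(ord) {
  s <- paste0("(", ord[1], ",", ord[2], ")")
  for (i in 3:6) s <- paste0("(", s, ",", ord[i], ")")
  parse_newick(paste0(s, ";"))
}

# rooted 3-taxon species tree ((A,B),C) with internal branch t
tree3 <- function(t) {
  phy <- parse_newick("((A,B),C);")
  is_tip <- phy$edge[, 2] <= 3
  phy$edge.length <- ifelse(is_tip, 1, t)
  phy
}

# independent unrooted-split enumeration (label sets, no bitsets/ape):
# non-trivial splits keyed by the sorted side not containing the smallest label
unrooted_split_keys <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  tipset <- function(v) {
    if (v <= n) return(phy$tip.label[v])
    sort(unlist(lapply(kids[[v]], tipset)))
  }
  lo <- min(phy$tip.label)
  keys <- character(0)
  for (v in (n + 1):nn) {
    side <- tipset(v)
    if (lo %in% side) side <- sort(setdiff(phy$tip.label, side))
    if (length(side) >= 2 && length(side) <= n - 2) {
      keys <- c(keys, paste(side, collapse = "|"))
    }
  }
  unique(keys)
}

# brute-force count of triplets mapped to an SBP with side label sets s1, s2:
# enumerate all 3-subsets of s1 U s2 and keep those split 2+1 across sides
brute_sbp_triplets <- function(s1, s2) {
  u <- c(s1, s2)
  if (length(u) < 3) return(0)
  subs <- utils::combn(u, 3)
  sum(apply(subs, 2, function(tri) {
    a <- sum(tri %in% s1)
    (a == 2 && 3 - a == 1) || (a == 1 && 3 - a == 2)
  }))
}

# all rooted binary topology scores on the gene set's taxa, by explicit
# recursive enumeration over label subsets with a per-(A,B) cross-weight
# memo; weights come from induced_triplet (LCA oracle), not the SBP path.
enumerate_topology_scores <- function(genes) {
  taxa <- genes$taxa
  n <- length(taxa)
  subs <- utils::combn(taxa, 3)
  # w[[key of 3-subset]][outlier] = number of gene trees inducing that triplet
  w <- new.env(parent = emptyenv())
  for (j in seq_len(ncol(subs))) {
    tri <- subs[, j]
    cnt <- c(0, 0, 0)
    names(cnt) <- tri
    for (gt in genes$trees) {
      o <- induced_triplet(gt, tri)
      cnt[o] <- cnt[o] + 1
    }
    assign(paste(tri, collapse = "|"), cnt, envir = w)
  }
  cross_memo <- new.env(parent = emptyenv())
  # triplets spanning a join of clades A and B (pair in one, outlier in the
  # other): sum of gene support for the induced outlier
  cross_w <- function(A, B) {
    key <- paste(paste(A, collapse = ","), paste(B, collapse = ","), sep = ";")
    got <- get0(key, envir = cross_memo)
    if (!is.null(got)) return(got)
    tot <- 0
    if (length(A) >= 2) {
      pr <- utils::combn(A, 2)
      for (i in seq_len(ncol(pr))) for (b in B) {
        tri <- sort(c(pr[, i], b))
        tot <- tot + get(paste(tri, collapse = "|"), envir = w)[b]
      }
    }
    if (length(B) >= 2) {
      pr <- utils::combn(B, 2)
      for (i in seq_len(ncol(pr))) for (a in A) {
        tri <- sort(c(pr[, i], a))
        tot <- tot + get(paste(tri, collapse = "|"), envir = w)[a]
      }
    }
    assign(key, tot, envir = cross_memo)
    tot
  }
  enum_memo <- new.env(parent = emptyenv())
  enum <- function(set) {                 # vector of scores, all topologies
    if (length(set) == 1) return(0)
    key <- paste(set, collapse = ",")
    got <- get0(key, envir = enum_memo)
    if (!is.null(got)) return(got)
    out <- numeric(0)
    m <- length(set)
    for (szA in 1:(m - 1)) {
      chs <- utils::combn(set[-1], szA - 1, simplify = FALSE)
      for (rest in chs) {
        A <- sort(c(set[1], rest))        # canonical: A holds the first label
        B <- sort(setdiff(set, A))
        if (length(B) == 0) next
        cw <- cross_w(A, B)
        sa <- enum(A)
        sb <- enum(B)
        out <- c(out, as.vector(outer(sa, sb, `+`)) + cw)
      }
    }
    assign(key, out, envir = enum_memo)
    out
  }
  enum(taxa)
}
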