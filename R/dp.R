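# Dynamic program over clades for maximum triplet consistency.
#
# V(A) is the best achievable triplet-consistency score of a rooted
# subtree on leaf set A: V(A) = 0 for singletons, and otherwise the max
# over candidate splits A'|A-A' of V(A') + V(A-A') + TC(A'|A-A'), where
# TC is the score of that subtree-bipartition against the pooled gene
# trees. Constrained mode restricts candidate splits to SBPs observed in
# the gene trees (polynomial); exact mode allows all 2^(|A|-1)-1 splits
# of every cluster (exponential, guarded by `exact_cap`). Clusters are
# processed in increasing size so every V on the right-hand side is
# final; ties in the max are broken by canonical SBP order
# (lexicographically smallest left-clade bitset) for full determinism.

#' Build the cluster search space for the triplet-consistency DP
#'
#' @param pool An [pool_sbps()] result.
#' @param mode `"constrained"` (candidate splits are the distinct
#'   gene-tree SBPs) or `"exact"` (all bipartitions of every cluster,
#'   generated lazily during the solve).
#' @param exact_cap Refuse exact mode above this many taxa (the exact DP
#'   evaluates Theta(3^n) splits). Hard ceiling 22.
#' @return A list of class `tt_space` describing clusters and candidate
#'   splits; consumed by [solve_ctc()].
#' @export
build_search_space <- function(pool, mode = c("constrained", "exact"),
                               exact_cap = 15L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pool, "sbp_pool"))
  n <- pool$n
  if (mode == "exact") {
    if (n > exact_cap) {
      stop("exact mode refused: n = ", n, " exceeds exact_cap = ", exact_cap,
           " (the exact DP evaluates ~3^n splits; raise exact_cap only for",
           " small n)", call. = FALSE)
    }
    if (exact_cap > 22L) stop("exact_cap above 22 is unsupported", call. = FALSE)
    return(structure(list(mode = "exact", n = n, taxa = pool$taxa),
                     class = "tt_space"))
  }
  U <- bitwOr(pool$left, pool$right)
  if (is.null(dim(U))) U <- matrix(U, ncol = pool$nw)
  ukey <- apply(U, 1L, bits_key)
  usize <- rows_and_popcount(U, rep(65535L, pool$nw))  # popcount of union
  full <- bits_from_positions(0:(n - 1L), pool$nw)
  if (!any(ukey == bits_key(full))) {
    stop("constrained search space has no split of the full taxon set",
         " (incomplete gene trees are unsupported)", call. = FALSE)
  }
  # canonical order of SBPs within each cluster: by left-clade key
  lkey <- apply(pool$left, 1L, bits_key)
  structure(
    list(mode = "constrained", n = n, taxa = pool$taxa,
         ukey = ukey, usize = usize, lkey = lkey, union = U),
    class = "tt_space"
  )
}

# words for an integer mask (exact mode, n <= 22)
int_to_words <- function(mask, nw) {
  w <- integer(nw)
  for (j in seq_len(nw)) {
    w[j] <- bitwAnd(bitwShiftR(mask, (j - 1L) * 16L), 65535L)
  }
  w
}

#' Solve the constrained triplet consensus problem
#'
#' Runs the DP over the given search space and backtracks the optimal
#' rooted binary species tree. Deterministic: equal-scoring splits are
#' resolved by canonical SBP order.
#'
#' @param space A [build_search_space()] result.
#' @param pool The [pool_sbps()] result the space was built from.
#' @return A list with `tree` (`phylo`), `score` (the optimal
#'   triplet-consistency score, `V` of the full taxon set), and `V`
#'   (named numeric vector of cluster scores).
#' @export
solve_ctc <- function(space, pool) {
  stopifnot(inherits(space, "tt_space"))
  if (space$mode == "exact") return(solve_exact(space, pool))
  n <- space$n
  nw <- pool$nw
  m <- nrow(pool$left)
  # TC score of every distinct SBP (cached once; reused across clusters)
  w <- numeric(m)
  for (i in seq_len(m)) {
    w[i] <- sbp_pool_score(pool$left[i, ], pool$right[i, ], pool)
  }
  lkeys <- apply(pool$left,  1L, bits_key)
  rkeys <- apply(pool$right, 1L, bits_key)
  V <- new.env(parent = emptyenv())
  back <- new.env(parent = emptyenv())
  # singletons
  for (p in 0:(n - 1L)) {
    assign(bits_key(bits_from_positions(p, nw)), 0, envir = V)
  }
  # iterate clusters by increasing size; within a size, each distinct union once
  idx_by_size <- split(seq_len(m), space$usize)
  for (sz in sort(unique(space$usize))) {
    idx <- idx_by_size[[as.character(sz)]]
    for (uk in unique(space$ukey[idx])) {
      cand <- idx[space$ukey[idx] == uk]
      cand <- cand[order(space$lkey[cand])]      # canonical tie-break order
      best <- -Inf
      besti <- NA_integer_
      for (i in cand) {
        vl <- get0(lkeys[i], envir = V, ifnotfound = NULL)
        vr <- get0(rkeys[i], envir = V, ifnotfound = NULL)
        if (is.null(vl) || is.null(vr)) {
          stop("internal error: DP child cluster missing (", lkeys[i], " / ",
               rkeys[i], ")")   # cannot occur for complete binary gene trees
        }
        v <- vl + vr + w[i]
        if (v > best) {
          best <- v
          besti <- i
        }
      }
      assign(uk, best, envir = V)
      assign(uk, besti, envir = back)
    }
  }
  full <- bits_from_positions(0:(n - 1L), nw)
  fkey <- bits_key(full)
  score <- get(fkey, envir = V)
  singles <- vapply(0:(n - 1L), function(p)
    bits_key(bits_from_positions(p, nw)), "")
  label_of <- structure(pool$taxa, names = singles)
  rec <- function(key) {
    lab <- label_of[key]
    if (!is.na(lab)) return(unname(lab))
    i <- get(key, envir = back)
    paste0("(", rec(lkeys[i]), ",", rec(rkeys[i]), ")")
  }
  nwk <- paste0(rec(fkey), ";")
  Vv <- unlist(as.list(V))
  list(tree = parse_newick(nwk), score = score, V = Vv, newick = nwk)
}

# exact-mode solve: clusters are all integer masks over n <= 22 taxa
solve_exact <- function(space, pool) {
  n <- space$n
  nw <- pool$nw
  nmask <- bitwShiftL(1L, n) - 1L
  V <- numeric(nmask)          # V[mask]; singletons are 0 like all init
  back <- integer(nmask)       # chosen left submask; 0 = leaf
  masks <- seq_len(nmask)
  sizes <- pc16()[bitwAnd(masks, 65535L) + 1L] +
           pc16()[bitwShiftR(masks, 16L) + 1L]
  for (A in masks[order(sizes, masks)]) {
    if (sizes[A] < 2L) next
    lsb <- bitwAnd(A, -A)
    # enumerate submasks of A containing the lowest bit (canonical left)
    sub <- bitwAnd(A - 1L, A)
    cands <- integer(0)
    while (sub > 0L) {
      if (bitwAnd(sub, lsb) != 0L) cands <- c(cands, sub)
      sub <- bitwAnd(sub - 1L, A)
    }
    cands <- sort(cands)       # canonical: smallest left-clade bitset first
    best <- -Inf
    bestl <- 0L
    for (l in cands) {
      r <- A - l
      v <- V[l] + V[r] +
        sbp_pool_score(int_to_words(l, nw), int_to_words(r, nw), pool)
      if (v > best) {
        best <- v
        bestl <- l
      }
    }
    V[A] <- best
    back[A] <- bestl
  }
  rec <- function(A) {
    if (back[A] == 0L) return(pool$taxa[which(bitwAnd(A, bitwShiftL(1L, 0:(n - 1L))) != 0L)])
    l <- back[A]
    paste0("(", rec(l), ",", rec(A - l), ")")
  }
  nwk <- paste0(rec(nmask), ";")
  list(tree = parse_newick(nwk), score = V[nmask], V = V, newick = nwk)
}

#' Estimate a species tree by maximum triplet consistency
#'
#' The main fitting function. Pools the subtree-bipartitions of the gene
#' trees, builds the search space, runs the cluster DP and backtracks the
#' optimal rooted species tree. In `"constrained"` mode (the default,
#' polynomial time) every subtree-bipartition of the returned tree occurs
#' in at least one gene tree; `"exact"` mode searches all rooted binary
#' topologies and is exponential, guarded by `exact_cap`. Both modes are
#' statistically consistent estimators of the species tree under the
#' multi-species coalescent when fed true gene trees.
#'
#' @param genes A [gene_trees()] object, a path to a newick file (one
#'   tree per line), or a character vector of newick strings.
#' @param mode `"constrained"` or `"exact"`.
#' @param exact_cap Taxon cap for exact mode (default 15).
#' @return An object of class `tripletree`: list with `tree` (rooted
#'   binary `phylo`), `score` (optimal triplet-consistency score, an
#'   exact integer count), `max_score` (`k * choose(n, 3)`), `n`, `k`,
#'   `n_sbp` (distinct subtree-bipartitions), `mode`, `taxa`, `call`.
#' @examples
#' g <- gene_trees(c("((b,c),a);", "((b,c),a);", "((a,c),b);"))
#' fit <- tripletree(g)
#' fit$score                 # 2
#' write_newick(fit$tree)    # "(a,(b,c));"
#' @export
tripletree <- function(genes, mode = c("constrained", "exact"),
                       exact_cap = 15L) {
  mode <- match.arg(mode)
  cl <- match.call()
  if (is.character(genes)) {
    genes <- if (length(genes) == 1L && file.exists(genes)) {
      read_gene_trees(genes)
    } else {
      gene_trees(genes)
    }
  }
  stopifnot(inherits(genes, "gene_trees"))
  pool <- pool_sbps(genes)
  space <- build_search_space(pool, mode, exact_cap)
  sol <- solve_ctc(space, pool)
  structure(
    list(tree = sol$tree, score = sol$score,
         max_score = genes$k * choose(genes$n, 3),
         n = genes$n, k = genes$k, n_sbp = nrow(pool$left),
         n_sbp_total = pool$total, mode = mode, taxa = genes$taxa,
         newick = sol$newick, call = cl),
    class = "tripletree"
  )
}

#' @export
print.tripletree <- function(x, ...) {
  cat("Maximum triplet consistency species tree (", x$mode, " mode)\n", sep = "")
  cat("  taxa: n =", x$n, "  gene trees: k =", x$k,
      "  distinct SBPs:", x$n_sbp, "\n")
  cat("  TC_SCORE=", format(x$score, scientific = FALSE),
      " of ", format(x$max_score, scientific = FALSE),
      " (", sprintf("%.4f", x$score / x$max_score), " of triplets)\n", sep = "")
  cat("  ", x$newick, "\n", sep = "")
  invisible(x)
}

#' @export
summary.tripletree <- function(object, ...) {
  structure(list(fit = object), class = "summary.tripletree")
}

#' @export
print.summary.tripletree <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nTriplet agreement: ", format(f$score, scientific = FALSE), " / ",
      format(f$max_score, scientific = FALSE), " = ",
      sprintf("%.6f", f$score / f$max_score), "\n", sep = "")
  cat("Pooled SBP multiset size:", f$n_sbp_total,
      "(", f$n_sbp, "distinct )\n")
  cat("Search mode:", f$mode,
      if (f$mode == "constrained") "(splits restricted to gene-tree SBPs)\n"
      else "(all rooted binary topologies)\n")
  invisible(x)
}

#' Plot the estimated species tree
#'
#' @param x A `tripletree` fit.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.tripletree <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
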