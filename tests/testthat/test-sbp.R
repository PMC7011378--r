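# label-set view of one extracted SBP row, for readable assertions
sbp_labels <- function(s, j) {
  pos_labels <- function(words) {
    out <- character(0)
    for (w in seq_along(words)) for (b in 0:15) {
      if (bitwAnd(words[w], bitwShiftL(1L, b)) != 0L) {
        out <- c(out, s$taxa[(w - 1L) * 16L + b + 1L])
      }
    }
    out
  }
  list(left = pos_labels(s$left[j, ]), right = pos_labels(s$right[j, ]))
}

sbp_row <- function(s, j) list(left = s$left[j, ], right = s$right[j, ])

test_that("subtree-bipartition extraction yields one SBP per internal node", {
  s <- extract_sbps(parse_newick("((a,b),c);"))
  expect_equal(nrow(s$left), 2)
  got <- lapply(seq_len(2), sbp_labels, s = s)
  keys <- sapply(got, function(x) paste(paste(x$left, collapse = ""),
                                        paste(x$right, collapse = ""), sep = "|"))
  expect_setequal(keys, c("a|b", "ab|c"))

  s4 <- extract_sbps(parse_newick("(((a,b),c),d);"))
  keys4 <- sapply(seq_len(3), function(j) {
    x <- sbp_labels(s4, j)
    paste(paste(x$left, collapse = ""), paste(x$right, collapse = ""), sep = "|")
  })
  expect_setequal(keys4, c("a|b", "ab|c", "abc|d"))

  set.seed(3)
  for (n in c(5, 9, 17, 33)) {           # crosses 16-bit word boundaries
    t <- rand_tree(n)
    expect_equal(nrow(extract_sbps(t)$left), n - 1)
  }
})

test_that("pooling preserves multiplicities and exposes the distinct set", {
  g <- gene_trees(rep("((a,b),c);", 3))
  p <- pool_sbps(g)
  expect_equal(nrow(p$left), 2)
  expect_equal(sort(p$count), c(3, 3))
  expect_equal(p$total, 6)

  g2 <- gene_trees(c("((a,b),c);", "((b,c),a);"))
  p2 <- pool_sbps(g2)
  expect_equal(nrow(p2$left), 4)
  expect_true(all(p2$count == 1))

  set.seed(11)
  g3 <- rand_gene_set(7, 5)
  expect_equal(pool_sbps(g3)$total, 5 * (7 - 1))
})

test_that("triplet_count matches brute-force subset enumeration", {
  expect_equal(triplet_count(1, 1), 0)
  expect_equal(triplet_count(2, 1), 1)
  expect_equal(triplet_count(3, 2), 9)
  expect_equal(triplet_count(3, 2), brute_sbp_triplets(letters[1:3], letters[4:5]))
  for (n1 in 0:5) for (n2 in 0:5) {
    s1 <- if (n1 > 0) letters[seq_len(n1)] else character(0)
    s2 <- if (n2 > 0) letters[5 + seq_len(n2)] else character(0)
    expect_equal(triplet_count(n1, n2), brute_sbp_triplets(s1, s2))
  }
  expect_error(triplet_count(-1, 2), "non-negative")
})

test_that("shared_triplets counts each common triplet once and is symmetric", {
  sbp_of <- function(nwk, j, taxa) {
    s <- extract_sbps(parse_newick(nwk), taxa)
    sbp_row(s, j)
  }
  taxa3 <- c("a", "b", "c")
  x <- sbp_of("((a,b),c);", 1, taxa3)    # {a,b}|{c} (root SBP row order varies)
  s <- extract_sbps(parse_newick("((a,b),c);"), taxa3)
  rows <- lapply(1:2, sbp_row, s = s)
  ab_c <- rows[[which(sapply(rows, function(r) sum(r$left) + sum(r$right) == 7))]]
  expect_equal(shared_triplets(ab_c, ab_c), 1)

  taxa4 <- c("a", "b", "c", "d")
  s1 <- extract_sbps(parse_newick("((a,b),(c,d));"), taxa4)
  s2 <- extract_sbps(parse_newick("((a,c),(b,d));"), taxa4)
  root1 <- sbp_row(s1, which(rowSums(cbind(s1$left, s1$right)) == 15))
  root2 <- sbp_row(s2, which(rowSums(cbind(s2$left, s2$right)) == 15))
  expect_equal(shared_triplets(root1, root2), 0)
})

test_that("shared_triplets on disjoint supports is zero", {
  # SBPs over a 6-taxon index with disjoint unions share no triplet
  taxa6 <- letters[1:6]
  mk <- function(l, r) {
    pos <- function(x) match(x, taxa6) - 1L
    list(left = tripletree:::bits_from_positions(pos(l), 1L),
         right = tripletree:::bits_from_positions(pos(r), 1L))
  }
  expect_equal(shared_triplets(mk(c("a", "b"), "c"), mk(c("d", "e"), "f")), 0)
})

test_that("triplet-to-SBP conservation: every triplet maps to exactly one SBP", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    s <- extract_sbps(rand_tree(n))
    tot <- 0
    for (j in seq_len(nrow(s$left))) {
      r <- sbp_row(s, j)
      n1 <- sum(sapply(r$left, function(w) sum(bitwAnd(w, 2^(0:15)) != 0)))
      n2 <- sum(sapply(r$right, function(w) sum(bitwAnd(w, 2^(0:15)) != 0)))
      tot <- tot + triplet_count(n1, n2)
      # self-overlap equals the SBP's own capacity
      expect_equal(shared_triplets(r, r), triplet_count(n1, n2))
    }
    expect_equal(tot, choose(n, 3))
  }
})

test_that("shared_triplets is symmetric on random SBP pairs", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(5:10, 1)
    s1 <- extract_sbps(rand_tree(n))
    s2 <- extract_sbps(rand_tree(n))
    j1 <- sample(nrow(s1$left), 1)
    j2 <- sample(nrow(s2$left), 1)
    a <- sbp_row(s1, j1)
    b <- sbp_row(s2, j2)
    expect_equal(shared_triplets(a, b), shared_triplets(b, a))
  }
})

test_that("tc_score matches hand counts and the triplet oracle", {
  g <- gene_trees(rep("((a,b),c);", 3))
  p <- pool_sbps(g)
  s <- extract_sbps(parse_newick("((a,b),c);"), g$taxa)
  root <- which(rowSums(cbind(s$left, s$right)) == 7)
  expect_equal(tc_score_sbp(sbp_row(s, root), p), 3)
  alt <- extract_sbps(parse_newick("((a,c),b);"), g$taxa)
  root2 <- which(rowSums(cbind(alt$left, alt$right)) == 7)
  expect_equal(tc_score_sbp(sbp_row(alt, root2), p), 0)

  t5 <- rand_tree(5)
  expect_equal(tc_score(t5, gene_trees(list(t5))), 10)

  g3 <- gene_trees(c("((b,c),a);", "((b,c),a);", "((a,c),b);"))
  expect_equal(tc_score(parse_newick("((b,c),a);"), g3), 2)

  # k identical gene trees saturate the k * C(n,3) bound
  set.seed(5)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    k <- sample(2:6, 1)
    t <- rand_tree(n)
    g4 <- gene_trees(rep(list(t), k))
    expect_equal(tc_score(t, g4), k * choose(n, 3))
  }
})

test_that("closed-form score equals the brute-force oracle on random instances", {
  set.seed(47)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    k <- sample(1:8, 1)
    g <- rand_gene_set(n, k)
    s <- rand_tree(n)
    sc <- tc_score(s, g)
    expect_equal(sc, triplet_oracle(s, g))
    expect_gte(sc, 0)
    expect_lte(sc, k * choose(n, 3))
  }
})
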