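#' Parse a rooted binary tree from a newick string
#'
#' Wraps [ape::read.tree()] and enforces the input contract of the
#' triplet-consistency machinery: the tree must be rooted and strictly
#' binary (every internal node, including the root, has exactly two
#' children). Branch lengths, internal node labels and support values are
#' accepted and discarded; the estimator is topology-only.
#'
#' @param text A newick string terminated by `";"`.
#' @param taxa Optional character vector of expected taxon labels. If
#'   given, the tree's leaf set must match it exactly.
#' @return An object of class `phylo` (rooted, binary, no branch lengths).
#' @examples
#' parse_newick("((a,b),c);")
#' @export
parse_newick <- function(text, taxa = NULL) {
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("newick parse error in: ", substr(text, 1L, 60L), call. = FALSE)
  }
  validate_rooted_binary(phy, taxa)
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy
}

# shared validation: rooted + binary + unique labels (+ optional index match)
validate_rooted_binary <- function(phy, taxa = NULL) {
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  outdeg <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
  internal <- outdeg[(n + 1L):(n + phy$Nnode)]
  if (any(internal != 2L)) {
    stop("non-binary tree: internal node(s) with ",
         paste(sort(unique(internal[internal != 2L])), collapse = "/"),
         " children (rooted binary trees required)", call. = FALSE)
  }
  if (!is.null(taxa) && !setequal(phy$tip.label, taxa)) {
    miss  <- setdiff(taxa, phy$tip.label)
    extra <- setdiff(phy$tip.label, taxa)
    stop("taxon set mismatch; symmetric difference: {",
         paste(sort(c(miss, extra)), collapse = ", "), "}", call. = FALSE)
  }
  invisible(phy)
}

#' Bundle gene trees sharing one taxon set
#'
#' Builds the container consumed by [tripletree()], [tc_score()] and the
#' scoring machinery: a list of rooted binary `phylo` trees all
#' leaf-labelled by exactly the same taxa, plus the canonical taxon index
#' (labels sorted lexicographically; bit positions are assigned in that
#' order, so results never depend on file or argument order).
#'
#' @param trees A list of `phylo` objects, or a character vector of newick
#'   strings (one tree per element).
#' @return An object of class `gene_trees`: list with elements `trees`
#'   (list of `phylo`), `taxa` (sorted labels), `n`, `k`.
#' @examples
#' g <- gene_trees(c("((a,b),c);", "((b,c),a);"))
#' g$k
#' @export
gene_trees <- function(trees) {
  if (is.character(trees)) trees <- lapply(trees, parse_newick)
  if (!is.list(trees) || length(trees) == 0L) {
    stop("no trees found", call. = FALSE)
  }
  trees <- lapply(trees, function(t) {
    validate_rooted_binary(t)
    t$edge.length <- NULL
    t$node.label <- NULL
    t
  })
  taxa <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tryCatch(validate_rooted_binary(trees[[i]], taxa),
             error = function(e) stop("tree ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }
  structure(
    list(trees = trees, taxa = taxa, n = length(taxa), k = length(trees)),
    class = "gene_trees"
  )
}

#' Read gene trees from a newick file
#'
#' One rooted binary tree per non-blank line. The taxon index is built
#' from the first tree; every later tree must carry exactly the same
#' leaf set. Errors name the offending 1-based line number.
#'
#' @param path Path to a text file of newick strings, one per line.
#' @return A [gene_trees()] object.
#' @export
read_gene_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no trees found in ", path, call. = FALSE)
  trees <- vector("list", length(keep))
  taxa <- NULL
  for (i in seq_along(keep)) {
    ln <- keep[i]
    trees[[i]] <- tryCatch(
      parse_newick(lines[ln], taxa),
      error = function(e) stop("line ", ln, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    if (is.null(taxa)) taxa <- sort(trees[[1L]]$tip.label)
  }
  gene_trees(trees)
}

#' @export
print.gene_trees <- function(x, ...) {
  cat("Gene tree set: k =", x$k, "rooted binary trees on n =", x$n, "taxa\n")
  cat("Taxa:", paste(utils::head(x$taxa, 8L), collapse = ", "),
      if (x$n > 8L) "..." else "", "\n")
  invisible(x)
}

#' Write a rooted tree as canonical newick
#'
#' Emits the topology only (no branch lengths). Child order is
#' canonicalized — at every node the subtree containing the
#' lexicographically smallest taxon label comes first — so equal
#' topologies always serialize to byte-identical strings.
#'
#' @param tree A rooted binary `phylo`.
#' @param path Optional file path; when given the string is also written
#'   there (one line).
#' @return The newick string, invisibly when `path` is given.
#' @examples
#' write_newick(parse_newick("((b,a),c);"))  # "((a,b),c);"
#' @export
write_newick <- function(tree, path = NULL) {
  validate_rooted_binary(tree)
  n <- length(tree$tip.label)
  taxa <- sort(tree$tip.label)
  pos <- match(tree$tip.label, taxa)          # 1-based canonical positions
  nn <- n + tree$Nnode
  kids <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  # min canonical position in each subtree, bottom-up
  minpos <- integer(nn)
  minpos[seq_len(n)] <- pos
  ord <- unique(reorder_postorder(tree)$edge[, 1L])  # parents, leaves-up
  for (p in ord) minpos[p] <- min(minpos[kids[[p]]])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    ch <- kids[[v]]
    ch <- ch[order(minpos[ch])]
    paste0("(", rec(ch[1L]), ",", rec(ch[2L]), ")")
  }
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

reorder_postorder <- function(phy) ape::reorder.phylo(phy, "postorder")
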