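# Clades are bitsets over the taxon index, stored as integer vectors of
# 16-bit words (word w, bit b <=> taxon position (w-1)*16 + b, 0-based).
# 16-bit words keep every bitwAnd/bitwOr result in [0, 65535], so popcounts
# are a single table lookup and signed-integer overflow is impossible.

.tt_env <- new.env(parent = emptyenv())

# popcount lookup for all 16-bit values, built once per session
pc16 <- function() {
  if (is.null(.tt_env$pc16)) {
    v <- integer(65536L)
    for (b in 0:15) {
      on <- bitwAnd(bitwShiftR(0:65535, b), 1L) == 1L
      v[on] <- v[on] + 1L
    }
    .tt_env$pc16 <- v
  }
  .tt_env$pc16
}

n_words <- function(n) as.integer((n + 15L) %/% 16L)

empty_bits <- function(nw) integer(nw)

# set bits at 0-based positions
bits_from_positions <- function(pos, nw) {
  b <- integer(nw)
  w <- pos %/% 16L + 1L
  r <- bitwShiftL(1L, pos %% 16L)
  for (i in seq_along(pos)) b[w[i]] <- bitwOr(b[w[i]], r[i])
  b
}

bits_popcount <- function(b) sum(pc16()[b + 1L])

bits_and <- function(a, b) bitwAnd(a, b)
bits_or  <- function(a, b) bitwOr(a, b)

bits_positions <- function(b) {
  out <- integer(0)
  for (w in seq_along(b)) {
    x <- b[w]
    if (x != 0L) {
      bs <- which(bitwAnd(bitwShiftR(x, 0:15), 1L) == 1L) - 1L
      out <- c(out, (w - 1L) * 16L + bs)
    }
  }
  out
}

# TRUE iff `a` contains the lowest set bit of `u` (u assumed nonzero)
bits_has_lowest_of <- function(a, u) {
  j <- which(u != 0L)[1L]
  lsb <- bitwAnd(u[j], -u[j])
  bitwAnd(a[j], lsb) != 0L
}

# deterministic sortable string key; also used for canonical SBP ordering
bits_key <- function(b) paste(sprintf("%05d", b), collapse = ".")

# row-wise popcount of bitwAnd(M, v) for a matrix of bitset rows
rows_and_popcount <- function(M, v) {
  pc <- pc16()
  nw <- length(v)
  if (nw == 1L) return(pc[bitwAnd(M[, 1L], v) + 1L])
  acc <- pc[bitwAnd(M[, 1L], v[1L]) + 1L]
  for (w in 2:nw) acc <- acc + pc[bitwAnd(M[, w], v[w]) + 1L]
  acc
}
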