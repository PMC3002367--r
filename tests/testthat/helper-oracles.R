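# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's DP code paths: scores are accumulated by naive loops
# and alignments by explicit recursion.

# All alignments of two plain sequences as state strings over M/I/D.
enum_pair_alignments <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  out <- list()
  rec <- function(i, j, states) {
    if (i == length(av) && j == length(bv)) {
      out[[length(out) + 1L]] <<- states
      return()
    }
    if (i < length(av) && j < length(bv)) rec(i + 1L, j + 1L, c(states, "M"))
    if (j < length(bv)) rec(i, j + 1L, c(states, "I"))
    if (i < length(av)) rec(i + 1L, j, c(states, "D"))
  }
  rec(0L, 0L, character())
  out
}

# Classical affine score of a pairwise alignment given as a state string:
# every gap character costs OP when it opens a run, EX when it extends one;
# terminal gaps included.
affine_score_states <- function(states, av, bv, scheme) {
  s <- 0; i <- 0L; j <- 0L; prev <- "M"
  for (st in states) {
    if (st == "M") {
      i <- i + 1L; j <- j + 1L
      s <- s + scheme$s[av[i], bv[j]]
    } else if (st == "I") {
      j <- j + 1L
      s <- s + if (prev == "I") scheme$EX else scheme$OP
    } else {
      i <- i + 1L
      s <- s + if (prev == "D") scheme$EX else scheme$OP
    }
    prev <- st
  }
  s
}

# Direct affine score of a 2-row gapped matrix.
affine_score_matrix <- function(m, scheme) {
  s <- 0
  for (j in seq_len(ncol(m)))
    if (m[1, j] != "-" && m[2, j] != "-")
      s <- s + scheme$s[m[1, j], m[2, j]]
  for (r in 1:2) {
    open <- FALSE
    for (j in seq_len(ncol(m))) {
      if (m[r, j] == "-") {
        s <- s + if (open) scheme$EX else scheme$OP
        open <- TRUE
      } else open <- FALSE
    }
  }
  s
}

# Best complete-alignment score through every column, by enumeration.
# Returns an environment keyed by "state i j".
brute_column_best <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- new.env()
  opt <- -Inf
  for (states in enum_pair_alignments(a, b)) {
    sc <- affine_score_states(states, av, bv, scheme)
    opt <- max(opt, sc)
    i <- 0L; j <- 0L
    for (st in states) {
      if (st == "M") { i <- i + 1L; j <- j + 1L }
      else if (st == "I") j <- j + 1L else i <- i + 1L
      key <- paste(st, i, j)
      if (sc > mget(key, best, ifnotfound = -Inf)[[1]]) assign(key, sc, best)
    }
  }
  list(best = best, opt = opt)
}

# Naive internal score of a gapped matrix: double loops over row pairs for
# both the similarity and the Table-style column-pair indel terms, with
# virtual all-residue boundary columns.
naive_internal <- function(m, w, scheme) {
  k <- nrow(m); L <- ncol(m)
  if (L == 0L) return(0)
  tot <- 0
  if (k >= 2L) {
    for (j in seq_len(L)) for (r in 1:(k - 1L)) for (t2 in (r + 1L):k)
      if (m[r, j] != "-" && m[t2, j] != "-")
        tot <- tot + w[r] * w[t2] * scheme$s[m[r, j], m[t2, j]]
    mb <- cbind("X", m, "X")
    for (j in seq_len(L + 1L)) for (r in 1:(k - 1L)) for (t2 in (r + 1L):k) {
      p1 <- paste0(if (mb[r, j] == "-") "-" else "*",
                   if (mb[r, j + 1L] == "-") "-" else "*")
      p2 <- paste0(if (mb[t2, j] == "-") "-" else "*",
                   if (mb[t2, j + 1L] == "-") "-" else "*")
      tot <- tot + w[r] * w[t2] * scheme$T4[p1, p2]
    }
  }
  tot
}

# All Start->End paths of a network as vertex-id vectors.
network_paths <- function(net) {
  V <- ncol(net$cols)
  out <- list()
  rec <- function(v, path) {
    if (v == V + 1L) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (s in net$succ[[v]]) rec(s, c(path, v))
  }
  for (s in net$start_succ)
    if (s == V + 1L) out[[length(out) + 1L]] <<- integer() else rec(s, integer())
  out
}

# Exhaustive oracle for aligning two networks: enumerate every pair of
# stored alignments and every interleaving, score naively, and record the
# best score through every (state, i, j) column identity plus the overall
# optimum.
cross_network_oracle <- function(netA, netB, scheme) {
  k <- nrow(netA$cols); l <- nrow(netB$cols)
  wA <- if (is.null(scheme$weights)) rep(1, k) else
    unname(scheme$weights[netA$ids])
  wB <- if (is.null(scheme$weights)) rep(1, l) else
    unname(scheme$weights[netB$ids])
  w <- c(wA, wB)
  best <- new.env(); opt <- -Inf
  for (A in network_paths(netA)) for (B in network_paths(netB)) {
    rec <- function(ia, ib, cols, tags) {
      if (ia > length(A) && ib > length(B)) {
        m <- do.call(cbind, cols)
        sc <- naive_internal(m, w, scheme)
        opt <<- max(opt, sc)
        for (tg in tags)
          if (sc > mget(tg, best, ifnotfound = -Inf)[[1]]) assign(tg, sc, best)
        return()
      }
      lastA <- if (ia > 1L) A[ia - 1L] else 0L
      lastB <- if (ib > 1L) B[ib - 1L] else 0L
      if (ia <= length(A) && ib <= length(B))
        rec(ia + 1L, ib + 1L,
            c(cols, list(c(netA$cols[, A[ia]], netB$cols[, B[ib]]))),
            c(tags, paste("M", A[ia], B[ib])))
      if (ib <= length(B))
        rec(ia, ib + 1L,
            c(cols, list(c(rep("-", k), netB$cols[, B[ib]]))),
            c(tags, paste("I", lastA, B[ib])))
      if (ia <= length(A))
        rec(ia + 1L, ib,
            c(cols, list(c(netA$cols[, A[ia]], rep("-", l)))),
            c(tags, paste("D", A[ia], lastB)))
    }
    rec(1L, 1L, list(), character())
  }
  list(best = best, opt = opt)
}

# Exhaustive optimum of the internal score for three sequences: DP over
# index triples and the previous column's gap pattern (including the
# all-residue boundary), which captures the adjoining-column indel terms.
brute_opt3 <- function(seqs, scheme, weights = rep(1, 3)) {
  sv <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  L <- vapply(sv, length, 0L)
  pats <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
               c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  pairsum <- function(prev, cur) {
    tot <- 0
    for (r in 1:2) for (t2 in (r + 1L):3) {
      p1 <- paste0(if (prev[r]) "*" else "-", if (cur[r]) "*" else "-")
      p2 <- paste0(if (prev[t2]) "*" else "-", if (cur[t2]) "*" else "-")
      tot <- tot + weights[r] * weights[t2] * scheme$T4[p1, p2]
    }
    tot
  }
  simcol <- function(idx, cur) {
    tot <- 0
    for (r in 1:2) for (t2 in (r + 1L):3) if (cur[r] && cur[t2])
      tot <- tot + weights[r] * weights[t2] *
        scheme$s[sv[[r]][idx[r]], sv[[t2]][idx[t2]]]
    tot
  }
  D <- array(-Inf, dim = c(L[1] + 1L, L[2] + 1L, L[3] + 1L, 8L))
  D[1, 1, 1, 8] <- 0
  for (i in 0:L[1]) for (j in 0:L[2]) for (k in 0:L[3]) for (pp in 1:8) {
    v <- D[i + 1L, j + 1L, k + 1L, pp]
    if (!is.finite(v)) next
    prev <- if (pp == 8L) c(1, 1, 1) else pats[[pp]]
    for (cp in 1:7) {
      cur <- pats[[cp]]
      ni <- i + cur[1]; nj <- j + cur[2]; nk <- k + cur[3]
      if (ni > L[1] || nj > L[2] || nk > L[3]) next
      val <- v + pairsum(prev, cur) + simcol(c(ni, nj, nk), cur)
      if (val > D[ni + 1L, nj + 1L, nk + 1L, cp])
        D[ni + 1L, nj + 1L, nk + 1L, cp] <- val
    }
  }
  best <- -Inf
  for (pp in 1:8) {
    v <- D[L[1] + 1L, L[2] + 1L, L[3] + 1L, pp]
    if (!is.finite(v)) next
    prev <- if (pp == 8L) c(1, 1, 1) else pats[[pp]]
    best <- max(best, v + pairsum(prev, c(1, 1, 1)))
  }
  best
}

random_protein <- function(len) paste(sample(AA_RESIDUES, len, TRUE),
                                      collapse = "")

test_scheme <- function(...) retalign_scheme(...)

# every edge of a network goes forward in the stored order
edges_forward <- function(net) {
  V <- ncol(net$cols)
  ok <- TRUE
  for (v in seq_len(V)) {
    if (any(net$pred[[v]] >= v)) ok <- FALSE
    if (any(net$succ[[v]] <= v)) ok <- FALSE
  }
  ok
}
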