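# The two-sequence Waterman-Byers variant: forward and backward affine-gap
# dynamic programmes over prefix/suffix pairs, per-column best scores, and
# the x-network of two sequences.

split_seq <- function(x) {
  if (length(x) == 1L && is.character(x)) strsplit(x, "")[[1]] else
    as.character(x)
}

#' Forward pairwise dynamic programme
#'
#' Best scores of alignments of the prefixes `A_i`, `B_j` ending in a match
#' (`M`), an insertion of `b_j` (`I`) or a deletion of `a_i` (`D`), under
#' affine gap scores: a gap run of length L costs `OP + (L-1)*EX`, terminal
#' gaps included. `-Inf` marks impossible cells.
#'
#' @param a,b Sequences (character strings).
#' @param scheme A [retalign_scheme()].
#' @return List with matrices `M`, `I`, `D` of dimension `(n+1) x (m+1)`
#'   (prefix lengths 0..n / 0..m), the sequences, and `opt`, the optimal
#'   alignment score `max(M[n,m], I[n,m], D[n,m])`.
#' @export
pairwise_forward <- function(a, b, scheme) {
  av <- split_seq(a); bv <- split_seq(b)
  residue_check(c(av, bv), scheme)
  n <- length(av); m <- length(bv)
  go <- scheme$OP; ge <- scheme$EX
  S <- scheme$s
  M <- I <- D <- matrix(-Inf, n + 1L, m + 1L,
                        dimnames = list(0:n, 0:m))
  M[1L, 1L] <- 0
  if (n > 0L) D[2:(n + 1L), 1L] <- go + (seq_len(n) - 1L) * ge
  if (m > 0L) I[1L, 2:(m + 1L)] <- go + (seq_len(m) - 1L) * ge
  for (i in seq_len(n)) {
    srow <- S[av[i], ]
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- max(M[i, j], I[i, j], D[i, j]) + srow[bv[j]]
      I[i + 1L, j + 1L] <- max(M[i + 1L, j] + go, I[i + 1L, j] + ge,
                               D[i + 1L, j] + go)
      D[i + 1L, j + 1L] <- max(M[i, j + 1L] + go, I[i, j + 1L] + go,
                               D[i, j + 1L] + ge)
    }
  }
  list(M = M, I = I, D = D, a = av, b = bv,
       opt = max(M[n + 1L, m + 1L], I[n + 1L, m + 1L], D[n + 1L, m + 1L]))
}

#' Backward pairwise dynamic programme
#'
#' Best scores of alignments of the suffixes `A^i`, `B^j`, scored as if
#' preceded by a match column (`M`), an insertion column (`I`) or a deletion
#' column (`D`): a suffix starting with a gap is charged the opening score
#' after a match context and the extension score after a gap context of the
#' same kind.
#'
#' @inheritParams pairwise_forward
#' @return List with matrices `M`, `I`, `D` indexed like
#'   [pairwise_forward()] (suffix start positions 0..n / 0..m).
#' @export
pairwise_backward <- function(a, b, scheme) {
  av <- split_seq(a); bv <- split_seq(b)
  residue_check(c(av, bv), scheme)
  n <- length(av); m <- length(bv)
  go <- scheme$OP; ge <- scheme$EX
  S <- scheme$s
  M <- I <- D <- matrix(-Inf, n + 1L, m + 1L, dimnames = list(0:n, 0:m))
  M[n + 1L, m + 1L] <- I[n + 1L, m + 1L] <- D[n + 1L, m + 1L] <- 0
  # last column (j = m): the suffix deletes the remaining characters of A
  if (n > 0L) {
    for (i in 0:(n - 1L)) {
      M[i + 1L, m + 1L] <- I[i + 1L, m + 1L] <- go + (n - i - 1L) * ge
      D[i + 1L, m + 1L] <- (n - i) * ge
    }
  }
  # last row (i = n): the suffix inserts the remaining characters of B
  if (m > 0L) {
    for (j in 0:(m - 1L)) {
      M[n + 1L, j + 1L] <- D[n + 1L, j + 1L] <- go + (m - j - 1L) * ge
      I[n + 1L, j + 1L] <- (m - j) * ge
    }
  }
  if (n > 0L && m > 0L) {
    for (i in (n - 1L):0) {
      for (j in (m - 1L):0) {
        diag <- M[i + 2L, j + 2L] + S[av[i + 1L], bv[j + 1L]]
        M[i + 1L, j + 1L] <- max(diag, I[i + 1L, j + 2L] + go,
                                 D[i + 2L, j + 1L] + go)
        I[i + 1L, j + 1L] <- max(diag, I[i + 1L, j + 2L] + ge,
                                 D[i + 2L, j + 1L] + go)
        D[i + 1L, j + 1L] <- max(diag, I[i + 1L, j + 2L] + go,
                                 D[i + 2L, j + 1L] + ge)
      }
    }
  }
  list(M = M, I = I, D = D, a = av, b = bv)
}

#' Optimal pairwise alignment score
#'
#' @inheritParams pairwise_forward
#' @return The optimal affine-gap alignment score of `a` and `b`.
#' @export
pairwise_opt <- function(a, b, scheme) pairwise_forward(a, b, scheme)$opt

#' Best complete-alignment score through each column
#'
#' For every feasible alignment column (match `a_i/b_j`, insertion
#' `-_i/b_j`, deletion `a_i/-_j`), the score of the best complete alignment
#' containing it: the sum of the forward and backward scores of the matching
#' state and indices. Cells that are `-Inf` on either side are omitted.
#'
#' @param fwd,bwd Results of [pairwise_forward()] and [pairwise_backward()]
#'   computed with the same scheme.
#' @return A data frame with columns `i`, `j`, `state` and `b`, in
#'   lexicographic (i, j, state M<I<D) order.
#' @export
column_best_scores <- function(fwd, bwd) {
  n <- nrow(fwd$M) - 1L; m <- ncol(fwd$M) - 1L
  res <- list()
  add <- function(state, F, B, imin, jmin) {
    idx <- which(is.finite(F) & is.finite(B), arr.ind = TRUE)
    if (!nrow(idx)) return()
    i <- idx[, 1L] - 1L; j <- idx[, 2L] - 1L
    keep <- i >= imin & j >= jmin
    res[[state]] <<- data.frame(i = i[keep], j = j[keep], state = state,
                                b = F[idx][keep] + B[idx][keep])
  }
  add("M", fwd$M, bwd$M, 1L, 1L)
  add("I", fwd$I, bwd$I, 0L, 1L)
  add("D", fwd$D, bwd$D, 1L, 0L)
  out <- do.call(rbind, res)
  st <- match(out$state, c("M", "I", "D"))
  out <- out[order(out$i, out$j, st), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The x-network of two sequences
#'
#' Builds the directed acyclic graph whose vertices are the alignment
#' columns appearing in some complete alignment scoring at least `opt - x`,
#' with an edge wherever one column can immediately follow another in such
#' an alignment. Paths from Start to End are exactly the retained
#' (sub)optimal alignments; the vertex order is the lexicographic
#' (i, j, state) linear extension.
#'
#' @inheritParams pairwise_forward
#' @param x Score slack, `>= 0` (`Inf` keeps every feasible column).
#' @param ids Sequence ids for the two rows.
#' @return An `"aln_network"` over the two sequences; `meta$opt` holds the
#'   optimal score and `origin` maps each vertex to its (i, j, state, b).
#' @examples
#' sch <- retalign_scheme()
#' net <- pairwise_x_network("ALLGVGQ", "AVGQ", x = 0, scheme = sch)
#' count_alignments(net)
#' @export
pairwise_x_network <- function(a, b, x, scheme, ids = c("A", "B")) {
  stopifnot(x >= 0)
  fwd <- pairwise_forward(a, b, scheme)
  bwd <- pairwise_backward(a, b, scheme)
  cbs <- column_best_scores(fwd, bwd)
  keep <- cbs$b >= fwd$opt - x - 1e-9
  cand <- cbs[keep, , drop = FALSE]
  build_pair_network(cand, fwd$a, fwd$b, ids,
                     meta = list(opt = fwd$opt, x = x,
                                 x_effective = fwd$opt - min(cand$b)))
}

# Assemble an aln_network over two plain sequences from admitted (i,j,state)
# columns (already in lexicographic order). Transition rule: into M(i,j)
# from any state at (i-1,j-1); into I(i,j) from any state at (i,j-1); into
# D(i,j) from any state at (i-1,j). Start feeds M(1,1), I(0,1), D(1,0);
# End is fed from any state at (n,m).
build_pair_network <- function(cand, av, bv, ids, meta) {
  n <- length(av); m <- length(bv)
  V <- nrow(cand)
  key <- function(i, j, s) paste(i, j, s)
  id_of <- setNames(seq_len(V), key(cand$i, cand$j, cand$state))
  look <- function(i, j, s) {
    v <- id_of[key(i, j, s)]
    v[!is.na(v)]
  }
  cols <- matrix(GAP, 2L, V, dimnames = list(ids, NULL))
  pred <- vector("list", V)
  for (v in seq_len(V)) {
    i <- cand$i[v]; j <- cand$j[v]; s <- cand$state[v]
    cols[, v] <- switch(s,
      M = c(av[i], bv[j]),
      I = c(GAP, bv[j]),
      D = c(av[i], GAP))
    p <- switch(s,
      M = c(look(i - 1L, j - 1L, "M"), look(i - 1L, j - 1L, "I"),
            look(i - 1L, j - 1L, "D"),
            if (i == 1L && j == 1L) 0L),
      I = c(look(i, j - 1L, "M"), look(i, j - 1L, "I"),
            look(i, j - 1L, "D"),
            if (i == 0L && j == 1L) 0L),
      D = c(look(i - 1L, j, "M"), look(i - 1L, j, "I"),
            look(i - 1L, j, "D"),
            if (i == 1L && j == 0L) 0L))
    pred[[v]] <- sort(unname(as.integer(p)))
  }
  succ <- rep(list(integer()), V)
  end_pred <- integer()
  for (v in seq_len(V)) {
    for (p in pred[[v]]) if (p >= 1L) succ[[p]] <- c(succ[[p]], v)
    if (cand$i[v] == n && cand$j[v] == m) {
      succ[[v]] <- c(succ[[v]], V + 1L)
      end_pred <- c(end_pred, v)
    }
  }
  succ <- lapply(succ, sort)
  start_succ <- which(vapply(pred, function(p) 0L %in% p, TRUE))
  net <- new_aln_network(ids, cols, cand$state, pred, succ,
                         start_succ, end_pred,
                         origin = data.frame(i = cand$i, j = cand$j,
                                             state = cand$state, b = cand$b),
                         meta = meta)
  chk <- validate_network(net)
  if (!chk$valid)
    stop("internal error: invalid pairwise x-network: ",
         paste(chk$violations, collapse = "; "))
  net
}
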