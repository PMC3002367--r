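# Column similarity, column-pair indel scores, the internal score of an
# alignment, and the count-based fast pair summation.

#' Fast pairwise pattern-score summation
#'
#' Computes `sum_k sum_l t_k t_l M[k, l]` from a tally of pattern types
#' (counts, or weight sums when sequence weighting is on) instead of looping
#' over all row pairs. The sum is over ordered pairs including self-pairs;
#' callers needing unordered distinct pairs subtract the per-row self terms
#' and halve (see [similarity_column()]).
#'
#' @param tally Named numeric vector of counts or weight sums; names must be
#'   rows/columns of `M`.
#' @param M Symmetric score matrix.
#' @return The ordered-pair sum, a single number.
#' @export
fast_pair_sum <- function(tally, M) {
  if (!isTRUE(all.equal(M, t(M)))) stop("pattern score matrix must be symmetric")
  p <- names(tally)
  if (is.null(p) || any(!p %in% rownames(M)))
    stop("tally names must index the score matrix")
  drop(tally %*% M[p, p, drop = FALSE] %*% tally)
}

# Unordered distinct pair sum over rows with values v (matrix labels) and
# weights w: collapse to tallies, then remove self terms and halve.
pair_sum_distinct <- function(v, w, M) {
  if (length(v) < 2L) return(0)
  s1 <- rowsum(w, v)           # weight sums per pattern
  s2 <- rowsum(w * w, v)       # squared-weight sums per pattern
  p <- rownames(s1)
  Msub <- M[p, p, drop = FALSE]
  (drop(t(s1) %*% Msub %*% s1) - sum(s2 * diag(Msub))) / 2
}

#' Similarity score of one alignment column
#'
#' Sum of substitution scores over all unordered pairs of non-gap cells,
#' each term multiplied by both sequence weights when weighting is on. Gap
#' cells contribute nothing; the score is computed for every column
#' regardless of its insertion/deletion state.
#'
#' @param cells Character vector of residues/`"-"`, optionally named by
#'   sequence id (names are used to look up scheme weights).
#' @param scheme A [retalign_scheme()].
#' @param weights Optional explicit weights (overrides the scheme's).
#' @return A single score.
#' @export
similarity_column <- function(cells, scheme, weights = NULL) {
  if (is.null(weights)) {
    weights <- if (!is.null(names(cells))) scheme_weights(scheme, names(cells))
               else rep(1, length(cells))
  }
  residue_check(cells, scheme)
  keep <- cells != GAP
  pair_sum_distinct(cells[keep], weights[keep], scheme$s)
}

#' Indel score of two adjoining alignment columns
#'
#' For every unordered pair of rows, the pattern each row forms over the two
#' columns (`"--"`, `"-*"`, `"*-"`, `"**"`) is looked up in the indel pattern
#' matrix and the entries are summed (with weight products when weighting is
#' on). Either side may be the virtual boundary before the first / after the
#' last column, written `"boundary"`, which behaves as an all-residue column
#' so that terminal gaps are charged like any other gap run.
#'
#' @param left,right Character vectors of residues/`"-"` over the same rows,
#'   or the string `"boundary"`.
#' @inheritParams similarity_column
#' @return A single score.
#' @export
indel_column_pair <- function(left, right, scheme, weights = NULL) {
  cells <- if (identical(left, "boundary")) right else left
  if (identical(left, "boundary")) left <- rep("X", length(right))
  if (identical(right, "boundary")) right <- rep("X", length(left))
  if (length(left) != length(right))
    stop("columns must share the same row set")
  if (is.null(weights)) {
    weights <- if (!is.null(names(cells))) scheme_weights(scheme, names(cells))
               else rep(1, length(cells))
  }
  pat <- paste0(ifelse(left == GAP, "-", "*"),
                ifelse(right == GAP, "-", "*"))
  pair_sum_distinct(pat, weights, scheme$T4)
}

#' Internal score of a multiple alignment
#'
#' The objective maximised by the progressive search: the sum of per-column
#' similarity scores plus the sum of column-pair indel scores over all
#' consecutive column pairs, including the virtual boundary pairs before the
#' first and after the last column (so terminal gaps are penalised). On two
#' rows this equals the classical affine-gap pairwise score; on more rows it
#' approximates the sum-of-pairs score from adjoining columns only. The
#' score is independent of the guide tree and of which groups were aligned
#' last.
#'
#' @param aln An [msa] object (or a character matrix of residues/gaps with
#'   rownames).
#' @inheritParams similarity_column
#' @return A single score.
#' @export
internal_score <- function(aln, scheme, weights = NULL) {
  m <- as.matrix(aln)
  if (is.null(weights)) {
    weights <- if (!is.null(rownames(m))) scheme_weights(scheme, rownames(m))
               else rep(1, nrow(m))
  }
  L <- ncol(m)
  if (L == 0L) return(0)
  total <- 0
  for (j in seq_len(L))
    total <- total + similarity_column(m[, j], scheme, weights = weights)
  bounded <- cbind("X", m, "X") # virtual all-residue boundary columns
  for (j in seq_len(L + 1L))
    total <- total + indel_column_pair(bounded[, j], bounded[, j + 1L],
                                       scheme, weights = weights)
  total
}

#' ClustalW-imitation similarity of one column
#'
#' Only cross-scores between the two groups being aligned count: pairs of
#' non-gap cells with one member in each group. Columns that are a full
#' insertion or deletion in the ongoing alignment step therefore score zero.
#'
#' @inheritParams similarity_column
#' @param groupA,groupB Integer indices partitioning the rows of `cells`
#'   into the two groups being aligned.
#' @return A single score.
#' @export
clustalw_similarity_column <- function(cells, groupA, groupB, scheme,
                                       weights = NULL) {
  if (is.null(weights)) {
    weights <- if (!is.null(names(cells))) scheme_weights(scheme, names(cells))
               else rep(1, length(cells))
  }
  residue_check(cells, scheme)
  a <- groupA[cells[groupA] != GAP]
  b <- groupB[cells[groupB] != GAP]
  if (!length(a) || !length(b)) return(0)
  wa <- rowsum(weights[a], cells[a])
  wb <- rowsum(weights[b], cells[b])
  drop(t(wa) %*% scheme$s[rownames(wa), rownames(wb), drop = FALSE] %*% wb)
}

#' ClustalW-imitation indel score of two adjoining columns
#'
#' One single gap penalty per full-column insertion or deletion event
#' between the two groups, regardless of gaps hidden inside the groups'
#' columns: opening (`OP`) when the preceding column is not the same kind of
#' event, extension (`EX`) when it is. Match columns cost nothing.
#'
#' @inheritParams indel_column_pair
#' @param groupA,groupB Integer row indices of the two groups.
#' @return A single score.
#' @export
clustalw_indel <- function(left, right, groupA, groupB, scheme) {
  state_of <- function(col) {
    if (identical(col, "boundary")) return("M")
    if (all(col[groupA] == GAP)) "I" else if (all(col[groupB] == GAP)) "D"
    else "M"
  }
  sr <- state_of(right)
  if (sr == "M") return(0)
  if (state_of(left) == sr) scheme$EX else scheme$OP
}
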