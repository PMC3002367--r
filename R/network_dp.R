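# Aligning a network of alignments against a network of alignments: R
# surface over the compiled generalised Waterman-Byers kernel, plus
# construction of the x-network of two networks under a size threshold.

# Encode a network for the kernel: residue codes (0 = gap) and the
# predecessor lists (element v = preds of vertex v, last element = preds of
# End; 0 denotes Start).
encode_network <- function(net, scheme) {
  V <- n_vertices(net)
  codes <- match(net$cols, rownames(scheme$s), nomatch = 0L)
  cols <- matrix(as.integer(codes), nrow = length(net$ids), ncol = V)
  bad <- net$cols[codes == 0L & net$cols != GAP]
  if (length(bad))
    stop("residue(s) without a matrix entry: ",
         paste(unique(bad), collapse = ", "))
  preds <- c(net$pred, list(as.integer(net$end_pred)))
  if (V == 0L) preds <- list(0L)
  preds <- lapply(preds, as.integer)
  list(cols = cols, preds = preds,
       w = scheme_weights(scheme, net$ids))
}

# G4 reindexed to the kernel's pattern coding 2*gapLeft + gapRight:
# ("**", "*-", "-*", "--")
kernel_G4 <- function(scheme) {
  ord <- c("**", "*-", "-*", "--")
  scheme$G4[ord, ord]
}

net_dp_kernel <- function(netA, netB, scheme, backward = TRUE, path = TRUE) {
  ea <- encode_network(netA, scheme)
  eb <- encode_network(netB, scheme)
  .net_dp_tables(ea$cols, ea$preds, eb$cols, eb$preds,
                 scheme$s, ea$w, eb$w, kernel_G4(scheme),
                 if (scheme$mode == "clustalw") 1L else 0L,
                 scheme$OP, scheme$EX, backward, path)
}

relabel_tables <- function(tab, VA, VB) {
  dn <- list(0:(VA + 1L), 0:(VB + 1L))
  for (nm in intersect(names(tab), c("Mf", "If", "Df", "Mb", "Ib", "Db")))
    dimnames(tab[[nm]]) <- dn
  tab
}

#' Forward dynamic programme over two networks of alignments
#'
#' Generalises the pairwise forward pass: cells are indexed by a vertex of
#' each network and a state (match / insertion with an anchor in the first
#' network / deletion with an anchor in the second), visited in the
#' networks' linear extensions. Start sentinels carry index 0.
#'
#' @param netA,netB `"aln_network"` objects (validated, vertices in a linear
#'   extension).
#' @param scheme A [retalign_scheme()].
#' @return List of matrices `Mf`, `If`, `Df` indexed `0..V+1` on each side,
#'   and `opt`, the best achievable score over any pair of stored
#'   alignments.
#' @export
network_forward <- function(netA, netB, scheme) {
  tab <- net_dp_kernel(netA, netB, scheme, backward = FALSE, path = FALSE)
  relabel_tables(tab, n_vertices(netA), n_vertices(netB))
}

#' Backward dynamic programme over two networks of alignments
#'
#' @inheritParams network_forward
#' @return List with the backward matrices `Mb`, `Ib`, `Db` (suffix scores
#'   under the preceded-by-this-column convention) alongside the forward
#'   matrices and `opt`.
#' @export
network_backward <- function(netA, netB, scheme) {
  tab <- net_dp_kernel(netA, netB, scheme, backward = TRUE, path = FALSE)
  relabel_tables(tab, n_vertices(netA), n_vertices(netB))
}

#' Optimal score of aligning two networks
#'
#' @inheritParams network_forward
#' @return Best score over all pairs of stored alignments and all their
#'   alignments-of-alignments.
#' @export
network_opt <- function(netA, netB, scheme) {
  net_dp_kernel(netA, netB, scheme, backward = FALSE, path = FALSE)$opt
}

#' Lexicographic linear extension of combined columns
#'
#' Orders columns of an x-network of two networks by (index in the first
#' network's extension, index in the second network's extension, state with
#' M < I < D). When both component indexings are linear extensions this
#' ordering is a certified linear extension of the combined network.
#'
#' @param i,j Integer anchor/vertex indices of each column.
#' @param state Character vector of `"M"`/`"I"`/`"D"`.
#' @return Integer permutation putting the columns in lexicographic order.
#' @export
lexicographic_extension <- function(i, j, state) {
  order(i, j, match(state, c("M", "I", "D")))
}

#' Align two networks into the x-network of the pair
#'
#' The core progressive step. Forward and backward passes give `b(alpha)`,
#' the best achievable score of a complete alignment through each candidate
#' column; the deterministic best alignment fixes the size cap
#' `ceiling((1 + t/100) * L_opt)`; equal-score groups of columns are then
#' admitted in descending `b` order while the cap permits (the optimal group
#' is always admitted). Edges follow the dynamic-programming adjacency rule,
#' the vertex order is the lexicographic extension, and the result is
#' validated (no dead ends).
#'
#' @inheritParams network_forward
#' @param t Threshold parameter (percent surplus network size, `>= 0`;
#'   `Inf` disables the cap and keeps every feasible column).
#' @return An `"aln_network"` over the concatenated rows (first network's
#'   rows first). `meta` records `opt`, `x_effective`, `L_opt`, `size_cap`,
#'   `n_groups` (admitted score groups) and `k` (rows of the first side);
#'   `origin` maps vertices to (i, j, state, b).
#' @examples
#' sch <- retalign_scheme()
#' a <- seq_network("ALLGVGQ", "s1")
#' b <- seq_network("AVGQ", "s2")
#' net <- align_networks(a, b, sch, t = 200)
#' net$meta$opt
#' @export
align_networks <- function(netA, netB, scheme, t = 0) {
  stopifnot(t >= 0)
  VA <- n_vertices(netA); VB <- n_vertices(netB)
  tab <- net_dp_kernel(netA, netB, scheme, backward = TRUE, path = TRUE)

  b_entries <- function(F, B, state, imin, jmin) {
    b <- F + B
    idx <- which(is.finite(b), arr.ind = TRUE)
    i <- idx[, 1L] - 1L; j <- idx[, 2L] - 1L
    keep <- i >= imin & j >= jmin & i <= VA & j <= VB
    data.frame(i = i[keep], j = j[keep], state = state, b = b[idx][keep])
  }
  cand <- rbind(
    b_entries(tab$Mf, tab$Mb, "M", 1L, 1L),
    b_entries(tab$If, tab$Ib, "I", 0L, 1L),
    b_entries(tab$Df, tab$Db, "D", 1L, 0L))

  opt <- tab$opt
  path <- tab$path
  L_opt <- nrow(path)
  size_cap <- if (is.infinite(t)) Inf else ceiling((1 + t / 100) * L_opt)

  br <- round(cand$b, 9L)
  groups <- sort(unique(br), decreasing = TRUE)
  sizes <- as.numeric(table(factor(br, levels = groups)))
  cum <- cumsum(sizes)
  n_groups <- max(1L, sum(cum <= size_cap))
  cutoff <- groups[n_groups]
  admitted <- cand[br >= cutoff, , drop = FALSE]
  x_effective <- max(0, opt - cutoff)
  if (x_effective < 1e-8) x_effective <- 0 # float noise around the optimum

  ord <- lexicographic_extension(admitted$i, admitted$j, admitted$state)
  admitted <- admitted[ord, , drop = FALSE]

  net <- build_combined_network(admitted, netA, netB,
                                meta = list(opt = opt,
                                            x_effective = x_effective,
                                            L_opt = L_opt,
                                            size_cap = size_cap,
                                            n_groups = n_groups,
                                            t = t,
                                            k = length(netA$ids)))
  chk <- validate_network(net)
  if (!chk$valid)
    stop("internal error: invalid x-network: ",
         paste(chk$violations, collapse = "; "))
  net
}

# Materialise the combined network from admitted (i, j, state, b) columns
# already in lexicographic order. An edge runs alpha' -> alpha exactly when
# the DP transition is valid: into M(i,j) from any state at (i' in N+(i),
# j' in N+(j)); into I(i,j) from any state at (i, j' in N+(j)); into D(i,j)
# from any state at (i' in N+(i), j). Start feeds columns whose implied
# predecessor position is (Start, Start); End collects columns whose
# position is end-adjacent on both sides.
build_combined_network <- function(admitted, netA, netB, meta) {
  VA <- n_vertices(netA); VB <- n_vertices(netB)
  k <- length(netA$ids); l <- length(netB$ids)
  ids <- c(netA$ids, netB$ids)
  V <- nrow(admitted)
  stc <- match(admitted$state, c("M", "I", "D"))
  idmap <- array(0L, dim = c(VA + 1L, VB + 1L, 3L))
  idmap[cbind(admitted$i + 1L, admitted$j + 1L, stc)] <- seq_len(V)

  # index by vertex+1; pred lists already contain 0 for Start-adjacent
  predsA <- c(list(integer()), netA$pred)
  predsB <- c(list(integer()), netB$pred)
  endA <- netA$end_pred; endB <- netB$end_pred
  if (VA == 0L) endA <- 0L
  if (VB == 0L) endB <- 0L

  cols <- matrix(GAP, k + l, V, dimnames = list(ids, NULL))
  gapk <- rep(GAP, k); gapl <- rep(GAP, l)
  pred <- vector("list", V)
  for (v in seq_len(V)) {
    i <- admitted$i[v]; j <- admitted$j[v]; s <- admitted$state[v]
    cols[, v] <- switch(s,
      M = c(netA$cols[, i], netB$cols[, j]),
      I = c(gapk, netB$cols[, j]),
      D = c(netA$cols[, i], gapl))
    pi <- switch(s, M = predsA[[i + 1L]], I = i, D = predsA[[i + 1L]])
    pj <- switch(s, M = predsB[[j + 1L]], I = predsB[[j + 1L]], D = j)
    p <- integer()
    for (ip in pi) for (jp in pj) {
      if (ip == 0L && jp == 0L) p <- c(p, 0L)
      trio <- idmap[ip + 1L, jp + 1L, ]
      p <- c(p, trio[trio > 0L])
    }
    pred[[v]] <- sort(unique(p))
  }
  succ <- rep(list(integer()), V)
  end_pred <- integer()
  for (v in seq_len(V)) {
    for (p in pred[[v]]) if (p >= 1L) succ[[p]] <- c(succ[[p]], v)
    if (admitted$i[v] %in% endA && admitted$j[v] %in% endB) {
      succ[[v]] <- c(succ[[v]], V + 1L)
      end_pred <- c(end_pred, v)
    }
  }
  succ <- lapply(succ, function(x) sort(unique(x)))
  start_succ <- which(vapply(pred, function(p) 0L %in% p, TRUE))
  rownames(admitted) <- NULL
  new_aln_network(ids, cols, admitted$state, pred, succ, start_succ,
                  end_pred, origin = admitted, meta = meta)
}
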