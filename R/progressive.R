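# The reticular progressive driver: guide-tree traversal, per-node
# x-network construction, and best-alignment extraction.

# Chain network holding exactly one multiple alignment (used by the
# best-only baseline mode and for single sequences).
chain_network <- function(aln, meta = list()) {
  m <- as.matrix(aln)
  V <- ncol(m)
  state <- if (!is.null(aln$state)) aln$state else rep("M", V)
  if (V == 0L)
    return(new_aln_network(rownames(m), m, character(), list(), list(),
                           start_succ = 1L, end_pred = 0L, meta = meta))
  new_aln_network(rownames(m), m, state,
                  pred = as.list(0:(V - 1L)), succ = as.list(2:(V + 1L)),
                  start_succ = 1L, end_pred = V, meta = meta)
}

#' Extract the best-scoring alignment stored in a network
#'
#' Dynamic programme over the DAG maximising the path score under the
#' scheme's objective (the internal score in pairwise mode; the
#' cross-group objective in ClustalW-imitation mode). Ties are broken
#' deterministically: state M before D before I, then the smaller column id.
#'
#' @param net An `"aln_network"`.
#' @param scheme A [retalign_scheme()].
#' @return An [msa]; attribute `score` holds the path score.
#' @export
extract_best <- function(net, scheme) {
  V <- n_vertices(net)
  ids <- net$ids
  if (V == 0L) {
    out <- msa(net$cols)
    attr(out, "score") <- 0
    return(out)
  }
  w <- scheme_weights(scheme, ids)
  clustal <- scheme$mode == "clustalw" && !is.null(net$meta$k)
  k <- net$meta$k
  gA <- if (clustal) seq_len(k) else integer()
  gB <- if (clustal) (k + 1L):length(ids) else integer()

  simv <- vapply(seq_len(V), function(v) {
    if (clustal) clustalw_similarity_column(net$cols[, v], gA, gB, scheme,
                                            weights = w)
    else similarity_column(net$cols[, v], scheme, weights = w)
  }, 0)
  colof <- function(v) if (v == 0L || v > V) "boundary" else net$cols[, v]
  ts <- function(p, v) {
    if (clustal) clustalw_indel(colof(p), colof(v), gA, gB, scheme)
    else indel_column_pair(colof(p), colof(v), scheme, weights = w)
  }

  strank <- c(M = 1L, D = 2L, I = 3L)[net$state]
  score <- numeric(V)
  back <- integer(V)
  for (v in seq_len(V)) {
    ps <- net$pred[[v]]
    vals <- vapply(ps, function(p) (if (p == 0L) 0 else score[p]) + ts(p, v), 0)
    best <- max(vals)
    cand <- ps[vals >= best - 1e-9]
    # ties: Start (rank 0) then state M < D < I, then smaller id
    cr <- ifelse(cand == 0L, 0L, strank[pmax(cand, 1L)])
    pick <- cand[order(cr, cand)][1L]
    back[v] <- pick
    score[v] <- best + simv[v]
  }
  ev <- vapply(net$end_pred, function(e) score[e] + ts(e, V + 1L), 0)
  best <- max(ev)
  cand <- net$end_pred[ev >= best - 1e-9]
  cr <- strank[cand]
  cur <- cand[order(cr, cand)][1L]
  path <- integer()
  while (cur != 0L) {
    path <- c(cur, path)
    cur <- back[cur]
  }
  cols <- net$cols[, path, drop = FALSE]
  rownames(cols) <- ids
  out <- msa(cols, state = net$state[path])
  attr(out, "score") <- best
  out
}

#' Reticular progressive multiple sequence alignment
#'
#' Aligns protein sequences progressively along a guide tree, keeping at
#' every internal node a network of optimal and suboptimal alignments (the
#' x-network of the two child networks) rather than a single alignment.
#' The threshold `t` caps each node's network at `(t + 100)%` of the best
#' alignment's column count: `t = 0` mimics a standard progressive aligner
#' (only optimal columns are kept), larger `t` searches the alignment space
#' more deeply, and `t = Inf` is an exhaustive search.
#'
#' @param seqs Named character vector of protein sequences (or a
#'   `Biostrings::AAStringSet`).
#' @param t Reticular threshold, `>= 0` (percent surplus network size).
#' @param scheme A [retalign_scheme()]; its weights slot is overwritten by
#'   the tree-derived weights when `weighting = TRUE`.
#' @param tree Optional user guide tree: a [ape::phylo] object, newick
#'   string or file. Unrooted trees are mid-point rooted; multifurcations
#'   are resolved deterministically.
#' @param tree_method `"nj"` (neighbour joining, mid-point rooted) or
#'   `"upgma"`, used when no tree is supplied.
#' @param weighting Use ClustalW-style tree-derived sequence weights.
#' @param single_best Baseline mode: collapse every node's network to its
#'   single best alignment (a classical progressive aligner).
#' @param keep_networks Keep each internal node's network in the result.
#' @return An object of class `"retalign"`: list with `alignment` (an
#'   [msa], rows in input order), `score` (its internal score), `network`
#'   (the root x-network), `tree`, `weights`, `report` (one row per
#'   internal node: network sizes, opt, x_effective, admitted group count),
#'   `scheme` and `t`.
#' @examples
#' sch <- retalign_scheme()
#' fit <- retalign(c(s1 = "ALLGVGQ", s2 = "AVGQ", s3 = "ALGVQ"), t = 100,
#'                 scheme = sch)
#' fit
#' @export
retalign <- function(seqs, t = 0, scheme = retalign_scheme(), tree = NULL,
                     tree_method = c("nj", "upgma"), weighting = TRUE,
                     single_best = FALSE, keep_networks = FALSE) {
  tree_method <- match.arg(tree_method)
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("sequences must have unique non-empty names")
  residue_check(unlist(strsplit(unname(seqs), "")), scheme)

  if (length(seqs) == 1L) {
    net <- seq_network(seqs[[1L]], ids)
    aln <- msa(net$cols)
    out <- list(alignment = aln, score = internal_score(aln, scheme),
                network = net, tree = NULL,
                weights = setNames(1, ids), report = node_report_frame(),
                scheme = scheme, t = t, call = match.call())
    class(out) <- "retalign"
    return(out)
  }

  if (is.null(tree)) {
    D <- seq_distances(seqs, scheme)
    tree <- guide_tree(D, tree_method)
    if (tree_method == "nj") tree <- midpoint_root(tree)
  } else {
    tree <- prepare_guide_tree(tree, ids)
  }

  weights <- if (weighting) sequence_weights(tree)
             else setNames(rep(1, length(ids)), ids)
  scheme$weights <- weights / mean(weights)

  ntip <- length(tree$tip.label)
  children <- lapply(seq_len(ntip + tree$Nnode), function(nd)
    tree$edge[tree$edge[, 1L] == nd, 2L])
  nets <- vector("list", ntip + tree$Nnode)
  for (tip in seq_len(ntip))
    nets[[tip]] <- seq_network(seqs[[tree$tip.label[tip]]],
                               tree$tip.label[tip])

  postorder <- postorder_nodes(tree)
  report <- vector("list", length(postorder))
  kept <- if (keep_networks) vector("list", length(postorder)) else NULL
  for (s in seq_along(postorder)) {
    nd <- postorder[s]
    ch <- children[[nd]]
    if (length(ch) != 2L) stop("guide tree is not binary at node ", nd)
    net <- align_networks(nets[[ch[1L]]], nets[[ch[2L]]], scheme, t = t)
    report[[s]] <- data.frame(
      node = nd, n_left = n_vertices(nets[[ch[1L]]]),
      n_right = n_vertices(nets[[ch[2L]]]),
      n_vertices = n_vertices(net), L_opt = net$meta$L_opt,
      size_cap = net$meta$size_cap, opt = net$meta$opt,
      x_effective = net$meta$x_effective, n_groups = net$meta$n_groups)
    if (keep_networks) kept[[s]] <- net
    if (single_best && s < length(postorder)) {
      best <- extract_best(net, scheme)
      net <- chain_network(best, meta = net$meta)
    }
    nets[[nd]] <- net
  }
  root_net <- nets[[postorder[length(postorder)]]]
  aln <- extract_best(root_net, scheme)
  m <- as.matrix(aln)[ids, , drop = FALSE]
  aln_out <- msa(m, state = aln$state)
  out <- list(alignment = aln_out,
              score = internal_score(aln_out, scheme),
              network = root_net, tree = tree, weights = scheme$weights,
              report = do.call(rbind, report), scheme = scheme, t = t,
              networks = kept, call = match.call())
  class(out) <- "retalign"
  out
}

#' Standard progressive alignment (the t = 0 limit)
#'
#' The package's best-only progressive aligner: at every guide-tree node
#' only the columns of (co-)optimal alignments are retained, which is
#' exactly the `t = 0` limit of [retalign()] and runs through the same code
#' path. A stricter classical baseline that collapses every node to one
#' single best alignment is available via `retalign(..., single_best =
#' TRUE)`; it can score below the `t = 0` run whenever co-optimal
#' alternatives at a node enable a better-scoring parent alignment.
#'
#' @inheritParams retalign
#' @param ... Passed on to [retalign()].
#' @return A `"retalign"` object, see [retalign()].
#' @export
progressive_align <- function(seqs, ...) retalign(seqs, t = 0, ...)

node_report_frame <- function() {
  data.frame(node = integer(), n_left = integer(), n_right = integer(),
             n_vertices = integer(), L_opt = integer(), size_cap = double(),
             opt = double(), x_effective = double(), n_groups = integer())
}

# children-before-parent order of the internal nodes of a rooted tree
postorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer()
  walk <- function(nd) {
    if (nd <= ntip) return()
    for (ch in tree$edge[tree$edge[, 1L] == nd, 2L]) walk(ch)
    out <<- c(out, nd)
  }
  walk(root)
  out
}

#' @export
print.retalign <- function(x, ...) {
  cat("Reticular progressive alignment\n")
  cat(sprintf("  %d sequences, %d columns, internal score %.4g, t = %s\n",
              length(x$alignment$ids), ncol(as.matrix(x$alignment)),
              x$score, format(x$t)))
  if (!is.null(x$network$meta$opt))
    cat(sprintf("  root network: %d columns, %s stored alignments\n",
                n_vertices(x$network),
                format(count_alignments(x$network))))
  cat("\n")
  print(x$alignment)
  invisible(x)
}

#' @export
summary.retalign <- function(object, ...) {
  cat("Reticular progressive alignment\n")
  cat(sprintf("  threshold t = %s, mode = %s, weighting %s\n",
              format(object$t), object$scheme$mode,
              if (all(object$weights == 1)) "off" else "on"))
  cat(sprintf("  internal score: %.6g\n", object$score))
  if (nrow(object$report)) {
    cat("\nPer-node report (children before parents):\n")
    print(object$report, row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.retalign <- function(x, ...) {
  if (is.null(x$tree)) {
    warning("single-sequence result; nothing to plot")
    return(invisible(x))
  }
  ape::plot.phylo(x$tree, ...)
  invisible(x)
}
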