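# Guide-tree construction: pairwise DP distances, NJ/UPGMA, mid-point
# rooting, and ClustalW-style tree-derived sequence weights.

#' Pairwise alignment distances between sequences
#'
#' Full dynamic-programming alignment between each pair of sequences;
#' similarity scores are turned into distances as
#' `D_ij = S_ii + S_jj - 2 * S_ij`. Negative values (possible for
#' high-scoring unrelated pairs under arbitrary matrices) are clamped to 0
#' with a warning.
#'
#' @param seqs Named character vector of sequences.
#' @param scheme A [retalign_scheme()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
seq_distances <- function(seqs, scheme) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must have unique names")
  self <- vapply(seqs, function(s) pairwise_opt(s, s, scheme), 0)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sij <- pairwise_opt(seqs[[i]], seqs[[j]], scheme)
    D[i, j] <- D[j, i] <- self[i] + self[j] - 2 * sij
  }
  if (any(D < 0)) {
    warning("negative alignment distances clamped to 0")
    D[D < 0] <- 0
  }
  D
}

#' Build a guide tree from a distance matrix
#'
#' Neighbour joining (unrooted; root afterwards with [midpoint_root()]) or
#' UPGMA (rooted ultrametric tree).
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param method `"nj"` or `"upgma"`.
#' @return An [ape::phylo] tree.
#' @export
guide_tree <- function(D, method = c("nj", "upgma")) {
  method <- match.arg(method)
  if (any(!is.finite(D))) stop("non-finite distances")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
               edge.length = rep(D[1L, 2L] / 2, 2L),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  if (method == "nj") ape::nj(stats::as.dist(D))
  else phangorn::upgma(stats::as.dist(D))
}

#' Root a tree at the mid-point of its longest leaf-to-leaf path
#'
#' Standard mid-point rooting; the resulting rooted binary tree minimises
#' the maximum root-to-leaf depth. Trees whose branch lengths are all zero
#' cannot be mid-point rooted meaningfully and are rooted at a
#' deterministically chosen edge with a warning.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A rooted binary [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip == 2L) {
    total <- sum(tree$edge.length)
    tr <- tree
    tr$edge.length <- rep(total / 2, 2L)
    return(tr)
  }
  if (is.null(tree$edge.length) || all(tree$edge.length == 0)) {
    warning("all branch lengths zero; rooting at an arbitrary internal edge")
    tree <- ape::unroot(tree)
    rooted <- ape::root(tree, outgroup = sort(tree$tip.label)[1L],
                        resolve.root = TRUE)
    return(rooted)
  }
  phangorn::midpoint(tree)
}

#' Tree-derived sequence weights
#'
#' ClustalW-style weighting from a rooted guide tree: each branch length is
#' divided equally among the leaves below it, and a leaf's weight is the sum
#' of its shares along its root path. Members of overrepresented clades
#' share their deep branches and so receive smaller weights. Weights are
#' rescaled to mean 1 so weighted and unweighted scores are comparable.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return Named numeric weights, one per leaf, mean 1.
#' @export
sequence_weights <- function(tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using equal weights")
    return(setNames(rep(1, ntip), tree$tip.label))
  }
  w <- setNames(rep(0, ntip), tree$tip.label)
  # leaves below each edge
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], type = "tips")
  for (e in seq_len(nrow(tree$edge))) {
    tips <- desc[[e]]
    w[tips] <- w[tips] + tree$edge.length[e] / length(tips)
  }
  if (all(w == 0)) return(setNames(rep(1, ntip), tree$tip.label))
  w / mean(w)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D Symmetric distance matrix with dimnames.
#' @param path Output file.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(format(D[i, ], trim = TRUE), collapse = " ")),
               con)
  invisible(path)
}

# Prepare a user-supplied or constructed tree for the progressive pass:
# rooted, binary, leaves matching the sequence ids.
prepare_guide_tree <- function(tree, ids) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("guide tree must be a phylo object, file or newick string")
  if (!setequal(tree$tip.label, ids))
    stop("guide tree leaves do not match the sequence names")
  if (!ape::is.binary(tree)) {
    warning("multifurcating guide tree resolved into binary nodes with zero-length edges")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}
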