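# Tree-based synthetic sequence generator: evolves a root sequence down a
# guide tree with substitutions and geometric-length indels, tracking the
# event history so the true alignment of the leaves is known.

#' Random tree for synthetic families
#'
#' Random topology with uniform branch lengths, reproducible per seed.
#'
#' @param n_leaves Number of leaves.
#' @param seed Integer seed.
#' @param min_bl,max_bl Branch length range (substitutions per site scale).
#' @return A rooted binary [ape::phylo] tree with leaves `t1..tn`.
#' @export
synth_tree <- function(n_leaves, seed = 1L, min_bl = 0.15, max_bl = 0.5) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE,
                     br = function(n) stats::runif(n, min_bl, max_bl))
  tree$tip.label <- paste0("t", seq_len(n_leaves))
  tree
}

#' Generate a synthetic protein family with its true alignment
#'
#' A random root sequence evolves along each branch: every site is
#' substituted with probability `1 - exp(-sub_rate * l)` (`l` the branch
#' length), replacement residues drawn with BLOSUM-biased probabilities
#' proportional to `2^(s(a, b) / 2)`; insertion/deletion events arrive at
#' rate `indel_rate` per site per unit branch length, with geometric
#' lengths of mean `mean_indel_len` and uniform positions. Homology columns
#' are tracked through all events, so the returned alignment is the true
#' one implied by the history. Fully deterministic for a fixed seed.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths (for example
#'   from [synth_tree()]).
#' @param root_len Length of the root sequence.
#' @param sub_rate Substitution rate per site per unit branch length.
#' @param indel_rate Indel event rate per site per unit branch length.
#' @param mean_indel_len Mean indel length (geometric).
#' @param seed Integer seed.
#' @param scheme Scheme providing the substitution bias (default BLOSUM62).
#' @return List with `sequences` (named by leaf), `alignment` (the true
#'   [msa] of the leaves), `tree` and the parameters.
#' @examples
#' fam <- synth_msa(synth_tree(4, seed = 7), root_len = 20, seed = 7)
#' fam$alignment
#' @export
synth_msa <- function(tree, root_len = 25L, sub_rate = 1.3, indel_rate = 0.06,
                      mean_indel_len = 2, seed = 1L,
                      scheme = retalign_scheme()) {
  stopifnot(sub_rate >= 0, indel_rate >= 0, mean_indel_len >= 1,
            root_len >= 1)
  force(tree) # tree builders may seed the RNG; evaluate before seeding
  set.seed(seed)
  res <- rownames(scheme$s)
  # substitution profile: P(b | a) over b != a, BLOSUM-biased
  subprob <- 2^(scheme$s / 2)
  diag(subprob) <- 0
  subprob <- sweep(subprob, 1L, rowSums(subprob), "/")

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  next_id <- root_len + 1L
  master <- seq_len(root_len) # global homology column order
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[root]] <- list(res = sample(res, root_len, replace = TRUE),
                           col = seq_len(root_len))

  evolve <- function(state, bl) {
    r <- state$res; cols <- state$col
    L <- length(r)
    if (L && sub_rate > 0) {
      hit <- which(stats::runif(L) < 1 - exp(-sub_rate * bl))
      for (i in hit) r[i] <- sample(res, 1L, prob = subprob[r[i], ])
    }
    n_ev <- stats::rpois(1L, indel_rate * bl * max(L, 1L))
    for (ev in seq_len(n_ev)) {
      len <- stats::rgeom(1L, 1 / mean_indel_len) + 1L
      if (stats::runif(1L) < 0.5 && length(r) > 0L) { # deletion
        pos <- sample.int(length(r), 1L)
        drop <- pos:min(pos + len - 1L, length(r))
        r <- r[-drop]; cols <- cols[-drop]
      } else { # insertion after position pos (0 = front)
        pos <- sample.int(length(r) + 1L, 1L) - 1L
        ids <- next_id:(next_id + len - 1L)
        next_id <<- next_id + len
        anchor <- if (pos == 0L) 0L else cols[pos]
        at <- if (anchor == 0L) 0L else match(anchor, master)
        master <<- append(master, ids, after = at)
        r <- append(r, sample(res, len, replace = TRUE), after = pos)
        cols <- append(cols, ids, after = pos)
      }
    }
    list(res = r, col = cols)
  }

  tree <- stats::reorder(tree, "cladewise") # parents before children
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    node_seq[[child]] <- evolve(node_seq[[parent]], tree$edge.length[e])
  }

  leaves <- tree$tip.label
  leaf_states <- node_seq[seq_len(ntip)]
  used <- sort(unique(unlist(lapply(leaf_states, `[[`, "col"))))
  order_used <- master[master %in% used]
  m <- matrix(GAP, ntip, length(order_used),
              dimnames = list(leaves, NULL))
  for (tip in seq_len(ntip)) {
    st <- leaf_states[[tip]]
    m[tip, match(st$col, order_used)] <- st$res
  }
  seqs <- setNames(vapply(seq_len(ntip), function(tip)
    paste(leaf_states[[tip]]$res, collapse = ""), ""), leaves)
  if (any(!nzchar(seqs)))
    warning("a leaf sequence became empty during simulation")
  list(sequences = seqs, alignment = msa(m), tree = tree,
       params = list(root_len = root_len, sub_rate = sub_rate,
                     indel_rate = indel_rate,
                     mean_indel_len = mean_indel_len, seed = seed))
}
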