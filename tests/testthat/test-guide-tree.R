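sch <- retalign_scheme()

test_that("alignment-score distances are symmetric, zero-diagonal and
           zero for identical sequences", {
  seqs <- c(a = "ACDEF", b = "ACDFF", c = "ACDEF", d = "WYHKM")
  D <- seq_distances(seqs, sch)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))
  expect_equal(D["a", "c"], 0)  # identical sequences
  sab <- pairwise_opt(seqs["a"], seqs["b"], sch)
  expect_equal(D["a", "b"],
               pairwise_opt(seqs["a"], seqs["a"], sch) +
                 pairwise_opt(seqs["b"], seqs["b"], sch) - 2 * sab)
})

test_that("NJ recovers additive trees, UPGMA recovers ultrametric trees", {
  # additive matrix from a known 4-taxon tree:
  # ((a:2,b:3):1,(c:4,d:5)) internal edge 1
  ids <- c("a", "b", "c", "d")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 5
  D["a", "c"] <- D["c", "a"] <- 7
  D["a", "d"] <- D["d", "a"] <- 8
  D["b", "c"] <- D["c", "b"] <- 8
  D["b", "d"] <- D["d", "b"] <- 9
  D["c", "d"] <- D["d", "c"] <- 9
  tr <- guide_tree(D, "nj")
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[ids, ids]),
               unname(D))
  # ultrametric matrix: ((a:1,b:1):2,(c:2,d:2):1) heights 1,2,3
  U <- matrix(6, 4, 4, dimnames = list(ids, ids))
  diag(U) <- 0
  U["a", "b"] <- U["b", "a"] <- 2
  U["c", "d"] <- U["d", "c"] <- 4
  tu <- guide_tree(U, "upgma")
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tu))[ids, ids]),
               unname(U))
  expect_true(ape::is.rooted(tu))
  # two taxa: a single split
  t2 <- guide_tree(D[1:2, 1:2], "nj")
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(sum(t2$edge.length), 5)
})

test_that("mid-point rooting minimises the maximum root-to-leaf depth", {
  # two leaves with branch lengths 3 and 1: root sits 2 from the first
  t2 <- guide_tree(matrix(c(0, 4, 4, 0), 2, 2,
                          dimnames = list(c("x", "y"), c("x", "y"))), "nj")
  r2 <- midpoint_root(t2)
  expect_equal(unname(r2$edge.length), c(2, 2))
  # symmetric quartet roots on the central edge
  set.seed(81)
  for (rep in 1:6) {
    tr <- ape::rtree(sample(4:7, 1))
    rooted <- midpoint_root(ape::unroot(tr))
    depth <- function(phy) {
      nt <- length(phy$tip.label)
      max(ape::dist.nodes(phy)[nt + 1L, seq_len(nt)])
    }
    # brute force: minimal achievable max depth over all rootings along edges
    ut <- ape::unroot(tr)
    dmat <- ape::cophenetic.phylo(ut)
    best_possible <- max(dmat) / 2
    expect_equal(depth(rooted), best_possible, tolerance = 1e-8)
  }
})

test_that("all-zero branch lengths fall back to a deterministic rooting", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_warning(r <- midpoint_root(ape::unroot(tr)), "zero")
  expect_true(ape::is.rooted(r))
})

test_that("tree-derived weights divide shared branches equally", {
  # two leaves: pre-normalisation weights are the branch lengths
  t2 <- ape::read.tree(text = "(a:3,b:1);")
  w2 <- sequence_weights(t2)
  expect_equal(unname(w2[c("a", "b")]), c(3, 1) / 2)
  # caterpillar: hand computation of the shared-branch partition
  tc <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:4);")
  wc <- sequence_weights(tc)
  raw <- c(a = 1 + 1 / 2 + 1 / 3, b = 1 + 1 / 2 + 1 / 3,
           c = 2 + 1 / 3, d = 4)
  expect_equal(unname(wc[names(raw)]), unname(raw / mean(raw)))
  # star-like: equal branch lengths give equal weights
  ts <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):0);")
  expect_equal(unname(sequence_weights(ts)), rep(1, 4))
  # members of a tight clade are down-weighted against a lone leaf
  tt <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.2):2,d:2.2);")
  wt <- sequence_weights(tt)
  expect_true(all(wt[c("a", "b", "c")] < wt["d"]))
})

test_that("tree building is equivariant under relabelling", {
  set.seed(82)
  seqs <- setNames(vapply(1:5, function(i) random_protein(8), ""),
                   letters[1:5])
  D <- seq_distances(seqs, sch)
  perm <- c(3, 1, 5, 2, 4)
  Dp <- D[perm, perm]
  t1 <- guide_tree(D, "upgma")
  t2 <- guide_tree(Dp, "upgma")
  expect_equal(ape::cophenetic.phylo(t1)[names(seqs), names(seqs)],
               ape::cophenetic.phylo(t2)[names(seqs), names(seqs)])
})

test_that("PHYLIP export and newick preparation behave", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile()
  write_phylip_dist(D, f)
  lines <- readLines(f)
  expect_equal(trimws(lines[1]), "2")
  expect_equal(length(lines), 3L)
  # multifurcating user tree resolved with a warning
  expect_warning(
    tr <- prepare_guide_tree("(a:1,b:1,c:1,d:1);", c("a", "b", "c", "d")),
    "multifurcating")
  expect_true(ape::is.binary(tr))
  expect_error(prepare_guide_tree("(a:1,b:1);", c("a", "x")), "leaves")
})
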