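sch <- retalign_scheme()

test_that("column similarity matches the naive double loop", {
  expect_equal(similarity_column(c("A", "-", "-"), sch), 0)
  expect_equal(similarity_column(c("A", "A"), sch), sch$s["A", "A"])
  set.seed(41)
  for (rep in 1:20) {
    k <- 12L
    cells <- sample(c(AA_RESIDUES[1:6], "-"), k, TRUE)
    w <- runif(k, 0.3, 2)
    naive <- 0
    for (r in 1:(k - 1)) for (t2 in (r + 1):k)
      if (cells[r] != "-" && cells[t2] != "-")
        naive <- naive + w[r] * w[t2] * sch$s[cells[r], cells[t2]]
    expect_equal(similarity_column(cells, sch, weights = w), naive)
  }
})

test_that("column-pair indel scores follow the pattern matrix", {
  # two rows: one continues a gap, the other stays residue -> extension
  expect_equal(indel_column_pair(c("-", "A"), c("-", "C"), sch), sch$EX)
  # deletion immediately followed by insertion -> full opening
  expect_equal(indel_column_pair(c("-", "A"), c("A", "-"), sch), sch$OP)
  expect_error(indel_column_pair(c("-", "A"), c("A"), sch), "row set")
})

test_that("a length-3 insertion scores OP + 2*EX in total", {
  m <- rbind(a = c("K", "-", "-", "-", "W", "F", "R"),
             b = c("K", "A", "A", "A", "W", "F", "R"))
  mb <- cbind("X", m, "X")
  indel_total <- sum(vapply(seq_len(ncol(mb) - 1L), function(j)
    indel_column_pair(mb[, j], mb[, j + 1L], sch), 0))
  expect_equal(indel_total, sch$OP + 2 * sch$EX)
})

test_that("internal score equals the affine pairwise score on 2 rows", {
  set.seed(42)
  for (rep in 1:25) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    states <- sample(enum_pair_alignments(a, b), 1)[[1]]
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    i <- 0L; j <- 0L
    m <- matrix("-", 2L, length(states), dimnames = list(c("r1", "r2"), NULL))
    for (cc in seq_along(states)) {
      st <- states[cc]
      if (st != "I") { i <- i + 1L; m[1, cc] <- av[i] }
      if (st != "D") { j <- j + 1L; m[2, cc] <- bv[j] }
    }
    expect_equal(internal_score(msa(m), sch),
                 affine_score_states(states, av, bv, sch))
  }
})

test_that("internal score is reverse-symmetric and row-permutation invariant", {
  set.seed(43)
  fam <- synth_msa(synth_tree(4, seed = 5), root_len = 12, seed = 5)
  m <- as.matrix(fam$alignment)
  w <- setNames(runif(nrow(m), 0.5, 1.5), rownames(m))
  schw <- retalign_scheme(weights = w)
  s1 <- internal_score(msa(m), schw)
  expect_equal(internal_score(msa(m[, rev(seq_len(ncol(m)))]), schw), s1)
  perm <- sample(nrow(m))
  expect_equal(internal_score(msa(m[perm, ]), schw), s1)
})

test_that("fast pair summation equals the naive double loop", {
  set.seed(44)
  M <- sch$T4
  for (rep in 1:20) {
    v <- sample(rownames(M), 15, TRUE)
    w <- runif(15, 0.2, 3)
    naive <- 0
    for (i in 1:15) for (j in 1:15) naive <- naive + w[i] * w[j] * M[v[i], v[j]]
    tal <- rowsum(w, v)[, 1]
    expect_equal(fast_pair_sum(tal, M), naive)
  }
  # closed forms
  expect_equal(fast_pair_sum(c("--" = 2), M), 4 * M["--", "--"])
  expect_equal(fast_pair_sum(c("-*" = 1.5), M), 2.25 * M["-*", "-*"])
})

test_that("ambiguous-pattern choice: exact for gap-closing cases, harsher for
           gap-extending ones", {
  # A row pair seen through a window where the second row is gapped and the
  # first row encloses all-gap columns. The pattern-matrix contribution is
  # the sum of T4 over consecutive column pairs of the window; the true
  # sum-of-pairs contribution is the T4 value of the adjoining pattern left
  # after removing the columns where both rows are gapped.
  T4 <- sch$T4
  window_score <- function(r1, r2) {
    p1 <- strsplit(r1, "")[[1]]; p2 <- strsplit(r2, "")[[1]]
    sum(vapply(seq_len(length(p1) - 1L), function(j)
      T4[paste0(p1[j], p1[j + 1L]), paste0(p2[j], p2[j + 1L])], 0))
  }
  degapped_pattern <- function(r1, r2) {
    m <- rbind(strsplit(r1, "")[[1]], strsplit(r2, "")[[1]])
    m <- m[, colSums(m != "-") > 0, drop = FALSE]
    T4[paste0(m[1, 1], m[1, 2]), paste0(m[2, 1], m[2, 2])]
  }
  # gap extended through the window: true contribution is EX, the matrix
  # charges a full OP -- a systematically harsher penalty
  expect_equal(window_score("*--*", "----"), sch$OP)
  expect_equal(degapped_pattern("*--*", "----"), sch$EX)
  expect_lt(window_score("*--*", "----"), degapped_pattern("*--*", "----"))
  # gap closing cases are matched exactly
  expect_equal(window_score("*---", "---*"), degapped_pattern("*---", "---*"))
  expect_equal(window_score("*--*", "---*"), degapped_pattern("*--*", "---*"))
})

test_that("clustalw-imitation similarity counts cross pairs only", {
  cells <- c("A", "C", "-", "A", "W")
  gA <- 1:2; gB <- 3:5
  expect_equal(clustalw_similarity_column(cells, gA, gB, sch),
               sch$s["A", "A"] + sch$s["A", "W"] +
                 sch$s["C", "A"] + sch$s["C", "W"])
  # full insertion column scores zero
  expect_equal(clustalw_similarity_column(c("-", "-", "A", "A", "C"),
                                          gA, gB, sch), 0)
  # 1-vs-1 match column agrees with pairwise mode
  expect_equal(clustalw_similarity_column(c("A", "W"), 1L, 2L, sch),
               similarity_column(c("A", "W"), sch))
  set.seed(45)
  for (rep in 1:10) {
    cells <- sample(c(AA_RESIDUES[1:5], "-"), 7, TRUE)
    naive <- 0
    for (r in 1:3) for (t2 in 4:7)
      if (cells[r] != "-" && cells[t2] != "-")
        naive <- naive + sch$s[cells[r], cells[t2]]
    expect_equal(clustalw_similarity_column(cells, 1:3, 4:7, sch), naive)
  }
})

test_that("clustalw-imitation indel charges one penalty per event", {
  gA <- 1:2; gB <- 3:4
  mcol <- c("A", "C", "A", "C")
  icol <- c("-", "-", "A", "C")  # insertion: group A all gap
  expect_equal(clustalw_indel(mcol, icol, gA, gB, sch), sch$OP)
  expect_equal(clustalw_indel(icol, icol, gA, gB, sch), sch$EX)
  expect_equal(clustalw_indel(mcol, mcol, gA, gB, sch), 0)
  # run of 3 insertions: OP + 2*EX
  run <- list(mcol, icol, icol, icol, mcol)
  tot <- sum(vapply(1:4, function(i)
    clustalw_indel(run[[i]], run[[i + 1]], gA, gB, sch), 0))
  expect_equal(tot, sch$OP + 2 * sch$EX)
})

test_that("unknown residues are rejected by name", {
  expect_error(similarity_column(c("A", "Z"), sch), "Z")
  expect_error(pairwise_forward("AB", "A", sch), "B")
})
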