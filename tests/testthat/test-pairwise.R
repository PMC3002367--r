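sch <- retalign_scheme()

test_that("forward initialisation and boundary rows are as defined", {
  f <- pairwise_forward("ACD", "WY", sch)
  expect_equal(f$M["0", "0"], 0)
  expect_equal(f$I["0", "0"], -Inf)
  expect_equal(f$D["0", "0"], -Inf)
  expect_equal(f$D["3", "0"], sch$OP + 2 * sch$EX)  # -12 at defaults
  expect_equal(f$I["0", "2"], sch$OP + sch$EX)
  expect_equal(f$M["2", "0"], -Inf)
})

test_that("backward initialisation and boundary rows are as defined", {
  b <- pairwise_backward("ACDEF", "WYHK", sch)
  n <- 5; m <- 4
  expect_equal(b$M[n + 1, m + 1], 0)
  expect_equal(b$I[n + 1, m + 1], 0)
  expect_equal(b$D[n + 1, m + 1], 0)
  expect_equal(b$M[n, m + 1], sch$OP)       # one trailing deletion, M context
  expect_equal(b$I[n, m + 1], sch$OP)
  expect_equal(b$M["1", as.character(m)], sch$OP + (n - 1 - 1) * sch$EX)
  expect_equal(b$D["2", as.character(m)], (n - 2) * sch$EX)
  expect_equal(b$I[n + 1, "0"], m * sch$EX) # trailing insertions, I context
  expect_equal(b$M[n + 1, m], sch$OP)
})

test_that("optimum and per-column best scores match exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:15) {
    a <- random_protein(sample(1:5, 1))
    b <- random_protein(sample(1:5, 1))
    fwd <- pairwise_forward(a, b, sch)
    bwd <- pairwise_backward(a, b, sch)
    oracle <- brute_column_best(a, b, sch)
    expect_equal(fwd$opt, oracle$opt)
    cbs <- column_best_scores(fwd, bwd)
    expect_equal(nrow(cbs), length(ls(oracle$best)))
    for (r in seq_len(nrow(cbs))) {
      key <- paste(cbs$state[r], cbs$i[r], cbs$j[r])
      expect_equal(cbs$b[r], get(key, oracle$best), label = key)
    }
  }
})

test_that("columns on an optimal path attain b = opt", {
  fwd <- pairwise_forward("ALLGVGQ", "AVGQ", sch)
  bwd <- pairwise_backward("ALLGVGQ", "AVGQ", sch)
  cbs <- column_best_scores(fwd, bwd)
  expect_equal(max(cbs$b), fwd$opt)
  expect_equal(pairwise_forward("A", "A", sch)$opt, sch$s["A", "A"])
  # the single-match alignment is the only one containing a1/b1
  cbs1 <- column_best_scores(pairwise_forward("A", "A", sch),
                             pairwise_backward("A", "A", sch))
  expect_equal(cbs1$b[cbs1$state == "M"], sch$s["A", "A"])
})

test_that("x-network vertex sets match the enumeration threshold rule", {
  set.seed(32)
  for (rep in 1:8) {
    a <- random_protein(sample(2:5, 1))
    b <- random_protein(sample(2:5, 1))
    oracle <- brute_column_best(a, b, sch)
    for (x in c(0, 2, 5, Inf)) {
      net <- pairwise_x_network(a, b, x, sch)
      keys_net <- sort(paste(net$origin$state, net$origin$i, net$origin$j))
      keys_bf <- ls(oracle$best)
      vals <- vapply(keys_bf, function(k) get(k, oracle$best), 0)
      keys_bf <- sort(keys_bf[vals >= oracle$opt - x - 1e-9])
      expect_identical(keys_net, keys_bf)
      expect_true(validate_network(net)$valid)
    }
  }
})

test_that("x-networks grow monotonically and keep the optimal path score", {
  a <- "GHKLMVA"; b <- "GQKLV"
  prev <- character()
  for (x in c(0, 1, 3, 7, 15, Inf)) {
    net <- pairwise_x_network(a, b, x, sch)
    keys <- paste(net$origin$state, net$origin$i, net$origin$j)
    expect_true(all(prev %in% keys))
    best <- extract_best(net, sch)
    expect_equal(attr(best, "score"), net$meta$opt)
    prev <- keys
  }
})

test_that("a large enough x retains every feasible column and alignment", {
  a <- "AVG"; b <- "WY"
  net <- pairwise_x_network(a, b, Inf, sch)
  # Delannoy-style count of all global alignments of lengths 3 and 2
  expect_equal(count_alignments(net), length(enum_pair_alignments(a, b)))
})

test_that("swapping the sequences swaps I and D and transposes indices", {
  set.seed(33)
  for (rep in 1:5) {
    a <- random_protein(4); b <- random_protein(3)
    f1 <- pairwise_forward(a, b, sch)
    f2 <- pairwise_forward(b, a, sch)
    expect_equal(f1$M, t(f2$M))
    expect_equal(f1$I, t(f2$D))
    expect_equal(f1$D, t(f2$I))
    expect_equal(f1$opt, f2$opt)
    # b multiset invariant
    b1 <- column_best_scores(f1, pairwise_backward(a, b, sch))
    b2 <- column_best_scores(f2, pairwise_backward(b, a, sch))
    expect_equal(sort(b1$b), sort(b2$b))
  }
})
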