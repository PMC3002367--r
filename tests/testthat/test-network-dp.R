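sch <- retalign_scheme()

# small x-networks to use as inputs for network-vs-network tests
toy_networks <- function(seed, t = 100) {
  set.seed(seed)
  netA <- align_networks(seq_network(random_protein(3), "a1"),
                         seq_network(random_protein(2), "a2"), sch, t = t)
  netB <- align_networks(seq_network(random_protein(2), "b1"),
                         seq_network(random_protein(3), "b2"), sch, t = t)
  list(A = netA, B = netB)
}

test_that("network DP on single-sequence chains reproduces the pairwise
           tables cell for cell", {
  set.seed(51)
  for (rep in 1:10) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    fwd <- pairwise_forward(a, b, sch)
    bwd <- pairwise_backward(a, b, sch)
    tab <- network_backward(seq_network(a, "A"), seq_network(b, "B"), sch)
    n <- nchar(a); m <- nchar(b)
    expect_equal(tab$opt, fwd$opt)
    for (i in 1:n) for (j in 1:m) {
      expect_equal(tab$Mf[i + 1, j + 1], fwd$M[i + 1, j + 1])
      expect_equal(tab$Mb[i + 1, j + 1], bwd$M[i + 1, j + 1])
    }
    for (i in 0:n) for (j in 1:m) {
      expect_equal(tab$If[i + 1, j + 1], fwd$I[i + 1, j + 1])
      expect_equal(tab$Ib[i + 1, j + 1], bwd$I[i + 1, j + 1])
    }
    for (i in 1:n) for (j in 0:m) {
      expect_equal(tab$Df[i + 1, j + 1], fwd$D[i + 1, j + 1])
      expect_equal(tab$Db[i + 1, j + 1], bwd$D[i + 1, j + 1])
    }
  }
})

test_that("forward initialisation and empty-side behaviour", {
  a <- seq_network("AVG", "A")
  suppressWarnings(e <- seq_network("", "B"))
  tab <- network_forward(a, a, sch)
  expect_equal(tab$Mf["0", "0"], 0)
  expect_equal(tab$If["0", "0"], -Inf)
  expect_equal(tab$Df["0", "0"], -Inf)
  # aligning against an empty network: only deletion cells are finite
  tab2 <- network_forward(a, e, sch)
  expect_true(all(is.infinite(tab2$If)))
  expect_true(all(is.finite(tab2$Df[2:4, 1])))
  expect_equal(tab2$opt, sch$OP + 2 * sch$EX)
})

test_that("b-values over real networks match exhaustive cross enumeration", {
  for (seed in c(61, 62, 63)) {
    nets <- toy_networks(seed)
    tab <- network_backward(nets$A, nets$B, sch)
    oracle <- cross_network_oracle(nets$A, nets$B, sch)
    expect_equal(tab$opt, oracle$opt)
    VA <- ncol(nets$A$cols); VB <- ncol(nets$B$cols)
    get_tab_b <- function(st, i, j) {
      F <- tab[[paste0(st, "f")]]; B <- tab[[paste0(st, "b")]]
      F[as.character(i), as.character(j)] + B[as.character(i), as.character(j)]
    }
    keys <- ls(oracle$best)
    for (key in keys) {
      p <- strsplit(key, " ")[[1]]
      expect_equal(get_tab_b(p[1], p[2], p[3]), get(key, oracle$best),
                   label = key)
    }
    # DP produces no feasible column the oracle does not know
    for (st in c("M", "I", "D")) {
      bmat <- tab[[paste0(st, "f")]] + tab[[paste0(st, "b")]]
      idx <- which(is.finite(bmat), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1] - 1L; j <- idx[r, 2] - 1L
        if (i > VA || j > VB) next
        if (st == "M" && (i < 1 || j < 1)) next
        if (st == "I" && j < 1) next
        if (st == "D" && i < 1) next
        expect_true(paste(st, i, j) %in% keys)
      }
    }
  }
})

test_that("b-values with sequence weighting match the weighted oracle", {
  nets <- toy_networks(64)
  w <- c(a1 = 1.4, a2 = 0.6, b1 = 0.9, b2 = 1.1)
  schw <- retalign_scheme(weights = w)
  tab <- network_backward(nets$A, nets$B, schw)
  oracle <- cross_network_oracle(nets$A, nets$B, schw)
  expect_equal(tab$opt, oracle$opt)
  for (key in sample(ls(oracle$best), 20)) {
    p <- strsplit(key, " ")[[1]]
    F <- tab[[paste0(p[1], "f")]]; B <- tab[[paste0(p[1], "b")]]
    expect_equal(F[as.character(p[2]), as.character(p[3])] +
                   B[as.character(p[2]), as.character(p[3])],
                 get(key, oracle$best), label = key)
  }
})

test_that("the admitted vertex set equals the enumeration threshold rule", {
  nets <- toy_networks(65, t = 60)
  oracle <- cross_network_oracle(nets$A, nets$B, sch)
  for (t in c(0, 100, Inf)) {
    net <- align_networks(nets$A, nets$B, sch, t = t)
    x_eff <- net$meta$x_effective
    keys_net <- sort(paste(net$origin$state, net$origin$i, net$origin$j))
    keys <- ls(oracle$best)
    vals <- vapply(keys, function(k) get(k, oracle$best), 0)
    keys_bf <- sort(keys[vals >= oracle$opt - x_eff - 1e-9])
    expect_identical(keys_net, keys_bf)
  }
})

test_that("the admitted set is monotone in t and the best score constant", {
  nets <- toy_networks(66)
  prev <- character()
  for (t in c(0, 50, 100, 200, 400, 800)) {
    net <- align_networks(nets$A, nets$B, sch, t = t)
    keys <- paste(net$origin$state, net$origin$i, net$origin$j)
    expect_true(all(prev %in% keys))
    expect_equal(attr(extract_best(net, sch), "score"), net$meta$opt)
    prev <- keys
  }
})

test_that("the size cap counts columns of the best alignment", {
  nets <- toy_networks(67)
  net <- align_networks(nets$A, nets$B, sch, t = 50)
  expect_equal(net$meta$size_cap, ceiling(1.5 * net$meta$L_opt))
  expect_lte(ncol(net$cols),
             max(net$meta$size_cap, sum(round(net$origin$b, 9) ==
                                          round(net$meta$opt, 9))))
  t0 <- align_networks(nets$A, nets$B, sch, t = 0)
  expect_equal(t0$meta$x_effective, 0)
  expect_true(all(abs(t0$origin$b - t0$meta$opt) < 1e-6))
})

test_that("produced networks certify the lexicographic linear extension", {
  for (seed in 68:70) {
    nets <- toy_networks(seed)
    net <- align_networks(nets$A, nets$B, sch, t = 200)
    expect_true(edges_forward(net))
    o <- net$origin
    ord <- lexicographic_extension(o$i, o$j, o$state)
    expect_identical(ord, seq_len(nrow(o)))  # already stored in lex order
    expect_true(validate_network(net)$valid)
  }
})

test_that("chain x chain yields the row-major lexicographic order", {
  net <- align_networks(seq_network("AV", "A"), seq_network("GQ", "B"),
                        sch, t = Inf)
  o <- net$origin
  expect_identical(order(o$i, o$j, match(o$state, c("M", "I", "D"))),
                   seq_len(nrow(o)))
})

test_that("paths of a combined network restrict to paths of the children", {
  nets <- toy_networks(71)
  net <- align_networks(nets$A, nets$B, sch, t = 150)
  k <- length(nets$A$ids)
  child_paths_A <- lapply(network_paths(nets$A), function(p)
    apply(nets$A$cols[, p, drop = FALSE], 2, paste, collapse = ""))
  child_paths_B <- lapply(network_paths(nets$B), function(p)
    apply(nets$B$cols[, p, drop = FALSE], 2, paste, collapse = ""))
  alns <- enumerate_alignments(net, limit = 200L)
  for (al in alns[seq_len(min(25, length(alns)))]) {
    m <- as.matrix(al)
    mA <- m[seq_len(k), , drop = FALSE]
    keepA <- colSums(mA != "-") > 0
    sigA <- apply(mA[, keepA, drop = FALSE], 2, paste, collapse = "")
    expect_true(any(vapply(child_paths_A, identical, TRUE, x = sigA)))
    mB <- m[-seq_len(k), , drop = FALSE]
    keepB <- colSums(mB != "-") > 0
    sigB <- apply(mB[, keepB, drop = FALSE], 2, paste, collapse = "")
    expect_true(any(vapply(child_paths_B, identical, TRUE, x = sigB)))
  }
})
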