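# Tree distances and scaling.

test_that("newick round trip and outgroup rooting contracts", {
  tr <- readNewick(text = "((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3L)
  expect_true(ape::is.rooted(tr))

  t4 <- readNewick(text = "((A:1,B:1):1,(C:1,D:4):1);")
  r <- rootAt(t4, "D")
  expect_true(ape::is.rooted(r))
  rootNode <- ape::Ntip(r) + 1L
  kids <- r$edge[r$edge[, 1] == rootNode, 2]
  expect_true(match("D", r$tip.label) %in% kids)
  # root splits D's pendant edge at its midpoint; total length conserved
  dEdge <- which(r$edge[, 2] == match("D", r$tip.label))
  expect_equal(r$edge.length[dEdge], 2)
  expect_equal(sum(r$edge.length), sum(t4$edge.length))

  expect_error(rootAt(t4, "Z"), "Z")

  path <- tempfile(fileext = ".nwk")
  writeNewick(t4, path)
  t4b <- readNewick(path)
  expect_equal(rfDistance(t4, t4b), 0)
  expect_equal(bsDistance(t4, t4b), 0)
})

test_that("RF distance: identical trees, the 4-leaf split swap, leaf-set mismatch", {
  a <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- readNewick(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rfDistance(a, a), 0)
  expect_equal(rfDistance(a, b), 2)
  z <- readNewick(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(rfDistance(a, z), "leaf sets")
})

test_that("RF agrees with the monophyly-enumeration oracle on 6-leaf topologies", {
  trees <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = c("A", "B", "C", "D", "E", "F"))
  # exhaustive oracle on a subsample of pairs (the full 105x105 grid is
  # covered by the bipartition-set comparison in the acceptance suite)
  set.seed(5)
  pick <- sample(length(trees), 12)
  oracleSplits <- lapply(trees[pick], enumSplits)
  for (i in seq_along(pick)) {
    for (j in seq_along(pick)) {
      want <- length(setdiff(oracleSplits[[i]], oracleSplits[[j]])) +
              length(setdiff(oracleSplits[[j]], oracleSplits[[i]]))
      expect_equal(rfDistance(trees[[pick[i]]], trees[[pick[j]]]), want)
    }
  }
})

test_that("KC distance: cherry-swap hand value and branch-length weighting", {
  a <- readNewick(text = "((A:1,B:1):1,C:1);")
  b <- readNewick(text = "((A:1,C:1):1,B:1);")
  expect_equal(kcDistance(a, a, 0), 0)
  # pair entries at lambda 0: (1,0,0) vs (0,1,0); leaf entries identical
  expect_equal(kcDistance(a, b, 0), sqrt(2), tolerance = 1e-9)
  # lambda 0 ignores branch lengths entirely
  a10 <- a; a10$edge.length <- a$edge.length * 10
  expect_equal(kcDistance(a, a10, 0), 0)
  expect_gt(kcDistance(a, a10, 1), 0)
  # vector layout: C(n,2) pair entries then n leaf entries
  expect_length(kcVector(a, 0.5), choose(3, 2) + 3)
  # unrooted input is refused with advice to root
  u <- ape::unroot(readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_error(kcDistance(u, u, 0), "root")
})

test_that("KC at lambda 0 is zero exactly when rooted topologies match (5 leaves)", {
  trees <- phangorn::allTrees(5, rooted = TRUE,
                              tip.label = c("A", "B", "C", "D", "E"))
  trees <- lapply(trees, function(t) {
    t$edge.length <- rep(1, nrow(t$edge)); t
  })
  vecs <- lapply(trees, kcVector, lambda = 0)
  set.seed(6)
  pick <- sample(length(trees), 20)
  for (i in pick) {
    for (j in pick) {
      d <- sqrt(sum((vecs[[i]] - vecs[[j]])^2))
      same <- phangorn::RF.dist(trees[[i]], trees[[j]], rooted = TRUE) == 0
      expect_equal(d == 0, same)
    }
  }
})

test_that("branch score: hand values and equivalence with phangorn's KF distance", {
  a <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  b <- readNewick(text = "((A:1,B:1):1.5,(C:1,D:1):1);")
  expect_equal(bsDistance(a, a), 0)
  expect_equal(bsDistance(a, b), 0.5, tolerance = 1e-9)
  # no shared internal splits: closed form over both internal branches plus
  # pendant differences
  c1 <- readNewick(text = "((A:1,B:1):0.7,(C:1,D:1):0);")
  c2 <- readNewick(text = "((A:1,C:1):0.4,(B:1,D:1):0);")
  expect_equal(bsDistance(c1, c2), sqrt(0.7^2 + 0.4^2), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:10) {
    t1 <- randomTree(10, seed = i)
    t2 <- perturbTree(t1, nNNI = 2, lengthJitter = 0.4, seed = i + 50)
    expect_equal(bsDistance(t1, t2), phangorn::KF.dist(t1, t2), tolerance = 1e-9)
    expect_equal(rfDistance(t1, t2), phangorn::RF.dist(t1, t2))
    # BS on identical topologies is the Euclidean norm of length differences
    t3 <- perturbTree(t1, nNNI = 0, lengthJitter = 0.3, seed = i + 99)
    expect_equal(bsDistance(t1, t3),
                 sqrt(sum((t1$edge.length - t3$edge.length)^2)),
                 tolerance = 1e-9)
  }
})

test_that("distances are symmetric, nonnegative and zero on identical trees", {
  for (i in 1:5) {
    t1 <- randomTree(8, seed = i)
    t2 <- perturbTree(t1, nNNI = 1, lengthJitter = 0.2, seed = i + 10)
    r1 <- rootAt(t1, t1$tip.label[1]); r2 <- rootAt(t2, t1$tip.label[1])
    expect_equal(rfDistance(t1, t2), rfDistance(t2, t1))
    expect_equal(bsDistance(t1, t2), bsDistance(t2, t1))
    expect_equal(kcDistance(r1, r2, 0.5), kcDistance(r2, r1, 0.5))
    expect_gte(bsDistance(t1, t2), 0)
    expect_equal(rfDistance(t1, t1), 0)
    expect_equal(kcDistance(r1, r1, 0.5), 0)
  }
})

test_that("scaling denominators match the published dataset size n = 56", {
  expect_equal(scalingDenominator("RF", 56), 109)
  expect_equal(scalingDenominator("KC_T", 56), 1540)
  expect_equal(scalingDenominator("KC", 56), 1596)
  t1 <- randomTree(6, seed = 1); t2 <- randomTree(6, seed = 2)
  expect_equal(scalingDenominator("BS", t1 = t1, t2 = t2),
               sum(t1$edge.length) + sum(t2$edge.length))
  z1 <- t1; z1$edge.length[] <- 0
  expect_error(scalingDenominator("BS", t1 = z1, t2 = z1), "zero")
  expect_equal(scaledDistance(4, "RF", n = 56), 4 / 109)
})

test_that("compareSuite reports raw and scaled values, honouring topologyOnly", {
  t1 <- randomTree(20, seed = 31)
  t2 <- perturbTree(t1, nNNI = 2, lengthJitter = 0.2, seed = 32)
  row <- compareSuite(t1, t2, outgroup = t1$tip.label[1])
  expect_equal(row$n, 20)
  expect_equal(row$rf_scaled, row$rf / 37)
  expect_true(row$bs_scaled >= 0 && row$bs_scaled <= 1)
  expect_true(row$rf_scaled >= 0 && row$rf_scaled < 1)
  same <- compareSuite(t1, t1, outgroup = t1$tip.label[1])
  expect_equal(unlist(same[c("rf", "kct", "kc", "bs")]), c(rf = 0, kct = 0, kc = 0, bs = 0))
  topo <- compareSuite(t1, t2, outgroup = t1$tip.label[1], topologyOnly = TRUE)
  expect_true(is.na(topo$kc) && is.na(topo$bs))
  expect_false(is.na(topo$kct))
})
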