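test_that("bipartite construction keeps shapes and degree bookkeeping", {
  d <- TransactionDataset(
    itemsets = list(c("a", "b"), c("b", "c"), c("a", "d"), c("c", "d"), "a"),
    labels = c("pos", "pos", "pos", "neg", "neg"),
    items = c("a", "b", "c", "d"), classes = c("neg", "pos"))
  g <- buildBipartite(d, "pos")
  expect_equal(nrow(g@La), 3L)
  expect_equal(nrow(g@Lb), 2L)
  expect_length(g@dIn, 4L)
  expect_equal(unname(g@dIn), c(3, 2, 2, 2))
  expect_equal(sum(g@dOut), sum(lengths(itemsets(d))))
  expect_true(validObject(g))

  # item present in every transaction has in-degree n
  d2 <- TransactionDataset(itemsets = list(c("u", "x"), c("u", "y"), "u"),
                           labels = c("pos", "neg", "neg"),
                           classes = c("neg", "pos"))
  expect_equal(unname(buildBipartite(d2, "pos")@dIn["u"]), 3)

  toy <- labeledToy()$dataset
  gt <- buildBipartite(toy, "pos")
  expect_equal(unname(gt@dIn["84"]), 5)
  expect_equal(unname(gt@dIn["85"]), 3)

  expect_error(buildBipartite(toyCompoundData()$dataset, "pos"), "labeled")
  expect_error(buildBipartite(toy, "nosuch"), "unknown class")
  d3 <- TransactionDataset(itemsets = list("a", character()),
                           labels = c("pos", "neg"), items = "a",
                           classes = c("neg", "pos"))
  expect_warning(g3 <- buildBipartite(d3, "pos"), "empty itemsets dropped")
  expect_equal(nrow(g3@Lb), 0L)
})

test_that("authority operators reproduce hand-computed single-transaction maps", {
  d <- TransactionDataset(ids = "t", itemsets = list(c("f1", "f2")),
                          labels = "pos", classes = c("neg", "pos"))
  g <- buildBipartite(d, "pos")
  opH <- authorityOperator(g, "a", linkWeightParam(variant = "hits"))
  expect_equal(opH(c(1, 0)), c(1, 1))   # L^T L is the all-ones 2x2 map
  opU <- authorityOperator(g, "a", linkWeightParam(variant = "unified"))
  expect_equal(opU(c(1, 0)), c(1 / 2, 1 / 2))
  # zero maps to zero for every variant; nonnegativity is preserved
  for (v in c("hits", "pagerank", "unified")) {
    op <- authorityOperator(g, "a", linkWeightParam(variant = v))
    expect_equal(op(c(0, 0)), c(0, 0))
    expect_true(all(op(c(0.3, 0.7)) >= 0))
  }
  # empty subsystem yields the zero map
  opB <- authorityOperator(g, "b", linkWeightParam(variant = "hits"))
  expect_equal(opB(c(1, 1)), c(0, 0))
})

test_that("hits authority with beta = 1 matches the dense eigendecomposition", {
  set.seed(21)
  for (rep in 1:5) {
    nI <- sample(3:8, 1)
    d <- randomDataset(sample(4:8, 1), nI, labeled = TRUE)
    # ensure at least one positive transaction with items
    ok <- lengths(d@itemsets) > 0
    if (!any(ok)) next
    d@labels[which(ok)[1]] <- "pos"
    d@itemsets[lengths(d@itemsets) == 0] <- list("i1")
    g <- buildBipartite(d, "pos")
    eg <- eigen(crossprod(as.matrix(g@La)), symmetric = TRUE)
    # the principal eigenvector is only well-defined on generic instances
    if (length(eg$values) > 1 &&
        eg$values[1] - eg$values[2] < 1e-8 * max(1, eg$values[1])) next
    w <- suppressWarnings(computeLinkWeights(
      g, linkWeightParam(beta = 1, variant = "hits", tol = 1e-12,
                         maxIter = 5000L, normalizeMeanToOne = FALSE)))
    ev <- abs(eg$vectors[, 1])
    ev <- ev / sum(ev)
    expect_equal(unname(weights(w)), ev, tolerance = 1e-6)
  }
})

test_that("beta = 1 ignores the inactive system entirely", {
  toy <- labeledToy()$dataset
  g <- buildBipartite(toy, "pos")
  onlyPos <- TransactionDataset(ids = toy@ids[1:3], itemsets = toy@itemsets[1:3],
                                labels = toy@labels[1:3], items = toy@items,
                                classes = toy@classes)
  gPos <- buildBipartite(onlyPos, "pos")
  for (v in c("hits", "unified", "pagerank")) {
    p <- linkWeightParam(beta = 1, variant = v)
    expect_equal(weights(computeLinkWeights(g, p)),
                 weights(computeLinkWeights(gPos, p)), tolerance = 1e-7)
  }
})

test_that("complete bipartite active system gives uniform weights", {
  d <- TransactionDataset(itemsets = rep(list(c("a", "b", "c")), 4),
                          labels = rep("pos", 4), classes = c("neg", "pos"))
  g <- buildBipartite(d, "pos")
  for (v in c("hits", "unified", "pagerank")) {
    w <- computeLinkWeights(g, linkWeightParam(beta = 1, variant = v))
    expect_equal(unname(weights(w)), c(1, 1, 1), tolerance = 1e-8)
  }
})

test_that("converged scores are nonnegative and invariant under one more step", {
  set.seed(33)
  toy <- labeledToy()$dataset
  g <- buildBipartite(toy, "pos")
  for (v in c("hits", "unified", "pagerank")) {
    p <- linkWeightParam(beta = 0.9, variant = v, tol = 1e-10,
                         normalizeMeanToOne = FALSE)
    x <- unname(weights(computeLinkWeights(g, p)))
    expect_true(all(x >= 0))
    wa <- if (v == "unified") sqrt(0.9) else 0.9
    wb <- if (v == "unified") sqrt(0.1) else 0.1
    opA <- authorityOperator(g, "a", p); opB <- authorityOperator(g, "b", p)
    xn <- wa * opA(x) + wb * opB(x)
    xn <- xn / sum(xn)
    expect_lt(sum(abs(xn - x)), 1e-8)
  }
})

test_that("larger beta promotes items linked to active compounds", {
  # symmetric construction: A only in actives, B only in inactives
  d <- TransactionDataset(
    itemsets = c(rep(list(c("A", "shared")), 3), rep(list(c("B", "shared")), 3)),
    labels = rep(c("pos", "neg"), each = 3), classes = c("neg", "pos"))
  g <- buildBipartite(d, "pos")
  for (v in c("unified", "hits", "pagerank")) {
    gaps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(b) {
      w <- weights(computeLinkWeights(g, linkWeightParam(beta = b, variant = v)))
      unname(w["A"] - w["B"])
    }, numeric(1))
    expect_true(all(diff(gaps) >= -1e-9))         # weakly increasing in beta
    expect_lt(abs(gaps[3]), 1e-7)                 # symmetric at beta = 0.5
    expect_gt(gaps[5], 0)                         # promoted at beta = 0.9
  }
})

test_that("permuting transactions or items permutes the weights accordingly", {
  set.seed(55)
  d <- randomDataset(8L, 6L, labeled = TRUE)
  d@itemsets[lengths(d@itemsets) == 0] <- list("i1")
  d@labels[1] <- "pos"; d@labels[2] <- "neg"
  perm <- sample(nTransactions(d))
  ipos <- sample(length(d@items))
  d2 <- TransactionDataset(ids = d@ids[perm], itemsets = d@itemsets[perm],
                           labels = d@labels[perm], items = d@items[ipos],
                           classes = d@classes)
  p <- linkWeightParam(beta = 0.8)
  w1 <- weights(computeLinkWeights(buildBipartite(d, "pos"), p))
  w2 <- weights(computeLinkWeights(buildBipartite(d2, "pos"), p))
  expect_equal(w1[sort(names(w1))], w2[sort(names(w2))], tolerance = 1e-9)
})

test_that("frequency and uniform baselines behave as documented", {
  toy <- toyCompoundData()$dataset
  wf <- weights(frequencyWeights(toy))
  expect_equal(unname(wf["84"] / wf["85"]), 5 / 3)
  expect_equal(mean(wf), 1)
  wu <- weights(uniformWeights(toy))
  expect_true(all(wu == 1))
  # equally frequent items: frequency reduces to uniform
  d <- TransactionDataset(itemsets = list(c("a", "b"), c("a", "b")))
  expect_equal(weights(frequencyWeights(d)), weights(uniformWeights(d)))
})

test_that("zero in-degree items get zero weight; all-zero graphs are refused", {
  d <- TransactionDataset(itemsets = list(c("a", "b"), "a"),
                          labels = c("pos", "neg"),
                          items = c("a", "b", "ghost"), classes = c("neg", "pos"))
  w <- weights(computeLinkWeights(buildBipartite(d, "pos"), linkWeightParam()))
  expect_equal(unname(w["ghost"]), 0)
  expect_gt(unname(w["a"]), 0)
})
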