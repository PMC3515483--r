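test_that("rule confidence is the class share of supporting transaction weight", {
  d <- TransactionDataset(itemsets = list("f1", "f1", "f1", "f2"),
                          labels = c("pos", "pos", "neg", "neg"),
                          classes = c("neg", "pos"))
  u <- uniformWeights(d)
  for (mode in c("classical", "adjusted")) {
    p <- miningParam(minsup = 0, minconf = 0, supportMode = mode)
    fr <- mineFrequentItemsets(d, u, p)
    rs <- generateRules(fr, d, u, p)
    r <- rs[rs$antecedent == "f1" & rs$class == "pos", ]
    expect_equal(r$confidence, 2 / 3)
    # antecedent seen only in one class gives confidence 1
    r2 <- rs[rs$antecedent == "f2" & rs$class == "neg", ]
    expect_equal(r2$confidence, 1)
  }
  # minconf = 0 keeps every frequent (X, c) pair with support >= minsup
  p0 <- miningParam(minsup = 0, minconf = 0, supportMode = "adjusted")
  rs0 <- generateRules(mineFrequentItemsets(d, u, p0), d, u, p0)
  expect_setequal(paste(rs0$antecedent, rs0$class),
                  c("f1 pos", "f1 neg", "f2 pos", "f2 neg"))
  expect_equal(rs0[rs0$antecedent == "f2" & rs0$class == "pos", "support"], 0)
  expect_error(generateRules(data.frame(), toyCompoundData()$dataset,
                             uniformWeights(toyCompoundData()$dataset)),
               "labeled")
})

test_that("rule support and confidence use class-augmented transaction weights", {
  toy <- labeledToy()
  d <- toy$dataset; w <- toy$weights
  p <- miningParam(minsup = 0, minconf = 0, supportMode = "adjusted")
  fr <- mineFrequentItemsets(d, w, p, extraTransactionWeight = mean(weights(w)))
  rs <- generateRules(fr, d, w, p)
  classW <- mean(weights(w))                   # virtual class item weight
  tw <- vapply(itemsets(d), function(t) sum(weights(w)[t]), numeric(1)) + classW
  r <- rs[rs$antecedent == "81;83" & rs$class == "pos", ]
  expect_equal(r$support, unname(tw[1] / sum(tw)))            # C1 only
  expect_equal(r$confidence, unname(tw[1] / (tw[1] + tw[5]))) # C1 of {C1, C5}
})

test_that("rule ranking follows confidence, support, generation order", {
  rs <- data.frame(antecedent = c("a", "b", "c", "d"),
                   class = "pos",
                   support = c(0.3, 0.4, 0.4, 0.3),
                   confidence = c(0.8, 0.9, 0.9, 0.8),
                   genId = c(7L, 5L, 2L, 3L), stringsAsFactors = FALSE)
  ranked <- rankRules(rs)
  expect_equal(ranked$antecedent, c("c", "b", "d", "a"))
  # oracle: insertion by explicit pairwise precedence on random rule lists
  precedes <- function(r1, r2) {
    if (r1$confidence != r2$confidence) return(r1$confidence > r2$confidence)
    if (r1$support != r2$support) return(r1$support > r2$support)
    r1$genId < r2$genId
  }
  set.seed(12)
  for (draw in 1:10) {
    n <- sample(3:12, 1)
    rr <- data.frame(antecedent = paste0("x", 1:n), class = "pos",
                     support = sample(c(0.2, 0.5, 0.7), n, TRUE),
                     confidence = sample(c(0.6, 0.9), n, TRUE),
                     genId = sample(n), stringsAsFactors = FALSE)
    got <- rankRules(rr)
    for (i in seq_len(n - 1))
      expect_true(precedes(got[i, ], got[i + 1, ]))
  }
})

test_that("database coverage keeps useful rules and picks the best prefix", {
  d <- TransactionDataset(itemsets = list("a", "a", "b", "b", c("a", "b"), "c"),
                          labels = c("pos", "pos", "neg", "neg", "pos", "neg"),
                          classes = c("neg", "pos"))
  # a single rule classifying everything correctly
  perfect <- data.frame(antecedent = c("a", "b"), class = c("pos", "neg"),
                        support = c(0.5, 0.5), confidence = c(1, 1),
                        genId = 1:2, stringsAsFactors = FALSE)
  clf <- buildClassifier(perfect[1, ], TransactionDataset(
    itemsets = list("a", "a"), labels = c("pos", "pos"),
    classes = c("neg", "pos")))
  expect_equal(nrow(rules(clf)), 1L)
  expect_equal(trainingAccuracy(clf), 1)

  # rules that never correctly cover anything are all dropped
  useless <- data.frame(antecedent = "c", class = "pos", support = 0.1,
                        confidence = 0.4, genId = 1L, stringsAsFactors = FALSE)
  clf2 <- buildClassifier(useless, d)
  expect_equal(nrow(rules(clf2)), 0L)
  # 3 pos vs 3 neg: exact tie falls back to class-universe order
  expect_equal(defaultClass(clf2), "neg")
})

test_that("prefix truncation minimizes training error (oracle on random cases)", {
  set.seed(88)
  for (draw in 1:15) {
    d <- randomDataset(sample(6:14, 1), 5L, labeled = TRUE)
    u <- uniformWeights(d)
    p <- miningParam(minsup = 0, minconf = 0, maxLen = 2L,
                     supportMode = "classical")
    ranked <- rankRules(generateRules(mineFrequentItemsets(d, u, p), d, u, p))
    clf <- buildClassifier(ranked, d)
    # oracle: replay M1 coverage, then evaluate every prefix by first-match
    labels <- classLabels(d); sets <- unname(itemsets(d))
    uncovered <- rep(TRUE, length(sets)); kept <- integer()
    for (r in seq_len(nrow(ranked))) {
      ant <- strsplit(ranked$antecedent[r], ";", fixed = TRUE)[[1]]
      m <- uncovered & vapply(sets, function(t) all(ant %in% t), logical(1))
      if (any(m & labels == ranked$class[r])) {
        kept <- c(kept, r); uncovered[m] <- FALSE
      }
    }
    firstMatch <- function(ruleIdx, t) {
      for (r in ruleIdx)
        if (all(strsplit(ranked$antecedent[r], ";", fixed = TRUE)[[1]] %in% t))
          return(ranked$class[r])
      NA_character_
    }
    bestErr <- Inf
    pfxRange <- if (length(kept)) seq_along(kept) else 0L
    for (pfx in pfxRange) {
      idx <- kept[seq_len(pfx)]
      pred <- vapply(sets, function(t) firstMatch(idx, t), character(1))
      # best default for this prefix: the majority of unmatched rows
      unm <- is.na(pred)
      errRules <- sum(pred[!unm] != labels[!unm])
      classes <- classUniverse(d)
      defErr <- if (any(unm))
        min(vapply(classes, function(cl) sum(labels[unm] != cl), numeric(1)))
        else 0
      bestErr <- min(bestErr, errRules + defErr)
    }
    expect_equal(trainingAccuracy(clf), 1 - bestErr / length(sets))
  }
})

test_that("prediction is first-match, order-insensitive, oracle-consistent", {
  set.seed(19)
  d <- randomDataset(12L, 5L, labeled = TRUE)
  u <- uniformWeights(d)
  p <- miningParam(minsup = 0, minconf = 0.4, maxLen = 3L,
                   supportMode = "classical")
  clf <- buildClassifier(rankRules(generateRules(
    mineFrequentItemsets(d, u, p), d, u, p)), d)
  for (t in itemsets(d)) {
    expect_equal(unname(predict(clf, list(t))), oraclePredict(clf, t))
    expect_equal(predict(clf, list(t)), predict(clf, list(rev(t))))
  }
  expect_equal(unname(predict(clf, list(character()))), defaultClass(clf))
  # a transaction matching rule 1 gets rule 1's class even if later rules match
  if (nrow(rules(clf)) >= 1) {
    t1 <- strsplit(rules(clf)$antecedent[1], ";", fixed = TRUE)[[1]]
    full <- itemUniverse(d)   # superset of every antecedent
    expect_equal(unname(predict(clf, list(full))), rules(clf)$class[1])
    expect_equal(rules(clf)$class[1],
                 unname(predict(clf, list(t1))))
  }
})

test_that("appending pruned rules back never changes covered predictions", {
  set.seed(77)
  for (draw in 1:5) {
    d <- randomDataset(10L, 4L, labeled = TRUE)
    u <- uniformWeights(d)
    p <- miningParam(minsup = 0, minconf = 0, maxLen = 2L,
                     supportMode = "classical")
    ranked <- rankRules(generateRules(mineFrequentItemsets(d, u, p), d, u, p))
    clf <- buildClassifier(ranked, d)
    kept <- rules(clf)
    if (!nrow(kept)) next
    covered <- vapply(itemsets(d), function(t)
      any(vapply(kept$antecedent, function(a)
        all(strsplit(a, ";", fixed = TRUE)[[1]] %in% t), logical(1))),
      logical(1))
    extended <- new("RuleClassifier",
                    rules = rbind(kept, ranked[!(ranked$genId %in% kept$genId), ]),
                    defaultClass = defaultClass(clf),
                    classes = classUniverse(clf),
                    trainingAccuracy = trainingAccuracy(clf))
    pred1 <- predict(clf, d); pred2 <- predict(extended, d)
    expect_equal(pred1[covered], pred2[covered])
  }
})

test_that("uniform weights reduce the pipeline to classical CBA semantics", {
  d <- TransactionDataset(itemsets = list("a", "a", c("a", "b"), "b"),
                          labels = c("pos", "pos", "neg", "neg"),
                          classes = c("neg", "pos"))
  clf <- trainClassifier(d, scheme = "uniform",
                         miningParam = miningParam(minsup = 0.2, minconf = 0.6,
                                                   supportMode = "classical"))
  # hand-computed CBA: {b}->neg (conf 1, supp 0.5) ranks first, covers rows
  # 3-4 with zero errors; default over rows 1-2 is pos; total error 0 ->
  # truncation after the first rule
  expect_equal(rules(clf)$antecedent, "b")
  expect_equal(rules(clf)$class, "neg")
  expect_equal(defaultClass(clf), "pos")
  expect_equal(trainingAccuracy(clf), 1)
  expect_equal(unname(predict(clf, d)), c("pos", "pos", "neg", "neg"))
  # adjusted mode with uniform weights gives the same classifier here
  clf2 <- trainClassifier(d, scheme = "uniform",
                          miningParam = miningParam(minsup = 0.2, minconf = 0.6,
                                                    supportMode = "adjusted"))
  expect_equal(rules(clf2)$antecedent, rules(clf)$antecedent)
  expect_equal(defaultClass(clf2), defaultClass(clf))
})

test_that("classifier model files round-trip exactly", {
  toy <- labeledToy()
  clf <- trainClassifier(toy$dataset, weights = toy$weights,
                         miningParam = miningParam(minsup = 0.1, minconf = 0.5))
  f <- withr::local_tempfile(fileext = ".txt")
  writeClassifier(clf, f)
  back <- readClassifier(f)
  expect_identical(rules(back), rules(clf))
  expect_identical(defaultClass(back), defaultClass(clf))
  expect_identical(trainingAccuracy(back), trainingAccuracy(clf))
  expect_identical(predict(back, toy$dataset), predict(clf, toy$dataset))
})
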