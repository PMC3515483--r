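# shared fixtures and independent oracles, built in code

# the worked example with a pos/neg labeling (C1-C3 active, C4-C6 inactive)
labeledToy <- function() {
  toy <- toyCompoundData()
  d <- toy$dataset
  d@labels <- c("pos", "pos", "pos", "neg", "neg", "neg")
  d@classes <- c("neg", "pos")
  list(dataset = d, weights = toy$weights)
}

# random dataset; caller controls the RNG seed
randomDataset <- function(nTrans = 8L, nItems = 5L, labeled = FALSE,
                          itemProb = 0.4) {
  items <- paste0("i", seq_len(nItems))
  sets <- lapply(seq_len(nTrans), function(i) items[runif(nItems) < itemProb])
  labels <- if (labeled) sample(c("pos", "neg"), nTrans, replace = TRUE)
            else NULL
  TransactionDataset(itemsets = sets, labels = labels, items = items,
                     classes = if (labeled) c("neg", "pos") else NULL)
}

randomWeights <- function(items, lo = 0.1, hi = 2) {
  itemWeights(setNames(runif(length(items), lo, hi), items))
}

# --- independent oracles (first principles, no package mining code) ---------

# transaction weight = sum of member weights
oracleTw <- function(sets, w) {
  vapply(sets, function(t) if (length(t)) sum(w[t]) else 0, numeric(1))
}

# adjusted weighted support from explicit sums
oracleAws <- function(is, sets, w) {
  tw <- oracleTw(sets, w)
  supp <- vapply(sets, function(t) all(is %in% t), logical(1))
  sum(tw[supp]) / sum(tw)
}

# brute-force frequent itemsets under AWS: powerset enumeration up to maxLen,
# frequent iff supported by >= 1 transaction and AWS >= minsup
oracleFrequentAws <- function(dataset, w, minsup, maxLen) {
  items <- itemUniverse(dataset)
  sets <- unname(itemsets(dataset))
  out <- character()
  for (k in seq_len(min(maxLen, length(items)))) {
    for (ix in combn(seq_along(items), k, simplify = FALSE)) {
      is <- items[ix]
      cnt <- sum(vapply(sets, function(t) all(is %in% t), logical(1)))
      if (cnt >= 1L && oracleAws(is, sets, w) >= minsup)
        out <- c(out, paste(is, collapse = ";"))
    }
  }
  out
}

# exhaustive-match rule evaluator: scan ALL rules, take the best-precedence
# (lowest index) match
oraclePredict <- function(clf, itemset) {
  r <- rules(clf)
  matchIdx <- which(vapply(seq_len(nrow(r)), function(i)
    all(strsplit(r$antecedent[i], ";", fixed = TRUE)[[1]] %in% itemset),
    logical(1)))
  if (length(matchIdx)) r$class[min(matchIdx)] else defaultClass(clf)
}
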