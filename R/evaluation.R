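#' @include AllClasses.R cba.R
NULL

# run expr under a fixed seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.subsetDataset <- function(dataset, idx) {
  new("TransactionDataset", ids = dataset@ids[idx],
      itemsets = dataset@itemsets[idx], items = dataset@items,
      classes = dataset@classes, labels = dataset@labels[idx])
}

#' k-fold cross-validation of the full pipeline
#'
#' Partitions the dataset into \code{k} seeded random folds (stratified by
#' class by default, which stabilizes folds when a class is small) and, for
#' each fold, fits the entire pipeline — item weights, mining, rule
#' generation, pruning — on the training split only, then scores accuracy
#' (correct / total) on the held-out fold. Held-out transactions never
#' influence the trained model unless \code{weightsOnFull = TRUE}, an
#' explicit leakage mode that computes item weights once on the full
#' dataset.
#'
#' @param dataset a labeled \linkS4class{TransactionDataset} with at least
#'   \code{k} transactions.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param scheme weighting scheme, see \code{\link{trainClassifier}}.
#' @param positiveClass class treated as active for the link scheme.
#' @param linkParam a \linkS4class{LinkWeightParam}.
#' @param miningParam a \linkS4class{MiningParam}.
#' @param stratified stratify folds by class (default TRUE).
#' @param weightsOnFull compute item weights on the full dataset instead of
#'   per training split (default FALSE; leaks information).
#' @return an \linkS4class{EvalReport}
#' @examples
#' d <- generateTransactions(synthParam(60, 6, plantedRules = list(
#'   list(antecedent = "f1", class = "pos", penetrance = 1)),
#'   backgroundItemProb = 0.3, seed = 7))
#' crossValidate(d, k = 5, seed = 1, scheme = "uniform",
#'               miningParam = miningParam(minsup = 0.1, minconf = 0.5,
#'                                         maxLen = 2))
#' @export
crossValidate <- function(dataset, k = 10L, seed = 1L,
                          scheme = c("link", "frequency", "uniform"),
                          positiveClass = NULL,
                          linkParam = linkWeightParam(),
                          miningParam = linkAC::miningParam(),
                          stratified = TRUE, weightsOnFull = FALSE) {
  scheme <- match.arg(scheme)
  if (!isLabeled(dataset)) stop("cross-validation requires a labeled dataset")
  n <- length(dataset@ids)
  k <- as.integer(k)
  if (k > n) stop("k (", k, ") exceeds the number of transactions (", n, ")")
  foldId <- .withSeed(seed, {
    f <- integer(n)
    if (stratified) {
      ordered <- unlist(lapply(dataset@classes, function(cl) {
        ix <- which(dataset@labels == cl)
        if (length(ix) > 1L) sample(ix) else ix
      }), use.names = FALSE)
      f[ordered] <- rep_len(seq_len(k), length(ordered))
    } else {
      f[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    f
  })
  folds <- split(seq_len(n), foldId)
  fullWeights <- if (weightsOnFull)
    .schemeWeights(dataset, scheme, positiveClass, linkParam) else NULL
  acc <- vapply(folds, function(testIdx) {
    train <- .subsetDataset(dataset, setdiff(seq_len(n), testIdx))
    test <- .subsetDataset(dataset, testIdx)
    w <- if (weightsOnFull) fullWeights
         else .schemeWeights(train, scheme, positiveClass, linkParam)
    clf <- trainClassifier(train, weights = w, miningParam = miningParam)
    mean(predict(clf, test) == test@labels)
  }, numeric(1))
  names(acc) <- NULL
  new("EvalReport", foldAccuracies = acc, meanAccuracy = mean(acc),
      folds = unname(folds),
      config = list(k = k, scheme = scheme, positiveClass = positiveClass,
                    stratified = stratified, weightsOnFull = weightsOnFull,
                    linkParam = linkParam, miningParam = miningParam),
      seed = as.integer(seed))
}

.schemeWeights <- function(dataset, scheme, positiveClass, linkParam) {
  switch(scheme,
    uniform   = uniformWeights(dataset),
    frequency = frequencyWeights(dataset),
    link = {
      if (is.null(positiveClass))
        positiveClass <- dataset@classes[length(dataset@classes)]
      computeLinkWeights(buildBipartite(dataset, positiveClass), linkParam)
    })
}

#' Compare two item weight vectors
#'
#' Pearson correlation of the weight values, Spearman rank correlation
#' (average ranks on ties), and a per-item rank table in which a larger
#' rank means a more important item under that scheme. Both vectors must
#' cover the same item universe. A zero-variance vector makes the
#' correlations undefined; they are returned as \code{NA} with
#' \code{degenerate = TRUE}.
#'
#' @param w1,w2 \linkS4class{ItemWeights} over the same items.
#' @return list with elements \code{pearson}, \code{spearman},
#'   \code{degenerate}, and \code{rankTable} (data.frame with columns
#'   \code{item}, \code{weight1}, \code{weight2}, \code{rank1},
#'   \code{rank2})
#' @examples
#' toy <- toyCompoundData()
#' compareWeights(toy$weights, frequencyWeights(toy$dataset))
#' @export
compareWeights <- function(w1, w2) {
  v1 <- w1@weights
  items <- names(v1)
  if (!setequal(items, names(w2@weights)))
    stop("weight vectors cover different item universes")
  v2 <- w2@weights[items]
  degenerate <- stats::sd(v1) == 0 || stats::sd(v2) == 0
  pearson <- if (degenerate) NA_real_ else stats::cor(v1, v2)
  spearman <- if (degenerate) NA_real_ else stats::cor(rank(v1), rank(v2))
  list(pearson = pearson, spearman = spearman, degenerate = degenerate,
       rankTable = data.frame(item = items, weight1 = unname(v1),
                              weight2 = unname(v2),
                              rank1 = rank(v1), rank2 = rank(v2),
                              row.names = NULL, stringsAsFactors = FALSE))
}
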