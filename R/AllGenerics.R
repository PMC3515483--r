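#' @include AllClasses.R
NULL

#' Number of transactions in a dataset
#' @param x a \linkS4class{TransactionDataset}
#' @return integer count
#' @examples nTransactions(toyCompoundData()$dataset)
#' @export
setGeneric("nTransactions", function(x) standardGeneric("nTransactions"))

#' @rdname nTransactions
#' @export
setMethod("nTransactions", "TransactionDataset", function(x) length(x@ids))

#' Transaction identifiers
#' @param x a \linkS4class{TransactionDataset}
#' @return character vector
#' @export
setGeneric("transactionIds", function(x) standardGeneric("transactionIds"))

#' @rdname transactionIds
#' @export
setMethod("transactionIds", "TransactionDataset", function(x) x@ids)

#' Per-transaction itemsets
#' @param x a \linkS4class{TransactionDataset}
#' @return named list of character vectors
#' @export
setGeneric("itemsets", function(x) standardGeneric("itemsets"))

#' @rdname itemsets
#' @export
setMethod("itemsets", "TransactionDataset",
          function(x) stats::setNames(x@itemsets, x@ids))

#' Item universe of an object
#' @param x a \linkS4class{TransactionDataset}, \linkS4class{ItemWeights} or
#'   \linkS4class{BipartiteGraph}
#' @return character vector of item identifiers, in the fixed total order
#' @export
setGeneric("itemUniverse", function(x) standardGeneric("itemUniverse"))

#' @rdname itemUniverse
#' @export
setMethod("itemUniverse", "TransactionDataset", function(x) x@items)

#' @rdname itemUniverse
#' @export
setMethod("itemUniverse", "ItemWeights", function(x) names(x@weights))

#' @rdname itemUniverse
#' @export
setMethod("itemUniverse", "BipartiteGraph", function(x) x@items)

#' Class universe of an object
#' @param x a \linkS4class{TransactionDataset} or \linkS4class{RuleClassifier}
#' @return character vector of class labels (may be empty)
#' @export
setGeneric("classUniverse", function(x) standardGeneric("classUniverse"))

#' @rdname classUniverse
#' @export
setMethod("classUniverse", "TransactionDataset", function(x) x@classes)

#' @rdname classUniverse
#' @export
setMethod("classUniverse", "RuleClassifier", function(x) x@classes)

#' Per-transaction class labels
#' @param x a \linkS4class{TransactionDataset}
#' @return character vector (NA for unlabeled transactions)
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "TransactionDataset",
          function(x) stats::setNames(x@labels, x@ids))

#' Whether every transaction carries a class label
#' @param x a \linkS4class{TransactionDataset}
#' @return logical
#' @export
setGeneric("isLabeled", function(x) standardGeneric("isLabeled"))

#' @rdname isLabeled
#' @export
setMethod("isLabeled", "TransactionDataset",
          function(x) length(x@labels) > 0L && !anyNA(x@labels))

#' Extract the numeric weight vector
#' @param object an \linkS4class{ItemWeights}
#' @param ... ignored
#' @return named numeric vector
#' @examples weights(toyCompoundData()$weights)
#' @export
setMethod("weights", "ItemWeights", function(object, ...) object@weights)

#' Ordered rule list of a classifier
#' @param x a \linkS4class{RuleClassifier}
#' @return data.frame of rules in precedence order
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))

#' @rdname rules
#' @export
setMethod("rules", "RuleClassifier", function(x) x@rules)

#' Default class of a classifier
#' @param x a \linkS4class{RuleClassifier}
#' @return character label
#' @export
setGeneric("defaultClass", function(x) standardGeneric("defaultClass"))

#' @rdname defaultClass
#' @export
setMethod("defaultClass", "RuleClassifier", function(x) x@defaultClass)

#' Training accuracy recorded while pruning
#' @param x a \linkS4class{RuleClassifier}
#' @return numeric in [0, 1]
#' @export
setGeneric("trainingAccuracy", function(x) standardGeneric("trainingAccuracy"))

#' @rdname trainingAccuracy
#' @export
setMethod("trainingAccuracy", "RuleClassifier", function(x) x@trainingAccuracy)

#' Per-fold accuracies of a cross-validation report
#' @param x an \linkS4class{EvalReport}
#' @return numeric vector
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))

#' @rdname foldAccuracies
#' @export
setMethod("foldAccuracies", "EvalReport", function(x) x@foldAccuracies)

#' Mean held-out accuracy of a cross-validation report
#' @param x an \linkS4class{EvalReport}
#' @return numeric scalar
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @rdname meanAccuracy
#' @export
setMethod("meanAccuracy", "EvalReport", function(x) x@meanAccuracy)

setMethod("show", "TransactionDataset", function(object) {
  cat(sprintf("TransactionDataset: %d transactions, %d items, %d classes\n",
              length(object@ids), length(object@items), length(object@classes)))
  if (length(object@classes)) {
    lab <- object@labels
    tab <- table(factor(lab[!is.na(lab)], levels = object@classes))
    cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        if (anyNA(lab)) sprintf("; %d unlabeled", sum(is.na(lab))) else "", "\n",
        sep = "")
  }
  k <- min(3L, length(object@ids))
  for (i in seq_len(k))
    cat(sprintf("  %s: {%s}\n", object@ids[i],
                paste(object@itemsets[[i]], collapse = ",")))
  if (length(object@ids) > k) cat("  ...\n")
})

setMethod("show", "ItemWeights", function(object) {
  cat(sprintf("ItemWeights: %d items (provenance=%s, normalization=%s)\n",
              length(object@weights), object@provenance, object@normalization))
  if (!is.null(object@metadata$converged))
    cat(sprintf("  converged=%s after %d iterations\n",
                object@metadata$converged, object@metadata$iterations))
  w <- utils::head(object@weights, 5L)
  cat(" ", paste(sprintf("%s=%.4g", names(w), w), collapse = " "),
      if (length(object@weights) > 5L) "..." else "", "\n")
})

setMethod("show", "BipartiteGraph", function(object) {
  cat(sprintf(
    "BipartiteGraph: %d active + %d inactive transactions x %d items, %d edges\n",
    nrow(object@La), nrow(object@Lb), length(object@items), sum(object@dIn)))
})

setMethod("show", "RuleClassifier", function(object) {
  cat(sprintf("RuleClassifier: %d rules, default class '%s', training accuracy %.3f\n",
              nrow(object@rules), object@defaultClass, object@trainingAccuracy))
  k <- min(5L, nrow(object@rules))
  for (i in seq_len(k))
    cat(sprintf("  [%d] {%s} -> %s (supp %.3f, conf %.3f)\n", i,
                object@rules$antecedent[i], object@rules$class[i],
                object@rules$support[i], object@rules$confidence[i]))
  if (nrow(object@rules) > k) cat("  ...\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d-fold CV, mean accuracy %.4f (seed %d)\n",
              length(object@foldAccuracies), object@meanAccuracy, object@seed))
  cat("  folds:", paste(sprintf("%.3f", object@foldAccuracies), collapse = " "), "\n")
})

setMethod("show", "LinkWeightParam", function(object) {
  cat(sprintf(
    "LinkWeightParam: variant=%s beta=%.3g damping=%.3g tol=%.1e maxIter=%d\n",
    object@variant, object@beta, object@damping, object@tol, object@maxIter))
})

setMethod("show", "MiningParam", function(object) {
  cat(sprintf(
    "MiningParam: minsup=%.3g minconf=%.3g maxLen=%d maxCandidates=%d mode=%s\n",
    object@minsup, object@minconf, object@maxLen, object@maxCandidates,
    object@supportMode))
})
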