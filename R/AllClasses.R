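#' TransactionDataset: binary-feature transactions with optional class labels
#'
#' The central data container: a set of transactions (compounds, samples),
#' each holding an itemset drawn from a fixed item universe (for example
#' MACCS/MDL key bits as strings, or bioassay readouts such as
#' \code{"MCF7 inactive"}), plus an optional class label per transaction.
#'
#' @slot ids character, unique transaction identifiers.
#' @slot itemsets list of character vectors; each a duplicate-free subset of
#'   \code{items}.
#' @slot items character, the ordered item universe. The order fixes the
#'   total item order used throughout mining, so results are deterministic.
#' @slot classes character, the class universe (may be empty for unlabeled
#'   data).
#' @slot labels character, one label per transaction; \code{NA} where a
#'   transaction is unlabeled.
#'
#' @seealso \code{\link{TransactionDataset}} (constructor),
#'   \code{\link{readTransactions}}, \code{\link{toyCompoundData}}
#' @exportClass TransactionDataset
setClass("TransactionDataset",
  representation(
    ids      = "character",
    itemsets = "list",
    items    = "character",
    classes  = "character",
    labels   = "character"
  )
)

setValidity("TransactionDataset", function(object) {
  msg <- NULL
  n <- length(object@ids)
  if (length(object@itemsets) != n)
    msg <- c(msg, "lengths of 'ids' and 'itemsets' differ")
  if (length(object@labels) != n)
    msg <- c(msg, "lengths of 'ids' and 'labels' differ")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "transaction ids must be unique")
  if (anyDuplicated(object@items))
    msg <- c(msg, "item universe contains duplicates")
  for (i in seq_len(n)) {
    is <- object@itemsets[[i]]
    if (!is.character(is)) {
      msg <- c(msg, sprintf("itemset %d is not a character vector", i))
      break
    }
    if (anyDuplicated(is)) {
      msg <- c(msg, sprintf("itemset of '%s' contains duplicates", object@ids[i]))
      break
    }
    if (!all(is %in% object@items)) {
      msg <- c(msg, sprintf("itemset of '%s' contains items outside the universe",
                            object@ids[i]))
      break
    }
  }
  if (any(!is.na(object@labels))) {
    if (length(object@classes) < 1L)
      msg <- c(msg, "labeled transactions present but class universe is empty")
    else if (!all(object@labels[!is.na(object@labels)] %in% object@classes))
      msg <- c(msg, "labels outside the class universe")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a TransactionDataset
#'
#' @param ids character vector of unique transaction identifiers. Defaults to
#'   \code{"T1"}, \code{"T2"}, ...
#' @param itemsets list of character vectors (items per transaction).
#'   Anything coercible (e.g. numeric bit labels) is converted with
#'   \code{as.character}.
#' @param labels optional character vector of class labels (\code{NA} for
#'   unlabeled transactions).
#' @param items optional item universe; defaults to the sorted union of
#'   observed items.
#' @param classes optional class universe; defaults to the sorted unique
#'   non-missing labels.
#'
#' @return a \linkS4class{TransactionDataset}
#' @examples
#' d <- TransactionDataset(
#'   itemsets = list(c("81", "84"), c("82", "84"), "85"),
#'   labels   = c("active", "active", "inactive")
#' )
#' nTransactions(d)
#' @export
TransactionDataset <- function(ids = NULL, itemsets = list(), labels = NULL,
                               items = NULL, classes = NULL) {
  itemsets <- lapply(itemsets, function(x) unique(as.character(x)))
  n <- length(itemsets)
  if (is.null(ids)) ids <- paste0("T", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  labels <- as.character(labels)
  if (is.null(items)) items <- sort(unique(unlist(itemsets, use.names = FALSE)))
  if (is.null(classes)) classes <- sort(unique(labels[!is.na(labels)]))
  new("TransactionDataset",
      ids = as.character(ids), itemsets = itemsets,
      items = as.character(items), classes = as.character(classes),
      labels = labels)
}

#' ItemWeights: nonnegative per-item weights
#'
#' A weight vector over an item universe together with how it was normalized
#' (\code{"mean_one"}: mean weight 1, the default so that weighted supports
#' live on the scale of classical supports; \code{"l1"}: weights sum to 1;
#' \code{"none"}) and where it came from (\code{"link"}, \code{"frequency"},
#' \code{"uniform"}, \code{"user"}). Link-derived weights carry convergence
#' diagnostics and per-system hub scores in \code{metadata}.
#'
#' @slot weights named numeric, all entries \eqn{\ge 0}.
#' @slot normalization character flag, one of \code{"mean_one"}, \code{"l1"},
#'   \code{"none"}.
#' @slot provenance character flag, one of \code{"link"}, \code{"frequency"},
#'   \code{"uniform"}, \code{"user"}.
#' @slot metadata list of diagnostics (e.g. \code{converged},
#'   \code{iterations}, \code{hubScores}).
#'
#' @exportClass ItemWeights
setClass("ItemWeights",
  representation(
    weights       = "numeric",
    normalization = "character",
    provenance    = "character",
    metadata      = "list"
  ),
  prototype(normalization = "none", provenance = "user", metadata = list())
)

setValidity("ItemWeights", function(object) {
  msg <- NULL
  w <- object@weights
  if (length(w) && is.null(names(w)))
    msg <- c(msg, "weights must be named by item")
  if (anyDuplicated(names(w)))
    msg <- c(msg, "duplicated item names in weights")
  if (any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "weights must be finite and nonnegative")
  if (!object@normalization %in% c("mean_one", "l1", "none"))
    msg <- c(msg, "unknown normalization")
  if (!object@provenance %in% c("link", "frequency", "uniform", "user"))
    msg <- c(msg, "unknown provenance")
  if (length(w)) {
    if (object@normalization == "l1" && abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, "l1-normalized weights must sum to 1")
    if (object@normalization == "mean_one" && abs(mean(w) - 1) > 1e-8)
      msg <- c(msg, "mean_one-normalized weights must have mean 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ItemWeights object
#'
#' @param weights named numeric vector of nonnegative weights, or a list.
#' @param normalization one of \code{"none"}, \code{"mean_one"}, \code{"l1"};
#'   a declaration of the scale the weights are on, not a transformation.
#' @param provenance one of \code{"user"}, \code{"link"}, \code{"frequency"},
#'   \code{"uniform"}.
#' @param metadata list of diagnostics.
#' @return an \linkS4class{ItemWeights}
#' @examples
#' itemWeights(c("81" = 0.8, "84" = 1.6))
#' @export
itemWeights <- function(weights, normalization = "none", provenance = "user",
                        metadata = list()) {
  w <- unlist(weights)
  storage.mode(w) <- "double"
  new("ItemWeights", weights = w, normalization = normalization,
      provenance = provenance, metadata = metadata)
}

#' BipartiteGraph: class-split compound-by-feature incidence
#'
#' The bipartite representation of a labeled dataset: transactions on one
#' side, items on the other, an edge where a transaction contains an item.
#' Transactions of the positive ("active") class form subsystem \code{a},
#' all others subsystem \code{b}. Item in-degrees are column sums over the
#' stacked incidence; transaction out-degrees are row sums. Transactions
#' with empty itemsets are dropped (with a warning) before construction.
#'
#' @slot La sparse 0/1 incidence, active transactions x items.
#' @slot Lb sparse 0/1 incidence, inactive transactions x items.
#' @slot items character, item universe (column order of both matrices).
#' @slot posIds,negIds character, transaction ids per subsystem.
#' @slot dIn named numeric, per-item in-degree over both subsystems.
#' @slot dOut named numeric, per-transaction out-degree (stacked order:
#'   active then inactive).
#'
#' @exportClass BipartiteGraph
setClass("BipartiteGraph",
  representation(
    La     = "Matrix",
    Lb     = "Matrix",
    items  = "character",
    posIds = "character",
    negIds = "character",
    dIn    = "numeric",
    dOut   = "numeric"
  )
)

setValidity("BipartiteGraph", function(object) {
  msg <- NULL
  if (ncol(object@La) != length(object@items) ||
      ncol(object@Lb) != length(object@items))
    msg <- c(msg, "incidence column counts must equal the item universe size")
  if (nrow(object@La) != length(object@posIds) ||
      nrow(object@Lb) != length(object@negIds))
    msg <- c(msg, "incidence row counts must match subsystem id vectors")
  entries <- c(object@La@x, object@Lb@x)
  if (length(entries) && !all(entries %in% c(0, 1)))
    msg <- c(msg, "incidence entries must be 0/1")
  din <- Matrix::colSums(object@La) + Matrix::colSums(object@Lb)
  if (!isTRUE(all.equal(unname(object@dIn), unname(din))))
    msg <- c(msg, "dIn inconsistent with incidence column sums")
  dout <- c(Matrix::rowSums(object@La), Matrix::rowSums(object@Lb))
  if (!isTRUE(all.equal(unname(object@dOut), unname(dout))))
    msg <- c(msg, "dOut inconsistent with incidence row sums")
  if (any(object@dOut == 0))
    msg <- c(msg, "zero out-degree transactions must be dropped before construction")
  if (is.null(msg)) TRUE else msg
})

#' Link-weighting parameters
#'
#' @slot beta class factor in [0, 1]; weight of the active subsystem in the
#'   mixed recursion. Values above 0.5 promote features of active compounds.
#' @slot variant one of \code{"unified"}, \code{"hits"}, \code{"pagerank"}.
#' @slot damping PageRank damping factor in (0, 1].
#' @slot tol L1 convergence tolerance of the power iteration.
#' @slot maxIter iteration cap.
#' @slot normalizeMeanToOne rescale converged scores to mean weight 1.
#' @exportClass LinkWeightParam
setClass("LinkWeightParam",
  representation(beta = "numeric", variant = "character", damping = "numeric",
                 tol = "numeric", maxIter = "integer",
                 normalizeMeanToOne = "logical"))

setValidity("LinkWeightParam", function(object) {
  msg <- NULL
  if (object@beta < 0 || object@beta > 1) msg <- c(msg, "beta must be in [0,1]")
  if (!object@variant %in% c("hits", "pagerank", "unified"))
    msg <- c(msg, "variant must be one of hits, pagerank, unified")
  if (object@damping <= 0 || object@damping > 1)
    msg <- c(msg, "damping must be in (0,1]")
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct link-weighting parameters
#'
#' Defaults follow the method's reference settings: class factor
#' \code{beta = 0.9}, unified HITS/PageRank variant, damping 0.85,
#' L1 tolerance 1e-8, mean-one rescaling of the final weights.
#'
#' @param beta class factor in [0, 1].
#' @param variant \code{"unified"}, \code{"hits"} or \code{"pagerank"}.
#' @param damping damping factor in (0, 1] (pagerank variant).
#' @param tol L1 convergence tolerance.
#' @param maxIter maximum number of power iterations.
#' @param normalizeMeanToOne logical; rescale converged authority scores so
#'   the mean item weight is 1.
#' @return a \linkS4class{LinkWeightParam}
#' @examples
#' linkWeightParam(beta = 0.9, variant = "hits")
#' @export
linkWeightParam <- function(beta = 0.9, variant = c("unified", "hits", "pagerank"),
                            damping = 0.85, tol = 1e-8, maxIter = 1000L,
                            normalizeMeanToOne = TRUE) {
  new("LinkWeightParam", beta = beta, variant = match.arg(variant),
      damping = damping, tol = tol, maxIter = as.integer(maxIter),
      normalizeMeanToOne = normalizeMeanToOne)
}

#' Mining parameters
#'
#' @slot minsup minimum support threshold in [0, 1].
#' @slot minconf minimum rule confidence in [0, 1].
#' @slot maxLen maximum antecedent length.
#' @slot maxCandidates budget on cumulative candidate itemsets across levels.
#' @slot supportMode \code{"adjusted"}, \code{"classical"} or \code{"weighted"}.
#' @exportClass MiningParam
setClass("MiningParam",
  representation(minsup = "numeric", minconf = "numeric", maxLen = "integer",
                 maxCandidates = "integer", supportMode = "character"))

setValidity("MiningParam", function(object) {
  msg <- NULL
  if (object@minsup < 0 || object@minsup > 1) msg <- c(msg, "minsup must be in [0,1]")
  if (object@minconf < 0 || object@minconf > 1) msg <- c(msg, "minconf must be in [0,1]")
  if (object@maxLen < 1L) msg <- c(msg, "maxLen must be >= 1")
  if (object@maxCandidates < 1L) msg <- c(msg, "maxCandidates must be >= 1")
  if (!object@supportMode %in% c("classical", "weighted", "adjusted"))
    msg <- c(msg, "supportMode must be one of classical, weighted, adjusted")
  if (is.null(msg)) TRUE else msg
})

#' Construct mining parameters
#'
#' Defaults mirror the reference mining settings: antecedents of at most 4
#' items and a budget of 200,000 cumulative candidate itemsets. Support mode
#' \code{"adjusted"} uses the adjusted weighted support (AWS), which keeps
#' the downward closure property and hence sound level-wise pruning.
#'
#' @param minsup minimum support in [0, 1].
#' @param minconf minimum confidence in [0, 1].
#' @param maxLen maximum antecedent length.
#' @param maxCandidates candidate itemset budget (cumulative over levels).
#' @param supportMode \code{"adjusted"}, \code{"classical"} or
#'   \code{"weighted"}. The weighted mode violates downward closure and is
#'   refused by the level-wise miner (use \code{\link{enumerateItemsets}}).
#' @return a \linkS4class{MiningParam}
#' @examples
#' miningParam(minsup = 0.2, minconf = 0.7)
#' @export
miningParam <- function(minsup = 0.2, minconf = 0.7, maxLen = 4L,
                        maxCandidates = 200000L,
                        supportMode = c("adjusted", "classical", "weighted")) {
  new("MiningParam", minsup = minsup, minconf = minconf,
      maxLen = as.integer(maxLen), maxCandidates = as.integer(maxCandidates),
      supportMode = match.arg(supportMode))
}

#' Synthetic dataset parameters
#'
#' @slot nTransactions number of transactions to generate.
#' @slot nItems number of background items (\code{"f1"}, \code{"f2"}, ...).
#' @slot classBalance probability of the positive class, in (0, 1).
#' @slot plantedRules list of planted rules, each a list with elements
#'   \code{antecedent} (character), \code{class} and \code{penetrance}.
#' @slot backgroundItemProb independent inclusion probability of each
#'   background item.
#' @slot seed integer seed of the generator's single pseudo-random stream.
#' @exportClass SynthParam
setClass("SynthParam",
  representation(nTransactions = "integer", nItems = "integer",
                 classBalance = "numeric", plantedRules = "list",
                 backgroundItemProb = "numeric", seed = "integer"))

setValidity("SynthParam", function(object) {
  msg <- NULL
  if (object@nTransactions < 0L) msg <- c(msg, "nTransactions must be >= 0")
  if (object@nItems < 0L) msg <- c(msg, "nItems must be >= 0")
  if (object@classBalance <= 0 || object@classBalance >= 1)
    msg <- c(msg, "classBalance must be in (0,1)")
  if (object@backgroundItemProb < 0 || object@backgroundItemProb > 1)
    msg <- c(msg, "backgroundItemProb must be in [0,1]")
  for (r in object@plantedRules) {
    if (!all(c("antecedent", "class", "penetrance") %in% names(r))) {
      msg <- c(msg, "each planted rule needs antecedent, class, penetrance")
      break
    }
    if (r$penetrance < 0 || r$penetrance > 1) {
      msg <- c(msg, "penetrance must be in [0,1]")
      break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct synthetic dataset parameters
#'
#' @param nTransactions number of transactions.
#' @param nItems number of background items named \code{"f1"} ...
#' @param classBalance probability that a transaction is positive.
#' @param plantedRules list of lists with \code{antecedent}, \code{class},
#'   \code{penetrance}: for each transaction of the matching class the whole
#'   antecedent is inserted with probability \code{penetrance}.
#' @param backgroundItemProb per-item independent inclusion probability.
#' @param seed integer seed.
#' @return a \linkS4class{SynthParam}
#' @examples
#' synthParam(100, 10, plantedRules = list(
#'   list(antecedent = "f1", class = "pos", penetrance = 1)))
#' @export
synthParam <- function(nTransactions = 200L, nItems = 20L, classBalance = 0.5,
                       plantedRules = list(), backgroundItemProb = 0.1,
                       seed = 1L) {
  plantedRules <- lapply(plantedRules, function(r) {
    r$antecedent <- as.character(r$antecedent)
    r
  })
  new("SynthParam", nTransactions = as.integer(nTransactions),
      nItems = as.integer(nItems), classBalance = classBalance,
      plantedRules = plantedRules, backgroundItemProb = backgroundItemProb,
      seed = as.integer(seed))
}

#' RuleClassifier: precedence-ordered class association rules + default class
#'
#' Produced by \code{\link{buildClassifier}}. Prediction walks \code{rules}
#' in order and fires the first rule whose antecedent is contained in the
#' transaction; when no rule fires, \code{defaultClass} is returned.
#'
#' @slot rules data.frame with columns \code{antecedent} (items joined by
#'   \code{";"}), \code{class}, \code{support}, \code{confidence},
#'   \code{genId}; rows in precedence order.
#' @slot defaultClass class label used when no rule matches.
#' @slot classes the class universe seen at training time.
#' @slot trainingAccuracy fraction of training transactions classified
#'   correctly by the pruned rule list plus default.
#' @exportClass RuleClassifier
setClass("RuleClassifier",
  representation(rules = "data.frame", defaultClass = "character",
                 classes = "character", trainingAccuracy = "numeric"))

setValidity("RuleClassifier", function(object) {
  msg <- NULL
  need <- c("antecedent", "class", "support", "confidence", "genId")
  if (!all(need %in% names(object@rules)))
    msg <- c(msg, paste("rules must have columns:", paste(need, collapse = ", ")))
  if (length(object@defaultClass) != 1L || !object@defaultClass %in% object@classes)
    msg <- c(msg, "defaultClass must be one of the classes")
  if (length(object@trainingAccuracy) == 1L &&
      (object@trainingAccuracy < 0 || object@trainingAccuracy > 1))
    msg <- c(msg, "trainingAccuracy must be in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' EvalReport: cross-validation result
#'
#' @slot foldAccuracies per-fold held-out accuracies.
#' @slot meanAccuracy arithmetic mean of the fold accuracies.
#' @slot folds list of integer vectors: the test indices of each fold
#'   (a disjoint cover of the dataset).
#' @slot config snapshot of the pipeline configuration.
#' @slot seed integer seed used for the fold assignment.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(foldAccuracies = "numeric", meanAccuracy = "numeric",
                 folds = "list", config = "list", seed = "integer"))

setValidity("EvalReport", function(object) {
  msg <- NULL
  if (length(object@foldAccuracies) &&
      !isTRUE(all.equal(object@meanAccuracy, mean(object@foldAccuracies))))
    msg <- c(msg, "meanAccuracy must be the mean of foldAccuracies")
  if (length(object@folds) != length(object@foldAccuracies))
    msg <- c(msg, "one accuracy per fold required")
  if (is.null(msg)) TRUE else msg
})
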