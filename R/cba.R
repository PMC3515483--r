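#' @include AllClasses.R warm.R
NULL

.splitAntecedent <- function(s) {
  if (!nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
}

# majority class of a label subset; ties broken toward the globally more
# frequent class, then toward class-universe order
.majorityClass <- function(labels, classes, globalCounts) {
  if (!length(labels)) {
    cand <- classes[globalCounts == max(globalCounts)]
    return(cand[1L])
  }
  tab <- table(factor(labels, levels = classes))
  cand <- classes[tab == max(tab)]
  if (length(cand) > 1L)
    cand <- cand[globalCounts[cand] == max(globalCounts[cand])]
  cand[1L]
}

#' Generate class association rules from frequent antecedents
#'
#' For every frequent antecedent \eqn{X} (a row of \code{frequent}) and
#' every class \eqn{c}, the rule \eqn{X \rightarrow c} is scored with the
#' adjusted-weighted-support machinery: class labels act as virtual items
#' of weight equal to the mean item weight, so each transaction weight is
#' augmented by that constant, and
#' \deqn{supp(X \to c) = \sum_{t \supseteq X, class(t)=c} tw(t) / \sum_t tw(t),
#'       \quad conf(X \to c) = \sum_{t \supseteq X, class(t)=c} tw(t) /
#'             \sum_{t \supseteq X} tw(t).}
#' Under \code{supportMode = "classical"} the transaction weights collapse
#' to 1 and these are the ordinary CBA support and confidence. Rules with
#' support \eqn{\ge} \code{minsup} and confidence \eqn{\ge} \code{minconf}
#' are kept, each stamped with a \code{genId} in discovery order
#' (antecedents in mining order, classes in class-universe order).
#'
#' @param frequent data.frame from \code{\link{mineFrequentItemsets}}.
#' @param dataset a labeled \linkS4class{TransactionDataset}.
#' @param weights an \linkS4class{ItemWeights}.
#' @param param a \linkS4class{MiningParam}.
#' @return data.frame with columns \code{antecedent}, \code{class},
#'   \code{support}, \code{confidence}, \code{genId}
#' @export
generateRules <- function(frequent, dataset, weights, param = miningParam()) {
  if (!isLabeled(dataset))
    stop("rule generation requires a fully labeled dataset")
  if (param@supportMode == "weighted")
    stop("supportMode 'weighted' is not a sound rule-support mode; ",
         "use 'adjusted' or 'classical'")
  n <- length(dataset@ids)
  labels <- dataset@labels
  if (param@supportMode == "adjusted") {
    classW <- mean(weights@weights)
    tw <- .transactionWeights(dataset, weights) + classW
  } else {
    tw <- rep(1, n)
  }
  total <- sum(tw)
  rows <- list()
  for (i in seq_len(nrow(frequent))) {
    X <- .splitAntecedent(frequent$itemset[i])
    sup <- .supportingRows(X, dataset)
    denom <- sum(tw[sup])
    if (denom <= 0) next
    for (cl in dataset@classes) {
      num <- sum(tw[sup[labels[sup] == cl]])
      support <- num / total
      confidence <- num / denom
      if (support >= param@minsup && confidence >= param@minconf)
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = frequent$itemset[i], class = cl,
          support = support, confidence = confidence,
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(antecedent = character(), class = character(),
               support = numeric(), confidence = numeric(),
               stringsAsFactors = FALSE)
  out$genId <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank rules by CBA precedence
#'
#' Total order: higher confidence first, ties by higher support, remaining
#' ties by smaller \code{genId} (earlier generated, hence shorter-or-equal
#' antecedent). The sort is stable and deterministic.
#'
#' @param ruleSet data.frame as returned by \code{\link{generateRules}}.
#' @return the same data.frame, rows reordered to precedence order
#' @export
rankRules <- function(ruleSet) {
  if (!nrow(ruleSet)) return(ruleSet)
  out <- ruleSet[order(-ruleSet$confidence, -ruleSet$support, ruleSet$genId), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a classifier by database-coverage pruning
#'
#' Walks the ranked rules in precedence order. A rule is kept iff it
#' correctly classifies at least one still-uncovered training transaction;
#' every transaction the kept rule matches is then marked covered. After
#' each kept rule the majority class of the uncovered remainder becomes the
#' provisional default, and the total training error of (kept rules so far
#' + that default) is recorded. The final classifier truncates the kept
#' list at the earliest prefix minimizing total training errors and appends
#' the corresponding default class; when no rule is kept it degenerates to
#' a default-only classifier predicting the global majority. Majority ties
#' break toward the globally more frequent class.
#'
#' @param ruleSet ranked rules (see \code{\link{rankRules}}).
#' @param dataset the labeled training \linkS4class{TransactionDataset}.
#' @return a \linkS4class{RuleClassifier}
#' @export
buildClassifier <- function(ruleSet, dataset) {
  if (!isLabeled(dataset))
    stop("classifier construction requires a fully labeled dataset")
  n <- length(dataset@ids)
  labels <- dataset@labels
  classes <- dataset@classes
  globalCounts <- table(factor(labels, levels = classes))
  globalDefault <- .majorityClass(labels, classes, globalCounts)
  defaults <- character()
  errors <- integer()
  keptIdx <- integer()
  uncovered <- rep(TRUE, n)
  ruleErrors <- 0L
  for (r in seq_len(nrow(ruleSet))) {
    X <- .splitAntecedent(ruleSet$antecedent[r])
    matches <- vapply(dataset@itemsets, function(t) all(X %in% t), logical(1))
    m <- uncovered & matches
    if (!any(m & labels == ruleSet$class[r])) next
    keptIdx <- c(keptIdx, r)
    ruleErrors <- ruleErrors + sum(labels[m] != ruleSet$class[r])
    uncovered[m] <- FALSE
    def <- .majorityClass(labels[uncovered], classes, globalCounts)
    defaults <- c(defaults, def)
    errors <- c(errors, ruleErrors + sum(labels[uncovered] != def))
  }
  if (!length(keptIdx)) {
    return(new("RuleClassifier",
               rules = ruleSet[integer(), , drop = FALSE],
               defaultClass = globalDefault, classes = classes,
               trainingAccuracy = 1 - sum(labels != globalDefault) / n))
  }
  best <- which.min(errors)              # earliest minimum
  rulesOut <- ruleSet[keptIdx[seq_len(best)], , drop = FALSE]
  rownames(rulesOut) <- NULL
  new("RuleClassifier", rules = rulesOut, defaultClass = defaults[best],
      classes = classes, trainingAccuracy = 1 - errors[best] / n)
}

#' Classify transactions by first matching rule
#'
#' Rules are tried in precedence order; the first rule whose antecedent is
#' contained in the transaction fires, and its class is returned. When no
#' rule fires, the default class is returned. Matching depends only on set
#' membership, not on the order of items inside the transaction.
#'
#' @param object a \linkS4class{RuleClassifier}.
#' @param newdata a \linkS4class{TransactionDataset}, a list of character
#'   itemsets, or a single character itemset.
#' @param ... ignored.
#' @return character vector of predicted class labels
#' @examples
#' toy <- toyCompoundData()$dataset
#' toy@labels <- c("pos", "pos", "pos", "neg", "neg", "neg")
#' toy@classes <- c("neg", "pos")
#' clf <- trainClassifier(toy, scheme = "uniform",
#'                        miningParam = miningParam(minsup = 0.2, minconf = 0.6))
#' predict(clf, toy)
#' @export
setMethod("predict", "RuleClassifier", function(object, newdata, ...) {
  sets <- if (is(newdata, "TransactionDataset")) newdata@itemsets
          else if (is.list(newdata)) lapply(newdata, as.character)
          else list(as.character(newdata))
  ants <- lapply(object@rules$antecedent, .splitAntecedent)
  vapply(sets, function(t) {
    for (r in seq_along(ants))
      if (all(ants[[r]] %in% t)) return(object@rules$class[r])
    object@defaultClass
  }, character(1))
})

#' Train a full link-weighted associative classifier
#'
#' Convenience wrapper for the whole pipeline: derive item weights (by the
#' requested scheme, unless given), mine frequent antecedents (with the
#' virtual class-item augmentation when \code{supportMode = "adjusted"}),
#' generate and rank class association rules, and prune them into a
#' \linkS4class{RuleClassifier}.
#'
#' @param dataset a labeled \linkS4class{TransactionDataset}.
#' @param weights optional \linkS4class{ItemWeights}; when missing, derived
#'   by \code{scheme}.
#' @param scheme \code{"link"}, \code{"frequency"} or \code{"uniform"}.
#' @param positiveClass class treated as active for the link scheme;
#'   defaults to the last class in the class universe.
#' @param linkParam a \linkS4class{LinkWeightParam} (link scheme only).
#' @param miningParam a \linkS4class{MiningParam}.
#' @return a \linkS4class{RuleClassifier}
#' @export
trainClassifier <- function(dataset, weights = NULL,
                            scheme = c("link", "frequency", "uniform"),
                            positiveClass = NULL,
                            linkParam = linkWeightParam(),
                            miningParam = linkAC::miningParam()) {
  if (!isLabeled(dataset))
    stop("classifier training requires a fully labeled dataset")
  if (is.null(weights)) {
    scheme <- match.arg(scheme)
    weights <- switch(scheme,
      uniform   = uniformWeights(dataset),
      frequency = frequencyWeights(dataset),
      link = {
        if (is.null(positiveClass))
          positiveClass <- dataset@classes[length(dataset@classes)]
        computeLinkWeights(buildBipartite(dataset, positiveClass), linkParam)
      })
  }
  extra <- if (miningParam@supportMode == "adjusted") mean(weights@weights) else 0
  frequent <- mineFrequentItemsets(dataset, weights, miningParam,
                                   extraTransactionWeight = extra)
  ruleSet <- rankRules(generateRules(frequent, dataset, weights, miningParam))
  buildClassifier(ruleSet, dataset)
}

#' Write / read a trained classifier as a structured text model file
#'
#' The model file holds a small header (default class, class universe,
#' training accuracy) followed by the ranked rule table in the rules-TSV
#' layout; the round-trip reproduces the classifier exactly.
#'
#' @param classifier a \linkS4class{RuleClassifier}.
#' @param path file path.
#' @return \code{writeClassifier}: invisibly, \code{path};
#'   \code{readClassifier}: a \linkS4class{RuleClassifier}.
#' @export
writeClassifier <- function(classifier, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#linkAC-classifier",
               paste0("defaultClass\t", classifier@defaultClass),
               paste0("classes\t", paste(classifier@classes, collapse = ";")),
               paste0("trainingAccuracy\t", fmtNum(classifier@trainingAccuracy)),
               "antecedent\tclass\tsupport\tconfidence\tgenId"), con)
  r <- classifier@rules
  if (nrow(r))
    writeLines(paste(r$antecedent, r$class, fmtNum(r$support),
                     fmtNum(r$confidence), r$genId, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || lines[1L] != "#linkAC-classifier")
    stop("not a linkAC classifier model file: ", path)
  getField <- function(i, key) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (f[1L] != key) stop("line ", i, ": expected field '", key, "'")
    if (length(f) < 2L) "" else f[2L]
  }
  defaultClass <- getField(2L, "defaultClass")
  classes <- strsplit(getField(3L, "classes"), ";", fixed = TRUE)[[1L]]
  acc <- as.numeric(getField(4L, "trainingAccuracy"))
  body <- lines[-(1:5)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  rulesDf <- data.frame(
    antecedent = vapply(fields, `[`, character(1), 1L),
    class      = vapply(fields, `[`, character(1), 2L),
    support    = as.numeric(vapply(fields, `[`, character(1), 3L)),
    confidence = as.numeric(vapply(fields, `[`, character(1), 4L)),
    genId      = as.integer(vapply(fields, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
  new("RuleClassifier", rules = rulesDf, defaultClass = defaultClass,
      classes = classes, trainingAccuracy = acc)
}
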