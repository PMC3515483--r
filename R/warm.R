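#' @include AllClasses.R linkrank.R
NULL

.weightOf <- function(items, weights) {
  w <- weights@weights[items]
  if (anyNA(w))
    stop("unknown item(s): ",
         paste(items[is.na(w)], collapse = ", "))
  w
}

# indices of transactions containing the itemset
.supportingRows <- function(itemset, dataset) {
  if (length(itemset) == 0L) return(seq_along(dataset@ids))
  bad <- setdiff(itemset, dataset@items)
  if (length(bad))
    stop("unknown item(s): ", paste(bad, collapse = ", "))
  which(vapply(dataset@itemsets, function(t) all(itemset %in% t), logical(1)))
}

# per-transaction weights (sum of member item weights)
.transactionWeights <- function(dataset, weights) {
  vapply(dataset@itemsets,
         function(t) if (length(t)) sum(.weightOf(t, weights)) else 0,
         numeric(1))
}

#' Itemset weight: mean of member item weights
#'
#' The aggregate weight \eqn{W(is)} of an itemset is the arithmetic mean of
#' its members' item weights.
#'
#' @param itemset character vector of items (nonempty).
#' @param weights an \linkS4class{ItemWeights} covering all members.
#' @return numeric scalar
#' @examples
#' toy <- toyCompoundData()
#' itemsetWeight(c("81", "83", "84"), toy$weights)  # 3.2/3
#' @export
itemsetWeight <- function(itemset, weights) {
  itemset <- as.character(itemset)
  if (length(itemset) == 0L) stop("itemset must be nonempty")
  mean(.weightOf(itemset, weights))
}

#' Classical support of an itemset
#'
#' Fraction of transactions containing the itemset. The empty itemset has
#' support 1 (every transaction contains it).
#'
#' @param itemset character vector of items.
#' @param dataset a nonempty \linkS4class{TransactionDataset}.
#' @return numeric in [0, 1]
#' @export
classicalSupport <- function(itemset, dataset) {
  n <- length(dataset@ids)
  if (n == 0L) stop("dataset is empty")
  length(.supportingRows(as.character(itemset), dataset)) / n
}

#' Weighted support: itemset weight times classical support
#'
#' \eqn{WS(is) = W(is) \times |S|/|T|} with \eqn{S} the supporting
#' transactions and \eqn{T} all transactions. Note that weighted support
#' violates the downward closure property: a superset can score higher than
#' one of its subsets, so it cannot drive level-wise pruning (see
#' \code{\link{adjustedWeightedSupport}}).
#'
#' @inheritParams itemsetWeight
#' @inheritParams classicalSupport
#' @return numeric \eqn{\ge 0}
#' @examples
#' toy <- toyCompoundData()
#' weightedSupport(c("81", "84"), toy$dataset, toy$weights)  # 1.2 * 4/6
#' @export
weightedSupport <- function(itemset, dataset, weights) {
  itemsetWeight(itemset, weights) * classicalSupport(itemset, dataset)
}

#' Transaction weight: sum of the weights of a transaction's items
#'
#' @param transaction character vector of items (a transaction's itemset);
#'   the empty transaction has weight 0.
#' @param weights an \linkS4class{ItemWeights} covering all members.
#' @return numeric \eqn{\ge 0}
#' @examples
#' toy <- toyCompoundData()
#' transactionWeight(c("81", "82", "83", "84"), toy$weights)  # 4.2
#' @export
transactionWeight <- function(transaction, weights) {
  transaction <- as.character(transaction)
  if (length(transaction) == 0L) return(0)
  sum(.weightOf(transaction, weights))
}

#' Adjusted weighted support (AWS)
#'
#' \eqn{AWS(is) = \sum_{t \supseteq is} tw(t) / \sum_{t \in T} tw(t)}, the
#' share of total transaction weight carried by the supporting transactions.
#' Because every transaction supporting a superset also supports each of its
#' subsets, \eqn{X \subseteq Y} implies \eqn{AWS(X) \ge AWS(Y)}: the
#' downward closure property holds and level-wise Apriori pruning is sound.
#' The empty itemset has AWS exactly 1.
#'
#' @inheritParams weightedSupport
#' @return numeric in [0, 1]
#' @examples
#' toy <- toyCompoundData()
#' adjustedWeightedSupport("81", toy$dataset, toy$weights)  # 16.2/21.6 = 0.75
#' @export
adjustedWeightedSupport <- function(itemset, dataset, weights) {
  if (length(dataset@ids) == 0L) stop("dataset is empty")
  tw <- .transactionWeights(dataset, weights)
  total <- sum(tw)
  if (total <= 0)
    stop("all transaction weights are zero; adjusted weighted support undefined")
  sum(tw[.supportingRows(as.character(itemset), dataset)]) / total
}

#' All support statistics of one itemset
#'
#' @inheritParams weightedSupport
#' @return one-row data.frame with columns \code{itemset}, \code{size},
#'   \code{itemsetWeight}, \code{classicalSupport}, \code{weightedSupport},
#'   \code{adjustedWeightedSupport}, \code{supportCount}
#' @examples
#' toy <- toyCompoundData()
#' itemsetStats(c("81", "83"), toy$dataset, toy$weights)
#' @export
itemsetStats <- function(itemset, dataset, weights) {
  itemset <- as.character(itemset)
  rows <- .supportingRows(itemset, dataset)
  tw <- .transactionWeights(dataset, weights)
  data.frame(
    itemset = paste(itemset, collapse = ";"),
    size = length(itemset),
    itemsetWeight = if (length(itemset)) itemsetWeight(itemset, weights) else NA_real_,
    classicalSupport = length(rows) / length(dataset@ids),
    weightedSupport = if (length(itemset))
      itemsetWeight(itemset, weights) * length(rows) / length(dataset@ids)
    else NA_real_,
    adjustedWeightedSupport = sum(tw[rows]) / sum(tw),
    supportCount = length(rows),
    stringsAsFactors = FALSE)
}

# shared mining engine internals ---------------------------------------------

# stats for a list of itemsets given precomputed structures; extraTw is a
# uniform additive transaction-weight term (virtual class item, see cba)
.statsTable <- function(sets, dataset, weights, extraTw = 0) {
  n <- length(dataset@ids)
  tw <- .transactionWeights(dataset, weights) + extraTw
  total <- sum(tw)
  do.call(rbind, lapply(sets, function(is) {
    rows <- .supportingRows(is, dataset)
    data.frame(
      itemset = paste(is, collapse = ";"),
      size = length(is),
      itemsetWeight = mean(.weightOf(is, weights)),
      classicalSupport = length(rows) / n,
      weightedSupport = mean(.weightOf(is, weights)) * length(rows) / n,
      adjustedWeightedSupport = sum(tw[rows]) / total,
      supportCount = length(rows),
      stringsAsFactors = FALSE)
  }))
}

.supportColumn <- function(mode) switch(mode,
  classical = "classicalSupport",
  weighted  = "weightedSupport",
  adjusted  = "adjustedWeightedSupport")

#' Mine frequent itemsets by level-wise (Apriori) search
#'
#' Candidates of size \eqn{k} are joined from frequent \eqn{(k-1)}-itemsets
#' sharing a \eqn{(k-2)}-prefix under the dataset's fixed total item order;
#' a candidate survives only if all of its \eqn{(k-1)}-subsets are frequent
#' and its support under \code{supportMode} reaches \code{minsup}. An
#' itemset must additionally occur in at least one transaction to count as
#' frequent, so a zero threshold enumerates exactly the observed itemsets.
#' Expansion stops at \code{maxLen} or when the cumulative number of
#' candidates would exceed \code{maxCandidates} (a message reports the
#' truncation). Mining is fully deterministic.
#'
#' Support mode \code{"weighted"} is refused: weighted support violates the
#' downward closure property, so level-wise pruning would silently drop
#' frequent supersets of infrequent itemsets. Use
#' \code{\link{enumerateItemsets}} for exhaustive weighted-support search on
#' small universes.
#'
#' @param dataset a nonempty \linkS4class{TransactionDataset}.
#' @param weights an \linkS4class{ItemWeights}; defaults to
#'   \code{\link{uniformWeights}} on the dataset.
#' @param param a \linkS4class{MiningParam}.
#' @param extraTransactionWeight uniform additive term on every transaction
#'   weight. The training pipeline uses this to account for the virtual
#'   class item each labeled transaction carries (weight = mean item
#'   weight), so that antecedent supports match the class-augmented rule
#'   supports. Leave at 0 for plain mining.
#' @return data.frame of frequent itemsets (columns as
#'   \code{\link{itemsetStats}} plus \code{support}, the column selected by
#'   \code{supportMode}), sorted by size then lexicographically.
#' @examples
#' toy <- toyCompoundData()
#' mineFrequentItemsets(toy$dataset, toy$weights,
#'                      miningParam(minsup = 0.3, supportMode = "adjusted"))
#' @export
mineFrequentItemsets <- function(dataset, weights = uniformWeights(dataset),
                                 param = miningParam(),
                                 extraTransactionWeight = 0) {
  if (length(dataset@ids) == 0L) stop("dataset is empty")
  if (param@supportMode == "weighted")
    stop("supportMode 'weighted' violates the downward closure property; ",
         "level-wise pruning would be unsound. Use enumerateItemsets() ",
         "for exhaustive search on small universes.")
  items <- dataset@items
  n <- length(dataset@ids)
  tw <- .transactionWeights(dataset, weights) + extraTransactionWeight
  total <- sum(tw)
  if (param@supportMode == "adjusted" && total <= 0)
    stop("all transaction weights are zero; adjusted weighted support undefined")
  M <- as.matrix(.incidence(dataset) > 0)   # dense logical, fine at desk scale
  isFrequent <- function(cols) {            # cols: integer item indices
    inAll <- rowSums(M[, cols, drop = FALSE]) == length(cols)
    cnt <- sum(inAll)
    sup <- switch(param@supportMode,
                  classical = cnt / n,
                  adjusted  = sum(tw[inAll]) / total)
    cnt >= 1L && sup >= param@minsup
  }
  frequent <- list()                        # per level: integer index vectors
  cand <- as.list(seq_along(items))
  used <- 0L
  k <- 1L
  repeat {
    used <- used + length(cand)
    if (used > param@maxCandidates) {
      message("candidate budget (", param@maxCandidates, ") exceeded at level ",
              k, "; deeper levels truncated")
      break
    }
    lvl <- Filter(isFrequent, cand)
    if (!length(lvl)) break
    frequent[[k]] <- lvl
    if (k >= param@maxLen) break
    # join: frequent k-itemsets sharing a (k-1)-prefix under the item order;
    # a candidate survives only if all of its k-subsets are frequent
    prevKeys <- vapply(lvl, paste, character(1), collapse = " ")
    cand <- list()
    for (i in seq_along(lvl)) {
      for (j in seq_along(lvl)) {
        if (j <= i) next
        a <- lvl[[i]]; b <- lvl[[j]]
        if ((k == 1L || identical(a[-k], b[-k])) && a[k] != b[k]) {
          cc <- c(if (k > 1L) a[-k], sort(c(a[k], b[k])))
          ok <- all(vapply(seq_along(cc), function(d)
            paste(cc[-d], collapse = " ") %in% prevKeys, logical(1)))
          if (ok) cand[[length(cand) + 1L]] <- cc
        }
      }
    }
    if (!length(cand)) break
    k <- k + 1L
  }
  sets <- unlist(frequent, recursive = FALSE)
  if (!length(sets)) {
    return(data.frame(itemset = character(), size = integer(),
                      itemsetWeight = numeric(), classicalSupport = numeric(),
                      weightedSupport = numeric(),
                      adjustedWeightedSupport = numeric(),
                      supportCount = integer(), support = numeric(),
                      stringsAsFactors = FALSE))
  }
  keys <- vapply(sets, function(ix) paste(sprintf("%08d", ix), collapse = ""),
                 character(1))
  ord <- order(lengths(sets), keys)
  out <- .statsTable(lapply(sets[ord], function(ix) items[ix]), dataset, weights,
                     extraTw = extraTransactionWeight)
  out$support <- out[[.supportColumn(param@supportMode)]]
  rownames(out) <- NULL
  out
}

#' Exhaustively enumerate itemsets with their supports
#'
#' Brute-force companion to \code{\link{mineFrequentItemsets}} for small
#' item universes: every nonempty itemset up to \code{maxLen} items that
#' occurs in at least one transaction is scored, with a \code{frequent}
#' flag under the requested support mode. This is the only sound way to
#' search under plain weighted support, which breaks downward closure.
#'
#' @inheritParams mineFrequentItemsets
#' @param maxUniverse guard: refuse universes larger than this (default 16).
#' @return data.frame of itemset statistics plus \code{support} and
#'   \code{frequent} columns, sorted by size then lexicographically.
#' @examples
#' toy <- toyCompoundData()
#' e <- enumerateItemsets(toy$dataset, toy$weights,
#'                        miningParam(minsup = 0.3, supportMode = "weighted"))
#' subset(e, itemset %in% c("81;83", "81;83;84"))
#' @export
enumerateItemsets <- function(dataset, weights = uniformWeights(dataset),
                              param = miningParam(), maxUniverse = 16L) {
  items <- dataset@items
  if (length(items) > maxUniverse)
    stop("item universe too large for exhaustive enumeration (",
         length(items), " > ", maxUniverse, ")")
  if (length(dataset@ids) == 0L) stop("dataset is empty")
  sets <- list()
  for (k in seq_len(min(param@maxLen, length(items)))) {
    combs <- utils::combn(seq_along(items), k, simplify = FALSE)
    sets <- c(sets, lapply(combs, function(ix) items[ix]))
  }
  out <- .statsTable(sets, dataset, weights)
  out <- out[out$supportCount >= 1L, , drop = FALSE]
  out$support <- out[[.supportColumn(param@supportMode)]]
  out$frequent <- out$support >= param@minsup
  rownames(out) <- NULL
  out
}
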