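#' @include AllClasses.R evaluation.R
NULL

#' Generate a labeled transaction dataset with planted rules
#'
#' Draws transactions from a single seeded pseudo-random stream with a
#' documented draw order, so regeneration is bit-stable: for each
#' transaction in turn, (1) one uniform draw decides the class (positive
#' \code{"pos"} with probability \code{classBalance}, otherwise
#' \code{"neg"}); (2) one uniform draw per background item, in item order,
#' includes it with probability \code{backgroundItemProb}; (3) for each
#' planted rule whose class matches, in rule order, one uniform draw
#' inserts the whole antecedent with probability \code{penetrance}.
#' The expected classical support of a planted antecedent (ignoring
#' background collisions) is therefore \code{classBalance * penetrance}
#' for a positive-class rule.
#'
#' @param param a \linkS4class{SynthParam}. Planted-rule classes must be
#'   \code{"pos"} or \code{"neg"}.
#' @return a \linkS4class{TransactionDataset} with classes
#'   \code{c("neg", "pos")}
#' @examples
#' generateTransactions(synthParam(10, 5, plantedRules = list(
#'   list(antecedent = "f1", class = "pos", penetrance = 1)),
#'   backgroundItemProb = 0, seed = 42))
#' @export
generateTransactions <- function(param) {
  bg <- if (param@nItems > 0L) paste0("f", seq_len(param@nItems)) else character()
  planted <- unique(unlist(lapply(param@plantedRules, `[[`, "antecedent")))
  items <- sort(unique(c(bg, planted)))
  n <- param@nTransactions
  .withSeed(param@seed, {
    sets <- vector("list", n)
    labels <- character(n)
    for (i in seq_len(n)) {
      cls <- if (stats::runif(1) < param@classBalance) "pos" else "neg"
      labels[i] <- cls
      t <- bg[stats::runif(param@nItems) < param@backgroundItemProb]
      for (r in param@plantedRules) {
        if (r$class == cls && stats::runif(1) < r$penetrance)
          t <- union(t, r$antecedent)
      }
      sets[[i]] <- t
    }
    TransactionDataset(ids = paste0("S", seq_len(n)), itemsets = sets,
                       labels = labels, items = items,
                       classes = c("neg", "pos"))
  })
}

#' Generate a dataset with class-skewed marker items
#'
#' Like \code{\link{generateTransactions}} without planted rules, but one
#' named item appears with probability \code{activeRate} in positive
#' transactions and \code{inactiveRate} in negative ones. An optional
#' \code{mirrorItem} receives the swapped rates, giving a matched pair of
#' oppositely skewed items — the construction used to show that link
#' weighting with class factor \eqn{\beta > 0.5} promotes items whose
#' connections are mostly active compounds. Draw order per transaction:
#' class, background items in item order, \code{item}, then
#' \code{mirrorItem}.
#'
#' @param param a \linkS4class{SynthParam} (its \code{plantedRules} are
#'   ignored here).
#' @param item name of the skewed item.
#' @param activeRate inclusion probability in positive transactions.
#' @param inactiveRate inclusion probability in negative transactions.
#' @param mirrorItem optional name of a matched item with the rates
#'   swapped.
#' @return a \linkS4class{TransactionDataset}
#' @examples
#' generateClassSkewedFeature(synthParam(20, 3, seed = 5), "mk",
#'                            activeRate = 0.9, inactiveRate = 0.1,
#'                            mirrorItem = "mk2")
#' @export
generateClassSkewedFeature <- function(param, item, activeRate, inactiveRate,
                                       mirrorItem = NULL) {
  stopifnot(activeRate >= 0, activeRate <= 1,
            inactiveRate >= 0, inactiveRate <= 1)
  bg <- if (param@nItems > 0L) paste0("f", seq_len(param@nItems)) else character()
  items <- sort(unique(c(bg, item, mirrorItem)))
  n <- param@nTransactions
  .withSeed(param@seed, {
    sets <- vector("list", n)
    labels <- character(n)
    for (i in seq_len(n)) {
      cls <- if (stats::runif(1) < param@classBalance) "pos" else "neg"
      labels[i] <- cls
      t <- bg[stats::runif(param@nItems) < param@backgroundItemProb]
      p <- if (cls == "pos") activeRate else inactiveRate
      if (stats::runif(1) < p) t <- c(t, item)
      if (!is.null(mirrorItem)) {
        pm <- if (cls == "pos") inactiveRate else activeRate
        if (stats::runif(1) < pm) t <- c(t, mirrorItem)
      }
      sets[[i]] <- t
    }
    TransactionDataset(ids = paste0("S", seq_len(n)), itemsets = sets,
                       labels = labels, items = items,
                       classes = c("neg", "pos"))
  })
}
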