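#' @include AllClasses.R
NULL

# sparse 0/1 incidence (transactions x items) over the dataset's item order
.incidence <- function(dataset, ids = dataset@ids) {
  idx <- match(ids, dataset@ids)
  items <- dataset@items
  sets <- dataset@itemsets[idx]
  j <- match(unlist(sets, use.names = FALSE), items)
  i <- rep(seq_along(sets), lengths(sets))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(sets), length(items)),
                       dimnames = list(ids, items))
}

# pseudo-inverse of a degree vector: 1/d with 0 where d == 0
.pinv <- function(d) ifelse(d > 0, 1 / d, 0)

#' Build the class-split bipartite graph of a labeled dataset
#'
#' Transactions become one node set, items the other, with an edge wherever
#' a transaction contains an item. Transactions labeled
#' \code{positiveClass} form the "active" subsystem \code{a}; all other
#' labeled transactions form the "inactive" subsystem \code{b}. Transactions
#' with empty itemsets carry no link information and are dropped with a
#' warning.
#'
#' @param dataset a labeled \linkS4class{TransactionDataset}.
#' @param positiveClass the class treated as active/positive.
#' @return a \linkS4class{BipartiteGraph}
#' @examples
#' toy <- toyCompoundData()$dataset
#' toy@labels <- c("pos", "pos", "pos", "neg", "neg", "neg")
#' toy@classes <- c("neg", "pos")
#' buildBipartite(toy, "pos")
#' @export
buildBipartite <- function(dataset, positiveClass) {
  if (!isLabeled(dataset))
    stop("dataset must be fully labeled to build a bipartite graph")
  if (!positiveClass %in% dataset@classes)
    stop("unknown class label: ", positiveClass)
  empty <- lengths(dataset@itemsets) == 0L
  if (any(empty)) {
    warning(sum(empty), " transaction(s) with empty itemsets dropped from the graph")
  }
  keep <- !empty
  posIds <- dataset@ids[keep & dataset@labels == positiveClass]
  negIds <- dataset@ids[keep & dataset@labels != positiveClass]
  La <- .incidence(dataset, posIds)
  Lb <- .incidence(dataset, negIds)
  dIn <- Matrix::colSums(La) + Matrix::colSums(Lb)
  dOut <- c(Matrix::rowSums(La), Matrix::rowSums(Lb))
  new("BipartiteGraph", La = La, Lb = Lb, items = dataset@items,
      posIds = posIds, negIds = negIds, dIn = dIn, dOut = dOut)
}

#' Authority operator of one subsystem
#'
#' Returns the linear map on item-score vectors that one power-iteration
#' step applies for the named subsystem, under the chosen variant. With
#' \eqn{L} the subsystem's incidence and \eqn{D_{in}}, \eqn{D_{out}} the
#' diagonal degree scalings of that subsystem (pseudo-inverted where a
#' degree is zero):
#' \describe{
#'   \item{\code{hits}}{\eqn{A(x) = L^T L x}, the classic mutual
#'     reinforcement step.}
#'   \item{\code{pagerank}}{\eqn{A(x) = \alpha D_{in}^{-1} L^T D_{out}^{-1}
#'     L \tilde x + (1-\alpha) u} with \eqn{\tilde x} the L1-renormalized
#'     input, \eqn{u} uniform, and \eqn{\alpha} the damping factor. The zero
#'     vector maps to zero (no teleport mass is created from nothing).}
#'   \item{\code{unified}}{\eqn{A(x) = D_{in}^{-1/2} L^T D_{out}^{-1} L
#'     D_{in}^{-1/2} x}, the symmetric normalization that interpolates the
#'     two: HITS-style reinforcement with PageRank-style edge-weight
#'     normalization.}
#' }
#' All variants map nonnegative vectors to nonnegative vectors. An empty
#' subsystem yields the zero map.
#'
#' @param graph a \linkS4class{BipartiteGraph}.
#' @param system \code{"a"} (active) or \code{"b"} (inactive).
#' @param param a \linkS4class{LinkWeightParam}.
#' @return a function taking and returning a numeric vector of length
#'   \code{length(itemUniverse(graph))}
#' @export
authorityOperator <- function(graph, system = c("a", "b"),
                              param = linkWeightParam()) {
  system <- match.arg(system)
  L <- if (system == "a") graph@La else graph@Lb
  nItems <- length(graph@items)
  if (nrow(L) == 0L)
    return(function(x) numeric(nItems))
  dinInv  <- .pinv(Matrix::colSums(L))
  doutInv <- .pinv(Matrix::rowSums(L))
  variant <- param@variant
  if (variant == "hits") {
    function(x) unname(as.numeric(Matrix::crossprod(L, L %*% x)))
  } else if (variant == "unified") {
    s <- unname(sqrt(dinInv))
    function(x)
      unname(s * as.numeric(Matrix::crossprod(L, doutInv * as.numeric(L %*% (s * x)))))
  } else { # pagerank
    alpha <- param@damping
    dinInv <- unname(dinInv)
    function(x) {
      m <- sum(x)
      if (m == 0) return(numeric(nItems))
      xn <- x / m
      walk <- dinInv * as.numeric(Matrix::crossprod(L, doutInv * as.numeric(L %*% xn)))
      unname(alpha * walk + (1 - alpha) / nItems)
    }
  }
}

#' Derive item weights by class-mixed link analysis
#'
#' Runs the power iteration
#' \eqn{x^{(k+1)} \propto \beta A_a(x^{(k)}) + (1-\beta) A_b(x^{(k)})}
#' from a uniform start, L1-renormalizing each step, until the L1 change
#' falls below \code{tol} or \code{maxIter} is reached. \eqn{A_a} and
#' \eqn{A_b} are the \code{\link{authorityOperator}}s of the active and
#' inactive subsystems under the configured variant; for the unified
#' variant, whose operator carries the square-root in-degree scaling, the
#' mixing coefficients enter as \eqn{\sqrt\beta} and \eqn{\sqrt{1-\beta}}.
#' Items never observed in the data have no link evidence and receive
#' weight 0. The converged authority vector is rescaled to mean weight 1
#' by default so that weighted supports stay on the scale of classical
#' supports; hub scores of both subsystems are kept as diagnostics in
#' \code{metadata(...)$hubScores}.
#'
#' @param graph a \linkS4class{BipartiteGraph}.
#' @param param a \linkS4class{LinkWeightParam}.
#' @return an \linkS4class{ItemWeights} with provenance \code{"link"};
#'   \code{metadata} holds \code{converged}, \code{iterations}, and hub
#'   scores.
#' @examples
#' toy <- toyCompoundData()$dataset
#' toy@labels <- c("pos", "pos", "pos", "neg", "neg", "neg")
#' toy@classes <- c("neg", "pos")
#' g <- buildBipartite(toy, "pos")
#' computeLinkWeights(g, linkWeightParam(beta = 0.9))
#' @export
computeLinkWeights <- function(graph, param = linkWeightParam()) {
  nItems <- length(graph@items)
  if (all(graph@dIn == 0))
    stop("no item with nonzero in-degree; cannot derive link weights")
  opA <- authorityOperator(graph, "a", param)
  opB <- authorityOperator(graph, "b", param)
  if (param@variant == "unified") {
    wa <- sqrt(param@beta); wb <- sqrt(1 - param@beta)
  } else {
    wa <- param@beta; wb <- 1 - param@beta
  }
  x <- rep(1 / nItems, nItems)
  converged <- FALSE
  iter <- 0L
  while (iter < param@maxIter) {
    iter <- iter + 1L
    xn <- wa * opA(x) + wb * opB(x)
    s <- sum(xn)
    if (s <= 0)
      stop("authority mass vanished during iteration; check beta and the graph")
    xn <- xn / s
    if (sum(abs(xn - x)) < param@tol) {
      x <- xn
      converged <- TRUE
      break
    }
    x <- xn
  }
  if (!converged)
    warning("power iteration did not converge within ", param@maxIter,
            " iterations; returning last iterate")
  hub <- function(L) {
    if (nrow(L) == 0L) return(numeric(0))
    y <- as.numeric(L %*% x)
    if (sum(y) > 0) y <- y / sum(y)
    stats::setNames(y, rownames(L))
  }
  hubScores <- list(a = hub(graph@La), b = hub(graph@Lb))
  normalization <- "l1"
  if (param@normalizeMeanToOne) {
    x <- x / mean(x)
    normalization <- "mean_one"
  }
  itemWeights(stats::setNames(x, graph@items),
              normalization = normalization, provenance = "link",
              metadata = list(converged = converged, iterations = iter,
                              beta = param@beta, variant = param@variant,
                              hubScores = hubScores))
}

#' Baseline weighting schemes
#'
#' \code{frequencyWeights} weights each item proportionally to the number of
#' transactions containing it, rescaled to mean weight 1;
#' \code{uniformWeights} assigns every item weight exactly 1, reproducing
#' classical (unweighted) support semantics.
#'
#' @param dataset a \linkS4class{TransactionDataset}.
#' @return an \linkS4class{ItemWeights}
#' @examples
#' frequencyWeights(toyCompoundData()$dataset)
#' @export
frequencyWeights <- function(dataset) {
  counts <- Matrix::colSums(.incidence(dataset))
  normalization <- "none"
  if (length(counts) && mean(counts) > 0) {
    counts <- counts / mean(counts)
    normalization <- "mean_one"
  }
  itemWeights(stats::setNames(as.numeric(counts), dataset@items),
              normalization = normalization, provenance = "frequency")
}

#' @rdname frequencyWeights
#' @export
uniformWeights <- function(dataset) {
  itemWeights(stats::setNames(rep(1, length(dataset@items)), dataset@items),
              normalization = "mean_one", provenance = "uniform")
}
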