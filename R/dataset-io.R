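#' @include AllClasses.R
NULL

# shortest decimal representation that parses back to the same double, so
# written files are readable and write/read round-trips are exact
fmtNum <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L, 17L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Read a transaction dataset from a delimited text file
#'
#' Two dialects are supported.
#' \describe{
#'   \item{\code{itemlist}}{CSV with header \code{id,class,items}; the
#'     \code{items} field is a semicolon-separated item list and the
#'     \code{class} field may be empty. The item universe is the sorted union
#'     of observed items.}
#'   \item{\code{bitstring}}{TSV whose header declares the fingerprint width
#'     as \code{id<TAB>class<TAB>bits:<N>}; each row carries a fixed-width
#'     0/1 string (e.g. a 166-bit MACCS key). The item universe is all bit
#'     positions \code{"0"} ... \code{"N-1"}, set bits forming the itemset.}
#' }
#'
#' @param path file path.
#' @param format \code{"itemlist"} or \code{"bitstring"}.
#' @return a \linkS4class{TransactionDataset}
#' @examples
#' f <- system.file("extdata", "toy_compounds.csv", package = "linkAC")
#' readTransactions(f)
#' @seealso \code{\link{writeTransactions}}
#' @export
readTransactions <- function(path, format = c("itemlist", "bitstring")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > 1 & lines == "")]
  if (length(lines) < 1L) stop("empty file (no header): ", path)
  if (format == "itemlist") {
    header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
    if (length(header) != 3L || !identical(tolower(header), c("id", "class", "items")))
      stop("line 1: expected header 'id,class,items'")
    body <- lines[-1L]
    fields <- strsplit(body, ",", fixed = TRUE)
    ids <- character(length(body)); labels <- character(length(body))
    sets <- vector("list", length(body))
    for (i in seq_along(body)) {
      f <- fields[[i]]
      # a trailing empty items field is dropped by strsplit
      if (length(f) == 2L && endsWith(body[i], ",")) f <- c(f, "")
      if (length(f) != 3L)
        stop(sprintf("line %d: expected 3 comma-separated fields, got %d",
                     i + 1L, length(f)))
      ids[i] <- f[1L]
      labels[i] <- if (nzchar(f[2L])) f[2L] else NA_character_
      sets[[i]] <- if (nzchar(f[3L]))
        strsplit(f[3L], ";", fixed = TRUE)[[1L]] else character()
    }
    TransactionDataset(ids = ids, itemsets = sets, labels = labels)
  } else {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) != 3L || !identical(tolower(header[1:2]), c("id", "class")) ||
        !grepl("^bits:[0-9]+$", header[3L]))
      stop("line 1: expected header 'id\\tclass\\tbits:<N>'")
    width <- as.integer(sub("^bits:", "", header[3L]))
    items <- as.character(seq_len(width) - 1L)
    body <- lines[-1L]
    fields <- strsplit(body, "\t", fixed = TRUE)
    ids <- character(length(body)); labels <- character(length(body))
    sets <- vector("list", length(body))
    for (i in seq_along(body)) {
      f <- fields[[i]]
      if (length(f) == 2L && endsWith(body[i], "\t")) f <- c(f, "")
      if (length(f) != 3L)
        stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                     i + 1L, length(f)))
      bits <- f[3L]
      if (nchar(bits) != width)
        stop(sprintf("line %d: bitstring width %d does not match declared %d",
                     i + 1L, nchar(bits), width))
      if (grepl("[^01]", bits))
        stop(sprintf("line %d: bitstring contains characters other than 0/1", i + 1L))
      ids[i] <- f[1L]
      labels[i] <- if (nzchar(f[2L])) f[2L] else NA_character_
      sets[[i]] <- items[strsplit(bits, "", fixed = TRUE)[[1L]] == "1"]
    }
    TransactionDataset(ids = ids, itemsets = sets, labels = labels, items = items)
  }
}

#' Write a transaction dataset to a delimited text file
#'
#' Inverse of \code{\link{readTransactions}}: writing then reading gives back
#' an identical dataset (items, transactions, classes).
#'
#' @param dataset a \linkS4class{TransactionDataset}.
#' @param path output file path.
#' @param format \code{"itemlist"} or \code{"bitstring"}. The bitstring
#'   dialect requires the item universe to be the bit labels
#'   \code{"0"} ... \code{"N-1"}.
#' @return invisibly, \code{path}
#' @export
writeTransactions <- function(dataset, path, format = c("itemlist", "bitstring")) {
  format <- match.arg(format)
  lab <- ifelse(is.na(dataset@labels), "", dataset@labels)
  if (format == "itemlist") {
    rows <- vapply(seq_along(dataset@ids), function(i)
      paste(dataset@ids[i], lab[i],
            paste(dataset@itemsets[[i]], collapse = ";"), sep = ","),
      character(1))
    writeLines(c("id,class,items", rows), path)
  } else {
    width <- length(dataset@items)
    if (!identical(dataset@items, as.character(seq_len(width) - 1L)))
      stop("bitstring format requires item universe '0'...'", width - 1L, "'")
    rows <- vapply(seq_along(dataset@ids), function(i) {
      bits <- rep("0", width)
      bits[match(dataset@itemsets[[i]], dataset@items)] <- "1"
      paste(dataset@ids[i], lab[i], paste(bits, collapse = ""), sep = "\t")
    }, character(1))
    writeLines(c(sprintf("id\tclass\tbits:%d", width), rows), path)
  }
  invisible(path)
}

#' Write / read an item weight vector as two-column TSV
#'
#' Values are printed at full precision so the round-trip is exact.
#'
#' @param weights an \linkS4class{ItemWeights}.
#' @param path file path.
#' @return \code{writeWeights}: invisibly, \code{path};
#'   \code{readWeights}: an \linkS4class{ItemWeights} with provenance
#'   \code{"user"}.
#' @examples
#' tw <- toyCompoundData()$weights
#' f <- tempfile(fileext = ".tsv")
#' writeWeights(tw, f)
#' readWeights(f)
#' @export
writeWeights <- function(weights, path) {
  stopifnot(is(weights, "ItemWeights"))
  w <- weights@weights
  rows <- if (length(w)) paste(names(w), fmtNum(w), sep = "\t") else character()
  writeLines(c("item\tweight", rows), path)
  invisible(path)
}

#' @rdname writeWeights
#' @export
readWeights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || !identical(lines[1L], "item\tweight"))
    stop("line 1: expected header 'item\\tweight'")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("line %d: expected 2 tab-separated fields", bad[1L] + 1L))
  w <- as.numeric(vapply(fields, `[`, character(1), 2L))
  names(w) <- vapply(fields, `[`, character(1), 1L)
  itemWeights(w, normalization = "none", provenance = "user")
}

#' Write / read class association rules as TSV
#'
#' Columns: \code{antecedent} (items joined by \code{";"}), \code{class},
#' \code{support}, \code{confidence}, \code{rank} (1 = highest precedence).
#' Numeric columns are printed at full precision so the round-trip is exact.
#'
#' @param ruleSet data.frame of rules (as returned by
#'   \code{\link{rankRules}} or \code{\link{rules}}).
#' @param path file path.
#' @return \code{writeRules}: invisibly, \code{path}; \code{readRules}: a
#'   data.frame with the columns above.
#' @export
writeRules <- function(ruleSet, path) {
  n <- nrow(ruleSet)
  rows <- if (n) paste(ruleSet$antecedent, ruleSet$class,
                       fmtNum(ruleSet$support), fmtNum(ruleSet$confidence),
                       seq_len(n), sep = "\t") else character()
  writeLines(c("antecedent\tclass\tsupport\tconfidence\trank", rows), path)
  invisible(path)
}

#' @rdname writeRules
#' @export
readRules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L ||
      !identical(lines[1L], "antecedent\tclass\tsupport\tconfidence\trank"))
    stop("line 1: expected rules TSV header")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop(sprintf("line %d: expected 5 tab-separated fields", bad[1L] + 1L))
  data.frame(
    antecedent = vapply(fields, `[`, character(1), 1L),
    class      = vapply(fields, `[`, character(1), 2L),
    support    = as.numeric(vapply(fields, `[`, character(1), 3L)),
    confidence = as.numeric(vapply(fields, `[`, character(1), 4L)),
    rank       = as.integer(vapply(fields, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
}

#' Bundled worked example: six compounds over MDL key bits 81-85
#'
#' A small compound dataset encoded by five MDL public key bits together
#' with a per-bit weight vector, used throughout the documentation and tests
#' to trace every weighted-support quantity by hand. The dataset is
#' unlabeled; tests that need classes attach them explicitly.
#'
#' @return a list with elements \code{dataset}
#'   (\linkS4class{TransactionDataset}, compounds C1-C6) and \code{weights}
#'   (\linkS4class{ItemWeights} over bits 81-85).
#' @examples
#' toy <- toyCompoundData()
#' itemsets(toy$dataset)$C5
#' weights(toy$weights)["84"]
#' @export
toyCompoundData <- function() {
  dataset <- TransactionDataset(
    ids = paste0("C", 1:6),
    itemsets = list(
      c("81", "82", "83", "84"),
      c("82", "84"),
      c("81", "84"),
      c("81", "82", "84", "85"),
      c("81", "82", "83", "84", "85"),
      c("82", "83", "85")
    ),
    items = c("81", "82", "83", "84", "85")
  )
  w <- itemWeights(c("81" = 0.8, "82" = 1, "83" = 0.8, "84" = 1.6, "85" = 1),
                   normalization = "none", provenance = "user")
  list(dataset = dataset, weights = w)
}
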