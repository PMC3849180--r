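#' Construct a prediction matrix
#'
#' @param calls Logical (or 0/1) matrix, genes in rows (rownames = symbols),
#'   prediction tools in columns (colnames = tool names).
#' @return A [PredictionMatrix-class].
#' @export
PredictionMatrix <- function(calls) {
  m <- as.matrix(calls)
  storage.mode(m) <- "logical"
  rownames(m) <- toupper(rownames(m))
  new("PredictionMatrix", calls = m)
}

#' @describeIn PredictionMatrix Per-gene prediction-vote count P (number of
#'   tools calling the gene a target).
#' @param x A `PredictionMatrix`.
#' @export
predictionVotes <- function(x) {
  stopifnot(is(x, "PredictionMatrix"))
  setNames(as.integer(rowSums(x@calls)), rownames(x@calls))
}

#' @describeIn PredictionMatrix Genes predicted by at least `minTools`
#'   tools (default 1, the potential-target rule).
#' @param minTools Integer threshold.
#' @export
predictedGenes <- function(x, minTools = 1L) {
  P <- predictionVotes(x)
  names(P)[P >= minTools]
}

#' @describeIn PredictionMatrix Tool names.
#' @export
toolNames <- function(x) { stopifnot(is(x, "PredictionMatrix")); colnames(x@calls) }

setMethod("show", "PredictionMatrix", function(object) {
  cat(sprintf("PredictionMatrix: %d genes x %d tools; %d genes predicted by >=1 tool\n",
              nrow(object@calls), ncol(object@calls),
              sum(rowSums(object@calls) >= 1)))
})

#' Read / write a gene x tool prediction matrix (TSV)
#'
#' Format: first column `gene`, then one 0/1 column per tool.
#'
#' @param path TSV path.
#' @return [PredictionMatrix-class] (read) or the path (write, invisibly).
#' @export
readPredictionMatrix <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  PredictionMatrix(m)
}

#' @rdname readPredictionMatrix
#' @param x A [PredictionMatrix-class] to write.
#' @export
writePredictionMatrix <- function(x, path) {
  stopifnot(is(x, "PredictionMatrix"))
  out <- data.frame(gene = rownames(x@calls),
                    apply(x@calls, 2, as.integer), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Confidence-tier classification from vote counts
#'
#' Tiers, from strongest evidence down:
#' \describe{
#'   \item{high_confidence}{down-regulated in at least `dTop` experiments and
#'     predicted by at least `pHigh` tools, OR down-regulated in at least
#'     `dAlt` experiments.}
#'   \item{top_candidate}{D >= `dTop`.}
#'   \item{candidate}{D >= `dCandidate`.}
#'   \item{none}{everything else.}
#' }
#' Classification is monotone: increasing D or P never demotes a gene.
#'
#' @param D Integer vector of down-vote counts.
#' @param P Integer vector of prediction-vote counts (recycled if length 1).
#' @param dCandidate,dTop,dAlt,pHigh Tier thresholds (defaults 2/3/4/10).
#' @return Character vector of tier labels.
#' @examples
#' classifyTier(c(3, 4, 2, 3), c(10, 0, 12, 9))
#' @export
classifyTier <- function(D, P, dCandidate = 2L, dTop = 3L, dAlt = 4L,
                         pHigh = 10L) {
  stopifnot(all(D >= 0), all(P >= 0), dCandidate >= 1, dTop >= dCandidate,
            dAlt >= dTop, pHigh >= 1)
  if (length(P) == 1L) P <- rep(P, length(D))
  stopifnot(length(D) == length(P))
  tier <- rep("none", length(D))
  tier[D >= dCandidate] <- "candidate"
  tier[D >= dTop] <- "top_candidate"
  tier[(D >= dTop & P >= pHigh) | D >= dAlt] <- "high_confidence"
  tier
}

#' Combine down-votes and prediction votes into a ranked evidence table
#'
#' @param votes A [DownVoteTable-class].
#' @param predictions A [PredictionMatrix-class]; genes absent from it get
#'   P = 0.
#' @param ... Tier thresholds passed to [classifyTier()].
#' @return data.frame with columns `gene`, `D`, `P`, `predicted`, `tier`,
#'   ranked by (D, P) descending.
#' @export
evidenceTable <- function(votes, predictions, ...) {
  stopifnot(is(votes, "DownVoteTable"), is(predictions, "PredictionMatrix"))
  D <- voteCounts(votes)
  P <- predictionVotes(predictions)
  genes <- names(D)
  Pg <- ifelse(is.na(P[genes]), 0L, P[genes])
  out <- data.frame(gene = genes, D = unname(D), P = as.integer(unname(Pg)),
                    predicted = unname(Pg) >= 1L,
                    tier = classifyTier(unname(D), as.integer(unname(Pg)), ...),
                    stringsAsFactors = FALSE)
  out[order(-out$D, -out$P, out$gene), , drop = FALSE]
}

#' Exact enrichment test of predicted genes among top candidates
#'
#' Splits the candidate set by top-set membership and by predicted status,
#' and computes the one-sided (greater) exact hypergeometric tail p-value —
#' the directional Fisher exact test for "predicted genes are enriched among
#' top candidates". Exact arithmetic throughout; the two-sided Fisher p is
#' reported alongside.
#'
#' @param candidateSet Character vector (the universe, e.g. genes with
#'   D >= 2).
#' @param topSet Character vector, must be a subset of `candidateSet`.
#' @param predictedSet Character vector of predicted genes.
#' @return An [EnrichmentResult-class].
#' @examples
#' # the 2x2 layout: 24 top candidates of 266, 81 predicted overall, 20 of
#' # the top 24 predicted
#' res <- enrichmentTest(candidateSet = paste0("g", 1:266),
#'                       topSet = paste0("g", 1:24),
#'                       predictedSet = paste0("g", c(1:20, 25:85)))
#' enrichmentP(res)
#' @export
enrichmentTest <- function(candidateSet, topSet, predictedSet) {
  candidateSet <- unique(as.character(candidateSet))
  topSet <- unique(as.character(topSet))
  predictedSet <- unique(as.character(predictedSet))
  if (length(candidateSet) == 0L) stop("empty candidate set")
  if (!all(topSet %in% candidateSet))
    stop("top set must be a subset of the candidate set")
  rest <- setdiff(candidateSet, topSet)
  a <- sum(topSet %in% predictedSet)
  b <- length(topSet) - a
  cc <- sum(rest %in% predictedSet)
  d <- length(rest) - cc
  enrichmentFromCounts(a, b, cc, d)
}

#' @describeIn enrichmentTest Build the result directly from 2x2 counts
#'   (top&predicted, top&not, rest&predicted, rest&not).
#' @param topPred,topNot,restPred,restNot Non-negative integer counts.
#' @export
enrichmentFromCounts <- function(topPred, topNot, restPred, restNot) {
  stopifnot(topPred >= 0, topNot >= 0, restPred >= 0, restNot >= 0)
  tab <- matrix(as.integer(c(topPred, topNot, restPred, restNot)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("top", "rest"),
                                c("predicted", "not_predicted")))
  # one-sided upper tail of the exact hypergeometric distribution
  pG <- phyper(topPred - 1, m = topPred + restPred, n = topNot + restNot,
               k = topPred + topNot, lower.tail = FALSE)
  p2 <- fisher.test(tab)$p.value
  or <- (topPred * restNot) / (topNot * restPred)
  new("EnrichmentResult", table = tab, oddsRatio = or,
      pGreater = min(pG, 1), pTwoSided = min(p2, 1))
}

#' @describeIn enrichmentTest One-sided (greater) exact p-value.
#' @param x An `EnrichmentResult`.
#' @export
enrichmentP <- function(x) { stopifnot(is(x, "EnrichmentResult")); x@pGreater }

#' @describeIn enrichmentTest The 2x2 count table.
#' @export
enrichmentTable <- function(x) { stopifnot(is(x, "EnrichmentResult")); x@table }

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult (predicted among top candidates)\n")
  print(object@table)
  cat(sprintf("  odds ratio %.3g; one-sided exact p = %.3g (two-sided %.3g)\n",
              object@oddsRatio, object@pGreater, object@pTwoSided))
})
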