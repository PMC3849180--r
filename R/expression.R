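#' Construct an expression experiment
#'
#' @param id Short label, e.g. `"HACAT"`.
#' @param fc Named numeric vector of linear fold changes (treated/control).
#'   Supply either `fc` (with `calibrator`) or `downList`.
#' @param downList Character vector of down-regulated gene symbols.
#' @param calibrator Calibrator gene symbol; required in fold-change mode.
#'   The calibrator is a known target whose own fold change defines the
#'   experiment's down-regulation threshold.
#' @param species `"human"` or `"mouse"`. Mouse symbols are harmonized to
#'   uppercase when votes are counted.
#' @param log2fc Set `TRUE` if `fc` is on the log2 scale; values are then
#'   converted to linear ratios explicitly (never silently).
#' @return An [ExpressionExperiment-class] object.
#' @examples
#' ee <- ExpressionExperiment("HACAT",
#'   fc = c(MTOR = 0.88, HOXA1 = 0.70, GAPDH = 1.02), calibrator = "MTOR")
#' calibratorThreshold(ee)
#' @export
ExpressionExperiment <- function(id, fc = NULL, downList = NULL,
                                 calibrator = NA_character_,
                                 species = "human", log2fc = FALSE) {
  if (!is.null(fc) && !is.null(downList))
    stop("supply either 'fc' or 'downList', not both")
  if (is.null(fc) && is.null(downList))
    stop("an experiment needs fold changes or a down list")
  if (!is.null(fc)) {
    if (log2fc) fc <- 2^fc
    new("ExpressionExperiment", id = as.character(id), species = species,
        mode = "fold_change", fc = fc,
        calibrator = as.character(calibrator))
  } else {
    new("ExpressionExperiment", id = as.character(id), species = species,
        mode = "binary_list", downList = as.character(downList),
        calibrator = NA_character_)
  }
}

#' @describeIn ExpressionExperiment Experiment label.
#' @param x,object An `ExpressionExperiment`.
#' @export
experimentId <- function(x) x@id

#' @describeIn ExpressionExperiment `"fold_change"` or `"binary_list"`.
#' @export
experimentMode <- function(x) x@mode

#' @describeIn ExpressionExperiment Named linear fold-change vector.
#' @export
foldChanges <- function(x) x@fc

setMethod("show", "ExpressionExperiment", function(object) {
  cat(sprintf("ExpressionExperiment '%s' (%s, %s): %d genes%s\n",
              object@id, object@species, object@mode,
              if (object@mode == "fold_change") length(object@fc)
              else length(object@downList),
              if (object@mode == "fold_change")
                sprintf(", calibrator %s (FC threshold %.3g)",
                        object@calibrator, calibratorThreshold(object))
              else ""))
})

#' Calibrator-anchored down-regulation threshold
#'
#' The experiment's threshold is the fold change of its calibrator gene: a
#' gene counts as down-regulated when its fold change is equal to or less
#' than the calibrator's.
#'
#' @param exp A fold-change-mode [ExpressionExperiment-class].
#' @return The calibrator's linear fold change.
#' @export
calibratorThreshold <- function(exp) {
  stopifnot(is(exp, "ExpressionExperiment"))
  if (exp@mode != "fold_change")
    stop("calibrator thresholds apply to fold-change experiments only")
  i <- match(toupper(exp@calibrator), toupper(names(exp@fc)))
  if (is.na(i))
    stop(sprintf("calibrator '%s' absent from experiment '%s': cannot self-calibrate",
                 exp@calibrator, exp@id))
  unname(exp@fc[i])
}

#' Per-gene down-regulation flags for one experiment
#'
#' Fold-change mode: `flag(g) = fc[g] <= calibratorThreshold(exp)`, inclusive
#' at equality ("equal or less"). Binary-list mode: membership in the down
#' list. Symbols are case-folded to uppercase (mouse/human harmonization).
#'
#' @param exp An [ExpressionExperiment-class].
#' @return Named logical vector over the experiment's (uppercased) gene
#'   universe.
#' @export
downFlags <- function(exp) {
  stopifnot(is(exp, "ExpressionExperiment"))
  if (exp@mode == "fold_change") {
    g <- toupper(names(exp@fc))
    if (anyDuplicated(g))
      stop(sprintf("duplicate gene symbol(s) in experiment '%s': ambiguous fold change",
                   exp@id))
    setNames(unname(exp@fc) <= calibratorThreshold(exp), g)
  } else {
    g <- unique(toupper(exp@downList))
    if (length(g) == 0L) stop(sprintf("experiment '%s' is empty", exp@id))
    setNames(rep(TRUE, length(g)), g)
  }
}

#' Count down-regulation votes across experiments
#'
#' Builds the harmonized gene x experiment flag matrix and the per-gene vote
#' count D. A gene absent from an experiment's universe contributes a FALSE
#' flag for that experiment (absence of evidence, not missing data).
#'
#' @param experiments List of [ExpressionExperiment-class] objects.
#' @return A [DownVoteTable-class].
#' @examples
#' e1 <- ExpressionExperiment("A", fc = c(MTOR = 0.8, X1 = 0.5, X2 = 1.1),
#'                            calibrator = "MTOR")
#' e2 <- ExpressionExperiment("B", downList = c("X1", "X3"))
#' voteCounts(downVotes(list(e1, e2)))
#' @export
downVotes <- function(experiments) {
  if (is(experiments, "ExpressionExperiment")) experiments <- list(experiments)
  stopifnot(length(experiments) >= 1L,
            all(vapply(experiments, is, logical(1), "ExpressionExperiment")))
  flagList <- lapply(experiments, downFlags)
  genes <- sort(unique(unlist(lapply(flagList, names))))
  flags <- vapply(flagList, function(f) {
    out <- setNames(rep(FALSE, length(genes)), genes)
    out[names(f)] <- f
    out
  }, logical(length(genes)))
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(genes,
                                  vapply(experiments, experimentId, character(1))))
  new("DownVoteTable", flags = flags,
      D = setNames(as.integer(rowSums(flags)), genes),
      experimentIds = colnames(flags))
}

#' @describeIn downVotes Named integer vector of per-gene vote counts D.
#' @param x A `DownVoteTable`.
#' @export
voteCounts <- function(x) { stopifnot(is(x, "DownVoteTable")); x@D }

#' @describeIn downVotes Candidate set: genes down-regulated in at least
#'   `minVotes` experiments (default 2).
#' @param minVotes Integer vote threshold.
#' @export
candidateGenes <- function(x, minVotes = 2L) {
  stopifnot(is(x, "DownVoteTable"))
  names(x@D)[x@D >= minVotes]
}

#' @describeIn downVotes Top candidate set: genes down-regulated in at least
#'   `minVotes` experiments (default 3).
#' @export
topGenes <- function(x, minVotes = 3L) candidateGenes(x, minVotes)

#' @describeIn downVotes Gene x experiment logical flag matrix.
#' @export
downFlagMatrix <- function(x) { stopifnot(is(x, "DownVoteTable")); x@flags }

setMethod("show", "DownVoteTable", function(object) {
  cat(sprintf("DownVoteTable: %d genes x %d experiments (%s)\n",
              nrow(object@flags), ncol(object@flags),
              paste(object@experimentIds, collapse = ", ")))
  cat("  vote distribution:\n")
  print(table(D = object@D))
})

#' Read a fold-change or gene-list experiment from TSV
#'
#' Fold-change files have columns `gene` and `fold_change` (linear ratios);
#' list files have one symbol per line (no header needed when `mode =
#' "binary_list"` and the file has a single column).
#'
#' @param path TSV path.
#' @param id Experiment label (defaults to the file name).
#' @param mode `"fold_change"` or `"binary_list"`.
#' @param calibrator Calibrator symbol for fold-change files.
#' @param species `"human"` or `"mouse"`.
#' @param log2fc Convert a log2 fold-change column to linear ratios.
#' @return An [ExpressionExperiment-class].
#' @export
readExperiment <- function(path, mode = c("fold_change", "binary_list"),
                           id = sub("\\.[^.]*$", "", basename(path)),
                           calibrator = "MTOR", species = "human",
                           log2fc = FALSE) {
  mode <- match.arg(mode)
  if (mode == "fold_change") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene", "fold_change") %in% names(tab)))
      stop("fold-change TSV needs columns 'gene' and 'fold_change'")
    ExpressionExperiment(id, fc = setNames(tab$fold_change, tab$gene),
                         calibrator = calibrator, species = species,
                         log2fc = log2fc)
  } else {
    genes <- scan(path, what = character(), quiet = TRUE, sep = "\n")
    genes <- trimws(genes[nzchar(trimws(genes))])
    genes <- genes[genes != "gene"]  # tolerate a header line
    ExpressionExperiment(id, downList = genes, species = species)
  }
}

#' Write an experiment to TSV
#'
#' Fold-change experiments become two-column TSVs (`gene`, `fold_change`);
#' list experiments one symbol per line.
#'
#' @param exp [ExpressionExperiment-class].
#' @param path Output file.
#' @export
writeExperiment <- function(exp, path) {
  stopifnot(is(exp, "ExpressionExperiment"))
  if (exp@mode == "fold_change") {
    write.table(data.frame(gene = names(exp@fc),
                           fold_change = unname(exp@fc)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(exp@downList, path)
  }
  invisible(path)
}
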