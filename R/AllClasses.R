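#' @import methods
#' @importFrom stats rnorm runif setNames cor pt phyper fisher.test sd residuals lm
#' @importFrom utils read.delim write.table packageVersion
NULL

#' One miRNA-transfection expression experiment
#'
#' Holds the result of a single transfection-vs-control comparison, either as
#' a table of linear fold changes (treated/control) with a calibrator gene, or
#' as a precomputed list of down-regulated gene symbols.
#'
#' @slot id Short experiment label.
#' @slot species `"human"` or `"mouse"`.
#' @slot mode `"fold_change"` or `"binary_list"`.
#' @slot fc Named numeric vector of linear fold changes (mode
#'   `"fold_change"`).
#' @slot downList Character vector of down-regulated symbols (mode
#'   `"binary_list"`).
#' @slot calibrator Calibrator gene symbol (a known, experimentally confirmed
#'   target whose fold change anchors the down-regulation threshold), or
#'   `NA` for list-mode experiments.
#'
#' @seealso [ExpressionExperiment()], [calibratorThreshold()], [downFlags()]
#' @exportClass ExpressionExperiment
setClass("ExpressionExperiment",
  representation(
    id = "character",
    species = "character",
    mode = "character",
    fc = "numeric",
    downList = "character",
    calibrator = "character"
  ),
  prototype(species = "human", mode = "fold_change",
            fc = numeric(0), downList = character(0),
            calibrator = NA_character_)
)

setValidity("ExpressionExperiment", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (!object@species %in% c("human", "mouse"))
    msg <- c(msg, "'species' must be 'human' or 'mouse'")
  if (!object@mode %in% c("fold_change", "binary_list"))
    msg <- c(msg, "'mode' must be 'fold_change' or 'binary_list'")
  if (identical(object@mode, "fold_change")) {
    if (length(object@fc) == 0L)
      msg <- c(msg, "fold-change experiment has no fold changes")
    if (is.null(names(object@fc)) || any(!nzchar(names(object@fc))))
      msg <- c(msg, "'fc' must be named by gene symbol")
    if (any(!is.finite(object@fc)) || any(object@fc <= 0))
      msg <- c(msg, "fold changes must be finite and > 0 (linear ratios)")
    if (is.na(object@calibrator))
      msg <- c(msg, "fold-change experiment requires a calibrator gene")
    else if (!toupper(object@calibrator) %in% toupper(names(object@fc)))
      msg <- c(msg, sprintf("calibrator '%s' absent from fold-change table",
                            object@calibrator))
    if (anyDuplicated(toupper(names(object@fc))))
      msg <- c(msg, "duplicate gene symbols in fold-change table (ambiguous)")
  } else {
    if (length(object@downList) == 0L)
      msg <- c(msg, "binary-list experiment has an empty down list")
  }
  if (length(msg)) msg else TRUE
})

#' Down-vote table across experiments
#'
#' Gene-by-experiment boolean down-regulation flags plus the per-gene vote
#' count D. Symbols are harmonized to uppercase.
#'
#' @slot flags Logical matrix, genes x experiments.
#' @slot D Named integer vector of per-gene down-vote counts (row sums).
#' @slot experimentIds Experiment labels (column order of `flags`).
#' @exportClass DownVoteTable
setClass("DownVoteTable",
  representation(flags = "matrix", D = "integer", experimentIds = "character"))

setValidity("DownVoteTable", function(object) {
  msg <- character(0)
  if (!is.logical(object@flags)) msg <- c(msg, "'flags' must be logical")
  if (ncol(object@flags) != length(object@experimentIds))
    msg <- c(msg, "flag columns must match experiment ids")
  if (!identical(unname(object@D), unname(as.integer(rowSums(object@flags)))))
    msg <- c(msg, "D must equal the row sums of the flag matrix")
  if (any(object@D < 0) || any(object@D > ncol(object@flags)))
    msg <- c(msg, "D out of range [0, n experiments]")
  if (length(msg)) msg else TRUE
})

#' Gene x tool binary prediction matrix
#'
#' One column per sequence-based target prediction tool; entry TRUE when the
#' tool calls the gene a target of the miRNA under study.
#'
#' @slot calls Logical matrix, genes x tools.
#' @exportClass PredictionMatrix
setClass("PredictionMatrix", representation(calls = "matrix"))

setValidity("PredictionMatrix", function(object) {
  msg <- character(0)
  if (!is.logical(object@calls)) msg <- c(msg, "'calls' must be logical")
  if (is.null(rownames(object@calls)) || is.null(colnames(object@calls)))
    msg <- c(msg, "'calls' needs gene rownames and tool colnames")
  else if (anyDuplicated(rownames(object@calls)))
    msg <- c(msg, "duplicate gene rows in prediction matrix")
  if (length(msg)) msg else TRUE
})

#' Mature miRNA with its seed
#'
#' The seed is nucleotides 2-8 of the mature sequence (7 nt), the principal
#' determinant of canonical target recognition.
#'
#' @slot name miRNA name.
#' @slot seq [Biostrings::RNAString] of the mature sequence, 5'->3'
#'   (input T is normalized to U).
#' @exportClass MatureMiRNA
setClass("MatureMiRNA", representation(name = "character", seq = "RNAString"))

setValidity("MatureMiRNA", function(object) {
  msg <- character(0)
  if (length(object@seq) < 8L)
    msg <- c(msg, "mature sequence must be at least 8 nt (seed = positions 2-8)")
  s <- as.character(object@seq)
  if (grepl("[^ACGU]", s))
    msg <- c(msg, "sequence alphabet must be A/C/G/U after normalization")
  if (length(msg)) msg else TRUE
})

#' Annotated transcript
#'
#' A transcript sequence with 1-based inclusive region annotations
#' (5UTR / CDS / 3UTR), non-overlapping and ordered 5' to 3'.
#'
#' @slot id Transcript identifier.
#' @slot seq Uppercase sequence as supplied (DNA or RNA alphabet; scanning
#'   normalizes T to U internally, output preserves the input alphabet).
#' @slot regions data.frame with columns `label`, `start`, `end`.
#' @exportClass TranscriptRecord
setClass("TranscriptRecord",
  representation(id = "character", seq = "character", regions = "data.frame"))

setValidity("TranscriptRecord", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@seq) != 1L || nchar(object@seq) < 1L)
    msg <- c(msg, "'seq' must be one non-empty string")
  if (grepl("[^ACGTU]", object@seq))
    msg <- c(msg, "sequence alphabet must be A/C/G/T/U (uppercase)")
  r <- object@regions
  if (nrow(r)) {
    if (!all(c("label", "start", "end") %in% names(r)))
      msg <- c(msg, "regions need columns label/start/end")
    else {
      if (!all(r$label %in% c("5UTR", "CDS", "3UTR")))
        msg <- c(msg, "region labels must be 5UTR/CDS/3UTR")
      if (any(r$start < 1) || any(r$end > nchar(object@seq)) ||
          any(r$start > r$end))
        msg <- c(msg, "region spans must lie within [1, length]")
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
        msg <- c(msg, "regions must be non-overlapping and ordered 5'->3'")
      ord <- match(r$label, c("5UTR", "CDS", "3UTR"))
      if (is.unsorted(ord))
        msg <- c(msg, "region labels must appear in 5UTR < CDS < 3UTR order")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Nearest-neighbor duplex energy parameters
#'
#' Stacking free energies for adjacent base-pair doublets, loop/bulge
#' initiation penalties, the intermolecular initiation term, and the maximum
#' unpaired stretch allowed per strand. Shipped as versioned TSV files under
#' `inst/extdata/energy/`.
#'
#' @slot stack Numeric matrix 6x6 (rows/cols named by pair, e.g. "AU"),
#'   kcal/mol.
#' @slot bulge Numeric vector of bulge initiation penalties by size.
#' @slot internal Numeric vector of internal-loop initiation penalties by
#'   total size (index = size; sizes below 2 are NA).
#' @slot duplexInit Intermolecular duplex initiation, kcal/mol.
#' @slot asymCoef,asymMax Internal-loop asymmetry penalty per nt and its cap.
#' @slot maxLoop Maximum unpaired nucleotides per strand between two pairs.
#' @slot version Parameter-set version string.
#' @exportClass EnergyParameters
setClass("EnergyParameters",
  representation(stack = "matrix", bulge = "numeric", internal = "numeric",
                 duplexInit = "numeric", asymCoef = "numeric",
                 asymMax = "numeric", maxLoop = "integer",
                 version = "character"))

setValidity("EnergyParameters", function(object) {
  msg <- character(0)
  wc <- c("AU", "UA", "CG", "GC")
  if (any(object@stack[wc, wc] >= 0))
    msg <- c(msg, "Watson-Crick stack energies must be negative")
  if (any(object@bulge < 0) || is.unsorted(object@bulge))
    msg <- c(msg, "bulge penalties must be >= 0 and non-decreasing in size")
  int <- object@internal[!is.na(object@internal)]
  if (any(int < 0) || is.unsorted(int))
    msg <- c(msg, "internal-loop penalties must be >= 0 and non-decreasing")
  if (object@maxLoop < 1L) msg <- c(msg, "maxLoop must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Result of a miRNA:target duplex fold
#'
#' @slot mfe Minimum free energy in kcal/mol, or `NA` when no structure with
#'   at least two consecutive base pairs exists ("no stable duplex").
#' @slot stable FALSE when mfe is NA.
#' @slot pairing Integer matrix with columns `mirnaPos`, `targetPos`;
#'   miRNA positions strictly increasing, target positions strictly
#'   decreasing (antiparallel duplex, no pseudoknots, no intramolecular
#'   pairs).
#' @slot alignment Three-line text rendering (target 5'->3', pairing bars,
#'   miRNA 3'->5').
#' @exportClass DuplexResult
setClass("DuplexResult",
  representation(mfe = "numeric", stable = "logical", pairing = "matrix",
                 alignment = "character"))

#' Fisher enrichment result for predictions among top candidates
#'
#' @slot table 2x2 integer matrix: rows top/rest (within the candidate set),
#'   columns predicted/not-predicted.
#' @slot oddsRatio Sample odds ratio (ad/bc).
#' @slot pGreater One-sided (greater) exact hypergeometric tail p-value.
#' @slot pTwoSided Two-sided Fisher exact p-value, reported for transparency.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(table = "matrix", oddsRatio = "numeric",
                 pGreater = "numeric", pTwoSided = "numeric"))

#' A complete synthetic target-screen dataset with planted truth
#'
#' Emulates the full set of pipeline inputs: five expression experiments
#' (three fold-change with a calibrator, two binary lists, one mouse), a
#' gene x 12-tool prediction matrix, annotated transcripts with planted
#' seed-complementary sites, and cell-line/tissue Ct panels with planted
#' negative miRNA-target correlation.
#'
#' @slot experiments List of [ExpressionExperiment-class] (length 5).
#' @slot predictions [PredictionMatrix-class].
#' @slot mirna [MatureMiRNA-class] used for planting and scanning.
#' @slot transcripts List of [TranscriptRecord-class].
#' @slot siteLog data.frame of planted sites (transcript_id, start, end,
#'   region) — the scanner's ground truth.
#' @slot cellPanel,tissuePanel Long-format Ct tables (sample, assay, ct).
#' @slot truth List: trueTargets, decoyGenes, effectFc, noiseSd, seed,
#'   downAssignments, panel target correlations.
#' @slot params The generator parameters actually used.
#' @exportClass SyntheticTargetScreen
setClass("SyntheticTargetScreen",
  representation(experiments = "list", predictions = "PredictionMatrix",
                 mirna = "MatureMiRNA", transcripts = "list",
                 siteLog = "data.frame", cellPanel = "data.frame",
                 tissuePanel = "data.frame", truth = "list",
                 params = "list"))

setValidity("SyntheticTargetScreen", function(object) {
  msg <- character(0)
  if (length(object@experiments) != 5L)
    msg <- c(msg, "a synthetic screen has exactly 5 experiments")
  if (length(intersect(object@truth$trueTargets, object@truth$decoyGenes)))
    msg <- c(msg, "true targets and decoys must be disjoint")
  fc <- Filter(function(e) e@mode == "fold_change", object@experiments)
  if (!all(vapply(fc, function(e) toupper(e@calibrator) %in%
                  toupper(names(e@fc)), logical(1))))
    msg <- c(msg, "calibrator must be present in every fold-change experiment")
  if (length(msg)) msg else TRUE
})
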