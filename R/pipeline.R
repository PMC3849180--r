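#' Run the full target-prioritization pipeline
#'
#' End-to-end orchestration: obtain inputs (a synthetic screen generated
#' from `seed`, or a [SyntheticTargetScreen-class] / equivalent list of
#' ingested objects supplied via `screen`), count calibrator-anchored
#' down-votes, combine them with prediction votes into confidence tiers,
#' test enrichment of predicted genes among top candidates, scan transcripts
#' for seed sites and score their hybridization energies, screen both
#' expression panels for miRNA-target anticorrelation, and write every stage
#' product to `outputDir`. Outputs on disk are sufficient to re-derive the
#' report; nothing is kept as hidden state.
#'
#' @param outputDir Directory for stage outputs (created; partial outputs
#'   are removed if a stage fails).
#' @param seed Integer seed for the synthetic screen (ignored when `screen`
#'   is supplied).
#' @param screen Optional [SyntheticTargetScreen-class] to analyse instead
#'   of generating one.
#' @param dCandidate,dTop,dAlt,pHigh Tier thresholds (defaults 2/3/4/10).
#' @param rThreshold Absolute-r cutoff for the correlation direction call.
#' @param energyParams [EnergyParameters-class]; default shipped table.
#' @param writeInputs Also write the screen's input files under
#'   `outputDir/inputs/`.
#' @param ... Further generator parameters passed to
#'   [simulateTargetScreen()].
#' @return Invisibly, a list: file paths, the evidence table, enrichment
#'   result, scored sites, correlation screens, and per-stage record counts.
#' @examples
#' \donttest{
#' rep <- runPipeline(tempfile("run"), seed = 7, nGenes = 80, nTrue = 8,
#'                    nTranscripts = 2)
#' head(rep$evidence)
#' }
#' @export
runPipeline <- function(outputDir, seed = NULL, screen = NULL,
                        dCandidate = 2L, dTop = 3L, dAlt = 4L, pHigh = 10L,
                        rThreshold = 0.3,
                        energyParams = loadEnergyParameters(),
                        writeInputs = FALSE, ...) {
  stopifnot(dCandidate >= 1, dTop >= dCandidate, dAlt >= dTop)
  if (is.null(screen)) {
    if (is.null(seed))
      stop("supply either a screen object or a generator seed")
    screen <- simulateTargetScreen(seed = seed, ...)
  }
  stopifnot(is(screen, "SyntheticTargetScreen"))
  if (dTop > length(screen@experiments))
    stop("top-tier vote threshold exceeds the number of experiments")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(outputDir, recursive = TRUE), add = TRUE)

  if (writeInputs)
    writeTargetScreen(screen, file.path(outputDir, "inputs"))

  votes <- downVotes(screen@experiments)
  evidence <- evidenceTable(votes, screen@predictions,
                            dCandidate = dCandidate, dTop = dTop,
                            dAlt = dAlt, pHigh = pHigh)
  enr <- enrichmentTest(candidateGenes(votes, dCandidate),
                        topGenes(votes, dTop),
                        predictedGenes(screen@predictions))

  sites <- do.call(rbind, lapply(screen@transcripts, function(tx)
    scoreSites(scanSeedSites(tx, screen@mirna), tx, screen@mirna,
               energyParams)))
  if (is.null(sites))
    sites <- scanSeedSites(screen@transcripts[[1]], screen@mirna)[0, ]

  mirnaAssay <- screen@mirna@name
  cellScreen <- panelScreen(panelLog2Levels(screen@cellPanel, mirnaAssay),
                            mirnaAssay, rThreshold = rThreshold)
  tissueScreen <- panelScreen(panelLog2Levels(screen@tissuePanel, mirnaAssay),
                              mirnaAssay, rThreshold = rThreshold)
  cellScreen$panel <- "cell_line"
  tissueScreen$panel <- "tissue"
  correlations <- rbind(cellScreen, tissueScreen)

  paths <- list(
    evidence = file.path(outputDir, "evidence.tsv"),
    enrichment = file.path(outputDir, "enrichment.json"),
    sites = file.path(outputDir, "sites.tsv"),
    correlations = file.path(outputDir, "correlations.tsv"),
    report = file.path(outputDir, "report.json"))
  write.table(evidence, paths$evidence, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    table = as.data.frame(enrichmentTable(enr)),
    odds_ratio = enr@oddsRatio,
    p_one_sided = enrichmentP(enr),
    p_two_sided = enr@pTwoSided),
    paths$enrichment, auto_unbox = TRUE, digits = NA)
  writeSites(sites, paths$sites)
  write.table(correlations, paths$correlations, sep = "\t", quote = FALSE,
              row.names = FALSE)

  config <- list(dCandidate = dCandidate, dTop = dTop, dAlt = dAlt,
                 pHigh = pHigh, rThreshold = rThreshold,
                 energyVersion = energyParams@version,
                 generator = screen@params)
  cfgFile <- file.path(outputDir, "config.json")
  jsonlite::write_json(config, cfgFile, auto_unbox = TRUE, digits = NA)
  report <- list(
    package_version = as.character(packageVersion("miRVote")),
    seed = screen@truth$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    counts = list(
      experiments = length(screen@experiments),
      genes = nrow(evidence),
      candidates = sum(evidence$D >= dCandidate),
      top_candidates = sum(evidence$D >= dTop),
      high_confidence = sum(evidence$tier == "high_confidence"),
      sites = nrow(sites),
      correlations = nrow(correlations)),
    config = config)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(list(paths = paths, evidence = evidence, enrichment = enr,
                 sites = sites, correlations = correlations,
                 votes = votes, report = report, screen = screen))
}
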