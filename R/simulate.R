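#' Plant a seed-complementary site in a transcript
#'
#' Writes the reverse complement of the miRNA seed (positions 2-8) into the
#' transcript at `[position, position + 6]`, leaving every other base
#' unchanged. The written bases use the transcript's own alphabet (T or U).
#'
#' @param tx A [TranscriptRecord-class].
#' @param mirna A [MatureMiRNA-class].
#' @param position 1-based start of the 7-nt site.
#' @param region Optional expected region label; planting fails when the
#'   position does not fall inside a region with this label.
#' @return The modified [TranscriptRecord-class].
#' @export
plantSeedSite <- function(tx, mirna, position, region = NULL) {
  stopifnot(is(tx, "TranscriptRecord"), is(mirna, "MatureMiRNA"))
  position <- as.integer(position)
  len <- transcriptLength(tx)
  if (position < 1L || position + 6L > len)
    stop(sprintf("site [%d, %d] outside transcript '%s' (1..%d)",
                 position, position + 6L, tx@id, len))
  if (!is.null(region)) {
    actual <- regionOf(tx, position, position + 6L)
    if (!identical(actual, region))
      stop(sprintf("position %d lies in region '%s', not '%s'",
                   position, actual, region))
  }
  s <- transcriptSequence(tx)
  site <- seedComplement(mirna)
  if (!grepl("U", s)) site <- chartr("U", "T", site)
  TranscriptRecord(tx@id,
                   paste0(substr(s, 1L, position - 1L), site,
                          substr(s, position + 7L, len)),
                   transcriptRegions(tx))
}

# all (possibly overlapping) occurrence starts of `pattern` in `s`
occurrenceStarts <- function(s, pattern) {
  hits <- Biostrings::matchPattern(Biostrings::BString(pattern),
                                   Biostrings::BString(s))
  as.integer(Biostrings::start(hits))
}

# mutate bases so `s` contains `pattern` only at `keepStarts`; positions
# within protected intervals are never touched
scrubPattern <- function(s, pattern, keepStarts = integer(0)) {
  protected <- unlist(lapply(keepStarts, function(p) p:(p + 6L)))
  rot <- c(A = "C", C = "G", G = "A", T = "C", U = "C")
  for (iter in 1:100) {
    extra <- setdiff(occurrenceStarts(s, pattern), keepStarts)
    if (!length(extra)) return(s)
    for (st in extra) {
      pos <- setdiff(st:(st + 6L), protected)
      if (!length(pos)) next  # overlaps a planted site; leave for rescan
      pos <- pos[ceiling(length(pos) / 2)]
      substr(s, pos, pos) <- rot[[substr(s, pos, pos)]]
    }
  }
  stop("could not scrub accidental seed matches")
}

titleCaseSymbol <- function(x) paste0(substr(x, 1L, 1L), tolower(substring(x, 2L)))

randomDnaSeq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE), collapse = "")

#' Generate a complete synthetic target screen with planted ground truth
#'
#' Emulates the study design the pipeline consumes: five miRNA-transfection
#' experiments (three genome-wide fold-change experiments carrying the
#' calibrator gene at its literature fold changes 0.88 / 0.67 / 0.67, two
#' precomputed down-regulated gene lists, one of them from a "mouse" cell
#' line with title-cased symbols), a gene x 12-tool prediction matrix with
#' per-tool sensitivity and false-positive rates, annotated transcripts with
#' seed-complementary sites planted at logged coordinates (accidental
#' background matches are scrubbed so the planting log is the exact site
#' truth), and cell-line (10 samples) and tissue (7 samples) Ct panels
#' whose miRNA and true-target levels carry an exactly planted negative
#' log-scale correlation before Ct noise.
#'
#' All randomness flows from the single `seed` through one `set.seed()` call
#' and a fixed generation order, so a fixed seed yields a bit-identical
#' dataset.
#'
#' @param seed Integer RNG seed; required (reproducibility contract).
#' @param nGenes Number of non-calibrator genes (>= 50).
#' @param nTrue Number of planted true targets.
#' @param effectFc Linear fold change applied to true targets before noise
#'   (0 < effectFc < 1).
#' @param noiseSd SD of multiplicative log-scale noise on fold changes.
#' @param decoyDownRate Per-experiment probability that a decoy gene is
#'   incidentally down-regulated.
#' @param downIn Optional integer vector of experiment indices (1-5) in
#'   which every true target is planted down; default: a per-gene random
#'   draw of `trueDownCount` experiments.
#' @param trueDownCount Experiments per true target when `downIn` is NULL.
#' @param calibrator Calibrator gene symbol.
#' @param calibratorFc Named calibrator fold changes for the three
#'   fold-change experiments.
#' @param toolSens,toolFpr Per-tool sensitivity and false-positive rate
#'   (length 12).
#' @param nTranscripts Number of synthetic transcripts (>= 1); the first is
#'   a 2500-nt reporter-style transcript with sites planted at 409 (CDS) and
#'   2155 (3'UTR).
#' @param sitesPerTranscript Planted sites on each additional transcript.
#' @param nPanelGenes True targets carried on the qPCR panels.
#' @param cellPanelR,tissuePanelR Planted log-scale miRNA-target Pearson r
#'   for the two panels.
#' @param ctNoiseSd Additive Gaussian noise SD on the Ct scale.
#' @param mirna The [MatureMiRNA-class] under study.
#' @return A [SyntheticTargetScreen-class].
#' @examples
#' scr <- simulateTargetScreen(seed = 7, nGenes = 120, nTrue = 10)
#' scr
#' @export
simulateTargetScreen <- function(seed,
                                 nGenes = 300L, nTrue = 24L,
                                 effectFc = 0.5, noiseSd = 0.1,
                                 decoyDownRate = 0.1,
                                 downIn = NULL, trueDownCount = 3L,
                                 calibrator = "MTOR",
                                 calibratorFc = c(HACAT = 0.88,
                                                  LN1386 = 0.67,
                                                  C42 = 0.67),
                                 toolSens = rep(0.85, 12),
                                 toolFpr = rep(0.025, 12),
                                 nTranscripts = 10L,
                                 sitesPerTranscript = 2L,
                                 nPanelGenes = min(6L, nTrue),
                                 cellPanelR = -0.4,
                                 tissuePanelR = -0.79,
                                 ctNoiseSd = 0.2,
                                 mirna = MatureMiRNA("miR-100",
                                   "AACCCGUAGAUCCGAACUUGUG")) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required: synthetic datasets must be reproducible")
  stopifnot(nGenes >= 50L, nTrue >= 1L, nTrue < nGenes,
            effectFc > 0, effectFc < 1, noiseSd >= 0,
            length(toolSens) == length(toolFpr),
            nTranscripts >= 1L, nPanelGenes <= nTrue)
  set.seed(as.integer(seed))

  expIds <- c(names(calibratorFc), "SCC29", "MM4T1")
  nExp <- length(expIds)
  genes <- sprintf("GENE%04d", seq_len(nGenes))
  trueTargets <- sort(sample(genes, nTrue))
  decoys <- setdiff(genes, trueTargets)

  # planted down-regulation assignments (genes + calibrator) x experiments
  assign <- matrix(FALSE, nGenes + 1L, nExp,
                   dimnames = list(c(calibrator, genes), expIds))
  assign[calibrator, names(calibratorFc)] <- TRUE  # FC == threshold: down
  for (g in trueTargets) {
    idx <- if (is.null(downIn)) sample(nExp, trueDownCount) else downIn
    assign[g, idx] <- TRUE
  }
  for (j in seq_len(nExp))
    assign[decoys, j] <- runif(length(decoys)) < decoyDownRate

  experiments <- vector("list", nExp)
  for (j in seq_along(calibratorFc)) {
    thr <- unname(calibratorFc[j])
    down <- assign[genes, j]
    base <- numeric(nGenes)
    base[down] <- effectFc * runif(sum(down), 0.7, 1)
    base[!down] <- pmax(exp(rnorm(sum(!down), 0, 0.15)), thr * 1.08)
    fc <- base * exp(rnorm(nGenes, 0, noiseSd))
    experiments[[j]] <- ExpressionExperiment(
      expIds[j], fc = setNames(c(thr, fc), c(calibrator, genes)),
      calibrator = calibrator)
  }
  for (j in (length(calibratorFc) + 1L):nExp) {
    members <- genes[assign[genes, j]]
    if (!length(members)) {         # keep list experiments non-empty
      members <- decoys[1]
      assign[members, j] <- TRUE
    }
    mouse <- expIds[j] == "MM4T1"
    experiments[[j]] <- ExpressionExperiment(
      expIds[j],
      downList = if (mouse) titleCaseSymbol(members) else members,
      species = if (mouse) "mouse" else "human")
  }

  tools <- c("DIANAmT", "miRanda", "microCosm", "miRDB", "miRWalk",
             "RNAhybrid", "PicTar4", "PicTar5", "PITA", "RNA22",
             "TargetScan5", "TargetScanHuman6")[seq_along(toolSens)]
  calls <- matrix(FALSE, nGenes + 1L, length(tools),
                  dimnames = list(c(calibrator, genes), tools))
  calls[calibrator, ] <- TRUE       # the known target: called by every tool
  for (t in seq_along(tools)) {
    calls[trueTargets, t] <- runif(nTrue) < toolSens[t]
    calls[decoys, t] <- runif(length(decoys)) < toolFpr[t]
  }
  predictions <- PredictionMatrix(calls)

  # transcripts with planted, logged seed sites
  site <- chartr("U", "T", seedComplement(mirna))
  transcripts <- vector("list", nTranscripts)
  siteLog <- NULL
  plantInto <- function(id, len, regions, starts) {
    s <- scrubPattern(randomDnaSeq(len), site)
    tx <- TranscriptRecord(id, s, regions)
    for (p in starts) tx <- plantSeedSite(tx, mirna, p)
    # planting across a scrubbed background can abut new matches; rescrub
    tx <- TranscriptRecord(id, scrubPattern(transcriptSequence(tx), site,
                                            keepStarts = sort(starts)),
                           regions)
    stopifnot(identical(sort(occurrenceStarts(transcriptSequence(tx), site)),
                        sort(as.integer(starts))))
    tx
  }
  tx1regions <- data.frame(label = c("5UTR", "CDS", "3UTR"),
                           start = c(1L, 301L, 1801L),
                           end = c(300L, 1800L, 2500L))
  transcripts[[1]] <- plantInto("TX0001", 2500L, tx1regions, c(409L, 2155L))
  siteLog <- data.frame(transcript_id = "TX0001", start = c(409L, 2155L),
                        end = c(415L, 2161L), region = c("CDS", "3UTR"),
                        stringsAsFactors = FALSE)
  if (nTranscripts > 1L) for (i in 2:nTranscripts) {
    len <- sample(600:2000, 1)
    u <- sample(80:250, 1)
    d <- sample(150:400, 1)
    regions <- data.frame(label = c("5UTR", "CDS", "3UTR"),
                          start = c(1L, u + 1L, len - d + 1L),
                          end = c(u, len - d, len))
    starts <- integer(0)
    if (sitesPerTranscript > 0L) {
      cand <- seq(10L, len - 16L)
      for (s2 in seq_len(sitesPerTranscript)) {
        if (!length(cand)) break
        p <- sample(cand, 1)
        starts <- c(starts, p)
        cand <- cand[abs(cand - p) > 10L]
      }
    }
    id <- sprintf("TX%04d", i)
    transcripts[[i]] <- plantInto(id, len, regions, starts)
    if (length(starts))
      siteLog <- rbind(siteLog, data.frame(
        transcript_id = id, start = as.integer(starts),
        end = as.integer(starts) + 6L,
        region = vapply(starts, function(p)
          regionOf(transcripts[[i]], p, p + 6L), character(1)),
        stringsAsFactors = FALSE))
  }

  # qPCR panels with exactly planted log-scale correlation (pre-noise)
  panelGenes <- trueTargets[seq_len(nPanelGenes)]
  makePanel <- function(samples, plantedR) {
    ns <- length(samples)
    xs <- as.numeric(scale(rnorm(ns)))
    xlog2 <- xs * 1.5
    rows <- data.frame(sample = samples, assay = mirna@name,
                       ct = 24 - xlog2 + rnorm(ns, 0, ctNoiseSd))
    rows <- rbind(rows,
                  data.frame(sample = samples, assay = "U6",
                             ct = 20 + rnorm(ns, 0, ctNoiseSd * 0.25)),
                  data.frame(sample = samples, assay = "ACTB",
                             ct = 18 + rnorm(ns, 0, ctNoiseSd * 0.25)))
    for (g in panelGenes) {
      e <- rnorm(ns)
      es <- as.numeric(scale(residuals(lm(e ~ xs))))
      ylog2 <- (plantedR * xs + sqrt(1 - plantedR^2) * es) * 1.5
      rows <- rbind(rows, data.frame(sample = samples, assay = g,
                                     ct = 26 - ylog2 + rnorm(ns, 0, ctNoiseSd)))
    }
    rownames(rows) <- NULL
    rows
  }
  cellPanel <- makePanel(sprintf("CL%02d", 1:10), cellPanelR)
  tissuePanel <- makePanel(c("EMB07", "EMB11", "EMB15", "EMB17",
                             "BRAIN", "EYE", "SALGL"), tissuePanelR)

  new("SyntheticTargetScreen",
      experiments = experiments, predictions = predictions, mirna = mirna,
      transcripts = transcripts, siteLog = siteLog,
      cellPanel = cellPanel, tissuePanel = tissuePanel,
      truth = list(trueTargets = trueTargets, decoyGenes = decoys,
                   calibrator = calibrator, effectFc = effectFc,
                   noiseSd = noiseSd, seed = as.integer(seed),
                   downAssignments = assign, panelGenes = panelGenes,
                   cellPanelR = cellPanelR, tissuePanelR = tissuePanelR),
      params = list(nGenes = nGenes, nTrue = nTrue, effectFc = effectFc,
                    noiseSd = noiseSd, decoyDownRate = decoyDownRate,
                    downIn = downIn, trueDownCount = trueDownCount,
                    calibrator = calibrator,
                    calibratorFc = as.list(calibratorFc),
                    toolSens = toolSens, toolFpr = toolFpr,
                    nTranscripts = nTranscripts,
                    sitesPerTranscript = sitesPerTranscript,
                    nPanelGenes = nPanelGenes, cellPanelR = cellPanelR,
                    tissuePanelR = tissuePanelR, ctNoiseSd = ctNoiseSd,
                    mirnaName = mirna@name,
                    mirnaSeq = mirnaSequence(mirna),
                    seed = as.integer(seed)))
}

setMethod("show", "SyntheticTargetScreen", function(object) {
  cat(sprintf("SyntheticTargetScreen (seed %d): %d genes, %d true targets, %d experiments, %d transcripts, %d planted sites\n",
              object@truth$seed, object@params$nGenes, object@params$nTrue,
              length(object@experiments), length(object@transcripts),
              nrow(object@siteLog)))
})

#' Write every file of a synthetic screen to a directory
#'
#' Emits the TSV/FASTA/JSON formats the pipeline (and user-supplied real
#' data) uses: one TSV per experiment, the prediction matrix, transcripts as
#' FASTA with a region TSV, both Ct panels, the planted-site log, and a
#' manifest JSON recording seed, parameters and the truth set.
#'
#' @param screen A [SyntheticTargetScreen-class].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeTargetScreen <- function(screen, dir) {
  stopifnot(is(screen, "SyntheticTargetScreen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (e in screen@experiments) {
    suffix <- if (e@mode == "fold_change") ".tsv" else "_down.tsv"
    writeExperiment(e, file.path(dir, paste0(e@id, suffix)))
  }
  writePredictionMatrix(screen@predictions,
                        file.path(dir, "predictions.tsv"))
  writeTranscripts(screen@transcripts, file.path(dir, "transcripts.fasta"),
                   file.path(dir, "regions.tsv"))
  write.table(screen@siteLog, file.path(dir, "planted_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(screen@cellPanel, file.path(dir, "cell_panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(screen@tissuePanel, file.path(dir, "tissue_panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(params = screen@params,
                   truth = list(
                     trueTargets = screen@truth$trueTargets,
                     decoyGenes = screen@truth$decoyGenes,
                     calibrator = screen@truth$calibrator,
                     downAssignments = as.data.frame(
                       screen@truth$downAssignments),
                     panelGenes = screen@truth$panelGenes))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
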