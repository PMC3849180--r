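test_that("a fixed seed yields byte-identical emitted datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeTargetScreen(simulateTargetScreen(seed = 7, nGenes = 60, nTrue = 6,
                                         nTranscripts = 2), d1)
  writeTargetScreen(simulateTargetScreen(seed = 7, nGenes = 60, nTrue = 6,
                                         nTranscripts = 2), d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # a different seed changes the data
  other <- simulateTargetScreen(seed = 8, nGenes = 60, nTrue = 6,
                                nTranscripts = 2)
  expect_false(identical(other@truth$trueTargets,
                         simulateTargetScreen(seed = 7, nGenes = 60,
                                              nTrue = 6,
                                              nTranscripts = 2)@truth$trueTargets))
})

test_that("generator preconditions are enforced", {
  expect_error(simulateTargetScreen(nGenes = 100), "seed")
  expect_error(simulateTargetScreen(seed = 1, nGenes = 10), "nGenes")
  expect_error(simulateTargetScreen(seed = 1, effectFc = 1.2), "effectFc")
})

test_that("noise-free generation recovers planted votes exactly", {
  scr <- simulateTargetScreen(seed = 13, nGenes = 80, nTrue = 20,
                              noiseSd = 0, downIn = 1:3, nTranscripts = 1)
  D <- voteCounts(downVotes(scr@experiments))
  # every planted true target is down in exactly experiments 1-3
  expect_true(all(D[scr@truth$trueTargets] == 3L))
  # the full vote vector equals the planted assignment row sums
  planted <- rowSums(scr@truth$downAssignments)
  expect_identical(unname(D[names(planted)]), as.integer(unname(planted)))
  # the calibrator sits at its own threshold in all three FC experiments
  expect_identical(unname(D["MTOR"]), 3L)
})

test_that("the mouse experiment exercises the case-harmonization path", {
  scr <- simulateTargetScreen(seed = 19, nGenes = 60, nTrue = 10,
                              nTranscripts = 1)
  mouse <- scr@experiments[[5]]
  expect_identical(mouse@species, "mouse")
  expect_true(all(grepl("^[A-Z][a-z0-9]+$", mouse@downList)))
  # harmonized flags land on uppercase symbols
  expect_true(all(names(downFlags(mouse)) %in%
                  toupper(c(scr@truth$trueTargets, scr@truth$decoyGenes))))
})

test_that("planted seed sites are recovered as an exact coordinate multiset", {
  scr <- simulateTargetScreen(seed = 29, nGenes = 50, nTrue = 5,
                              nTranscripts = 10, sitesPerTranscript = 3)
  expect_gte(nrow(scr@siteLog), 25)  # 2 on TX0001 + ~3 on each of 9 more
  found <- do.call(rbind, lapply(scr@transcripts, function(tx)
    scanSeedSites(tx, scr@mirna)[, c("transcript_id", "start")]))
  log <- scr@siteLog[order(scr@siteLog$transcript_id, scr@siteLog$start), ]
  found <- found[order(found$transcript_id, found$start), ]
  expect_identical(found$transcript_id, log$transcript_id)
  expect_identical(found$start, log$start)
  # the flagship transcript mirrors the reporter-construct layout
  expect_identical(scr@siteLog$start[scr@siteLog$transcript_id == "TX0001"],
                   c(409L, 2155L))
  expect_identical(scr@siteLog$region[scr@siteLog$transcript_id == "TX0001"],
                   c("CDS", "3UTR"))
})

test_that("stronger knockdown never loses high-confidence recall (per seed)", {
  for (seed in c(3, 5, 11)) {
    recalls <- vapply(c(0.7, 0.5, 0.3), function(fc) {
      scr <- simulateTargetScreen(seed = seed, nGenes = 60, nTrue = 10,
                                  effectFc = fc, noiseSd = 0.15,
                                  nTranscripts = 1)
      ev <- evidenceTable(downVotes(scr@experiments), scr@predictions)
      hc <- ev$gene[ev$tier == "high_confidence"]
      mean(scr@truth$trueTargets %in% hc)
    }, numeric(1))
    expect_true(all(diff(recalls) >= 0),
                label = sprintf("recall monotone for seed %d", seed))
  }
})

test_that("emitted files support an independent brute-force vote recount", {
  dir <- withr::local_tempdir()
  scr <- simulateTargetScreen(seed = 37, nGenes = 70, nTrue = 8,
                              nTranscripts = 1)
  writeTargetScreen(scr, dir)
  D <- voteCounts(downVotes(scr@experiments))
  recount <- recountVotesFromDir(dir)
  expect_identical(unname(D[names(recount)]), unname(recount))
  # genes missing from the recount universe were never down anywhere
  expect_true(all(D[setdiff(names(D), names(recount))] == 0L))
  P <- predictionVotes(scr@predictions)
  recountP <- recountPredictionsFromDir(dir)
  expect_identical(unname(P[names(recountP)]), unname(recountP))
})

test_that("panels carry both references for every sample and planted r", {
  scr <- simulateTargetScreen(seed = 41, nGenes = 50, nTrue = 6,
                              nTranscripts = 1, ctNoiseSd = 0)
  for (panel in list(scr@cellPanel, scr@tissuePanel)) {
    byS <- split(panel$assay, panel$sample)
    expect_true(all(vapply(byS, function(a)
      all(c("U6", "ACTB", "miR-100") %in% a), logical(1))))
  }
  # with zero Ct noise the planted log-scale correlation is exact
  lv <- panelLog2Levels(scr@tissuePanel, "miR-100")
  for (g in scr@truth$panelGenes)
    expect_equal(correlationScreen(lv["miR-100", ], lv[g, ])$r,
                 scr@truth$tissuePanelR, tolerance = 1e-9)
  lvc <- panelLog2Levels(scr@cellPanel, "miR-100")
  for (g in scr@truth$panelGenes)
    expect_equal(correlationScreen(lvc["miR-100", ], lvc[g, ])$r,
                 scr@truth$cellPanelR, tolerance = 1e-9)
})
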