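test_that("the calibrator's own fold change sets the threshold", {
  hacat <- ExpressionExperiment("HACAT",
    fc = c(MTOR = 0.88, HOXA1 = 0.70, GAPDH = 1.01), calibrator = "MTOR")
  ln <- ExpressionExperiment("LN1386",
    fc = c(MTOR = 0.67, HOXA1 = 0.55, GAPDH = 0.99), calibrator = "MTOR")
  expect_equal(calibratorThreshold(hacat), 0.88)
  expect_equal(calibratorThreshold(ln), 0.67)
  expect_error(
    ExpressionExperiment("X", fc = c(HOXA1 = 0.5), calibrator = "MTOR"),
    "calibrator")
  expect_error(calibratorThreshold(
    ExpressionExperiment("L", downList = "HOXA1")), "fold-change")
})

test_that("down calls are inclusive at the threshold and case-harmonized", {
  ee <- ExpressionExperiment("A",
    fc = c(MTOR = 0.67, AT = 0.67, ABOVE = 0.68, BELOW = 0.669),
    calibrator = "MTOR")
  f <- downFlags(ee)
  expect_true(f[["AT"]])        # "equal or less": equality counts
  expect_false(f[["ABOVE"]])
  expect_true(f[["BELOW"]])
  expect_true(f[["MTOR"]])      # the calibrator sits exactly at its threshold
  mouse <- ExpressionExperiment("M", downList = c("Hoxa1", "Tmem30a"),
                                species = "mouse")
  expect_true(downFlags(mouse)[["HOXA1"]])
  expect_error(ExpressionExperiment("D", fc = c(A = 0.5, a = 0.6, MTOR = 0.9),
                                    calibrator = "MTOR"), "uplicate")
})

test_that("vote counting matches an independent recount and basic set rules", {
  set.seed(41)
  genes <- paste0("G", 1:10)
  exps <- lapply(1:4, function(j) {
    fc <- setNames(round(runif(10, 0.3, 1.4), 3), genes)
    ExpressionExperiment(paste0("E", j), fc = c(fc, MTOR = 0.7),
                         calibrator = "MTOR")
  })
  votes <- downVotes(exps)
  # independent recount
  for (g in genes) {
    manual <- sum(vapply(exps, function(e)
      unname(e@fc[g]) <= unname(e@fc["MTOR"]), logical(1)))
    expect_identical(unname(voteCounts(votes)[g]), as.integer(manual))
  }
  expect_identical(voteCounts(votes),
                   setNames(as.integer(rowSums(downFlagMatrix(votes))),
                            names(voteCounts(votes))))
  expect_setequal(candidateGenes(votes),
                  names(voteCounts(votes))[voteCounts(votes) >= 2])
  expect_setequal(topGenes(votes),
                  names(voteCounts(votes))[voteCounts(votes) >= 3])
})

test_that("votes are order-invariant and monotone in added experiments", {
  e1 <- ExpressionExperiment("A", fc = c(MTOR = 0.8, X1 = 0.5, X2 = 1.2),
                             calibrator = "MTOR")
  e2 <- ExpressionExperiment("B", downList = c("X1", "X3"))
  e3 <- ExpressionExperiment("C", downList = c("X2", "X3"))
  D123 <- voteCounts(downVotes(list(e1, e2, e3)))
  D321 <- voteCounts(downVotes(list(e3, e2, e1)))
  expect_identical(D123, D321[names(D123)])
  D12 <- voteCounts(downVotes(list(e1, e2)))
  expect_true(all(D123[names(D12)] >= D12))
  # a gene absent from an experiment's universe contributes no vote there
  expect_identical(unname(D123["X3"]), 2L)
  expect_identical(unname(D123["MTOR"]), 1L)
})

test_that("experiment TSV round trips preserve votes", {
  dir <- withr::local_tempdir()
  ee <- ExpressionExperiment("HACAT", fc = c(MTOR = 0.88, A1 = 0.3, B2 = 1.1),
                             calibrator = "MTOR")
  writeExperiment(ee, file.path(dir, "e.tsv"))
  back <- readExperiment(file.path(dir, "e.tsv"), mode = "fold_change",
                         calibrator = "MTOR")
  expect_equal(downFlags(back), downFlags(ee))
  lst <- ExpressionExperiment("L", downList = c("Hoxa1", "Nmt1"),
                              species = "mouse")
  writeExperiment(lst, file.path(dir, "l.tsv"))
  back2 <- readExperiment(file.path(dir, "l.tsv"), mode = "binary_list",
                          species = "mouse")
  expect_equal(downFlags(back2), downFlags(lst))
})
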