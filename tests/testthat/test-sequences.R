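test_that("seed is positions 2-8 of the mature sequence", {
  expect_identical(seedSequence(MatureMiRNA("x", "ACGUACGUACGUACGUACGUAC")),
                   "CGUACGU")
  expect_identical(seedSequence(MatureMiRNA("x", "ACGUACGU")), "CGUACGU")
  expect_error(MatureMiRNA("x", "ACGUACG"), "at least 8")
  # DNA-style input normalizes to RNA
  expect_identical(seedSequence(MatureMiRNA("x", "AACCCGTAGATCCGAACTTGTG")),
                   "ACCCGUA")
})

test_that("fragment extraction is 1-based inclusive with exact lengths", {
  tx <- TranscriptRecord("t", strrep("ACGT", 600))
  expect_identical(nchar(extractFragment(tx, 409, 465)), 57L)
  expect_identical(nchar(extractFragment(tx, 2155, 2208)), 54L)
  expect_identical(nchar(extractFragment(tx, 5, 5)), 1L)
  expect_identical(extractFragment(tx, 1, 4), "ACGT")
  expect_error(extractFragment(tx, 0, 5), "out of bounds")
  expect_error(extractFragment(tx, 2300, 2500), "out of bounds")
})

test_that("scanner finds planted sites with correct coordinates and regions", {
  m <- MatureMiRNA("miR-100", "AACCCGUAGAUCCGAACUUGUG")
  regions <- data.frame(label = c("5UTR", "CDS", "3UTR"),
                        start = c(1, 21, 71), end = c(20, 70, 100))
  base <- TranscriptRecord("toy", strrep("C", 100), regions)
  tx <- plantSeedSite(base, m, 21, region = "CDS")
  s <- scanSeedSites(tx, m)
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 21L)
  expect_identical(s$end, 27L)
  expect_identical(s$region, "CDS")
  # the scanned interval reproduces the seed complement exactly
  expect_identical(chartr("T", "U", extractFragment(tx, s$start, s$end)),
                   seedComplement(m))
  # two disjoint plantings -> two sites, including one in the 5'UTR
  tx2 <- plantSeedSite(tx, m, 3, region = "5UTR")
  s2 <- scanSeedSites(tx2, m)
  expect_identical(s2$start, c(3L, 21L))
  expect_identical(s2$region, c("5UTR", "CDS"))
  # a transcript that is exactly the seed complement
  lone <- TranscriptRecord("lone", seedComplement(m))
  s3 <- scanSeedSites(lone, m)
  expect_identical(c(s3$start, s3$end), c(1L, 7L))
  expect_identical(s3$region, "unannotated")
  expect_error(plantSeedSite(base, m, 98), "outside")
  expect_error(plantSeedSite(base, m, 30, region = "3UTR"), "not '3UTR'")
})

test_that("scanner equals naive substring search on random transcripts", {
  set.seed(91)
  m <- MatureMiRNA("m", paste0("A", randomRnaSeq(21)))
  pat <- seedComplement(m)
  for (i in 1:50) {
    seq <- randomRnaSeq(sample(60:400, 1))
    # sprinkle in a few true matches so positives occur
    for (k in seq_len(sample(0:3, 1))) {
      p <- sample(nchar(seq) - 7L, 1)
      substr(seq, p, p + 6L) <- pat
    }
    tx <- TranscriptRecord(paste0("r", i), seq)
    expect_identical(scanSeedSites(tx, m)$start, naiveScanStarts(seq, pat))
  }
})

test_that("seed-match mutagenesis abolishes exactly the mutated site", {
  m <- MatureMiRNA("miR-100", "AACCCGUAGAUCCGAACUUGUG")
  tx <- plantSeedSite(plantSeedSite(
    TranscriptRecord("t", strrep("A", 120)), m, 10), m, 60)
  frag <- extractFragment(tx, 1, 120)
  mut <- mutateSeedMatch(frag, 10)
  expect_identical(nchar(mut), nchar(frag))
  diffs <- which(strsplit(mut, "")[[1]] != strsplit(frag, "")[[1]])
  expect_lte(length(diffs), 7L)
  expect_true(all(diffs >= 10 & diffs <= 16))
  remaining <- scanSeedSites(TranscriptRecord("mut", mut), m)
  expect_identical(remaining$start, 60L)     # the untouched site survives
  both <- mutateSeedMatch(mut, 60)
  expect_identical(nrow(scanSeedSites(TranscriptRecord("b", both), m)), 0L)
  expect_error(mutateSeedMatch(extractFragment(tx, 1, 12), 10), "outside")
})

test_that("poly-T replacement falls back for the degenerate all-A seed", {
  allA <- MatureMiRNA("degenerate", "AAAAAAAAA")
  expect_identical(seedComplement(allA), "UUUUUUU")
  tx <- plantSeedSite(TranscriptRecord("t", strrep("G", 40)), allA, 12)
  mut <- mutateSeedMatch(transcriptSequence(tx), 12)
  expect_identical(nrow(scanSeedSites(TranscriptRecord("m", mut), allA)), 0L)
})

test_that("FASTA + region TSV round trip preserves transcripts", {
  dir <- withr::local_tempdir()
  regions <- data.frame(label = c("5UTR", "CDS"), start = c(1, 31),
                        end = c(30, 90))
  txs <- list(TranscriptRecord("tx1", strrep("ACGT", 30), regions),
              TranscriptRecord("tx2", strrep("GATTACA", 10)))
  writeTranscripts(txs, file.path(dir, "t.fasta"), file.path(dir, "r.tsv"))
  back <- readTranscripts(file.path(dir, "t.fasta"), file.path(dir, "r.tsv"))
  expect_identical(transcriptSequence(back[[1]]), transcriptSequence(txs[[1]]))
  expect_identical(transcriptRegions(back[[1]])$label, c("5UTR", "CDS"))
  expect_identical(transcriptRegions(back[[2]]),
                   transcriptRegions(txs[[2]]))
})
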