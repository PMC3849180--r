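params <- loadEnergyParameters()

test_that("shipped parameter table is sane and reversal-symmetric", {
  pairs <- rownames(params@stack)
  rev1 <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (p1 in pairs) for (p2 in pairs)
    expect_equal(params@stack[p1, p2], params@stack[rev1(p2), rev1(p1)])
  wc <- c("AU", "UA", "CG", "GC")
  expect_true(all(params@stack[wc, wc] < 0))
  # loop penalties non-negative and non-decreasing in total size
  for (l in 1:14)
    expect_lte(loopPenalty(params, l, 0), loopPenalty(params, l + 1, 0))
  for (l in 1:14)
    expect_lte(loopPenalty(params, l, l), loopPenalty(params, l + 1, l + 1))
  expect_gte(loopPenalty(params, 1, 0), 0)
  # asymmetric internal loops cost more than symmetric ones of equal size
  expect_gt(loopPenalty(params, 5, 1), loopPenalty(params, 3, 3))
})

test_that("perfect short duplex energy equals the hand sum from the table", {
  st <- read.delim(system.file("extdata", "energy", "stack.tsv",
                               package = "miRVote"), comment.char = "#")
  gg <- st$energy[st$pair5 == "GC" & st$pair3 == "GC"]
  me <- read.delim(system.file("extdata", "energy", "meta.tsv",
                               package = "miRVote"), comment.char = "#")
  init <- me$value[me$key == "duplex_init"]
  d <- duplexMfe("GGGG", "CCCC", params)
  expect_equal(mfe(d), init + 3 * gg)
  expect_identical(nrow(duplexPairing(d)), 4L)
  # pairing is antiparallel: miRNA ascending, target descending
  expect_identical(duplexPairing(d)[, "mirnaPos"], 1:4)
  expect_identical(duplexPairing(d)[, "targetPos"], 4:1)
})

test_that("non-complementary strands yield no stable duplex", {
  d <- duplexMfe("AAAA", "AAAA", params)
  expect_false(d@stable)
  expect_true(is.na(mfe(d)))
  # a single isolated pair is not a duplex either
  expect_false(duplexMfe("AC", "GC", params)@stable)
  expect_error(duplexMfe("ACGX", "ACGU", params), "A/C/G/U")
  expect_error(duplexMfe("ACGU", "A", params), "shorter")
})

test_that("dynamic program equals exhaustive enumeration on random pairs", {
  set.seed(17)
  checked <- 0L
  for (i in 1:120) {
    nm <- sample(2:8, 1)
    nt <- sample(2:min(8, 16 - nm), 1)
    mi <- randomRnaSeq(nm); tg <- randomRnaSeq(nt)
    got <- mfe(duplexMfe(mi, tg, params))
    want <- bfDuplexMfe(mi, tg, params)
    expect_equal(got, want, tolerance = 1e-9,
                 label = sprintf("mfe(%s, %s)", mi, tg))
    checked <- checked + 1L
  }
  expect_identical(checked, 120L)
})

test_that("recomputing the energy from the returned pairing reproduces mfe", {
  set.seed(23)
  for (i in 1:40) {
    mi <- randomRnaSeq(sample(4:12, 1))
    tg <- randomRnaSeq(sample(4:20, 1))
    d <- duplexMfe(mi, tg, params)
    if (!d@stable) next
    expect_equal(duplexEnergyFromPairing(mi, tg, duplexPairing(d), params),
                 mfe(d), tolerance = 1e-9)
    # no pseudoknots: strictly monotone in both strands
    pr <- duplexPairing(d)
    if (nrow(pr) > 1) {
      expect_true(all(diff(pr[, "mirnaPos"]) > 0))
      expect_true(all(diff(pr[, "targetPos"]) < 0))
    }
  }
})

test_that("extending a sequence never increases the minimum free energy", {
  set.seed(29)
  for (i in 1:25) {
    mi <- randomRnaSeq(6); tg <- randomRnaSeq(8)
    base <- mfe(duplexMfe(mi, tg, params))
    if (is.na(base)) next
    for (ext in c("A", "C", "G", "U")) {
      expect_lte(mfe(duplexMfe(paste0(mi, ext), tg, params)), base + 1e-9)
      expect_lte(mfe(duplexMfe(mi, paste0(ext, tg), params)), base + 1e-9)
    }
  }
})

test_that("tie-breaking makes repeated folds identical", {
  set.seed(31)
  for (i in 1:10) {
    mi <- randomRnaSeq(8); tg <- randomRnaSeq(10)
    d1 <- duplexMfe(mi, tg, params)
    d2 <- duplexMfe(mi, tg, params)
    expect_identical(duplexPairing(d1), duplexPairing(d2))
    expect_identical(d1@alignment, d2@alignment)
  }
})

test_that("site scoring uses the context window and sorts by stability", {
  m <- MatureMiRNA("miR-100", "AACCCGUAGAUCCGAACUUGUG")
  # perfect-complement window: closed-form perfect-duplex energy
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(mirnaSequence(m))))
  mi <- strsplit(mirnaSequence(m), "")[[1]]
  tgRev <- rev(strsplit(rc, "")[[1]])
  perfect <- params@duplexInit
  for (i in seq_len(length(mi) - 1))
    perfect <- perfect + params@stack[paste0(mi[i], tgRev[i]),
                                      paste0(mi[i + 1], tgRev[i + 1])]
  expect_equal(mfe(duplexMfe(m, rc, params)), perfect, tolerance = 1e-9)

  # a transcript with one perfect-complement site and one seed-only site
  seedOnly <- paste0(randomRnaSeq(0), strrep("A", 20), seedComplement(m),
                     strrep("A", 20))
  tx <- TranscriptRecord("t", paste0(strrep("A", 30), rc, strrep("A", 30),
                                     seedOnly))
  sites <- scoreSites(scanSeedSites(tx, m), tx, m, params)
  expect_identical(nrow(sites), 2L)
  expect_lt(sites$mfe[1], sites$mfe[2])  # perfect site strictly more stable
  expect_true(!is.unsorted(sites$mfe))
  # batch scoring equals direct per-site calls
  raw <- scanSeedSites(tx, m)
  direct <- vapply(seq_len(nrow(raw)), function(r)
    mfe(duplexMfe(m, extractFragment(tx, raw$window_start[r],
                                     raw$window_end[r]), params)),
    numeric(1))
  expect_equal(sort(sites$mfe), sort(direct), tolerance = 1e-9)
})
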