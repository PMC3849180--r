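# Independent brute-force oracles. These deliberately avoid the package's
# scanning / dynamic-programming / tail-probability code paths.

# naive O(n*7) substring search for a 7-mer (T/U-insensitive)
naiveScanStarts <- function(seq, pattern) {
  s <- chartr("T", "U", toupper(seq))
  p <- chartr("T", "U", toupper(pattern))
  n <- nchar(s)
  if (n < 7L) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - 6L))
    if (substr(s, i, i + 6L) == p) starts <- c(starts, i)
  starts
}

# exhaustive enumeration of all antiparallel monotone pairings (miRNA
# ascending, target descending, gaps <= maxLoop per strand), requiring at
# least two consecutive pairs; energies summed term by term from the
# parameter slots
bfDuplexMfe <- function(miSeq, tgSeq, params) {
  mi <- strsplit(chartr("T", "U", toupper(miSeq)), "")[[1]]
  tg <- strsplit(chartr("T", "U", toupper(tgSeq)), "")[[1]]
  n <- length(mi); m <- length(tg); L <- params@maxLoop
  keys <- rownames(params@stack)
  best <- Inf
  rec <- function(lastI, lastJ, energy, hasStack) {
    if (hasStack && energy < best) best <<- energy
    if (lastI >= n || lastJ <= 1L) return(invisible())
    for (i in (lastI + 1L):n) {
      g1 <- i - lastI - 1L
      if (g1 > L) break
      for (j in seq_len(lastJ - 1L)) {
        g2 <- lastJ - j - 1L
        if (g2 > L) next
        if (!paste0(mi[i], tg[j]) %in% keys) next
        if (g1 == 0L && g2 == 0L) {
          e <- params@stack[paste0(mi[lastI], tg[lastJ]),
                            paste0(mi[i], tg[j])]
          rec(i, j, energy + e, TRUE)
        } else {
          rec(i, j, energy + loopPenalty(params, g1, g2), hasStack)
        }
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    if (paste0(mi[i], tg[j]) %in% keys)
      rec(i, j, params@duplexInit, FALSE)
  if (is.finite(best)) best else NA_real_
}

# one-sided (greater) Fisher tail by log-factorial enumeration of every
# table at fixed margins
bfFisherGreater <- function(a, b, cc, d) {
  m <- a + cc; nn <- b + d; k <- a + b
  xs <- max(0L, k - nn):min(m, k)
  logp <- lchoose(m, xs) + lchoose(nn, k - xs) - lchoose(m + nn, k)
  sum(exp(logp[xs >= a]))
}

# recount down-votes straight from files emitted by writeTargetScreen(),
# without the package's readers or vote counter
recountVotesFromDir <- function(dir, calibrator = "MTOR") {
  fcFiles <- c("HACAT.tsv", "LN1386.tsv", "C42.tsv")
  listFiles <- c("SCC29_down.tsv", "MM4T1_down.tsv")
  downSets <- list()
  for (f in fcFiles) {
    tab <- read.delim(file.path(dir, f), stringsAsFactors = FALSE)
    thr <- tab$fold_change[toupper(tab$gene) == calibrator]
    downSets[[f]] <- toupper(tab$gene[tab$fold_change <= thr])
  }
  for (f in listFiles)
    downSets[[f]] <- toupper(readLines(file.path(dir, f)))
  genes <- sort(unique(unlist(downSets)))
  D <- vapply(genes, function(g)
    sum(vapply(downSets, function(s) g %in% s, logical(1))), integer(1))
  setNames(as.integer(D), genes)
}

recountPredictionsFromDir <- function(dir) {
  tab <- read.delim(file.path(dir, "predictions.tsv"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  setNames(as.integer(rowSums(tab[, -1])), toupper(tab$gene))
}

randomRnaSeq <- function(len)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
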