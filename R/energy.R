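#' Load nearest-neighbor duplex energy parameters
#'
#' Reads the versioned parameter TSVs shipped with the package (stacking
#' free energies for all adjacent base-pair doublets over the six allowed
#' pairs AU/UA/CG/GC/GU/UG, monotone loop/bulge initiation penalties, and
#' global terms).
#'
#' @param dir Directory containing `stack.tsv`, `loops.tsv`, `meta.tsv`;
#'   defaults to the copies shipped in the package.
#' @param maxLoop Maximum unpaired nucleotides allowed per strand between two
#'   consecutive pairs; overrides the shipped default when given.
#' @return An [EnergyParameters-class].
#' @export
loadEnergyParameters <- function(dir = system.file("extdata", "energy",
                                                   package = "miRVote"),
                                 maxLoop = NULL) {
  st <- read.delim(file.path(dir, "stack.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  lp <- read.delim(file.path(dir, "loops.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  me <- read.delim(file.path(dir, "meta.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  meta <- setNames(me$value, me$key)
  pairs <- sort(unique(st$pair5))
  S <- matrix(NA_real_, length(pairs), length(pairs),
              dimnames = list(pairs, pairs))
  S[cbind(st$pair5, st$pair3)] <- st$energy
  b <- lp[lp$type == "bulge", ]
  bulge <- setNames(b$energy, b$size)[order(b$size)]
  i <- lp[lp$type == "internal", ]
  internal <- rep(NA_real_, max(i$size))
  internal[i$size] <- i$energy
  new("EnergyParameters", stack = S, bulge = unname(bulge),
      internal = internal,
      duplexInit = unname(as.numeric(meta["duplex_init"])),
      asymCoef = unname(as.numeric(meta["asym_coef"])),
      asymMax = unname(as.numeric(meta["asym_max"])),
      maxLoop = as.integer(if (is.null(maxLoop)) meta["max_loop"] else maxLoop),
      version = as.character(meta["version"]))
}

setMethod("show", "EnergyParameters", function(object) {
  cat(sprintf("EnergyParameters v%s: %d stack doublets, init %.2f kcal/mol, maxLoop %d\n",
              object@version, sum(!is.na(object@stack)), object@duplexInit,
              object@maxLoop))
})

pairKey <- function(a, b) paste0(a, b)

canPairKey <- function(params) rownames(params@stack)

#' Stacking free energy of a base-pair doublet
#'
#' @param params [EnergyParameters-class].
#' @param pair5,pair3 Two-character pair codes, e.g. `"AU"` then `"GC"` for
#'   the doublet 5'-A G-3' / 3'-U C-5'.
#' @return kcal/mol.
#' @export
stackEnergy <- function(params, pair5, pair3) {
  e <- params@stack[pair5, pair3]
  if (is.na(e)) stop(sprintf("no stack energy for doublet %s/%s", pair5, pair3))
  unname(e)
}

#' Loop / bulge penalty between two consecutive base pairs
#'
#' `l1` unpaired nucleotides on one strand and `l2` on the other: a bulge
#' when one side is zero, an internal loop (with an asymmetry surcharge)
#' otherwise. Penalties beyond the tabulated sizes are extrapolated
#' logarithmically.
#'
#' @param params [EnergyParameters-class].
#' @param l1,l2 Non-negative unpaired counts; not both zero (that is a
#'   stack).
#' @return kcal/mol (>= 0, non-decreasing in total size).
#' @export
loopPenalty <- function(params, l1, l2) {
  stopifnot(l1 >= 0, l2 >= 0, l1 + l2 >= 1)
  n <- l1 + l2
  extrap <- function(tab, n) {
    k <- length(tab)
    if (n <= k) tab[n] else tab[k] + 1.75 * 0.616 * log(n / k)
  }
  if (l1 == 0L || l2 == 0L) {
    extrap(params@bulge, n)
  } else {
    base <- if (n <= length(params@internal) && !is.na(params@internal[n]))
      params@internal[n]
    else {
      k <- max(which(!is.na(params@internal)))
      params@internal[k] + 1.75 * 0.616 * log(n / k)
    }
    base + min(params@asymMax, params@asymCoef * abs(l1 - l2))
  }
}

splitChars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Minimum free energy of an intermolecular miRNA:target duplex
#'
#' Dynamic program over all antiparallel intermolecular secondary structures:
#' base pairs strictly increasing along the miRNA and strictly decreasing
#' along the target, Watson-Crick and G:U pairs allowed, at most
#' `params@maxLoop` unpaired nucleotides per strand between consecutive
#' pairs, and no intramolecular structure in either strand. The energy of a
#' structure is `duplexInit + sum(stacks) + sum(loop penalties)`. A structure
#' must contain at least two consecutive (stacked) base pairs to count as a
#' duplex; when none exists the result is flagged unstable with `mfe = NA`.
#'
#' Ties between equal-energy structures are broken deterministically toward
#' structures with more paired bases, then toward the earliest pairing in
#' scan order.
#'
#' @param mirna [MatureMiRNA-class] or character sequence (5'->3').
#' @param window Target subsequence, character or XString (5'->3'); T is
#'   normalized to U.
#' @param params [EnergyParameters-class]; defaults to the shipped table.
#' @return A [DuplexResult-class].
#' @examples
#' p <- loadEnergyParameters()
#' duplexMfe("GGGG", "CCCC", p)  # 3 stacked GC doublets + initiation
#' @export
duplexMfe <- function(mirna, window, params = loadEnergyParameters()) {
  miSeq <- if (is(mirna, "MatureMiRNA")) mirnaSequence(mirna) else
    asRNAChars(mirna)
  tgSeq <- asRNAChars(window)
  if (grepl("[^ACGU]", miSeq) || grepl("[^ACGU]", tgSeq))
    stop("sequences must be A/C/G/U (or T) only")
  if (nchar(tgSeq) < 2L) stop("target window shorter than 2 nt")
  if (nchar(miSeq) < 1L) stop("empty miRNA sequence")
  mi <- splitChars(miSeq)
  tg <- splitChars(tgSeq)
  n <- length(mi); m <- length(tg)
  rt <- rev(tg)                      # antiparallel: walk target 3'->5'
  L <- params@maxLoop
  keys <- canPairKey(params)
  pk <- outer(mi, rt, pairKey)
  ok <- matrix(pk %in% keys, n, m)
  # loop-cost lookup by gap sizes (1-indexed by gap+1); [1,1] is the stack slot
  LC <- matrix(NA_real_, L + 1L, L + 1L)
  for (g1 in 0:L) for (g2 in 0:L)
    if (g1 + g2 >= 1L) LC[g1 + 1L, g2 + 1L] <- loopPenalty(params, g1, g2)

  INF <- Inf
  E <- matrix(INF, n, m)   # best ending at pair (i,k), no stack required yet
  ES <- matrix(INF, n, m)  # best ending at (i,k) containing >= 1 stack
  npE <- matrix(0L, n, m); npES <- matrix(0L, n, m)
  parE <- array(0L, c(n, m, 3))   # parent i, k, matrix (0 none, 1 E, 2 ES)
  parES <- array(0L, c(n, m, 3))

  pickBest <- function(cand, np) {
    # cand/np parallel vectors; returns index of min energy, ties -> max np,
    # then earliest
    j <- which(cand <= min(cand) + 1e-9)
    j[order(-np[j], j)][1]
  }

  for (i in seq_len(n)) for (k in seq_len(m)) {
    if (!ok[i, k]) next
    i2r <- seq.int(max(1L, i - 1L - L), i - 1L)
    k2r <- seq.int(max(1L, k - 1L - L), k - 1L)
    # open a new duplex at (i,k)
    bestE <- params@duplexInit; bestEnp <- 1L; bestEpar <- c(0L, 0L, 0L)
    bestES <- INF; bestESnp <- 0L; bestESpar <- c(0L, 0L, 0L)
    if (length(i2r) && length(k2r) && i > 1L && k > 1L) {
      subE <- E[i2r, k2r, drop = FALSE]
      subES <- ES[i2r, k2r, drop = FALSE]
      g1 <- i - i2r - 1L; g2 <- k - k2r - 1L
      cost <- LC[cbind(rep(g1 + 1L, length(g2)),
                       rep(g2 + 1L, each = length(g1)))]
      cost <- matrix(cost, length(g1), length(g2))
      # adjacent predecessor: stack instead of loop (only when it can pair)
      ia <- match(i - 1L, i2r); ka <- match(k - 1L, k2r)
      if ((!is.na(ia) && !is.na(ka)) && !ok[i - 1L, k - 1L]) { ia <- NA; ka <- NA }
      if (!is.na(ia) && !is.na(ka))
        cost[ia, ka] <- stackEnergy(params, pk[i - 1L, k - 1L], pk[i, k])
      candE <- subE + cost
      candES <- subES + cost
      # loop transitions keep E in E and ES in ES; the adjacent (stack)
      # transition promotes E to ES
      fin <- which(is.finite(candE))
      if (length(fin)) {
        stackIdx <- if (!is.na(ia) && !is.na(ka))
          (ka - 1L) * length(i2r) + ia else -1L
        loopIdx <- setdiff(fin, stackIdx)
        if (length(loopIdx)) {
          v <- candE[loopIdx]; np <- npE[i2r, k2r][loopIdx] + 1L
          b <- pickBest(v, np)
          if (v[b] < bestE - 1e-9 ||
              (v[b] <= bestE + 1e-9 && np[b] > bestEnp)) {
            bestE <- v[b]; bestEnp <- np[b]
            ii <- ((loopIdx[b] - 1L) %% length(i2r)) + 1L
            kk <- ((loopIdx[b] - 1L) %/% length(i2r)) + 1L
            bestEpar <- c(i2r[ii], k2r[kk], 1L)
          }
        }
        if (stackIdx > 0L && is.finite(candE[stackIdx])) {
          v <- candE[stackIdx]; np <- npE[i - 1L, k - 1L] + 1L
          if (v < bestES - 1e-9 || (v <= bestES + 1e-9 && np > bestESnp)) {
            bestES <- v; bestESnp <- np; bestESpar <- c(i - 1L, k - 1L, 1L)
          }
        }
      }
      finS <- which(is.finite(candES))
      if (length(finS)) {
        v <- candES[finS]; np <- npES[i2r, k2r][finS] + 1L
        b <- pickBest(v, np)
        if (v[b] < bestES - 1e-9 ||
            (v[b] <= bestES + 1e-9 && np[b] > bestESnp)) {
          bestES <- v[b]; bestESnp <- np[b]
          ii <- ((finS[b] - 1L) %% length(i2r)) + 1L
          kk <- ((finS[b] - 1L) %/% length(i2r)) + 1L
          bestESpar <- c(i2r[ii], k2r[kk], 2L)
        }
      }
    }
    E[i, k] <- bestE; npE[i, k] <- bestEnp; parE[i, k, ] <- bestEpar
    ES[i, k] <- bestES; npES[i, k] <- bestESnp; parES[i, k, ] <- bestESpar
  }

  if (!any(is.finite(ES)))
    return(new("DuplexResult", mfe = NA_real_, stable = FALSE,
               pairing = matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("mirnaPos", "targetPos"))),
               alignment = character(0)))
  best <- min(ES)
  cand <- which(ES <= best + 1e-9, arr.ind = TRUE)
  cand <- cand[order(-npES[cand], cand[, 1], cand[, 2]), , drop = FALSE]
  ci <- cand[1, 1]; ck <- cand[1, 2]
  # traceback
  pairs <- matrix(integer(0), 0, 2)
  mat <- 2L; i <- ci; k <- ck
  while (i > 0L) {
    pairs <- rbind(c(i, k), pairs)
    par <- if (mat == 2L) parES[i, k, ] else parE[i, k, ]
    i <- par[1]; k <- par[2]; mat <- par[3]
  }
  pairing <- cbind(mirnaPos = pairs[, 1], targetPos = m - pairs[, 2] + 1L)
  new("DuplexResult", mfe = ES[ci, ck], stable = TRUE, pairing = pairing,
      alignment = renderDuplex(miSeq, tgSeq, pairing))
}

#' Recompute a structure's energy from its pairing list
#'
#' Independent of the dynamic program's internals: walks the pairing 5'->3'
#' along the miRNA, summing the initiation term, stack energies for adjacent
#' pairs and loop penalties for interrupted ones. Used for the self-
#' consistency contract `energy(pairing) == mfe`.
#'
#' @param mirna,window Sequences as in [duplexMfe()].
#' @param pairing Integer matrix with columns `mirnaPos`, `targetPos`.
#' @param params [EnergyParameters-class].
#' @return kcal/mol.
#' @export
duplexEnergyFromPairing <- function(mirna, window, pairing,
                                    params = loadEnergyParameters()) {
  miSeq <- if (is(mirna, "MatureMiRNA")) mirnaSequence(mirna) else
    asRNAChars(mirna)
  tgSeq <- asRNAChars(window)
  mi <- splitChars(miSeq); tg <- splitChars(tgSeq)
  stopifnot(nrow(pairing) >= 1L)
  o <- order(pairing[, 1])
  pairing <- pairing[o, , drop = FALSE]
  if (nrow(pairing) > 1L &&
      (any(diff(pairing[, 1]) <= 0) || any(diff(pairing[, 2]) >= 0)))
    stop("pairing must be strictly increasing in miRNA and decreasing in target")
  e <- params@duplexInit
  for (r in seq_len(nrow(pairing))) {
    key <- pairKey(mi[pairing[r, 1]], tg[pairing[r, 2]])
    if (!key %in% canPairKey(params))
      stop(sprintf("non-pairable bases at miRNA %d / target %d",
                   pairing[r, 1], pairing[r, 2]))
    if (r > 1L) {
      g1 <- pairing[r, 1] - pairing[r - 1L, 1] - 1L
      g2 <- pairing[r - 1L, 2] - pairing[r, 2] - 1L
      e <- e + if (g1 == 0L && g2 == 0L)
        stackEnergy(params,
                    pairKey(mi[pairing[r - 1L, 1]], tg[pairing[r - 1L, 2]]),
                    key)
      else loopPenalty(params, g1, g2)
    }
  }
  e
}

#' Render a duplex as aligned text
#'
#' Three lines in the style of hybridization tools: target 5'->3' on top,
#' pairing bars, miRNA 3'->5' below; loop nucleotides are padded with `-`.
#'
#' @param miSeq,tgSeq Character sequences (RNA alphabet).
#' @param pairing Pairing matrix as in [DuplexResult-class].
#' @return Character vector of three lines.
#' @keywords internal
renderDuplex <- function(miSeq, tgSeq, pairing) {
  if (!nrow(pairing)) return(character(0))
  mi <- splitChars(miSeq); tg <- splitChars(tgSeq)
  o <- order(pairing[, 1])
  pairing <- pairing[o, , drop = FALSE]
  top <- bars <- bot <- character(0)
  for (r in seq_len(nrow(pairing))) {
    if (r > 1L) {
      miGap <- mi[seq2(pairing[r - 1L, 1] + 1L, pairing[r, 1] - 1L)]
      tgGap <- tg[seq2(pairing[r, 2] + 1L, pairing[r - 1L, 2] - 1L)]
      tgGap <- rev(tgGap)
      w <- max(length(miGap), length(tgGap))
      top <- c(top, c(tgGap, rep("-", w - length(tgGap))))
      bot <- c(bot, c(miGap, rep("-", w - length(miGap))))
      bars <- c(bars, rep(" ", w))
    }
    top <- c(top, tg[pairing[r, 2]])
    bot <- c(bot, mi[pairing[r, 1]])
    bars <- c(bars, "|")
  }
  # top line runs target 3'->5' as built; flip all three for 5'->3' display
  c(paste0("target 5' ", paste(rev(top), collapse = ""), " 3'"),
    paste0("          ", paste(rev(bars), collapse = "")),
    paste0("miRNA  3' ", paste(rev(bot), collapse = ""), " 5'"))
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' @describeIn duplexMfe Minimum free energy (kcal/mol, `NA` when
#'   unstable).
#' @param x A `DuplexResult`.
#' @export
mfe <- function(x) { stopifnot(is(x, "DuplexResult")); x@mfe }

#' @describeIn duplexMfe Pairing matrix (`mirnaPos`, `targetPos`).
#' @export
duplexPairing <- function(x) { stopifnot(is(x, "DuplexResult")); x@pairing }

setMethod("show", "DuplexResult", function(object) {
  if (!object@stable) {
    cat("DuplexResult: no stable duplex\n")
  } else {
    cat(sprintf("DuplexResult: mfe %.2f kcal/mol, %d base pairs\n",
                object@mfe, nrow(object@pairing)))
    cat(paste0("  ", object@alignment, collapse = "\n"), "\n")
  }
})

#' Fill in per-site hybridization energies
#'
#' Computes [duplexMfe()] of the miRNA against each site's context window
#' (the seed match +/- the scan window, approximating reporter-fragment
#' scale) and writes it into the `mfe` column. Sites sort by `mfe`
#' ascending (most stable first).
#'
#' @param sites Site data.frame from [scanSeedSites()].
#' @param tx The [TranscriptRecord-class] the sites came from.
#' @param mirna [MatureMiRNA-class].
#' @param params [EnergyParameters-class].
#' @return The site data.frame with `mfe` filled, ordered by `mfe`.
#' @export
scoreSites <- function(sites, tx, mirna, params = loadEnergyParameters()) {
  stopifnot(is(tx, "TranscriptRecord"))
  if (!nrow(sites)) return(sites)
  stopifnot(all(sites$transcript_id == tx@id))
  sites$mfe <- vapply(seq_len(nrow(sites)), function(r) {
    win <- extractFragment(tx, sites$window_start[r], sites$window_end[r])
    mfe(duplexMfe(mirna, win, params))
  }, numeric(1))
  sites[order(sites$mfe), , drop = FALSE]
}
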