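#' Construct a mature miRNA
#'
#' @param name miRNA name, e.g. `"miR-100"`.
#' @param sequence Mature sequence 5'->3'; DNA-style T is normalized to U.
#' @return A [MatureMiRNA-class].
#' @examples
#' m <- MatureMiRNA("miR-100", "AACCCGUAGAUCCGAACUUGUG")
#' seedSequence(m)
#' @export
MatureMiRNA <- function(name, sequence) {
  s <- chartr("t", "u", chartr("T", "U", toupper(as.character(sequence))))
  new("MatureMiRNA", name = as.character(name),
      seq = Biostrings::RNAString(s))
}

#' @describeIn MatureMiRNA The mature sequence as a character string.
#' @param x A `MatureMiRNA`.
#' @export
mirnaSequence <- function(x) { stopifnot(is(x, "MatureMiRNA")); as.character(x@seq) }

#' Seed sequence (positions 2-8) of a mature miRNA
#'
#' @param mirna A [MatureMiRNA-class] (or a character sequence).
#' @return 7-nt character seed.
#' @export
seedSequence <- function(mirna) {
  if (is.character(mirna)) mirna <- MatureMiRNA("miRNA", mirna)
  stopifnot(is(mirna, "MatureMiRNA"))
  as.character(Biostrings::subseq(mirna@seq, 2L, 8L))
}

setMethod("show", "MatureMiRNA", function(object) {
  cat(sprintf("MatureMiRNA %s: 5'-%s-3' (%d nt), seed[2-8] = %s\n",
              object@name, as.character(object@seq), length(object@seq),
              seedSequence(object)))
})

#' Construct an annotated transcript
#'
#' @param id Transcript identifier.
#' @param sequence Transcript sequence 5'->3' (DNA or RNA alphabet; kept as
#'   supplied, uppercased).
#' @param regions data.frame with columns `label` (5UTR/CDS/3UTR), `start`,
#'   `end` (1-based inclusive, non-overlapping, ordered). May be empty.
#' @return A [TranscriptRecord-class].
#' @export
TranscriptRecord <- function(id, sequence, regions = data.frame(
                               label = character(), start = integer(),
                               end = integer())) {
  regions <- as.data.frame(regions)
  if (nrow(regions)) {
    regions$start <- as.integer(regions$start)
    regions$end <- as.integer(regions$end)
  }
  new("TranscriptRecord", id = as.character(id),
      seq = toupper(as.character(sequence)), regions = regions)
}

#' @describeIn TranscriptRecord Transcript sequence (input alphabet).
#' @param x A `TranscriptRecord`.
#' @export
transcriptSequence <- function(x) { stopifnot(is(x, "TranscriptRecord")); x@seq }

#' @describeIn TranscriptRecord Transcript length in nt.
#' @export
transcriptLength <- function(x) nchar(transcriptSequence(x))

#' @describeIn TranscriptRecord Region annotation data.frame.
#' @export
transcriptRegions <- function(x) { stopifnot(is(x, "TranscriptRecord")); x@regions }

setMethod("show", "TranscriptRecord", function(object) {
  r <- object@regions
  cat(sprintf("TranscriptRecord %s: %d nt%s\n", object@id, nchar(object@seq),
              if (nrow(r)) paste0("; ", paste(sprintf("%s:%d-%d", r$label,
                                                      r$start, r$end),
                                              collapse = " "))
              else " (unannotated)"))
})

#' Label of the region containing an interval
#'
#' @param tx A [TranscriptRecord-class].
#' @param start,end 1-based inclusive interval.
#' @return The containing region's label, or `"unannotated"` when no single
#'   annotated region contains the whole interval.
#' @export
regionOf <- function(tx, start, end = start) {
  r <- transcriptRegions(tx)
  if (!nrow(r)) return("unannotated")
  hit <- which(r$start <= start & r$end >= end)
  if (length(hit) == 1L) r$label[hit] else "unannotated"
}

#' Extract a transcript fragment by 1-based inclusive coordinates
#'
#' Mirrors reporter-construct cloning: the fragment spanning positions
#' `start..end` has length `end - start + 1`.
#'
#' @param tx A [TranscriptRecord-class] (or a plain character sequence).
#' @param start,end 1-based inclusive coordinates.
#' @return The fragment as a character string.
#' @examples
#' tx <- TranscriptRecord("t1", strrep("ACGT", 600))
#' nchar(extractFragment(tx, 409, 465))  # 57
#' @export
extractFragment <- function(tx, start, end) {
  s <- if (is(tx, "TranscriptRecord")) transcriptSequence(tx) else
    toupper(as.character(tx))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > nchar(s) ||
      start > end)
    stop(sprintf("coordinates [%s, %s] out of bounds for a %d-nt sequence",
                 start, end, nchar(s)))
  substr(s, start, end)
}

asRNAChars <- function(s) chartr("T", "U", toupper(as.character(s)))

#' Reverse complement of a miRNA seed, as it appears on the target
#'
#' @param mirna [MatureMiRNA-class] or character sequence.
#' @return 7-nt RNA-alphabet character string.
#' @export
seedComplement <- function(mirna) {
  as.character(Biostrings::reverseComplement(
    Biostrings::RNAString(seedSequence(mirna))))
}

#' Scan a transcript for seed-complementary target sites
#'
#' Reports every position where the sense strand (5'->3') contains the exact
#' reverse complement of the miRNA seed (positions 2-8), Watson-Crick pairing
#' only — no G:U wobble within the seed. All annotated regions are scanned,
#' including the 5'UTR. Matching is done on the T/U-normalized sequence via
#' [Biostrings::matchPattern()].
#'
#' @param tx A [TranscriptRecord-class].
#' @param mirna A [MatureMiRNA-class].
#' @param window Context half-width in nt for downstream energy scoring;
#'   the window is the seed match +/- `window`, clipped to the transcript.
#' @return data.frame with columns `transcript_id`, `start`, `end` (1-based
#'   inclusive 7-nt seed match), `region`, `window_start`, `window_end`,
#'   `mfe` (NA until scored).
#' @seealso [scoreSites()], [mutateSeedMatch()]
#' @export
scanSeedSites <- function(tx, mirna, window = 25L) {
  stopifnot(is(tx, "TranscriptRecord"), is(mirna, "MatureMiRNA"))
  if (transcriptLength(tx) < 7L)
    stop("transcript shorter than a seed match (7 nt)")
  subject <- Biostrings::RNAString(asRNAChars(transcriptSequence(tx)))
  hits <- Biostrings::matchPattern(Biostrings::RNAString(seedComplement(mirna)),
                                   subject)
  st <- Biostrings::start(hits)
  en <- Biostrings::end(hits)
  n <- length(st)
  data.frame(
    transcript_id = rep(tx@id, n),
    start = as.integer(st), end = as.integer(en),
    region = if (n) vapply(seq_len(n), function(i)
      regionOf(tx, st[i], en[i]), character(1)) else character(0),
    window_start = pmax(1L, as.integer(st) - as.integer(window)),
    window_end = pmin(transcriptLength(tx),
                      as.integer(en) + as.integer(window)),
    mfe = rep(NA_real_, n),
    stringsAsFactors = FALSE)
}

#' Replace a site's seed match with a poly-T/U run (reporter mutant)
#'
#' Emulates reporter mutagenesis: the 7-nt seed-complementary stretch is
#' replaced by `TTTTTTT` (or `UUUUUUU` when the fragment uses the RNA
#' alphabet), so a rescan finds no site at that position. For the degenerate
#' all-A seed, whose complement is the poly-T/U run itself, the replacement
#' falls back to `AAAAAAA` so the mutation always abolishes the site.
#'
#' @param fragment Character sequence (e.g. from [extractFragment()]).
#' @param siteStart 1-based start of the seed match in the coordinate system
#'   of `fragment` once `fragmentStart` is accounted for.
#' @param fragmentStart Transcript coordinate of the fragment's first base
#'   (default 1: `siteStart` is already fragment-local).
#' @return The mutant fragment; same length, differing from the input at no
#'   more than 7 positions, all inside the site interval.
#' @export
mutateSeedMatch <- function(fragment, siteStart, fragmentStart = 1L) {
  fragment <- toupper(as.character(fragment))
  local <- as.integer(siteStart) - as.integer(fragmentStart) + 1L
  if (local < 1L || local + 6L > nchar(fragment))
    stop("seed-match interval lies outside the fragment")
  isRNA <- grepl("U", fragment) && !grepl("T", fragment)
  repl <- if (isRNA) strrep("U", 7L) else strrep("T", 7L)
  if (identical(substr(fragment, local, local + 6L), repl))
    repl <- strrep("A", 7L)
  paste0(substr(fragment, 1L, local - 1L), repl,
         substr(fragment, local + 7L, nchar(fragment)))
}

#' Read / write annotated transcripts (FASTA + region TSV)
#'
#' The region table has columns `transcript_id`, `region`, `start`, `end`
#' (1-based inclusive).
#'
#' @param fastaPath FASTA file of transcript sequences.
#' @param regionPath Region TSV (optional on read).
#' @return List of [TranscriptRecord-class] (read); paths invisibly (write).
#' @export
readTranscripts <- function(fastaPath, regionPath = NULL) {
  seqs <- Biostrings::readBStringSet(fastaPath)
  regions <- if (!is.null(regionPath))
    read.delim(regionPath, stringsAsFactors = FALSE) else NULL
  lapply(names(seqs), function(id) {
    r <- if (!is.null(regions)) {
      sub <- regions[regions$transcript_id == id, , drop = FALSE]
      data.frame(label = sub$region, start = sub$start, end = sub$end)
    } else data.frame(label = character(), start = integer(),
                      end = integer())
    TranscriptRecord(id, as.character(seqs[[id]]), r)
  })
}

#' @rdname readTranscripts
#' @param transcripts List of [TranscriptRecord-class] to write.
#' @export
writeTranscripts <- function(transcripts, fastaPath, regionPath = NULL) {
  seqs <- Biostrings::BStringSet(setNames(
    vapply(transcripts, transcriptSequence, character(1)),
    vapply(transcripts, function(t) t@id, character(1))))
  Biostrings::writeXStringSet(seqs, fastaPath)
  if (!is.null(regionPath)) {
    reg <- do.call(rbind, lapply(transcripts, function(t) {
      r <- transcriptRegions(t)
      if (!nrow(r)) return(NULL)
      data.frame(transcript_id = t@id, region = r$label,
                 start = r$start, end = r$end)
    }))
    write.table(reg, regionPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fastaPath)
}

#' Write scanned sites as TSV
#'
#' Coordinates in the file are 1-based inclusive, matching the in-memory
#' representation; a header comment documents the convention.
#'
#' @param sites Site data.frame from [scanSeedSites()]/[scoreSites()].
#' @param path Output TSV.
#' @export
writeSites <- function(sites, path) {
  con <- file(path, "w")
  writeLines("# seed-match sites; start/end are 1-based inclusive (subtract 1 from start for BED half-open)",
             con)
  write.table(sites, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
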