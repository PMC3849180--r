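#' Delta-delta-Ct and 2^-ddCt relative quantification
#'
#' `ddCt = (target Ct - reference Ct)_sample - (target Ct - reference
#' Ct)_calibrator`; the relative quantity is `2^-ddCt` (amplification
#' efficiency fixed at 2). The quantity is scale-free: adding a constant to
#' all four Ct values leaves it unchanged, and a sample identical to the
#' calibrator has RQ = 1.
#'
#' @param targetCt,referenceCt Sample Ct values for the target and reference
#'   (e.g. U6 for miRNAs, beta-actin for mRNAs) assays.
#' @param calibratorTargetCt,calibratorReferenceCt The same pair in the
#'   calibrator (control) sample.
#' @return Relative quantity (vectorized), always > 0.
#' @examples
#' relativeQuantity(26, 18, 25, 18)  # ddCt = 1 -> 0.5
#' @export
relativeQuantity <- function(targetCt, referenceCt, calibratorTargetCt,
                             calibratorReferenceCt) {
  ct <- cbind(targetCt, referenceCt, calibratorTargetCt,
              calibratorReferenceCt)
  if (any(!is.finite(ct)))
    stop("all four Ct values must be finite (missing reference assay?)")
  2^(-deltaDeltaCt(targetCt, referenceCt, calibratorTargetCt,
                   calibratorReferenceCt))
}

#' @rdname relativeQuantity
#' @export
deltaDeltaCt <- function(targetCt, referenceCt, calibratorTargetCt,
                         calibratorReferenceCt) {
  (targetCt - referenceCt) - (calibratorTargetCt - calibratorReferenceCt)
}

#' Read a long-format Ct table (sample, assay, ct)
#'
#' @param path TSV with columns `sample`, `assay`, `ct`.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "assay", "ct") %in% names(tab)))
    stop("Ct table needs columns sample/assay/ct")
  tab
}

#' Reference-normalized log2 expression from a Ct panel
#'
#' For each sample, `log2 level = reference Ct - assay Ct` (a delta-Ct
#' against the appropriate internal control). miRNA assays are normalized to
#' the U6-like control, mRNA assays to the actin-like control.
#'
#' @param ct Long-format Ct data.frame (`sample`, `assay`, `ct`).
#' @param mirnaAssay Name of the miRNA assay row.
#' @param mirnaReference,mrnaReference Control assay names (defaults `"U6"`
#'   and `"ACTB"`).
#' @return Numeric matrix, assays x samples, of log2 relative levels
#'   (reference rows dropped).
#' @export
panelLog2Levels <- function(ct, mirnaAssay, mirnaReference = "U6",
                            mrnaReference = "ACTB") {
  wide <- tapply(ct$ct, list(ct$assay, ct$sample), mean)
  for (ref in c(mirnaReference, mrnaReference))
    if (!ref %in% rownames(wide))
      stop(sprintf("reference assay '%s' missing from panel", ref))
  out <- wide
  for (a in rownames(wide)) {
    ref <- if (a == mirnaAssay) mirnaReference else mrnaReference
    out[a, ] <- wide[ref, ] - wide[a, ]
  }
  out[setdiff(rownames(out), c(mirnaReference, mrnaReference)), ,
      drop = FALSE]
}

#' Pearson correlation between miRNA and target expression
#'
#' Product-moment correlation over the shared samples with a two-sided
#' p-value from the t transform `t = r * sqrt((n-2) / (1-r^2))` on `n - 2`
#' degrees of freedom. Sample order is irrelevant (named vectors are aligned
#' by name).
#'
#' @param mirnaLevels,geneLevels Numeric vectors (optionally named by
#'   sample).
#' @return data.frame with one row: `n`, `r`, `p`.
#' @examples
#' x <- c(a = 1, b = 2, c = 3, d = 4)
#' correlationScreen(x, -2 * x + 1)  # r = -1
#' @export
correlationScreen <- function(mirnaLevels, geneLevels) {
  if (!is.null(names(mirnaLevels)) && !is.null(names(geneLevels))) {
    shared <- intersect(names(mirnaLevels), names(geneLevels))
    mirnaLevels <- mirnaLevels[shared]
    geneLevels <- geneLevels[shared]
  }
  n <- length(mirnaLevels)
  if (n != length(geneLevels)) stop("sample sets must align")
  if (n < 3L) stop("need at least 3 shared samples")
  if (sd(mirnaLevels) == 0 || sd(geneLevels) == 0)
    stop("constant vector: correlation undefined")
  r <- cor(mirnaLevels, geneLevels)
  data.frame(n = n, r = r, p = pearsonP(r, n))
}

#' @describeIn correlationScreen Two-sided p-value for a given r and n via
#'   the t transform.
#' @param r Correlation coefficient.
#' @param n Sample count (>= 3).
#' @export
pearsonP <- function(r, n) {
  stopifnot(n >= 3, abs(r) <= 1)
  if (abs(r) == 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Correlate a miRNA against many genes across a panel
#'
#' @param panel Numeric matrix, assays x samples (e.g. from
#'   [panelLog2Levels()]).
#' @param mirnaAssay Row name holding the miRNA levels.
#' @param genes Gene rows to screen (default: every other row).
#' @param rThreshold Absolute-r cutoff for the direction summary.
#' @return data.frame with columns `gene`, `n`, `r`, `p`, `direction`
#'   (`inverse` / `positive` / `none`).
#' @export
panelScreen <- function(panel, mirnaAssay, genes = NULL, rThreshold = 0.3) {
  stopifnot(is.matrix(panel), mirnaAssay %in% rownames(panel))
  if (is.null(genes)) genes <- setdiff(rownames(panel), mirnaAssay)
  missing <- setdiff(genes, rownames(panel))
  if (length(missing))
    stop(sprintf("gene(s) absent from panel: %s",
                 paste(missing, collapse = ", ")))
  res <- do.call(rbind, lapply(genes, function(g)
    correlationScreen(panel[mirnaAssay, ], panel[g, ])))
  res$gene <- genes
  res$direction <- ifelse(abs(res$r) < rThreshold, "none",
                          ifelse(res$r < 0, "inverse", "positive"))
  res[, c("gene", "n", "r", "p", "direction")]
}
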