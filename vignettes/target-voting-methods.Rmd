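---
title: "Methods: multi-evidence miRNA target voting"
author: "miRVote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-evidence miRNA target voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRVote)
```

This vignette is the package's account of the statistical and sequence
models it implements, the parameters that matter, and the design choices
made where more than one reasonable option existed.

## 1. Calibrator-anchored down-regulation votes

The central difficulty in calling a gene "down-regulated after miRNA
transfection" across heterogeneous experiments (different cell lines,
platforms, labs) is that a fixed fold-change cutoff means different
things in each. `miRVote` instead anchors each fold-change experiment to
a **calibrator**: a gene already known to be a direct target of the miRNA
family (mTOR for the miR-99 family). A gene votes "down" in experiment
*e* when its linear fold change is *equal to or less than* the
calibrator's fold change in that same experiment. The comparison is
inclusive at equality — ties with the calibrator count as down, and the
calibrator itself always votes down in its own experiment, which is the
intended behavior for a known target.

Consequences of this rule worth knowing:

* Thresholds are per-experiment quantities (e.g. 0.88 in one cell line,
  0.67 in another) and are never pooled.
* Fold changes are handled on the **linear** scale throughout; a log2
  input must be declared via `log2fc = TRUE` in
  `ExpressionExperiment()` / `readExperiment()` and is converted
  explicitly, never silently.
* Experiments supplied as precomputed down-regulated gene lists
  contribute membership votes; no threshold is applied or reconstructed.
* Genes absent from an experiment's measured universe contribute a FALSE
  flag there — absence of evidence, not missing data. The vote count
  `D(g)` is therefore monotone in the experiment list and invariant to
  its order.
* Cross-species harmonization is symbol case-folding to uppercase only
  (mouse `Hoxa1` merges with human `HOXA1`). No orthology mapping is
  attempted: the merge is by symbol identity, and a duplicated symbol
  within one experiment is a hard error (ambiguous fold change) rather
  than something to average away.

## 2. Prediction votes, tiers, and enrichment

Sequence-based prediction tools are consumed as a binary gene × tool
matrix; the package deliberately does not reimplement any of the twelve
tools it is modeled on. `P(g)` is the row sum, and "predicted" means
`P >= 1`. Tier thresholds default to the published rule — candidate
`D >= 2`, top candidate `D >= 3`, high confidence
`(D >= 3 and P >= 10) or D >= 4` — and are configurable in
`classifyTier()`/`runPipeline()`. "Predicted by 10 out of 12" is read as
`P >= 10`, not equality, and the `P >= 10` cut stays absolute when a
matrix with a different tool count is supplied. Classification is
monotone in both vote counts by construction, which the test suite checks
exhaustively over a (D, P) grid.

Enrichment of predicted genes among top candidates uses the one-sided
(greater) exact hypergeometric tail — the directional Fisher exact test,
computed with exact tail arithmetic rather than any normal approximation,
and cross-checked in the tests against a log-factorial enumeration of all
tables at fixed margins. The test's sidedness is a design choice: the
claim being tested ("predicted genes are enriched in the top set") is
directional, so the one-sided p is primary and the two-sided Fisher p is
reported alongside for transparency.

## 3. Seed-site scanning and reporter logic

The seed is positions 2–8 of the mature miRNA (7 nt). A target site is an
exact Watson–Crick reverse complement of the seed on the transcript's
sense strand; G:U wobble is **disallowed within the seed** (the mutational
evidence the model rests on replaces exactly positions 2–8) but allowed
in duplex extension (section 4). All annotated regions are scanned —
5'UTR, CDS and 3'UTR alike — because validated sites occur in coding
regions and 5'UTRs, not only the 3'UTR. Coordinates are 1-based inclusive
end to end; `extractFragment()` on a scanned site reproduces the seed
complement exactly, and the site TSV documents the −1 conversion needed
for BED half-open coordinates.

`mutateSeedMatch()` reproduces reporter-mutant logic: the 7-nt
seed-complementary stretch is replaced by `TTTTTTT` (or `UUUUUUU` in RNA
alphabet), which abolishes the site while preserving fragment length. One
degenerate corner exists: an all-A seed has the poly-U/T run as its own
complement, so the replacement falls back to `AAAAAAA` there to keep the
"mutant has no site" contract unconditional.

Site classes (8mer, 7mer-A1, supplementary 3' pairing) are not used to
gate site calls; the prediction-matrix consensus already encodes
tool-specific site models, and the scanner's job is the canonical 7-mer
definition only.

## 4. Duplex minimum free energy

`duplexMfe()` scores miRNA:window hybridization with a nearest-neighbor
dynamic program over **intermolecular** structures only: base pairs
strictly increasing along the miRNA and decreasing along the target
(antiparallel, no pseudoknots), no intramolecular pairs in either strand
— the defining restriction of hybridization-only folding. Watson–Crick
and G:U pairs are allowed; a structure's energy is

    E = duplex_init + sum(stack energies) + sum(loop/bulge penalties)

and a structure must contain at least two consecutive pairs to count as a
duplex (otherwise "no stable duplex" is returned with `mfe = NA`).

Parameters ship as versioned TSVs (`inst/extdata/energy/`):

* **Stacks** — a Turner-2004-style table over all 36 doublets of the six
  allowed pairs, reversal-symmetric as shipped (checked by test), with
  all Watson–Crick doublets negative.
* **Loops** — initiation penalties monotone non-decreasing in size, using
  a logarithmic Jacobson–Stockmayer form (bulges from 2.8 kcal/mol,
  internal loops from 1.5 kcal/mol at size 2) plus a Ninio-style
  asymmetry surcharge of 0.6 kcal/mol per unpaired-length difference,
  capped at 3.0. The monotone form is a deliberate smoothing of the
  literature tables, whose small-bulge values are non-monotone; the
  package treats monotonicity as a model invariant.
* **Globals** — duplex initiation 4.09 kcal/mol, `max_loop = 15`
  unpaired nt per strand between consecutive pairs. Dangling-end and
  terminal-mismatch terms are omitted (documented simplification).

Because no published parameter set accompanies the tool this emulates,
numeric agreement with external hybridization programs is *not* a claim
the package makes. The correctness claim is internal and testable:
the dynamic program equals exhaustive enumeration of all monotone
pairings under the same parameters (verified on hundreds of seeded
random pairs with combined length ≤ 16), recomputing the energy from the
returned pairing reproduces the mfe to 1e-9, and extending either
sequence never raises the mfe. Ties between equal-energy structures are
broken toward more paired bases, then earliest in scan order, so
repeated folds are identical.

The per-site scoring window defaults to the seed match ±25 nt (clipped),
giving ~51–57-nt contexts comparable to cloned reporter fragments.

## 5. Quantification and correlation screens

Relative expression from Ct quartets uses 2^-ΔΔCt with amplification
efficiency fixed at 2 and no efficiency correction; the quantity is
scale-free (adding a constant to all four Ct values changes nothing) and
equals 1 for the calibrator sample by construction. Panels are
normalized per sample against the appropriate internal control (a
U6-like assay for the miRNA, an actin-like assay for mRNAs), and
correlation screens run on reference-normalized **log2** levels — the
scale on which the generator plants its correlations and on which
Pearson r is best behaved for expression data.

Pearson p-values are two-sided via the t transform
`t = r * sqrt((n-2)/(1-r^2))` on `n − 2` df (this choice reproduces the
familiar worked example: r = −0.79 over 7 samples gives p ≈ 0.035,
printed as 0.03). No multiple-testing correction is applied across the
small per-panel gene sets — raw per-gene r and p are reported, matching
how such screens are typically read; users screening many genes can
apply `p.adjust` downstream.

## 6. The synthetic generator: what it emulates, and what it does not

`simulateTargetScreen()` generates every input the pipeline consumes,
under one seed and a fixed generation order (one `set.seed()`, so a fixed
seed gives a byte-identical dataset). Its defaults are the study
conditions, chosen once:

* **5 experiments**: three fold-change experiments with the calibrator
  planted at the literature fold changes 0.88 / 0.67 / 0.67, and two
  list experiments, one flagged mouse with title-cased symbols to force
  the harmonization path. Defaults `nGenes = 300`, `nTrue = 24` (the
  scale of the published top-candidate set), `effectFc = 0.5` (planted
  targets halve their expression before noise), log-normal noise
  `noiseSd = 0.1`, and a 10% per-experiment incidental down rate for
  decoys (so decoys average well under one vote). Each true target is
  planted down in 3 experiments by default (`downIn` overrides).
* **12 tools** with per-tool sensitivity 0.85 and false-positive rate
  0.025 — the FPR chosen so roughly a quarter of decoy candidates attract
  at least one prediction, the flavor of published candidate tables; the
  calibrator is predicted by every tool, as a long-known target would be.
* **Transcripts**: the flagship 2500-nt transcript carries sites at 409
  (CDS) and 2155 (3'UTR), mirroring reporter-construct coordinates;
  additional transcripts get seeded random sites. Accidental background
  seed matches are scrubbed before planting, so the planting log is the
  *exact* site truth — this is what lets scanner tests assert multiset
  equality rather than supersets.
* **Panels**: 10 cell lines and 7 tissue samples (four embryo stages,
  three adult tissues) with planted log-scale miRNA–target correlations
  (defaults −0.4 and −0.79). The planted r is *exact* in the pre-noise
  log2 levels (the residual construction orthogonalizes the noise), so
  `ctNoiseSd = 0` recovers it to machine precision and the default 0.2 Ct
  noise attenuates it by only a few percent.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: probe-level array artifacts and normalization
(inputs are gene-level fold changes by design), correlated errors between
experiments sharing a platform, tool-to-tool correlation in prediction
errors (tools are sampled independently; real tools share sequence
features and err together), transcript secondary structure and site
accessibility, and translational repression that leaves mRNA levels
unchanged. The end-to-end recovery results (recall/precision of the
high-confidence tier against planted truth) therefore validate the
*integration logic*, not the field performance of any prediction tool.

## 7. Problem sizes, degenerate inputs, and limitations

The shipped tests run the duplex-vs-enumeration oracle on 500+ random
pairs at combined length ≤ 16 (where enumeration is exact and fast), the
scanner oracle on dozens of random transcripts up to 600 nt, and the
correlation-recovery study on 200 generator runs over a planted-r grid;
the full suite completes in well under a minute on one CPU. The
pipeline-scale dynamic program (22-nt miRNA against ~51-nt windows,
`max_loop = 15`) runs in well under a second per site in pure R, which is
why no compiled code is used.

Degenerate inputs are handled by refusal rather than guessing: missing
seeds, missing calibrators, duplicate symbols, constant correlation
vectors, sub-3-sample panels, out-of-bounds coordinates and non-ACGU/T
alphabets are all hard errors with specific messages. Known limitations:
no orthology-aware merging, no non-canonical (seedless) site discovery,
no site-accessibility or conservation scoring, and duplex energies are
comparable within this parameter set but not across programs.
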