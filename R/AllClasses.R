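#' @import methods
#' @importFrom stats rnorm runif sd median setNames
#' @importFrom utils head tail
#' @importFrom data.table data.table setkey setkeyv as.data.table rbindlist
#'   setorder setorderv setcolorder shift copy setDT setnames fread :=
NULL

setOldClass(c("data.table", "data.frame"))

#' Digestion parameters
#'
#' Parameters of the in-silico tryptic digestion used to build a
#' [PeptideIndex]. Defaults follow common MudPIT practice: up to 2 missed
#' cleavages, peptide length 6--60 residues, peptide neutral mass
#' 600--6000 Da, and cysteine carbamidomethylation (+57.02146 Da) as the
#' only static modification.
#'
#' @slot enzyme Cleavage rule identifier; only `"trypsin"` (cleave
#'   C-terminal to K/R, suppressed before P, fully tryptic) is supported.
#' @slot missedCleavages Maximum number of internal uncut sites.
#' @slot minLength,maxLength Peptide length window (residues).
#' @slot minMass,maxMass Peptide neutral mass window (Da).
#' @slot staticMods Named numeric vector of static modification deltas (Da).
#' @slot ambiguity Policy for non-canonical residues (B/J/O/U/X/Z):
#'   `"skip"` drops peptides containing them (counted in the build
#'   report), `"reject"` errors, `"map"` folds U to C and O to K.
#' @export
setClass("DigestionParams", representation(
  enzyme          = "character",
  missedCleavages = "integer",
  minLength       = "integer",
  maxLength       = "integer",
  minMass         = "numeric",
  maxMass         = "numeric",
  staticMods      = "numeric",
  ambiguity       = "character"
))

setValidity("DigestionParams", function(object) {
  msg <- character()
  if (object@enzyme != "trypsin") msg <- c(msg, "enzyme must be 'trypsin'")
  if (object@missedCleavages < 0L) msg <- c(msg, "missedCleavages must be >= 0")
  if (object@minLength < 1L) msg <- c(msg, "minLength must be >= 1")
  if (object@minLength > object@maxLength)
    msg <- c(msg, "minLength must be <= maxLength")
  if (object@minMass > object@maxMass)
    msg <- c(msg, "minMass must be <= maxMass")
  if (!object@ambiguity %in% c("skip", "reject", "map"))
    msg <- c(msg, "ambiguity must be one of skip/reject/map")
  if (length(object@staticMods) &&
      !all(names(object@staticMods) %in% names(.AA_MONO)))
    msg <- c(msg, "staticMods names must be canonical residues")
  if (length(msg)) msg else TRUE
})

#' @describeIn DigestionParams Constructor.
#' @param enzyme,missedCleavages,minLength,maxLength,minMass,maxMass,staticMods,ambiguity
#'   See the corresponding slots.
#' @return A `DigestionParams` object.
#' @export
#' @examples
#' digestionParams(missedCleavages = 0, minLength = 1)
digestionParams <- function(enzyme = "trypsin", missedCleavages = 2,
                            minLength = 6, maxLength = 60,
                            minMass = 600, maxMass = 6000,
                            staticMods = c(C = 57.02146),
                            ambiguity = c("skip", "reject", "map")) {
  ambiguity <- match.arg(ambiguity)
  if (is.null(staticMods)) staticMods <- numeric()
  new("DigestionParams", enzyme = enzyme,
      missedCleavages = as.integer(missedCleavages),
      minLength = as.integer(minLength), maxLength = as.integer(maxLength),
      minMass = as.numeric(minMass), maxMass = as.numeric(maxMass),
      staticMods = staticMods, ambiguity = ambiguity)
}

#' Search engine parameters
#'
#' Scoring parameters of the SEQUEST-lineage engine. The spectrum
#' preprocessing constants (1.0005079 Th bins, 10 normalization regions
#' scaled to 50, square-root transform, +/- 75 bin background window,
#' 1e-4 XCorr scaling, 0.25 flanking-bin weight) follow the classical
#' cross-correlation implementation and are deliberately isolated here so
#' they can be swapped as one block.
#'
#' @slot tolerancePpm Precursor mass tolerance of the wide search (ppm).
#' @slot reportHits Number of ranked peptide-spectrum matches reported per
#'   scan.
#' @slot charges Candidate precursor charges tried when a scan carries no
#'   charge assignment.
#' @slot binWidth Fragment bin width (Th).
#' @slot nRegions Number of equal m/z regions normalized to `regionMax`.
#' @slot regionMax Per-region maximum after normalization.
#' @slot bgWindow Half-width (bins) of the cross-correlation background
#'   window.
#' @slot flankWeight Weight of the +/- 1 bin flanks around each
#'   theoretical fragment.
#' @slot xcorrScale Final XCorr scaling factor.
#' @slot precursorRemoval Half-width (Th) of the precursor m/z exclusion
#'   zone applied before binning.
#' @export
setClass("SearchParams", representation(
  tolerancePpm     = "numeric",
  reportHits       = "integer",
  charges          = "integer",
  binWidth         = "numeric",
  nRegions         = "integer",
  regionMax        = "numeric",
  bgWindow         = "integer",
  flankWeight      = "numeric",
  xcorrScale       = "numeric",
  precursorRemoval = "numeric"
))

setValidity("SearchParams", function(object) {
  msg <- character()
  if (object@tolerancePpm <= 0) msg <- c(msg, "tolerancePpm must be > 0")
  if (object@reportHits < 1L) msg <- c(msg, "reportHits must be >= 1")
  if (!length(object@charges) || any(object@charges < 1L))
    msg <- c(msg, "charges must be positive integers")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (object@flankWeight < 0 || object@flankWeight > 1)
    msg <- c(msg, "flankWeight must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SearchParams Constructor.
#' @param tolerancePpm,reportHits,charges,binWidth,nRegions,regionMax,bgWindow,flankWeight,xcorrScale,precursorRemoval
#'   See the corresponding slots.
#' @return A `SearchParams` object.
#' @export
#' @examples
#' searchParams(tolerancePpm = 10)
searchParams <- function(tolerancePpm = 30, reportHits = 5, charges = c(2, 3),
                         binWidth = 1.0005079, nRegions = 10, regionMax = 50,
                         bgWindow = 75, flankWeight = 0.25, xcorrScale = 1e-4,
                         precursorRemoval = 1.5) {
  new("SearchParams", tolerancePpm = as.numeric(tolerancePpm),
      reportHits = as.integer(reportHits), charges = as.integer(charges),
      binWidth = as.numeric(binWidth), nRegions = as.integer(nRegions),
      regionMax = as.numeric(regionMax), bgWindow = as.integer(bgWindow),
      flankWeight = as.numeric(flankWeight), xcorrScale = as.numeric(xcorrScale),
      precursorRemoval = as.numeric(precursorRemoval))
}

#' Protein-level filtering parameters
#'
#' DTASelect-style acceptance gates: rank-1 matches with precursor mass
#' error strictly below `maxAbsPpm`, a minimum number of distinct peptides
#' per protein locus, and a locus-level XCorr threshold chosen so that the
#' target-decoy protein FDR stays at or below `maxProteinFdr`.
#'
#' @slot maxProteinFdr Maximum protein-level FDR (fraction in (0, 1]).
#' @slot minPeptides Minimum distinct peptides per protein locus.
#' @slot maxAbsPpm Strict upper bound on absolute precursor mass error (ppm).
#' @slot minDeltaCn Optional per-PSM DeltaCN gate (`NA` disables).
#' @slot minXcorr Optional per-PSM XCorr gate (`NA` disables).
#' @slot fdrEstimator `"ratio"` for decoys/targets (concatenated-database
#'   convention) or `"symmetric"` for 2d/(t+d).
#' @export
setClass("FilterParams", representation(
  maxProteinFdr = "numeric",
  minPeptides   = "integer",
  maxAbsPpm     = "numeric",
  minDeltaCn    = "numeric",
  minXcorr      = "numeric",
  fdrEstimator  = "character"
))

setValidity("FilterParams", function(object) {
  msg <- character()
  if (object@maxProteinFdr <= 0 || object@maxProteinFdr > 1)
    msg <- c(msg, "maxProteinFdr must be in (0, 1]")
  if (object@minPeptides < 1L) msg <- c(msg, "minPeptides must be >= 1")
  if (object@maxAbsPpm <= 0) msg <- c(msg, "maxAbsPpm must be > 0")
  if (!object@fdrEstimator %in% c("ratio", "symmetric"))
    msg <- c(msg, "fdrEstimator must be 'ratio' or 'symmetric'")
  if (length(msg)) msg else TRUE
})

#' @describeIn FilterParams Constructor.
#' @param maxProteinFdr,minPeptides,maxAbsPpm,minDeltaCn,minXcorr,fdrEstimator
#'   See the corresponding slots.
#' @return A `FilterParams` object.
#' @export
#' @examples
#' filterParams()
filterParams <- function(maxProteinFdr = 0.01, minPeptides = 2,
                         maxAbsPpm = 10, minDeltaCn = NA_real_,
                         minXcorr = NA_real_,
                         fdrEstimator = c("ratio", "symmetric")) {
  fdrEstimator <- match.arg(fdrEstimator)
  new("FilterParams", maxProteinFdr = as.numeric(maxProteinFdr),
      minPeptides = as.integer(minPeptides), maxAbsPpm = as.numeric(maxAbsPpm),
      minDeltaCn = as.numeric(minDeltaCn), minXcorr = as.numeric(minXcorr),
      fdrEstimator = fdrEstimator)
}

#' Simulation parameters for synthetic proteomes and MS/MS runs
#'
#' Controls the synthetic-data generator. Defaults emulate a small
#' MudPIT-style run: proteins of mean length 300 residues with uniform
#' residue usage, precursor charges 2+ and 3+, flat fragment intensities,
#' 10 uniform noise peaks per spectrum, 10 percent fragment dropout and
#' 5 ppm precursor mass jitter.
#'
#' @slot seed Integer seed; every generator draw is a deterministic
#'   function of it.
#' @slot nProteins Number of proteins to generate.
#' @slot lengthMean,lengthSd Protein length distribution (residues);
#'   lengths are drawn from a normal and truncated at 20 residues.
#' @slot residueFreqs Named 20-vector of residue frequencies summing to 1.
#' @slot nSpectra Number of spectra to simulate.
#' @slot noisePeaks Number of uniform-m/z noise peaks added per spectrum.
#' @slot peakDropout Probability that each fragment peak is dropped.
#' @slot chargeProbs Named probabilities over precursor charges.
#' @slot massJitterPpm Standard deviation of the precursor mass error (ppm).
#' @slot fragmentIntensity Intensity assigned to true fragment peaks.
#' @slot noiseIntensityRange Range of uniform noise-peak intensities.
#' @slot noiseMzRange Range (Th) of uniform noise-peak m/z values.
#' @export
setClass("SimulationParams", representation(
  seed               = "integer",
  nProteins          = "integer",
  lengthMean         = "numeric",
  lengthSd           = "numeric",
  residueFreqs       = "numeric",
  nSpectra           = "integer",
  noisePeaks         = "integer",
  peakDropout        = "numeric",
  chargeProbs        = "numeric",
  massJitterPpm      = "numeric",
  fragmentIntensity  = "numeric",
  noiseIntensityRange = "numeric",
  noiseMzRange       = "numeric"
))

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (abs(sum(object@residueFreqs) - 1) > 1e-8)
    msg <- c(msg, "residueFreqs must sum to 1")
  if (!all(names(object@residueFreqs) %in% names(.AA_MONO)))
    msg <- c(msg, "residueFreqs names must be canonical residues")
  if (object@peakDropout < 0 || object@peakDropout >= 1)
    msg <- c(msg, "peakDropout must be in [0, 1)")
  if (object@noisePeaks < 0L) msg <- c(msg, "noisePeaks must be >= 0")
  if (abs(sum(object@chargeProbs) - 1) > 1e-8)
    msg <- c(msg, "chargeProbs must sum to 1")
  if (object@lengthMean <= 0) msg <- c(msg, "lengthMean must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationParams Constructor.
#' @param seed,nProteins,lengthMean,lengthSd,residueFreqs,nSpectra,noisePeaks,peakDropout,chargeProbs,massJitterPpm,fragmentIntensity,noiseIntensityRange,noiseMzRange
#'   See the corresponding slots.
#' @return A `SimulationParams` object.
#' @export
#' @examples
#' simulationParams(seed = 1, nProteins = 10, nSpectra = 5)
simulationParams <- function(seed, nProteins = 100, lengthMean = 300,
                             lengthSd = 60,
                             residueFreqs = setNames(rep(1/20, 20),
                                                     names(.AA_MONO)),
                             nSpectra = 100, noisePeaks = 10,
                             peakDropout = 0.10,
                             chargeProbs = c(`2` = 0.6, `3` = 0.4),
                             massJitterPpm = 5, fragmentIntensity = 100,
                             noiseIntensityRange = c(10, 100),
                             noiseMzRange = c(200, 2000)) {
  new("SimulationParams", seed = as.integer(seed),
      nProteins = as.integer(nProteins), lengthMean = as.numeric(lengthMean),
      lengthSd = as.numeric(lengthSd), residueFreqs = residueFreqs,
      nSpectra = as.integer(nSpectra), noisePeaks = as.integer(noisePeaks),
      peakDropout = as.numeric(peakDropout), chargeProbs = chargeProbs,
      massJitterPpm = as.numeric(massJitterPpm),
      fragmentIntensity = as.numeric(fragmentIntensity),
      noiseIntensityRange = as.numeric(noiseIntensityRange),
      noiseMzRange = as.numeric(noiseMzRange))
}

#' Three-collection peptide index
#'
#' The central data object: a decoy-augmented protein collection
#' (`proteins`, the ProtDB analog), the distinct-peptide collection with
#' parent-protein occurrences (`peptides` + `occurrences`, the SeqDB
#' analog), and the mass-ordered peptide collection (`massdb`, the MassDB
#' analog) supporting ordered key-range scans for precursor windows.
#' Construct with [buildIndex()]; query with [queryMassWindow()] and
#' [lookupParents()].
#'
#' @slot proteins `data.table` of protein records: `protein_id` (0-based,
#'   unique), `defline`, `sequence`, `is_decoy`.
#' @slot peptides `data.table` keyed by `peptide`: one row per distinct
#'   peptide sequence with its neutral monoisotopic `mass` (Da) and
#'   integer `mass_key`.
#' @slot occurrences `data.table` keyed by `peptide`: one row per
#'   (peptide, protein, start offset) occurrence with flanking residues
#'   (`"-"` at protein termini) and missed-cleavage count.
#' @slot massdb `data.table` sorted by (`mass_key`, `mass`, `peptide`):
#'   the mass-range scan target. One row per distinct peptide, so each
#'   peptide lives under exactly one mass key.
#' @slot params The [DigestionParams] used to build the index.
#' @slot report Build report: record counts, shared target/decoy peptide
#'   accounting, ambiguous-residue drops.
#' @slot counters Environment of backend access counters (see
#'   [indexCounters()]).
#' @export
setClass("PeptideIndex", representation(
  proteins    = "data.table",
  peptides    = "data.table",
  occurrences = "data.table",
  massdb      = "data.table",
  params      = "DigestionParams",
  report      = "list",
  counters    = "environment"
))

setValidity("PeptideIndex", function(object) {
  msg <- character()
  if (nrow(object@peptides) != nrow(object@massdb))
    msg <- c(msg, "peptides and massdb must list the same peptide set")
  if (nrow(object@massdb) &&
      is.unsorted(object@massdb$mass_key, strictly = FALSE))
    msg <- c(msg, "massdb must be sorted by mass_key")
  if (nrow(object@peptides) && anyDuplicated(object@massdb$peptide))
    msg <- c(msg, "each peptide may appear under exactly one mass key")
  if (nrow(object@proteins) && anyDuplicated(object@proteins$protein_id))
    msg <- c(msg, "protein_id must be unique")
  if (length(msg)) msg else TRUE
})

#' Search results
#'
#' Ranked peptide-spectrum matches (PSMs) for a set of scans plus a run
#' summary. The `psms` table has one row per reported hit with columns
#' `scan_id`, `charge`, `peptide`, `calc_mass`, `obs_mass`, `xcorr`
#' (floored at 0), `xcorr_raw`, `delta_cn`, `z_score`, `ppm_error`,
#' `rank`, `is_decoy_only` and `candidate_count`.
#'
#' @slot psms `data.table` of ranked PSMs.
#' @slot summary List: scans scored, scans with at least one candidate,
#'   and a candidate-count histogram.
#' @slot params The [SearchParams] used.
#' @export
setClass("SearchResult", representation(
  psms    = "data.table",
  summary = "list",
  params  = "SearchParams"
))

#' Set of tandem mass spectra
#'
#' Lightweight container for centroided MS/MS scans read from MS2 or MGF
#' files or produced by the simulator. Each scan is a list with
#' `scan_id`, `precursor_mz`, `charges` (candidate precursor charges),
#' `charge_known`, and a two-column `peaks` matrix (m/z, intensity)
#' sorted by m/z.
#'
#' @slot scans List of scans.
#' @slot source Character scalar describing provenance.
#' @export
setClass("SpectrumSet", representation(
  scans  = "list",
  source = "character"
))
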