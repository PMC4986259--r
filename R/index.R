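#' Build the three-collection peptide index
#'
#' Digests every protein record in silico with trypsin specificity and
#' populates the three collections of a [PeptideIndex]: the protein
#' table, the distinct-peptide table with parent occurrences, and the
#' mass-ordered peptide table scanned by [queryMassWindow()]. Peptides
#' whose sequence already exists at a mass key are merged into the
#' existing entry, never duplicated, and rebuilding over the same input
#' (via `index =`) is idempotent: occurrences are deduplicated on
#' (protein, start offset).
#'
#' @param records Protein-record table ([readFasta()] output, usually
#'   after [appendDecoys()]).
#' @param params A [DigestionParams].
#' @param index Optional existing [PeptideIndex] to append to (its
#'   digestion parameters must match).
#' @param verbose Print progress.
#' @return A [PeptideIndex]. Its build report (see [buildReport()]) holds
#'   record counts, the count and length histogram of peptides mapping to
#'   both target and decoy parents, and the number of peptides dropped by
#'   the ambiguous-residue policy.
#' @export
#' @examples
#' recs <- appendDecoys(data.table::data.table(protein_id = 0L,
#'   defline = "p1", sequence = "MKRPAGGKAW", is_decoy = FALSE))
#' idx <- buildIndex(recs, digestionParams(missedCleavages = 0,
#'   minLength = 1, minMass = 0))
#' nPeptides(idx)
buildIndex <- function(records, params = digestionParams(), index = NULL,
                       verbose = FALSE) {
  records <- as.data.table(records)
  if (nrow(records) && anyDuplicated(records$protein_id))
    stop("duplicate protein_id in input records")
  dig <- .digestRecords(records, params)
  occ <- dig$peptides
  if (!is.null(index)) {
    stopifnot(is(index, "PeptideIndex"))
    if (!identical(index@params, params))
      stop("appending with different digestion parameters")
    old_prot <- index@proteins
    dup_prot <- intersect(old_prot$protein_id, records$protein_id)
    new_prot <- rbind(old_prot, records[!records$protein_id %in% dup_prot])
    occ <- rbind(index@occurrences[, c("protein_id", "peptide",
                                       "start_offset", "nmc", "prev", "nxt",
                                       "mass", "mass_key")],
                 occ)
    records <- new_prot
    ambiguous_dropped <- index@report$ambiguous_dropped + dig$ambiguous_dropped
  } else {
    ambiguous_dropped <- dig$ambiguous_dropped
  }
  ## idempotent re-import: one occurrence per (protein_id, start_offset,
  ## peptide); within one build duplicates can only arise from appending
  occ <- unique(occ, by = c("protein_id", "start_offset", "peptide"))

  peptides <- unique(occ[, c("peptide", "mass", "mass_key")], by = "peptide")
  setkey(peptides, peptide)
  setkey(occ, peptide)
  massdb <- copy(peptides)
  setorder(massdb, mass_key, mass, peptide)

  ## shared target/decoy peptide accounting
  shared_n <- 0L
  shared_hist <- list()
  if (nrow(occ)) {
    decoy_of <- records$is_decoy[match(occ$protein_id, records$protein_id)]
    side <- data.table(peptide = occ$peptide, d = decoy_of)[
      , list(t = any(!d), dec = any(d)), by = "peptide"]
    shared <- side$peptide[side$t & side$dec]
    shared_n <- length(shared)
    if (shared_n) {
      tb <- table(nchar(shared))
      ## named list keeps the length keys intact through JSON serialization
      shared_hist <- as.list(setNames(as.integer(tb), names(tb)))
    }
  }
  report <- list(
    n_proteins = nrow(records),
    n_targets = sum(!records$is_decoy),
    n_decoys = sum(records$is_decoy),
    n_distinct_peptides = nrow(peptides),
    n_mass_keys = length(unique(massdb$mass_key)),
    n_occurrences = nrow(occ),
    shared_target_decoy_peptides = shared_n,
    shared_peptide_length_histogram = shared_hist,
    ambiguous_dropped = ambiguous_dropped,
    partial_build = FALSE)
  if (verbose)
    message(sprintf("indexed %d proteins -> %d distinct peptides, %d mass keys",
                    report$n_proteins, report$n_distinct_peptides,
                    report$n_mass_keys))
  cnt <- new.env(parent = emptyenv())
  assign("rows_touched", 0, envir = cnt)
  assign("keys_touched", 0, envir = cnt)
  assign("probes", 0, envir = cnt)
  assign("queries", 0, envir = cnt)
  assign("peak_buffer", 0, envir = cnt)
  new("PeptideIndex", proteins = records, peptides = peptides,
      occurrences = occ, massdb = massdb, params = params, report = report,
      counters = cnt)
}

## first index i with v[i] >= x, and last index with v[i] <= x, for sorted v
.lowerBound <- function(v, x) findInterval(x, v, left.open = TRUE) + 1L
.upperBound <- function(v, x) findInterval(x, v)

#' Query peptide candidates in a precursor mass window
#'
#' Returns every indexed peptide whose neutral monoisotopic mass m
#' satisfies `|m - neutralMass| <= neutralMass * tolerancePpm * 1e-6`,
#' in deterministic order (ascending mass, ties broken by sequence).
#' The lookup is an ordered key-range scan over the mass-sorted
#' collection: two binary searches plus a contiguous slice, so the rows
#' touched are proportional to the window content, not the database size
#' (see [indexCounters()]).
#'
#' @param index A built [PeptideIndex].
#' @param neutralMass Neutral precursor mass (Da).
#' @param tolerancePpm Relative tolerance in ppm (> 0).
#' @return `data.table` with columns `peptide`, `mass`.
#' @export
queryMassWindow <- function(index, neutralMass, tolerancePpm) {
  stopifnot(is(index, "PeptideIndex"), tolerancePpm > 0)
  rng <- .windowRange(index, neutralMass, tolerancePpm)
  if (rng$lo > rng$hi)
    return(data.table(peptide = character(), mass = numeric()))
  out <- index@massdb[rng$lo:rng$hi, c("peptide", "mass")]
  setorder(out, mass, peptide)
  out
}

## Locate the contiguous massdb row range of a ppm window and charge the
## backend access counters: binary-search probes plus the slice length.
.windowRange <- function(index, neutralMass, tolerancePpm) {
  tol <- neutralMass * tolerancePpm * 1e-6
  v <- index@massdb$mass
  lo <- .lowerBound(v, neutralMass - tol)
  hi <- .upperBound(v, neutralMass + tol)
  cnt <- index@counters
  nprobe <- 2L * as.integer(ceiling(log2(max(2, length(v)))))
  cnt$queries <- cnt$queries + 1
  cnt$probes <- cnt$probes + nprobe
  if (hi >= lo) {
    cnt$rows_touched <- cnt$rows_touched + (hi - lo + 1)
    cnt$keys_touched <- cnt$keys_touched +
      length(unique(index@massdb$mass_key[lo:hi]))
  }
  list(lo = lo, hi = hi)
}

#' Look up a peptide and its parent proteins
#'
#' Point lookup in the distinct-peptide collection. Unknown sequences
#' yield `NULL` (a not-found signal, distinct from an error).
#'
#' @param index A built [PeptideIndex].
#' @param peptide Peptide sequence.
#' @return `NULL` if absent, else a list with `peptide`, `mass`,
#'   `mass_key` and `occurrences` (a `data.table` with `protein_id`,
#'   `start_offset`, `prev`, `nxt`, `nmc`, `is_decoy`, `defline`).
#' @export
lookupParents <- function(index, peptide) {
  stopifnot(is(index, "PeptideIndex"), is.character(peptide),
            length(peptide) == 1L)
  .pepquery <- peptide
  hit <- index@peptides[list(.pepquery), nomatch = NULL]
  if (!nrow(hit)) return(NULL)
  occ <- index@occurrences[list(.pepquery),
                           c("protein_id", "start_offset", "prev", "nxt",
                             "nmc")]
  m <- match(occ$protein_id, index@proteins$protein_id)
  occ$is_decoy <- index@proteins$is_decoy[m]
  occ$defline <- index@proteins$defline[m]
  list(peptide = hit$peptide, mass = hit$mass, mass_key = hit$mass_key,
       occurrences = occ)
}

## parent decoy status for a batch of peptides: TRUE when every parent of
## the peptide is a decoy record
.decoyOnly <- function(index, peptides) {
  occ <- index@occurrences[list(unique(peptides)),
                           c("peptide", "protein_id")]
  occ$is_decoy <- index@proteins$is_decoy[
    match(occ$protein_id, index@proteins$protein_id)]
  agg <- occ[, list(decoy_only = all(is_decoy)), by = "peptide"]
  agg$decoy_only[match(peptides, agg$peptide)]
}

#' Backend access counters
#'
#' The index records, per mass-window query, the binary-search probes and
#' the rows and distinct mass keys inside the scanned slice, plus the
#' peak candidate-buffer size observed by [scoreScan()]. These counters
#' make the scaling behaviour of the store testable without wall-clock
#' timing.
#'
#' @param index A [PeptideIndex].
#' @return Named list of counter values.
#' @export
indexCounters <- function(index) {
  as.list(index@counters)
}

#' @describeIn indexCounters Reset all counters to zero.
#' @export
resetCounters <- function(index) {
  for (nm in ls(index@counters)) assign(nm, 0, envir = index@counters)
  invisible(index)
}

#' @rdname PeptideIndex-accessors
#' @name PeptideIndex-accessors
#' @title Accessors for PeptideIndex
#' @param index A [PeptideIndex].
#' @return `proteinRecords()` the protein table; `peptideTable()` the
#'   distinct-peptide table; `massKeyTable()` the mass-ordered table;
#'   `buildReport()` the build report list; `nProteins()`, `nPeptides()`,
#'   `nMassKeys()` integer counts.
NULL

#' @rdname PeptideIndex-accessors
#' @export
proteinRecords <- function(index) copy(index@proteins)

#' @rdname PeptideIndex-accessors
#' @export
peptideTable <- function(index) copy(index@peptides)

#' @rdname PeptideIndex-accessors
#' @export
massKeyTable <- function(index) copy(index@massdb)

#' @rdname PeptideIndex-accessors
#' @export
buildReport <- function(index) index@report

#' @rdname PeptideIndex-accessors
#' @export
nProteins <- function(index) nrow(index@proteins)

#' @rdname PeptideIndex-accessors
#' @export
nPeptides <- function(index) nrow(index@peptides)

#' @rdname PeptideIndex-accessors
#' @export
nMassKeys <- function(index) index@report$n_mass_keys

setMethod("show", "PeptideIndex", function(object) {
  r <- object@report
  cat("PeptideIndex\n")
  cat(sprintf("  proteins:  %d (%d targets, %d decoys)\n",
              r$n_proteins, r$n_targets, r$n_decoys))
  cat(sprintf("  peptides:  %d distinct over %d mass keys (%d occurrences)\n",
              r$n_distinct_peptides, r$n_mass_keys, r$n_occurrences))
  cat(sprintf("  shared target/decoy peptides: %d\n",
              r$shared_target_decoy_peptides))
  cat(sprintf("  digestion: %s, <=%d missed cleavages, length %d-%d, mass %.0f-%.0f Da\n",
              object@params@enzyme, object@params@missedCleavages,
              object@params@minLength, object@params@maxLength,
              object@params@minMass, object@params@maxMass))
})

#' Full cross-collection consistency check
#'
#' Verifies the structural invariants of an index: the distinct-peptide
#' key set equals the union of the mass-key collection, no peptide lives
#' under two mass keys, every stored mass matches a recomputation from
#' the sequence to 1e-6 Da, every mass key is the discretization of its
#' stored mass, and every occurrence's substring check passes.
#'
#' @param index A [PeptideIndex].
#' @param recomputeMasses Also recompute peptide masses from sequences
#'   (slower; set `FALSE` for very large indexes).
#' @return `TRUE`, or an error describing the violated invariant.
#' @export
validateIndex <- function(index, recomputeMasses = TRUE) {
  stopifnot(is(index, "PeptideIndex"))
  if (!setequal(index@peptides$peptide, index@massdb$peptide))
    stop("SeqDB key set != union of MassDB peptide lists")
  if (anyDuplicated(index@massdb$peptide))
    stop("a peptide appears under two mass keys")
  if (!identical(index@massdb$mass_key,
                 as.integer(round(index@massdb$mass * 1e4))))
    stop("mass_key is not the discretization of the stored mass")
  if (nrow(index@occurrences)) {
    occ <- index@occurrences
    seqs <- index@proteins$sequence[match(occ$protein_id,
                                          index@proteins$protein_id)]
    sub <- stringi::stri_sub(seqs, occ$start_offset + 1L,
                             occ$start_offset + nchar(occ$peptide))
    if (!all(sub == occ$peptide))
      stop("occurrence substring check failed")
  }
  if (recomputeMasses && nrow(index@peptides)) {
    m <- computeMonoisotopicMass(index@peptides$peptide,
                                 staticMods = index@params@staticMods,
                                 ambiguity = if (index@params@ambiguity == "map")
                                   "map" else "reject")
    if (max(abs(m - index@peptides$mass)) > 1e-6)
      stop("stored peptide mass deviates from recomputation by > 1e-6 Da")
  }
  TRUE
}
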