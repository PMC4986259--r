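#' Per-PSM quality gates
#'
#' Keeps rank-1 matches whose absolute precursor mass error is strictly
#' below `maxAbsPpm` and which pass any optional XCorr / DeltaCN gates;
#' at most one PSM per scan survives.
#'
#' @param psmTable PSM `data.table` (from a [SearchResult] or
#'   [readSqt()]).
#' @param params A [FilterParams].
#' @return The gated PSM `data.table`.
#' @export
applyPsmGates <- function(psmTable, params = filterParams()) {
  tab <- as.data.table(psmTable)
  if (!nrow(tab)) return(tab)
  keep <- tab$rank == 1L & abs(tab$ppm_error) < params@maxAbsPpm
  if (!is.na(params@minXcorr)) keep <- keep & tab$xcorr >= params@minXcorr
  if (!is.na(params@minDeltaCn)) keep <- keep & tab$delta_cn >= params@minDeltaCn
  tab <- tab[keep]
  unique(tab, by = "scan_id")
}

#' Assemble gated PSMs into protein loci
#'
#' Every parent protein of every surviving peptide receives that peptide
#' (shared peptides fan out to all parents, including peptides shared
#' between target and decoy records, which are tallied separately).
#' Loci with identical peptide sets are collapsed into one group row
#' listing all member deflines; a group is a decoy locus only when every
#' member protein is a decoy record.
#'
#' @param psmTable Gated PSM `data.table` ([applyPsmGates()] output).
#' @param index The [PeptideIndex] searched.
#' @param group Collapse indistinguishable loci (identical peptide sets)
#'   into one row.
#' @return A `data.table` of loci: `locus_id`, `protein_ids` (list),
#'   `deflines` (list), `is_decoy`, `peptides` (list of distinct peptide
#'   sequences), `n_peptides`, `spectral_count`, `best_xcorr`, plus the
#'   shared target/decoy peptide count as attribute `shared_peptides`.
#' @export
assembleLoci <- function(psmTable, index, group = TRUE) {
  tab <- as.data.table(psmTable)
  empty <- data.table(locus_id = integer(), protein_ids = list(),
                      deflines = list(), is_decoy = logical(),
                      peptides = list(), n_peptides = integer(),
                      spectral_count = integer(), best_xcorr = numeric())
  if (!nrow(tab)) {
    attr(empty, "shared_peptides") <- 0L
    return(empty)
  }
  peps <- unique(tab$peptide)
  occ <- index@occurrences[list(peps), c("peptide", "protein_id"),
                           nomatch = NULL]
  missing <- setdiff(peps, occ$peptide)
  if (length(missing))
    stop("peptide(s) absent from index: ", paste(head(missing, 3),
                                                 collapse = ", "))
  occ <- unique(occ, by = c("peptide", "protein_id"))
  occ$is_decoy <- index@proteins$is_decoy[
    match(occ$protein_id, index@proteins$protein_id)]
  side <- occ[, list(t = any(!is_decoy), d = any(is_decoy)), by = "peptide"]
  shared <- sum(side$t & side$d)

  ## per-protein aggregation: distinct peptides, spectral count, best XCorr
  m <- merge(occ, tab[, c("peptide", "xcorr", "scan_id")], by = "peptide",
             allow.cartesian = TRUE)
  loci <- m[, list(peptides = list(sort(unique(peptide))),
                   n_peptides = length(unique(peptide)),
                   spectral_count = length(unique(scan_id)),
                   best_xcorr = max(xcorr)),
            by = "protein_id"]
  loci$is_decoy <- index@proteins$is_decoy[
    match(loci$protein_id, index@proteins$protein_id)]
  loci$defline <- index@proteins$defline[
    match(loci$protein_id, index@proteins$protein_id)]
  if (group) {
    loci$pepkey <- vapply(loci$peptides, paste, character(1), collapse = ";")
    g <- loci[, list(protein_ids = list(sort(protein_id)),
                     deflines = list(sort(defline)),
                     is_decoy = all(is_decoy),
                     peptides = peptides[1L],
                     n_peptides = n_peptides[1L],
                     spectral_count = spectral_count[1L],
                     best_xcorr = best_xcorr[1L]),
             by = "pepkey"]
    g$pepkey <- NULL
  } else {
    g <- data.table(protein_ids = as.list(loci$protein_id),
                    deflines = as.list(loci$defline),
                    is_decoy = loci$is_decoy, peptides = loci$peptides,
                    n_peptides = loci$n_peptides,
                    spectral_count = loci$spectral_count,
                    best_xcorr = loci$best_xcorr)
  }
  first_dl <- vapply(g$deflines, `[`, character(1), 1L)
  g <- g[order(-g$spectral_count, -g$best_xcorr, first_dl)]
  g[, locus_id := .I]
  setcolorder(g, c("locus_id", "protein_ids", "deflines", "is_decoy",
                   "peptides", "n_peptides", "spectral_count", "best_xcorr"))
  attr(g, "shared_peptides") <- shared
  g
}

## FDR of the locus set above a threshold, under the chosen estimator
.lociFdr <- function(nTarget, nDecoy, estimator) {
  if (estimator == "symmetric") {
    if (nTarget + nDecoy == 0L) return(0)
    return(2 * nDecoy / (nTarget + nDecoy))
  }
  if (nTarget == 0L) return(if (nDecoy > 0L) Inf else 0)
  nDecoy / nTarget
}

#' Filter protein loci by target-decoy FDR
#'
#' Drops loci with fewer than `minPeptides` distinct peptides, then finds
#' the least strict locus-level XCorr threshold at which the decoy-based
#' protein FDR estimate stays at or below `maxProteinFdr`. The accepted
#' set is the target loci passing that threshold; decoy loci are never
#' accepted.
#'
#' @param loci Locus table from [assembleLoci()].
#' @param params A [FilterParams].
#' @return A list with `accepted` (locus `data.table`) and `report`: input
#'   and surviving locus counts, the chosen threshold, the achieved FDR,
#'   the shared target/decoy peptide count and a `no_threshold` flag set
#'   when no threshold satisfies the bound.
#' @export
filterByProteinFdr <- function(loci, params = filterParams()) {
  loci <- as.data.table(loci)
  shared <- attr(loci, "shared_peptides")
  if (is.null(shared)) shared <- NA_integer_
  pepgate <- loci[loci$n_peptides >= params@minPeptides]
  report <- list(input_loci = nrow(loci),
                 loci_after_peptide_gate = nrow(pepgate),
                 target_loci = 0L, decoy_loci = 0L,
                 xcorr_threshold = NA_real_,
                 achieved_protein_fdr = NA_real_,
                 shared_peptides = shared, no_threshold = FALSE)
  if (!nrow(pepgate) || !any(!pepgate$is_decoy)) {
    if (!nrow(pepgate) || sum(!pepgate$is_decoy) == 0L)
      warning("no target loci pass the peptide-count gate")
    report$no_threshold <- !nrow(pepgate)
    return(list(accepted = pepgate[0L], report = report))
  }
  ## candidate thresholds: every observed locus XCorr, scanned from the
  ## least strict upward; the first (lowest) threshold meeting the bound
  ## maximizes the accepted set
  o <- order(pepgate$best_xcorr)
  x <- pepgate$best_xcorr[o]
  dec <- pepgate$is_decoy[o]
  nT <- sum(!dec); nD <- sum(dec)
  chosen <- NA_real_
  chosen_fdr <- NA_real_
  i <- 1L
  n <- length(x)
  while (i <= n) {
    ## threshold = x[i]: all loci with best_xcorr >= x[i] pass
    fdr <- .lociFdr(nT, nD, params@fdrEstimator)
    if (fdr <= params@maxProteinFdr) {
      chosen <- x[i]
      chosen_fdr <- fdr
      break
    }
    ## advance past all loci tied at x[i]
    j <- i
    while (j <= n && x[j] == x[i]) {
      if (dec[j]) nD <- nD - 1L else nT <- nT - 1L
      j <- j + 1L
    }
    i <- j
  }
  if (is.na(chosen)) {
    report$no_threshold <- TRUE
    return(list(accepted = pepgate[0L], report = report))
  }
  pass <- pepgate$best_xcorr >= chosen
  accepted <- pepgate[pass & !pepgate$is_decoy]
  report$target_loci <- sum(pass & !pepgate$is_decoy)
  report$decoy_loci <- sum(pass & pepgate$is_decoy)
  report$xcorr_threshold <- chosen
  report$achieved_protein_fdr <- chosen_fdr
  list(accepted = accepted, report = report)
}

#' One-call DTASelect-style filtering
#'
#' Convenience wrapper: [applyPsmGates()], [assembleLoci()],
#' [filterByProteinFdr()].
#'
#' @param psmTable PSM table.
#' @param index The [PeptideIndex] searched.
#' @param params A [FilterParams].
#' @return As [filterByProteinFdr()], with the gated PSM table added as
#'   `psms`; the report additionally carries `input_psms` and
#'   `psms_after_gates`.
#' @export
filterResults <- function(psmTable, index, params = filterParams()) {
  tab <- as.data.table(psmTable)
  gated <- applyPsmGates(tab, params)
  loci <- assembleLoci(gated, index)
  res <- filterByProteinFdr(loci, params)
  res$report$input_psms <- if (nrow(tab)) length(unique(tab$scan_id)) else 0L
  res$report$psms_after_gates <- nrow(gated)
  ## PSMs supporting accepted loci
  acc_peps <- unique(unlist(res$accepted$peptides))
  res$psms <- gated[gated$peptide %in% acc_peps]
  res
}

#' Write the filtered locus table and report
#'
#' Tab-delimited locus table (deflines, distinct peptide count, spectral
#' count, best XCorr) ordered by descending spectral count then defline,
#' plus a JSON report alongside (`<path>.report.json`).
#'
#' @param filtered Output of [filterByProteinFdr()] or [filterResults()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeFiltered <- function(filtered, path) {
  acc <- filtered$accepted
  tab <- data.table(
    defline = vapply(acc$deflines, paste, character(1), collapse = "; "),
    n_peptides = acc$n_peptides,
    spectral_count = acc$spectral_count,
    best_xcorr = acc$best_xcorr)
  setorder(tab, -spectral_count, defline)
  con <- file(path, "w")
  writeLines("defline\tn_peptides\tspectral_count\tbest_xcorr", con)
  if (nrow(tab))
    writeLines(sprintf("%s\t%d\t%d\t%.5f", tab$defline, tab$n_peptides,
                       tab$spectral_count, tab$best_xcorr), con)
  close(con)
  rep <- filtered$report
  rep$shared_peptides <- as.integer(rep$shared_peptides)
  jsonlite::write_json(rep, paste0(path, ".report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read back a filtered locus table
#'
#' @param path TSV path written by [writeFiltered()].
#' @return A `data.table` with the serialized columns.
#' @export
readFilteredLoci <- function(path) {
  out <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = "defline"))
  as.data.table(out)
}
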