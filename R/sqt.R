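#' Write search results in SQT-dialect text
#'
#' One `S` line per scan (scan id twice, charge, observed neutral mass,
#' candidate count), `M` lines per ranked hit (rank, calculated neutral
#' mass, XCorr, DeltaCN, Z-score, sequence) and one `L` line per parent
#' protein defline. Output is byte-deterministic for fixed input and
#' version string.
#'
#' @param result A [SearchResult] (or its PSM `data.table`).
#' @param index The [PeptideIndex] searched (for parent deflines and the
#'   header checksum).
#' @param path Output path.
#' @param version Version string recorded in the header.
#' @return `path`, invisibly.
#' @export
writeSqt <- function(result, index, path, version = "trypsearch-0.1.0") {
  tab <- if (is(result, "SearchResult")) result@psms else as.data.table(result)
  con <- file(path, "w")
  on.exit(close(con))
  p <- if (is(result, "SearchResult")) result@params else searchParams()
  checksum <- sum(as.numeric(index@massdb$mass_key) %% 97) %% 1e9
  writeLines(c(
    "H\tSQTGenerator\ttrypsearch",
    paste0("H\tSQTGeneratorVersion\t", version),
    sprintf("H\tDatabaseProteins\t%d", nProteins(index)),
    sprintf("H\tDatabasePeptides\t%d", nPeptides(index)),
    sprintf("H\tDatabaseChecksum\t%.0f", checksum),
    sprintf("H\tPrecursorTolerancePpm\t%g", p@tolerancePpm)), con)
  if (!nrow(tab)) return(invisible(path))
  setorderv(tab, c("scan_id", "rank"))
  for (sid in unique(tab$scan_id)) {
    g <- tab[tab$scan_id == sid]
    writeLines(sprintf("S\t%d\t%d\t%d\t%.5f\t%d", sid, sid, g$charge[1],
                       g$obs_mass[1], g$candidate_count[1]), con)
    for (j in seq_len(nrow(g))) {
      writeLines(sprintf("M\t%d\t%.5f\t%.5f\t%.5f\t%.5f\t%s",
                         g$rank[j], g$calc_mass[j], g$xcorr[j],
                         g$delta_cn[j], g$z_score[j], g$peptide[j]), con)
      par <- lookupParents(index, g$peptide[j])
      if (!is.null(par))
        for (dl in sort(unique(par$occurrences$defline)))
          writeLines(paste0("L\t", dl), con)
    }
  }
  invisible(path)
}

#' Read an SQT-dialect file back into a PSM table
#'
#' Reconstructs the PSM table written by [writeSqt()]. The precursor
#' mass error in ppm is recomputed from the observed and calculated
#' neutral masses.
#'
#' @param path Path to the SQT file.
#' @return A `data.table` with the PSM columns (without `xcorr_raw` and
#'   `is_decoy_only`, which are not serialized) plus `parents`, a list
#'   column of parent deflines.
#' @export
readSqt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  scan <- NULL
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) rows[[length(rows) + 1L]] <<- cur
    cur <<- NULL
  }
  for (ln in lines) {
    c1 <- substr(ln, 1, 1)
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (c1 == "H") next
    if (c1 == "S") {
      flush()
      scan <- list(scan_id = as.integer(f[2]), charge = as.integer(f[4]),
                   obs_mass = as.numeric(f[5]),
                   candidate_count = as.integer(f[6]))
    } else if (c1 == "M") {
      flush()
      cur <- data.table(
        scan_id = scan$scan_id, charge = scan$charge, peptide = f[7],
        calc_mass = as.numeric(f[3]), obs_mass = scan$obs_mass,
        xcorr = as.numeric(f[4]), delta_cn = as.numeric(f[5]),
        z_score = as.numeric(f[6]), rank = as.integer(f[2]),
        candidate_count = scan$candidate_count,
        parents = list(character()))
    } else if (c1 == "L") {
      cur$parents <- list(c(cur$parents[[1]], f[2]))
    }
  }
  flush()
  if (!length(rows))
    return(data.table(scan_id = integer(), charge = integer(),
                      peptide = character(), calc_mass = numeric(),
                      obs_mass = numeric(), xcorr = numeric(),
                      delta_cn = numeric(), z_score = numeric(),
                      ppm_error = numeric(), rank = integer(),
                      candidate_count = integer(), parents = list()))
  out <- rbindlist(rows)
  out$ppm_error <- (out$obs_mass - out$calc_mass) / out$calc_mass * 1e6
  setcolorder(out, c("scan_id", "charge", "peptide", "calc_mass", "obs_mass",
                     "xcorr", "delta_cn", "z_score", "ppm_error", "rank",
                     "candidate_count", "parents"))
  out
}
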