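#' Tryptic cleavage sites of a protein sequence
#'
#' Positions (1-based) after which trypsin cleaves: C-terminal to K or R
#' unless the following residue is proline. The position after the final
#' residue is never a site (it coincides with the C-terminus).
#'
#' @param sequence Uppercase amino-acid string.
#' @return Integer vector of internal cleavage positions.
#' @export
#' @examples
#' cleavageSites("MKRPA")  # cleave after K only (R is followed by P)
cleavageSites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  loc <- stringi::stri_locate_all_regex(sequence, "[KR](?!P)")[[1L]][, 1L]
  loc <- loc[!is.na(loc) & loc < nchar(sequence)]
  as.integer(loc)
}

## Batch cleavage-site location over a character vector of sequences.
## Returns a list of integer vectors.
.cleavageSitesMany <- function(sequences) {
  locs <- stringi::stri_locate_all_regex(sequences, "[KR](?!P)",
                                         omit_no_match = TRUE)
  n <- nchar(sequences)
  mapply(function(m, len) {
    p <- m[, 1L]
    as.integer(p[p < len])
  }, locs, n, SIMPLIFY = FALSE)
}

## Enumerate fully tryptic peptide spans for many proteins at once.
## Returns a data.table(row = protein row index, start0, end, nmc) where
## start0 is the 0-based start offset and end the 1-based inclusive end.
.digestSpans <- function(sequences, missedCleavages) {
  sites <- .cleavageSitesMany(sequences)
  lens <- nchar(sequences)
  nb <- lengths(sites) + 2L
  B <- data.table(
    row = rep(seq_along(sequences), nb),
    b   = unlist(lapply(seq_along(sequences),
                        function(i) c(0L, sites[[i]], lens[i])), use.names = FALSE)
  )
  out <- vector("list", missedCleavages + 1L)
  for (d in seq_len(missedCleavages + 1L)) {
    e <- B[, shift(b, -d), by = row]$V1
    keep <- !is.na(e)
    out[[d]] <- data.table(row = B$row[keep], start0 = B$b[keep],
                           end = e[keep], nmc = d - 1L)
  }
  rbindlist(out)
}

#' In-silico tryptic digestion of one protein
#'
#' Enumerates every fully tryptic peptide of the protein with at most
#' `missedCleavages` internal uncut sites, then applies the length and
#' neutral-mass windows of `params`. Duplicate sequences within one
#' protein yield separate occurrence rows.
#'
#' @param sequence Uppercase amino-acid string (or a single protein-record
#'   row's sequence).
#' @param params A [DigestionParams] object.
#' @return A `data.table` with one row per peptide occurrence: `peptide`,
#'   `start_offset` (0-based), `nmc` (missed cleavages), `prev` and `nxt`
#'   (flanking residues, `"-"` at protein termini), and `mass` (neutral
#'   monoisotopic, Da; `NA` only never appears because filtered).
#' @export
#' @examples
#' trypticDigest("MKRPA", digestionParams(missedCleavages = 0,
#'   minLength = 1, minMass = 0))
trypticDigest <- function(sequence, params = digestionParams()) {
  stopifnot(is(params, "DigestionParams"))
  res <- .digestRecords(data.table(protein_id = 0L, sequence = sequence),
                        params)
  res$peptides[, c("peptide", "start_offset", "nmc", "prev", "nxt", "mass")]
}

## Core batch digestion over a protein-record table.  Returns
## list(peptides = data.table(protein_id, peptide, start_offset, nmc,
## prev, nxt, mass, mass_key), ambiguous_dropped = count).
.digestRecords <- function(records, params) {
  records <- as.data.table(records)
  if (!nrow(records))
    return(list(peptides = data.table(protein_id = integer(),
                                      peptide = character(),
                                      start_offset = integer(), nmc = integer(),
                                      prev = character(), nxt = character(),
                                      mass = numeric(), mass_key = integer()),
                ambiguous_dropped = 0L))
  seqs <- records$sequence
  if (params@ambiguity == "reject") {
    bad <- stringi::stri_locate_first_regex(seqs, "[BJOUXZ]")[, 1L]
    if (any(!is.na(bad))) {
      i <- which(!is.na(bad))[1L]
      stop(sprintf(
        "residue '%s' at position %d of protein %s has no defined mass",
        substr(seqs[i], bad[i], bad[i]), bad[i], records$protein_id[i]))
    }
  }
  spans <- .digestSpans(seqs, params@missedCleavages)
  plen <- spans$end - spans$start0
  spans <- spans[plen >= params@minLength & plen <= params@maxLength]
  if (!nrow(spans))
    return(list(peptides = data.table(protein_id = integer(),
                                      peptide = character(),
                                      start_offset = integer(), nmc = integer(),
                                      prev = character(), nxt = character(),
                                      mass = numeric(), mass_key = integer()),
                ambiguous_dropped = 0L))

  ## Peptide masses by per-protein prefix sums of residue masses so the
  ## cost is linear in total residues + peptides, not peptide residues.
  ## Residues without a defined mass contribute 0 to the sums and are
  ## tracked by a parallel prefix count, so that only peptides actually
  ## containing such a residue are dropped.
  lut <- .massLookup(params@staticMods,
                     if (params@ambiguity == "map") "map" else "skip")
  lens <- nchar(seqs)
  offs <- cumsum(lens) - lens
  ## prefix sums restart at each protein, keeping rounding error at the
  ## scale of one protein mass rather than the whole database
  pre <- lapply(seqs, function(s) {
    v <- lut[utf8ToInt(s) + 1L]
    und <- is.na(v)
    if (any(und)) v[und] <- 0
    list(m = cumsum(v), a = cumsum(und))
  })
  flat <- unlist(lapply(pre, `[[`, "m"), use.names = FALSE)
  flatn <- unlist(lapply(pre, `[[`, "a"), use.names = FALSE)
  i_end <- offs[spans$row] + spans$end
  i_start <- offs[spans$row] + spans$start0
  zero <- spans$start0 == 0L
  startv <- ifelse(zero, 0, flat[pmax(i_start, 1L)])
  startn <- ifelse(zero, 0L, flatn[pmax(i_start, 1L)])
  mass <- flat[i_end] - startv + .WATER_MONO
  nambig <- flatn[i_end] - startn

  ambiguous_dropped <- sum(nambig > 0L)
  keep <- nambig == 0L & mass >= params@minMass & mass <= params@maxMass
  spans <- spans[keep]
  mass <- mass[keep]

  pep <- stringi::stri_sub(seqs[spans$row], spans$start0 + 1L, spans$end)
  prev <- ifelse(spans$start0 == 0L, "-",
                 stringi::stri_sub(seqs[spans$row], spans$start0, spans$start0))
  nxt <- ifelse(spans$end >= lens[spans$row], "-",
                stringi::stri_sub(seqs[spans$row], spans$end + 1L,
                                  spans$end + 1L))
  list(peptides = data.table(
         protein_id = records$protein_id[spans$row],
         peptide = pep, start_offset = spans$start0, nmc = spans$nmc,
         prev = prev, nxt = nxt, mass = mass,
         mass_key = as.integer(round(mass * 1e4))),
       ambiguous_dropped = as.integer(ambiguous_dropped))
}
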