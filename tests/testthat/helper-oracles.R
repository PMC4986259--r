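## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: masses come from elemental compositions, the
## digest oracle enumerates substrings, the XCorr oracle evaluates the full
## lagged correlation, and the query oracle is a linear scan.

## residue monoisotopic masses from elemental composition (independent of
## the table inside the package)
oracleResidueMasses <- local({
  iso <- c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
           O = 15.9949146196, S = 31.97207100)
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1))
  function() {
    vapply(comp, function(cc) sum(iso[names(cc)] * cc), numeric(1))
  }
})

oracleWater <- function() 2 * 1.00782503207 + 15.9949146196

## peptide neutral mass by direct elemental summation
oracleMass <- function(peptide, staticMods = NULL) {
  rm <- oracleResidueMasses()
  if (length(staticMods)) rm[names(staticMods)] <- rm[names(staticMods)] +
      staticMods
  vapply(peptide, function(p) {
    sum(rm[strsplit(p, "")[[1]]]) + oracleWater()
  }, numeric(1), USE.NAMES = FALSE)
}

## brute-force fully tryptic digestion: every substring whose termini are
## cleavage-valid and whose internal missed-site count is within bounds
bruteDigest <- function(sequence, missedCleavages, minLength = 1L,
                        maxLength = 1e9L, minMass = 0, maxMass = Inf,
                        staticMods = c(C = 57.02146)) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "")[[1]]
  ## site[p]: trypsin cleaves after position p
  site <- seq_len(n) < n & ch %in% c("K", "R") & c(ch[-1], "") != "P"
  cum <- c(0L, cumsum(site))
  ss <- integer(); ee <- integer(); nmc <- integer()
  for (s in 1:n) {
    if (!(s == 1 || site[s - 1])) next
    for (e in s:n) {
      if (!(e == n || site[e])) next
      internal <- cum[e] - cum[s]      # sites strictly inside [s, e)
      if (internal > missedCleavages) next
      len <- e - s + 1
      if (len < minLength || len > maxLength) next
      ss <- c(ss, s); ee <- c(ee, e); nmc <- c(nmc, internal)
    }
  }
  if (!length(ss))
    return(data.frame(peptide = character(), start_offset = integer(),
                      nmc = integer()))
  pep <- substring(sequence, ss, ee)
  m <- suppressWarnings(
    trypsearch::computeMonoisotopicMass(pep, staticMods, ambiguity = "skip"))
  keep <- !is.na(m) & m >= minMass & m <= maxMass
  data.frame(peptide = pep[keep], start_offset = ss[keep] - 1L,
             nmc = nmc[keep], stringsAsFactors = FALSE)
}

## naive cross-correlation: R(0) - mean of R(tau) over tau in [-w, w] \ {0},
## evaluated on the normalized pre-subtraction vector
naiveXcorr <- function(processed, theoretical, params) {
  v <- processed$bins_pre
  w <- params@bgWindow
  nb <- length(v)
  Rtau <- vapply(-w:w, function(tau) {
    b <- theoretical$bin + tau
    keep <- b >= 0 & b < nb
    sum(theoretical$weight[keep] * v[b[keep] + 1L])
  }, numeric(1))
  R0 <- Rtau[w + 1L]
  (R0 - mean(Rtau[-(w + 1L)])) * params@xcorrScale
}

## linear-scan window query over the distinct-peptide table
linearScanQuery <- function(index, neutralMass, tolerancePpm) {
  tab <- peptideTable(index)
  tol <- neutralMass * tolerancePpm * 1e-6
  hit <- tab[abs(tab$mass - neutralMass) <= tol, c("peptide", "mass")]
  hit[order(hit$mass, hit$peptide), ]
}

## exhaustive threshold scan for the protein-FDR filter
bruteFdrThreshold <- function(loci, params) {
  loci <- loci[loci$n_peptides >= params@minPeptides, ]
  if (!nrow(loci)) return(list(threshold = NA_real_, accepted = 0L))
  est <- function(t, d) {
    if (params@fdrEstimator == "symmetric") {
      if (t + d == 0) 0 else 2 * d / (t + d)
    } else if (t == 0) {
      if (d > 0) Inf else 0
    } else d / t
  }
  best <- list(threshold = NA_real_, accepted = -1L, fdr = NA_real_)
  for (thr in sort(unique(loci$best_xcorr))) {
    pass <- loci$best_xcorr >= thr
    t <- sum(pass & !loci$is_decoy)
    d <- sum(pass & loci$is_decoy)
    f <- est(t, d)
    if (f <= params@maxProteinFdr && t > best$accepted) {
      best <- list(threshold = thr, accepted = t, fdr = f)
    }
  }
  best
}

## small random protein generator for property tests
randomProteins <- function(n, minLen = 10, maxLen = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aas <- strsplit("GASPVTCLINDQKEMHFRYW", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(minLen:maxLen, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

## record table from bare sequences
recordsFromSequences <- function(seqs, prefix = "prot") {
  data.table::data.table(protein_id = seq_along(seqs) - 1L,
                         defline = sprintf("%s|%04d", prefix, seq_along(seqs)),
                         sequence = seqs, is_decoy = FALSE)
}

## a random centroided spectrum (for preprocessing / xcorr oracles)
randomSpectrum <- function(scanId = 1L, nPeaks = 20, mzRange = c(150, 1800),
                           premz = 600.0) {
  mz <- sort(runif(nPeaks, mzRange[1], mzRange[2]))
  list(scan_id = scanId, precursor_mz = premz,
       charges = 2L, charge_known = TRUE,
       peaks = matrix(c(mz, runif(nPeaks, 5, 500)), ncol = 2,
                      dimnames = list(NULL, c("mz", "intensity"))))
}
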