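#' Preprocess a spectrum for cross-correlation scoring
#'
#' Classical SEQUEST-style conditioning of a centroided scan at a given
#' precursor charge: peaks within `precursorRemoval` Th of the precursor
#' m/z are removed; intensities are square-root transformed and binned
#' (bin index `round(mz / binWidth)`, keeping the per-bin maximum); the
#' vector is split into `nRegions` equal regions each scaled to a maximum
#' of `regionMax`; finally the +/- `bgWindow` bin background mean is
#' subtracted, so that the cross-correlation score reduces to a single
#' dot product with the theoretical spectrum:
#' `v'[i] = v[i] - mean(v[i-75 .. i+75], excluding offset 0)`.
#'
#' @param spectrum One scan (list as held by a [SpectrumSet]).
#' @param charge Assumed precursor charge.
#' @param params A [SearchParams].
#' @return A list with `bins` (the conditioned intensity vector, index 1
#'   holding bin 0), `neutral_mass` (Da) and `bin_width`.
#' @export
preprocessSpectrum <- function(spectrum, charge, params = searchParams()) {
  stopifnot(is(params, "SearchParams"), charge >= 1)
  pk <- spectrum$peaks
  neutral <- (spectrum$precursor_mz - .PROTON_MASS) * charge
  keep <- abs(pk[, 1] - spectrum$precursor_mz) > params@precursorRemoval
  pk <- pk[keep, , drop = FALSE]
  bw <- params@binWidth
  nb <- as.integer(max(round((neutral + 50) / bw),
                       if (nrow(pk)) round(max(pk[, 1]) / bw) + 1L else 0L,
                       10L * params@nRegions))
  v <- numeric(nb)
  if (nrow(pk)) {
    b <- as.integer(round(pk[, 1] / bw)) + 1L     # bin 0 -> index 1
    b[b < 1L] <- 1L
    b[b > nb] <- nb
    s <- sqrt(pk[, 2])
    ## per-bin maximum
    o <- order(b, -s)
    bb <- b[o]; ss <- s[o]
    first <- !duplicated(bb)
    v[bb[first]] <- ss[first]
  }
  ## regional normalization: nRegions equal spans scaled to regionMax
  reg <- as.integer(ceiling(seq_len(nb) / (nb / params@nRegions)))
  reg[reg > params@nRegions] <- params@nRegions
  mx <- unname(vapply(split(v, reg), max, numeric(1)))
  scale <- ifelse(mx > 0, params@regionMax / mx, 0)
  v <- v * scale[reg]
  ## fast background subtraction over +/- bgWindow offsets (excluding 0)
  w <- params@bgWindow
  cs <- c(0, cumsum(v))
  hi <- pmin(seq_len(nb) + w, nb)
  lo <- pmax(seq_len(nb) - w, 1L)
  bg <- (cs[hi + 1L] - cs[lo]) - v
  vp <- v - bg / (2 * w)
  ## bins_pre (the normalized vector before background subtraction) is
  ## kept so the closed-form subtraction can be checked against the full
  ## lagged correlation definition
  list(bins = vp, bins_pre = v, neutral_mass = neutral, bin_width = bw)
}

#' Theoretical b/y fragment spectrum of a peptide
#'
#' Generates singly charged b ions (prefix mass + proton) and y ions
#' (suffix mass + water + proton), adding doubly charged fragments when
#' the precursor charge is at least 3. Each fragment contributes weight 1
#' at its bin (`round(mz / binWidth)`) and `flankWeight` at the two
#' flanking bins; overlapping contributions keep the maximum weight.
#'
#' @param peptide Peptide sequence (length >= 2).
#' @param precursorCharge Precursor charge state.
#' @param staticMods Named static modification deltas (Da).
#' @param params A [SearchParams].
#' @param nbins Optional vector length; bins beyond it are dropped.
#' @return A list with integer `bin` (0-based) and numeric `weight`.
#' @export
theoreticalIons <- function(peptide, precursorCharge = 2,
                            staticMods = c(C = 57.02146),
                            params = searchParams(), nbins = NULL) {
  n <- nchar(peptide)
  if (n < 2) stop("peptide must have at least 2 residues")
  lut <- .massLookup(staticMods, "skip")
  rm <- lut[utf8ToInt(peptide) + 1L]
  if (anyNA(rm)) stop("peptide contains residues without defined mass: ",
                      peptide)
  pre <- cumsum(rm[-n])                       # b fragments: prefix masses
  suf <- rev(cumsum(rev(rm[-1L])))            # y fragments: suffix masses
  fragCharges <- if (precursorCharge >= 3) 1:2 else 1L
  mz <- unlist(lapply(fragCharges, function(fc) {
    c((pre + fc * .PROTON_MASS) / fc,
      (suf + .WATER_MONO + fc * .PROTON_MASS) / fc)
  }), use.names = FALSE)
  bin <- as.integer(round(mz / params@binWidth))
  w <- params@flankWeight
  allbin <- c(bin, bin - 1L, bin + 1L)
  allw <- c(rep(1, length(bin)), rep(w, 2L * length(bin)))
  keep <- allbin >= 0L
  if (!is.null(nbins)) keep <- keep & allbin < nbins
  allbin <- allbin[keep]; allw <- allw[keep]
  o <- order(allbin, -allw)
  first <- !duplicated(allbin[o])
  list(bin = allbin[o][first], weight = allw[o][first])
}

#' SEQUEST-style cross-correlation score
#'
#' Dot product of the theoretical fragment weights with the conditioned
#' spectrum vector, scaled by `xcorrScale`. Because the background mean
#' over +/- `bgWindow` offsets is already folded into the vector by
#' [preprocessSpectrum()], this equals the full cross-correlation at lag
#' zero minus the mean correlation at non-zero lags. Reported scores are
#' floored at zero; set `floor = FALSE` to obtain the raw (possibly
#' negative) value used for candidate population statistics.
#'
#' @param processed Output of [preprocessSpectrum()].
#' @param theoretical Output of [theoreticalIons()].
#' @param params A [SearchParams].
#' @param floor Floor negative scores at 0.
#' @return Numeric score.
#' @export
xcorrScore <- function(processed, theoretical, params = searchParams(),
                       floor = TRUE) {
  b <- theoretical$bin
  keep <- b >= 0L & b < length(processed$bins)
  raw <- sum(theoretical$weight[keep] * processed$bins[b[keep] + 1L]) *
    params@xcorrScale
  if (floor) max(raw, 0) else raw
}

#' Score one scan against the index
#'
#' Streams mass-window candidates for each candidate precursor charge and
#' scores them one at a time, keeping only a bounded top-hit buffer and
#' running population statistics, so peak memory is independent of the
#' candidate count. When the charge is unknown both interpretations are
#' scored and the one with the higher top XCorr is kept. Candidates are
#' ranked by descending XCorr with lexicographic peptide tie-break; the
#' scan-level DeltaCN `(XCorr1 - XCorr2) / XCorr1` (0 when XCorr1 is 0, 1
#' when there is no second candidate) and the candidate-population
#' Z-score of the top hit (0 when fewer than 3 candidates or zero spread)
#' are attached to every reported hit.
#'
#' @param spectrum One scan (list as held by a [SpectrumSet]).
#' @param index A built [PeptideIndex].
#' @param params A [SearchParams].
#' @return A `data.table` of ranked PSMs (possibly empty if the window
#'   holds no candidate).
#' @export
scoreScan <- function(spectrum, index, params = searchParams()) {
  stopifnot(is(index, "PeptideIndex"))
  charges <- if (spectrum$charge_known) spectrum$charges else params@charges
  best <- NULL
  for (z in charges) {
    res <- .scoreScanAtCharge(spectrum, as.integer(z), index, params)
    if (is.null(res)) next
    if (is.null(best) || res$top_raw > best$top_raw) best <- res
  }
  if (is.null(best))
    return(.emptyPsms())
  hits <- best$hits
  n <- nrow(hits)
  x1 <- max(hits$xcorr[1], 0)
  x2 <- if (n >= 2) max(hits$xcorr[2], 0) else 0
  delta_cn <- if (x1 <= 0) 0 else (x1 - x2) / x1
  z_score <- if (best$n >= 3) {
    mu <- best$sum / best$n
    sdev <- sqrt(max(best$sumsq / best$n - mu^2, 0))
    if (sdev > 0) (best$top_raw - mu) / sdev else 0
  } else 0
  data.table(
    scan_id = spectrum$scan_id, charge = best$charge,
    peptide = hits$peptide, calc_mass = hits$mass,
    obs_mass = best$neutral, xcorr = pmax(hits$xcorr, 0),
    xcorr_raw = hits$xcorr,
    delta_cn = delta_cn, z_score = z_score,
    ppm_error = (best$neutral - hits$mass) / hits$mass * 1e6,
    rank = seq_len(n),
    is_decoy_only = .decoyOnly(index, hits$peptide),
    candidate_count = best$n)
}

.emptyPsms <- function() {
  data.table(scan_id = integer(), charge = integer(), peptide = character(),
             calc_mass = numeric(), obs_mass = numeric(), xcorr = numeric(),
             xcorr_raw = numeric(), delta_cn = numeric(), z_score = numeric(),
             ppm_error = numeric(), rank = integer(), is_decoy_only = logical(),
             candidate_count = integer())
}

## Score all candidates in the precursor window at one assumed charge.
## Iterates the mass-ordered slice row by row, maintaining a top-K buffer
## (K = reportHits) and running sum / sum of squares for the Z-score, so
## memory does not grow with the candidate count.
.scoreScanAtCharge <- function(spectrum, charge, index, params) {
  neutral <- (spectrum$precursor_mz - .PROTON_MASS) * charge
  rng <- .windowRange(index, neutral, params@tolerancePpm)
  if (rng$lo > rng$hi) return(NULL)
  proc <- preprocessSpectrum(spectrum, charge, params)
  nb <- length(proc$bins)
  K <- params@reportHits
  buf_pep <- character(0); buf_x <- numeric(0); buf_m <- numeric(0)
  n <- 0L; s1 <- 0; s2 <- 0
  peak_buf <- 0L
  mods <- index@params@staticMods
  massv <- index@massdb$mass
  pepv <- index@massdb$peptide
  for (i in rng$lo:rng$hi) {
    pep <- pepv[i]
    if (nchar(pep) < 2L) next
    theo <- theoreticalIons(pep, charge, mods, params, nbins = nb)
    x <- xcorrScore(proc, theo, params, floor = FALSE)
    n <- n + 1L; s1 <- s1 + x; s2 <- s2 + x * x
    ## insert into bounded buffer ordered by (-xcorr, peptide)
    pos <- .bufferPosition(buf_x, buf_pep, x, pep)
    if (pos <= K) {
      at <- pos - 1L
      buf_pep <- append(buf_pep, pep, after = at)
      buf_x <- append(buf_x, x, after = at)
      buf_m <- append(buf_m, massv[i], after = at)
      if (length(buf_x) > K) {
        buf_pep <- buf_pep[seq_len(K)]
        buf_x <- buf_x[seq_len(K)]
        buf_m <- buf_m[seq_len(K)]
      }
    }
    peak_buf <- max(peak_buf, length(buf_x))
  }
  if (n == 0L) return(NULL)
  cnt <- index@counters
  cnt$peak_buffer <- max(cnt$peak_buffer, peak_buf)
  list(charge = charge, neutral = neutral, n = n, sum = s1, sumsq = s2,
       top_raw = buf_x[1],
       hits = data.table(peptide = buf_pep, xcorr = buf_x, mass = buf_m))
}

## rank position at which (x, pep) inserts into the buffer ordered by
## descending xcorr then ascending peptide
.bufferPosition <- function(buf_x, buf_pep, x, pep) {
  better <- buf_x > x | (buf_x == x & buf_pep < pep)
  sum(better) + 1L
}

#' Search a set of spectra against a peptide index
#'
#' Applies [scoreScan()] to every scan. Scans are independent work
#' units: any execution order yields identical output.
#'
#' @param spectra A [SpectrumSet].
#' @param index A built [PeptideIndex].
#' @param params A [SearchParams].
#' @param verbose Print progress every 100 scans.
#' @return A [SearchResult].
#' @export
searchSpectra <- function(spectra, index, params = searchParams(),
                          verbose = FALSE) {
  stopifnot(is(spectra, "SpectrumSet"))
  out <- vector("list", length(spectra@scans))
  for (i in seq_along(spectra@scans)) {
    out[[i]] <- scoreScan(spectra@scans[[i]], index, params)
    if (verbose && i %% 100 == 0)
      message(sprintf("scored %d / %d scans", i, length(spectra@scans)))
  }
  psms <- rbindlist(out)
  ncand <- vapply(out, function(p) if (nrow(p)) p$candidate_count[1] else 0L,
                  integer(1))
  summary <- list(
    scans_scored = length(spectra@scans),
    scans_with_candidates = sum(ncand > 0L),
    candidate_count_histogram = table(ncand))
  new("SearchResult", psms = psms, summary = summary, params = params)
}

#' @rdname SearchResult-accessors
#' @name SearchResult-accessors
#' @title Accessors for SearchResult
#' @param result A [SearchResult].
#' @return `psms()` the ranked PSM table; `searchSummary()` the run
#'   summary list.
NULL

#' @rdname SearchResult-accessors
#' @export
psms <- function(result) copy(result@psms)

#' @rdname SearchResult-accessors
#' @export
searchSummary <- function(result) result@summary

setMethod("show", "SearchResult", function(object) {
  cat(sprintf("SearchResult: %d PSMs over %d scan(s) (%d with candidates)\n",
              nrow(object@psms), object@summary$scans_scored,
              object@summary$scans_with_candidates))
})
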