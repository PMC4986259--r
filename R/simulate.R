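#' Generate a synthetic proteome
#'
#' Draws `nProteins` random protein sequences from the configured residue
#' frequency distribution, with lengths from a truncated normal
#' (minimum 20 residues). Deterministic for a fixed seed: two calls with
#' the same parameters produce byte-identical FASTA files.
#'
#' @param params A [SimulationParams].
#' @param path Optional FASTA output path.
#' @return A list with `records` (protein-record `data.table`),
#'   `manifest` (`data.table` of ids and lengths) and `fasta` (the path,
#'   or `NA` when not written).
#' @export
#' @examples
#' generateProteome(simulationParams(seed = 7, nProteins = 3))$manifest
generateProteome <- function(params, path = NULL) {
  stopifnot(is(params, "SimulationParams"))
  if (params@lengthMean <= 0) stop("degenerate length distribution: mean <= 0")
  set.seed(params@seed)
  n <- params@nProteins
  if (n == 0L) {
    records <- data.table(protein_id = integer(), defline = character(),
                          sequence = character(), is_decoy = logical())
  } else {
    lens <- pmax(20L, as.integer(round(rnorm(n, params@lengthMean,
                                             params@lengthSd))))
    aas <- names(params@residueFreqs)
    seqs <- vapply(lens, function(L) {
      paste(sample(aas, L, replace = TRUE, prob = params@residueFreqs),
            collapse = "")
    }, character(1))
    records <- data.table(protein_id = seq_len(n) - 1L,
                          defline = sprintf("syn|P%05d", seq_len(n) - 1L),
                          sequence = seqs, is_decoy = FALSE)
  }
  fasta <- NA_character_
  if (!is.null(path)) {
    writeFasta(records, path)
    fasta <- path
  }
  list(records = records,
       manifest = data.table(protein_id = records$protein_id,
                             defline = records$defline,
                             length = nchar(records$sequence)),
       fasta = fasta)
}

#' Simulate a MudPIT-style MS/MS run with ground truth
#'
#' Samples tryptic peptides (within the digestion length and mass
#' windows) uniformly over the distinct peptides of the proteome, then
#' emits one centroided spectrum per sampled peptide: all singly charged
#' b/y fragments (plus doubly charged fragments for 3+ precursors) at
#' constant intensity, thinned by `peakDropout`, with `noisePeaks`
#' uniform-m/z noise peaks added and the precursor mass jittered by
#' `N(0, massJitterPpm)`. Deterministic per seed.
#'
#' @param records Protein-record table (targets only is typical).
#' @param params A [SimulationParams]; `nSpectra`, noise, dropout, charge
#'   and jitter fields control the run.
#' @param digestion A [DigestionParams]; must match the index the run
#'   will be searched against.
#' @param path Optional MS2 output path.
#' @return A list with `spectra` (a [SpectrumSet]), `truth` (`data.table`
#'   with `scan_id`, `peptide`, `protein_id`, `charge`) and `ms2` (path
#'   or `NA`).
#' @export
simulateRun <- function(records, params, digestion = digestionParams(),
                        path = NULL) {
  stopifnot(is(params, "SimulationParams"), is(digestion, "DigestionParams"))
  records <- as.data.table(records)
  if (!nrow(records)) stop("empty proteome")
  dig <- .digestRecords(records, digestion)$peptides
  if (!nrow(dig)) stop("no digestible peptides under these parameters")
  ## one row per distinct peptide; remember one generating parent
  dd <- unique(dig, by = "peptide")
  set.seed(params@seed + 1L)
  n <- params@nSpectra
  pick <- sample.int(nrow(dd), n, replace = TRUE)
  charges <- as.integer(sample(names(params@chargeProbs), n, replace = TRUE,
                               prob = params@chargeProbs))
  sp <- searchParams()  # fragment m/z arithmetic only; bins unused here
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    pep <- dd$peptide[pick[i]]
    z <- charges[i]
    mass <- dd$mass[pick[i]]
    jitter <- 1 + rnorm(1, 0, params@massJitterPpm) * 1e-6
    premz <- (mass * jitter + z * .PROTON_MASS) / z
    mz <- .fragmentMz(pep, z, digestion@staticMods)
    keep <- runif(length(mz)) >= params@peakDropout
    mz <- mz[keep]
    int <- rep(params@fragmentIntensity, length(mz))
    if (params@noisePeaks > 0L) {
      nm <- runif(params@noisePeaks, params@noiseMzRange[1],
                  params@noiseMzRange[2])
      ni <- runif(params@noisePeaks, params@noiseIntensityRange[1],
                  params@noiseIntensityRange[2])
      mz <- c(mz, nm); int <- c(int, ni)
    }
    o <- order(mz)
    scans[[i]] <- list(scan_id = i, precursor_mz = premz, charges = z,
                       charge_known = TRUE,
                       peaks = matrix(c(mz[o], int[o]), ncol = 2,
                                      dimnames = list(NULL,
                                                      c("mz", "intensity"))))
  }
  spectra <- new("SpectrumSet", scans = scans, source = "simulateRun")
  ms2 <- NA_character_
  if (!is.null(path)) {
    writeMs2(spectra, path)
    ms2 <- path
  }
  list(spectra = spectra,
       truth = data.table(scan_id = seq_len(n), peptide = dd$peptide[pick],
                          protein_id = dd$protein_id[pick], charge = charges),
       ms2 = ms2)
}

## primary b/y fragment m/z values of a peptide at a precursor charge
.fragmentMz <- function(peptide, precursorCharge, staticMods) {
  lut <- .massLookup(staticMods, "skip")
  rm <- lut[utf8ToInt(peptide) + 1L]
  n <- length(rm)
  pre <- cumsum(rm[-n])
  suf <- rev(cumsum(rev(rm[-1L])))
  fragCharges <- if (precursorCharge >= 3) 1:2 else 1L
  unlist(lapply(fragCharges, function(fc) {
    c((pre + fc * .PROTON_MASS) / fc,
      (suf + .WATER_MONO + fc * .PROTON_MASS) / fc)
  }), use.names = FALSE)
}

#' Small-versus-large database agreement experiment
#'
#' Desk-scale analog of searching one run against both a focused database
#' and a much larger superset: builds decoy-augmented indexes for both
#' protein sets, searches the same simulated run against each, filters
#' both at the same protein FDR, and reports (i) the fraction of scans
#' surviving both filters that received the identical peptide, (ii) the
#' sensitivity ratio (filtered PSMs in the large search / small search),
#' and (iii) per-run DeltaCN medians, whose suppression in the large
#' search is the expected signature of a heavier candidate load.
#'
#' @param smallRecords Target protein records of the focused database.
#' @param bigRecords Superset records (must contain every small sequence).
#' @param spectra A [SpectrumSet] simulated from `smallRecords` proteins.
#' @param truth Optional ground-truth table from [simulateRun()]; adds
#'   rank-1 recovery rates to the report.
#' @param digestion A [DigestionParams].
#' @param search A [SearchParams].
#' @param filter A [FilterParams].
#' @param verbose Print progress.
#' @return A list: `agreement` (fraction), `n_cofiltered`,
#'   `sensitivity_ratio`, `filtered_psms_small`, `filtered_psms_big`,
#'   `delta_cn_median_small`, `delta_cn_median_big`, and when truth is
#'   given `rank1_small`, `rank1_big`.
#' @export
spikeExperiment <- function(smallRecords, bigRecords, spectra, truth = NULL,
                            digestion = digestionParams(),
                            search = searchParams(),
                            filter = filterParams(), verbose = FALSE) {
  smallRecords <- as.data.table(smallRecords)
  bigRecords <- as.data.table(bigRecords)
  if (!all(smallRecords$sequence %in% bigRecords$sequence))
    stop("small database is not a subset of the big database")
  runSide <- function(recs) {
    idx <- buildIndex(appendDecoys(recs), digestion, verbose = verbose)
    res <- searchSpectra(spectra, idx, search, verbose = verbose)
    filt <- filterResults(res@psms, idx, filter)
    list(idx = idx, res = res, filt = filt)
  }
  s <- runSide(smallRecords)
  b <- runSide(bigRecords)
  psm_s <- s$filt$psms
  psm_b <- b$filt$psms
  co <- intersect(psm_s$scan_id, psm_b$scan_id)
  agree <- if (length(co)) {
    ps <- psm_s$peptide[match(co, psm_s$scan_id)]
    pb <- psm_b$peptide[match(co, psm_b$scan_id)]
    mean(ps == pb)
  } else NA_real_
  med <- function(r) {
    d <- r@psms$delta_cn[r@psms$rank == 1L]
    if (length(d)) median(d) else NA_real_
  }
  out <- list(
    agreement = agree,
    n_cofiltered = length(co),
    filtered_psms_small = nrow(psm_s),
    filtered_psms_big = nrow(psm_b),
    sensitivity_ratio = if (nrow(psm_s)) nrow(psm_b) / nrow(psm_s)
                        else NA_real_,
    delta_cn_median_small = med(s$res),
    delta_cn_median_big = med(b$res))
  if (!is.null(truth)) {
    r1 <- function(r) {
      top <- r@psms[r@psms$rank == 1L]
      m <- match(top$scan_id, truth$scan_id)
      mean(top$peptide == truth$peptide[m])
    }
    out$rank1_small <- r1(s$res)
    out$rank1_big <- r1(b$res)
  }
  out
}
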