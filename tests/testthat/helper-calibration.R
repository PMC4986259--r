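## Closed-loop FDR calibration experiment with known ground truth.
##
## The searched database holds nDb target proteins (plus their decoys); the
## simulated run draws spectra from the first nSource database proteins plus
## nForeign proteins absent from the database, so genuinely false locus
## identifications occur at a measurable rate.  Keeping nSource well below
## nDb matters: false matches that land on a protein already carrying a true
## peptide are absorbed into a true locus, which would starve the
## ground-truth false-locus count relative to the decoy estimate.
calibrationReplicate <- function(seed, nDb = 300, nSource = 60, nForeign = 60,
                                 nSpectra = 200,
                                 filter = filterParams(),
                                 digestion = digestionParams(),
                                 search = searchParams()) {
  prot <- generateProteome(simulationParams(seed = seed,
                                            nProteins = nDb + nForeign))
  idx <- buildIndex(appendDecoys(prot$records[seq_len(nDb)]), digestion)
  src <- prot$records[c(seq_len(nSource), nDb + seq_len(nForeign))]
  run <- simulateRun(src,
                     simulationParams(seed = seed, nProteins = nDb + nForeign,
                                      nSpectra = nSpectra),
                     digestion)
  res <- searchSpectra(run$spectra, idx, search)
  gated <- applyPsmGates(psms(res), filter)
  loci <- assembleLoci(gated, idx)
  filt <- filterByProteinFdr(loci, filter)
  acc <- filt$accepted
  truthPep <- run$truth$peptide[match(gated$scan_id, run$truth$scan_id)]
  correctScan <- gated$peptide == truthPep
  nFalse <- 0L
  if (nrow(acc)) {
    for (i in seq_len(nrow(acc))) {
      sup <- gated$peptide %in% acc$peptides[[i]]
      if (!any(correctScan[sup])) nFalse <- nFalse + 1L
    }
  }
  list(accepted = nrow(acc), false_loci = nFalse,
       target_loci = filt$report$target_loci,
       decoy_loci = filt$report$decoy_loci,
       threshold = filt$report$xcorr_threshold,
       no_threshold = filt$report$no_threshold,
       loci = loci, filt = filt)
}
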