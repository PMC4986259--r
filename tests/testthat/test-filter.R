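## minimal synthetic PSM / locus tables for unit-level filter checks
psmRow <- function(scan, pep, ppm = 0, rank = 1L, xcorr = 3, dcn = 0.3) {
  data.table::data.table(scan_id = scan, charge = 2L, peptide = pep,
                         calc_mass = 1000, obs_mass = 1000 * (1 + ppm * 1e-6),
                         xcorr = xcorr, xcorr_raw = xcorr, delta_cn = dcn,
                         z_score = 2, ppm_error = ppm, rank = rank,
                         is_decoy_only = FALSE, candidate_count = 10L)
}

test_that("PSM gates apply the strict ppm bound and rank-1 rule", {
  tab <- rbind(psmRow(1, "AAAK", ppm = 10.0),
               psmRow(2, "CCCK", ppm = 9.99),
               psmRow(3, "DDDK", ppm = -9.99),
               psmRow(4, "EEEK", ppm = 0, rank = 2L))
  out <- applyPsmGates(tab, filterParams())
  expect_setequal(out$peptide, c("CCCK", "DDDK"))  # +10.0 ppm is excluded
  ## score gates are optional
  out2 <- applyPsmGates(tab, filterParams(minXcorr = 10))
  expect_identical(nrow(out2), 0L)
})

test_that("locus assembly fans shared peptides out to all parents", {
  ## two proteins sharing both peptides -> collapsed into one group
  recs <- recordsFromSequences(c("AAAKGGGR", "AAAKGGGR"))
  idx <- buildIndex(appendDecoys(recs),
                    digestionParams(missedCleavages = 0, minLength = 1,
                                    minMass = 0))
  tab <- rbind(psmRow(1, "AAAK"), psmRow(2, "GGGR"))
  loci <- assembleLoci(tab, idx, group = FALSE)
  tl <- loci[!loci$is_decoy]
  expect_identical(nrow(tl), 2L)
  expect_true(all(tl$n_peptides == 2L))
  grouped <- assembleLoci(tab, idx, group = TRUE)
  gt <- grouped[!grouped$is_decoy]
  expect_identical(nrow(gt), 1L)
  expect_identical(length(gt$protein_ids[[1]]), 2L)
  expect_error(assembleLoci(psmRow(1, "WWWW"), idx), "absent from index")
})

test_that("decoy-only peptides form decoy loci; shared peptides are tallied", {
  recs <- appendDecoys(recordsFromSequences("GGGKAAAKGGGR"))
  idx <- buildIndex(recs, digestionParams(missedCleavages = 1, minLength = 1,
                                          minMass = 0))
  ## KGGGR exists only on the decoy strand (RGGGK reversed)
  dec <- peptideTable(idx)$peptide
  tgt <- trypticDigest(recs$sequence[1],
                       digestionParams(missedCleavages = 1, minLength = 1,
                                       minMass = 0))$peptide
  decoyOnly <- setdiff(dec, tgt)[1]
  loci <- assembleLoci(psmRow(1, decoyOnly), idx)
  expect_true(all(loci$is_decoy))
  ## palindromic peptide hits both strands and is counted as shared
  lociShared <- assembleLoci(psmRow(1, "AAAK"), idx)
  expect_identical(attr(lociShared, "shared_peptides"), 1L)
  expect_false(all(lociShared$is_decoy))
})

lociTable <- function(nT, nD, xT = NULL, xD = NULL, npep = 2L) {
  xT <- if (is.null(xT)) rep(4, nT) else xT
  xD <- if (is.null(xD)) rep(3, nD) else xD
  data.table::data.table(
    locus_id = seq_len(nT + nD),
    protein_ids = as.list(seq_len(nT + nD)),
    deflines = as.list(sprintf("p%03d", seq_len(nT + nD))),
    is_decoy = rep(c(FALSE, TRUE), c(nT, nD)),
    peptides = replicate(nT + nD, c("AK", "RK"), simplify = FALSE),
    n_peptides = rep(npep, nT + nD),
    spectral_count = rep(3L, nT + nD),
    best_xcorr = c(xT, xD))
}

test_that("protein FDR filtering matches the worked decoy/target ratios", {
  ## 200 targets, 2 decoys, all above any threshold: FDR 1%, all accepted
  res <- filterByProteinFdr(lociTable(200, 2), filterParams())
  expect_identical(nrow(res$accepted), 200L)
  expect_equal(res$report$achieved_protein_fdr, 0.01)
  ## no decoys: FDR 0
  res0 <- filterByProteinFdr(lociTable(50, 0), filterParams())
  expect_identical(nrow(res0$accepted), 50L)
  expect_equal(res0$report$achieved_protein_fdr, 0)
  ## single-peptide loci are never accepted at the default 2-peptide rule
  one <- lociTable(10, 0, npep = 1L)
  expect_warning(res1 <- filterByProteinFdr(one, filterParams()),
                 "no target loci")
  expect_identical(nrow(res1$accepted), 0L)
})

test_that("the threshold search raises the bar until the bound holds", {
  ## decoys score higher than some targets: threshold must exclude them
  loci <- lociTable(100, 3, xT = seq(2, 4, length.out = 100),
                    xD = c(3.9, 3.95, 1.0))
  res <- filterByProteinFdr(loci, filterParams(maxProteinFdr = 0.02))
  expect_lte(res$report$decoy_loci / res$report$target_loci, 0.02)
  expect_false(any(res$accepted$is_decoy))
  ## brute-force threshold scan agrees exactly
  brute <- bruteFdrThreshold(loci, filterParams(maxProteinFdr = 0.02))
  expect_equal(res$report$xcorr_threshold, brute$threshold)
  expect_identical(nrow(res$accepted), brute$accepted)
})

test_that("threshold search equals brute force over random locus tables", {
  set.seed(3)
  for (rep in 1:30) {
    nT <- sample(5:80, 1); nD <- sample(0:10, 1)
    loci <- lociTable(nT, nD, xT = round(runif(nT, 1, 5), 2),
                      xD = round(runif(nD, 1, 5), 2))
    for (fdr in c(0.01, 0.05, 0.2)) {
      p <- filterParams(maxProteinFdr = fdr)
      res <- filterByProteinFdr(loci, p)
      brute <- bruteFdrThreshold(loci, p)
      if (is.na(brute$threshold)) {
        expect_true(res$report$no_threshold)
      } else {
        expect_equal(res$report$xcorr_threshold, brute$threshold)
        expect_identical(nrow(res$accepted), brute$accepted)
      }
    }
  }
})

test_that("tightening gates never enlarges the accepted set", {
  fx_loci <- lociTable(40, 2, xT = round(runif(40, 1, 5), 2),
                       xD = c(2.5, 4.5))
  n_base <- nrow(filterByProteinFdr(fx_loci, filterParams())$accepted)
  fx3 <- data.table::copy(fx_loci)
  fx3$n_peptides <- rep(c(1L, 3L), 21)
  n_pep3 <- nrow(filterByProteinFdr(fx3,
                                    filterParams(minPeptides = 3))$accepted)
  expect_lte(n_pep3, n_base)
  ## on PSM side: lowering the ppm bound can only shrink the gated set
  tab <- rbind(psmRow(1, "A", ppm = 3), psmRow(2, "B", ppm = 8))
  expect_lte(nrow(applyPsmGates(tab, filterParams(maxAbsPpm = 5))),
             nrow(applyPsmGates(tab, filterParams(maxAbsPpm = 10))))
})

test_that("filtered locus tables round-trip through the writer", {
  res <- filterByProteinFdr(lociTable(3, 0), filterParams())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFiltered(res, f)
  back <- readFilteredLoci(f)
  expect_identical(nrow(back), 3L)
  expect_identical(back$n_peptides, res$accepted$n_peptides)
  expect_identical(back$spectral_count, res$accepted$spectral_count)
  rep <- jsonlite::read_json(paste0(f, ".report.json"))
  expect_equal(rep$target_loci, 3)
  ## empty accepted set -> header-only table
  expect_warning(resE <- filterByProteinFdr(lociTable(3, 0, npep = 1L),
                                            filterParams()),
                 "no target loci")
  writeFiltered(resE, f)
  expect_identical(nrow(readFilteredLoci(f)), 0L)
})
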