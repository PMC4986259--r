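---
title: "Methods: mass-indexed peptide search with target-decoy protein FDR"
author: "trypsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-indexed peptide search with target-decoy protein FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trypsearch)
```

## The problem

Shotgun proteomics identifies proteins by fragmenting tryptic peptides in a
mass spectrometer and matching each MS/MS scan against a database of protein
sequences. For multi-organism samples (gut microbiome, environmental
communities) the database must be very large, which stresses three stages:
candidate retrieval (which peptides could have produced this precursor
mass?), scoring (which candidate explains the fragments best?), and error
control (how many reported proteins are wrong?). trypsearch implements the
full loop at desk scale: a three-collection peptide index, a SEQUEST-lineage
scoring engine, DTASelect-style protein-level FDR filtering, and a synthetic
data generator so every stage can be tested closed-loop with known ground
truth.

## The data model

`buildIndex()` digests a decoy-augmented FASTA in silico and populates three
collections inside a `PeptideIndex`:

* **protein records** — defline, sequence, decoy flag, a stable 0-based id;
* **distinct peptides** — one row per peptide sequence with its neutral
  monoisotopic mass and all parent occurrences (protein id, 0-based start
  offset, flanking residues);
* **mass-ordered peptides** — the same peptide set sorted by a fixed-point
  mass key, `round(mass * 1e4)` (0.1 mDa), the unit of precursor-window
  retrieval.

Decoys are whole-protein sequence reversals appended after all targets with
a `Reversed_` defline prefix, the concatenated-database convention for
target-decoy FDR. Peptides shared between target and decoy strands (e.g.
palindromic tryptic words) stay in the index, are counted in the build
report, and later fan out to both locus classes; the two-peptide rule at
filter time is what neutralizes them.

The 0.1 mDa key grid is a deliberate compromise: identical sequences always
collide onto one key, while a 10 ppm window at 6 kDa still spans hundreds of
keys, so discretization never loses candidates. A query is two binary
searches plus a contiguous slice of the mass-sorted collection; access
counters (`indexCounters()`) record probes and rows touched so the scaling
contract — cost proportional to window content, independent of database
size — is testable without wall-clock timing.

### Digestion parameters

Trypsin cleaves C-terminal to K/R unless the next residue is proline; only
fully tryptic peptides are indexed. Defaults follow common MudPIT practice:
up to 2 missed cleavages, length 6–60 residues, neutral mass 600–6000 Da,
cysteine carbamidomethylation (+57.02146 Da) as a static modification.
Non-canonical residues (B/J/O/U/X/Z) default to a skip-peptide policy
(affected peptides are dropped and counted); `reject` and `map` (U→C, O→K)
are selectable. Peptide masses are computed by per-protein prefix sums of
residue masses, which keeps floating-point error at the scale of a single
protein; stored masses agree with direct per-peptide summation to well
below 1e-6 Da (asserted in the tests against an independent
elemental-composition oracle).

## Scoring

`preprocessSpectrum()` applies the classical cross-correlation conditioning:
peaks within 1.5 Th of the precursor are removed, intensities are
square-root transformed and binned at 1.0005079 Th (per-bin maximum), the
vector is split into 10 equal regions each normalized to a maximum of 50,
and the ±75-bin background mean is subtracted in closed form, so the XCorr
of a candidate reduces to one sparse dot product:

\[
\mathrm{XCorr}(P) = 10^{-4} \sum_{b \in \mathrm{ions}(P)} w_b \,
  v'[b], \qquad
  v'[i] = v[i] - \tfrac{1}{150}\sum_{\tau=-75,\,\tau\neq 0}^{75} v[i+\tau].
\]

Theoretical ions are singly charged b and y fragments (doubly charged added
for 3+ precursors) with weight 1 at the fragment bin and 0.25 at the ±1
flanks. The tests verify the closed form against the full lagged-correlation
definition to 1e-6. These constants (bin width, region count and maximum,
background half-width, flank weight, 1e-4 scaling) live in one
`SearchParams` block so they can be swapped together. Note that with
unit-weight theoretical peaks the resulting scores are roughly two orders of
magnitude smaller than classical implementations that assign intensity 50 to
theoretical ions; rankings, DeltaCN and Z-scores are unaffected because they
are scale-invariant.

Per scan, `scoreScan()` streams the mass-window slice one candidate at a
time, keeping only a bounded top-K buffer plus running sums, so peak memory
is independent of the candidate count (asserted via the buffer counter).
Scans without a charge assignment are scored as both 2+ and 3+ and the
higher-XCorr interpretation is kept. Ties in ranking break lexicographically
on the peptide sequence, making output deterministic. Reported per scan:

* **XCorr**, floored at 0 for reporting (raw values are retained internally);
* **DeltaCN** = (XCorr1 − XCorr2)/XCorr1; defined as 0 when XCorr1 = 0 and
  as 1 when the window holds a single candidate;
* **Z-score** of the top raw XCorr against the whole candidate population
  (population SD; reported as 0 when fewer than 3 candidates or zero
  spread);
* signed ppm error, rank, candidate count, and a decoy-only flag.

Results serialize to an SQT-dialect text file (`writeSqt()`/`readSqt()`)
with H/S/M/L lines; output is byte-deterministic for fixed input.

## Filtering and protein-level FDR

`applyPsmGates()` keeps rank-1 PSMs with |ppm error| strictly below 10 ppm
(the search itself runs wide at 30 ppm; the strict gate belongs to the
filter stage). `assembleLoci()` fans every surviving peptide out to all its
parent proteins; loci with identical peptide sets are collapsed into one
group row, and a group is a decoy locus only if every member is a decoy.
`filterByProteinFdr()` first applies the two-peptide rule, then scans locus
best-XCorr thresholds from least strict upward and stops at the first
threshold where decoys/targets ≤ the FDR bound (default 1%); a brute-force
threshold scan in the tests confirms the search is optimal. The symmetric
estimator 2d/(t+d) is available by configuration. Decoy loci are never
reported as accepted.

## The synthetic-data generator

`generateProteome()` draws proteins with uniform residue usage and normal
lengths (default mean 300, SD 60, truncated at 20 residues).
`simulateRun()` samples peptides uniformly over the distinct tryptic
peptides of the proteome (within the index windows) and emits, per peptide,
a centroided spectrum containing every primary b/y fragment at constant
intensity 100, thinned by a 10% dropout, plus 10 noise peaks uniform over
200–2000 Th with intensity uniform in [10, 100], and a precursor mass
jittered by N(0, 5 ppm). Charges are 2+ (60%) and 3+ (40%). Every draw is a
deterministic function of the seed; fixed seeds give byte-identical FASTA
and MS2 files.

What the generator does *not* emulate: realistic fragmentation intensity
propensities, neutral losses, isotope envelopes, chimeric spectra, retention
time, and real residue usage. Flat fragment intensities are deliberately
harmless here because the square-root transform and regional normalization
make XCorr insensitive to intensity scale. Consequently, passing tests
demonstrate correctness of the algorithms and calibration of the error
control under these idealized spectra — not instrument-level performance.

## Closed-loop experiments

**Self-recovery.** On a noiseless run (500 spectra, 1000-protein database)
the generating peptide must be the rank-1 match in ≥99% of scans; the
tests assert this with a median candidate load above 10 competitors per
window.

**Small-versus-large database comparison.** `spikeExperiment()` searches one
run simulated from a 100-protein proteome against both that proteome and a
superset with 50,000 distractor proteins (the tests) or 10,000 (the
acceptance script, sized to its runtime budget), filters both at 1% protein
FDR, and reports the peptide agreement on co-filtered scans, the sensitivity
ratio, and per-run median DeltaCN. The expected signature of a larger search
space — agreement staying high (≥95% asserted), sensitivity not increasing,
and DeltaCN medians dropping — mirrors what full-scale comparisons of
focused versus comprehensive databases show qualitatively; the thresholds
here are deliberately looser than full-scale reported values because a
synthetic desk-scale run carries different statistics.

**FDR calibration.** Twenty seeded noisy runs are searched against a
database of 300 proteins of which only 60 produce spectra, together with 60
foreign proteins absent from the database, so false loci occur at a known,
measurable rate. Keeping the spectrum-producing subset small relative to the
database matters: a false match that lands on a protein already carrying a
true peptide is absorbed into a true locus, which starves the ground-truth
false count while leaving the decoy count intact. The decoy-estimated locus
FDR is compared with the true false-locus fraction pooled over replicates
with the score threshold disengaged and single-peptide loci admitted —
conditions under which both rates are statistically identifiable (roughly
20% here) — and must agree within a factor of 2. At the strict reporting
conditions (1% FDR, two-peptide rule) both rates collapse below the
one-locus resolution of an experiment this size (about 50 accepted loci per
run, so the estimator cannot express a nonzero value under ~2%); there the
tests assert the structural guarantees instead: the threshold search matches
an exhaustive scan exactly and no decoy-only locus is ever accepted.

## Numerical and degenerate-input choices

* Mass keys are 32-bit safe (6 kDa → 6e7).
* Window bounds are inclusive (|m − M| ≤ M·ppm·1e-6), evaluated on exact
  stored masses after the key-range scan, so grid rounding never changes
  membership.
* Background subtraction always divides by 150 (2×75), treating
  out-of-range offsets as zero, which keeps the closed form identical to
  the zero-padded naive correlation.
* Empty scans are skipped with a warning at parse time; scans whose window
  holds no candidate yield no PSMs; an all-tie top pair has DeltaCN 0.
* `filterByProteinFdr()` with zero surviving target loci warns and returns
  an empty set; when no threshold satisfies the bound the report carries a
  `no_threshold` flag rather than silently relaxing it.
* Rebuilding an index over the same records is idempotent (occurrences are
  deduplicated on protein, offset and sequence).

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely from synthetic data
generated at call time: 500-protein digestion-oracle sweeps, 1000-query
window-oracle sweeps on 1000-protein builds, 500-spectrum self-recovery and
spike runs, 20-replicate calibration experiments, and 1×/10×/100× database
inflations for the scaling contract. These sizes were chosen so the whole
loop exercises thousands of scans and millions of indexed peptides while
remaining runnable on a laptop in minutes.

## Known limitations

* Static modifications only; no variable modifications, isotope-error
  windows, neutral-loss or a/c/x/z ions, and no semi-tryptic peptides.
* One enzyme (trypsin).
* The embedded in-memory backend targets desk scale (millions of peptides);
  the index is rebuilt from FASTA rather than persisted in a binary store.
* Protein grouping is minimal (identical peptide sets only); no parsimony
  inference across partially overlapping sets.
* Decoy-based FDR shares the usual caveat quantified in the calibration
  experiment: at very small locus counts its resolution is one decoy locus.
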