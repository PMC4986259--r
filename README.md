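# trypsearch

Desk-scale shotgun-proteomics (and metaproteomics) database searching in R.

Identifying proteins from tandem mass spectra requires three coupled pieces:
a peptide database that can answer "which peptides have neutral mass within
a few ppm of this precursor?", a scorer that decides which candidate best
explains the observed fragments, and an error-control stage that limits how
many reported proteins are wrong. trypsearch implements all three, plus a
synthetic-data generator, so the complete loop — FASTA in, filtered protein
loci out — runs and is testable on a laptop with no instrument data. It is
aimed at people studying or prototyping search-engine behaviour (candidate
retrieval cost, score distributions, FDR calibration, the effect of database
size) rather than at production analysis of instrument runs.

## The model

**Index.** Proteins (targets plus whole-sequence reversed decoys, defline
prefix `Reversed_`) are digested in silico with trypsin specificity (cleave
C-terminal to K/R, suppressed before P; fully tryptic; ≤2 missed cleavages,
length 6–60, mass 600–6000 Da, Cys +57.02146 Da by default). Three
collections result: protein records; distinct peptides with parent
occurrences; and peptides ordered by the fixed-point mass key
`round(mass × 10⁴)`. A precursor query is an ordered key-range scan, so
retrieval cost tracks the window content, not the database size.

**Scoring.** For a scan at assumed charge z with precursor m/z *p*, the
neutral mass (p − m_H⁺)·z selects candidates within ±tolerance (30 ppm
default). The observed spectrum is square-root transformed, binned at
1.0005079 Th, normalized in 10 regions to max 50, and background-corrected
so the SEQUEST-style cross-correlation reduces to a sparse dot product:

    XCorr(P) = 1e-4 · Σ_b w_b · v′[b],   v′[i] = v[i] − mean v[i±1..75]

with b/y fragment ions at weight 1 and ±1-bin flanks at 0.25. Per scan the
engine reports ranked XCorr, DeltaCN = (XCorr₁ − XCorr₂)/XCorr₁, the
candidate-population Z-score of the top hit, and the signed ppm error.

**Filtering.** Rank-1 PSMs with |ppm| < 10 fan out to all parent proteins;
loci need ≥2 distinct peptides, and a locus-level XCorr threshold is raised
until decoy/target ≤ 1% (protein FDR). Decoy loci are never reported.

## Worked example

Using the small synthetic dataset shipped under `inst/extdata` (8 proteins,
12 simulated scans):

```r
library(trypsearch)
fa  <- system.file("extdata", "example_proteome.fasta", package = "trypsearch")
ms2 <- system.file("extdata", "example_run.ms2", package = "trypsearch")

idx <- buildIndex(appendDecoys(readFasta(fa)))
idx
#> PeptideIndex
#>   proteins:  16 (8 targets, 8 decoys)
#>   peptides:  440 distinct over 357 mass keys (440 occurrences)
#>   shared target/decoy peptides: 0
#>   digestion: trypsin, <=2 missed cleavages, length 6-60, mass 600-6000 Da

res <- searchSpectra(readSpectra(ms2), idx)
head(psms(res)[rank == 1,
               .(scan_id, peptide, xcorr, delta_cn, ppm_error)], 3)
#>    scan_id                       peptide      xcorr  delta_cn ppm_error
#> 1:       1         YIQDMCTYSWHNIQPSQCRGR 0.18082437 1.0000000  0.863299
#> 2:       2       MGELYIFYKVHFHSDYKMTIHNK 0.17649638 0.9814806 10.479374
#> 3:       3 ANDFNEHNMSDCGPQADCANPWAWAYKPK 0.24567904 1.0000000  4.160910

filt <- filterResults(psms(res), idx)
filt$report[c("target_loci", "decoy_loci", "achieved_protein_fdr")]
#> $target_loci
#> [1] 3
#> $decoy_loci
#> [1] 0
#> $achieved_protein_fdr
#> [1] 0
```

Reading the output: scan 2's best match carries a +10.5 ppm precursor error
(this run simulates 5 ppm mass jitter), so the strict <10 ppm gate drops it
at filter time; the remaining matches assemble into 3 accepted protein loci
with two or more distinct peptides each and no decoy locus above the
threshold, hence an estimated protein FDR of 0.

A command-line front end wraps the same functions:

```sh
exec/trypsearch simulate --seed 7 --proteins 100 --spectra 200 --out sim/
exec/trypsearch build    --fasta sim/proteome.fasta --out index/
exec/trypsearch search   --fasta index/database.fasta --spectra sim/run.ms2 --out run.sqt
exec/trypsearch filter   --sqt run.sqt --fasta index/database.fasta --out loci.tsv
```

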