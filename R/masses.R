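## Monoisotopic residue masses (Da), canonical 20 amino acids.  Values are
## residue (dehydrated) masses; a neutral peptide is the residue sum plus one
## water.  Precision is kept at 1e-9 Da so that peptide-level sums agree with
## an elemental-composition computation to well below 1e-6 Da.
.AA_MONO <- c(
  G =  57.021463721, A =  71.037113785, S =  87.032028404, P =  97.052763849,
  V =  99.068413913, T = 101.047678468, C = 103.009184785, L = 113.084063977,
  I = 113.084063977, N = 114.042927441, D = 115.026943024, Q = 128.058577505,
  K = 128.094963014, E = 129.042593088, M = 131.040484913, H = 137.058911858,
  F = 147.068413913, R = 156.101111024, Y = 163.063328533, W = 186.079312950
)

.WATER_MONO  <- 18.0105646837
.PROTON_MASS <- 1.0072764668

.AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Physical constants used throughout the package
#'
#' @return A named numeric vector with the monoisotopic mass of water
#'   (`water`) and of a proton (`proton`), in Da.
#' @export
#' @examples
#' massConstants()
massConstants <- function() {
  c(water = .WATER_MONO, proton = .PROTON_MASS)
}

#' Monoisotopic residue masses
#'
#' Residue (dehydrated) monoisotopic masses of the 20 canonical amino
#' acids, optionally shifted by static modifications.
#'
#' @param staticMods Named numeric vector of static modification mass
#'   deltas in Da, e.g. `c(C = 57.02146)` for cysteine
#'   carbamidomethylation.
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' residueMasses()[["G"]]
#' residueMasses(c(C = 57.02146))[["C"]]
residueMasses <- function(staticMods = NULL) {
  m <- .AA_MONO
  if (length(staticMods)) {
    stopifnot(is.numeric(staticMods), !is.null(names(staticMods)))
    bad <- setdiff(names(staticMods), names(m))
    if (length(bad))
      stop("static modification on unknown residue(s): ",
           paste(bad, collapse = ", "))
    m[names(staticMods)] <- m[names(staticMods)] + staticMods
  }
  m
}

## 256-slot byte lookup of residue masses; NA for anything undefined.
## ambiguity = "map" folds U -> C (selenocysteine as cysteine) and
## O -> K (pyrrolysine as lysine) before lookup.
.massLookup <- function(staticMods = NULL, ambiguity = c("skip", "reject", "map")) {
  ambiguity <- match.arg(ambiguity)
  m <- residueMasses(staticMods)
  lut <- rep(NA_real_, 256)
  lut[utf8ToInt(paste(names(m), collapse = "")) + 1L] <- m
  if (ambiguity == "map") {
    lut[utf8ToInt("U") + 1L] <- lut[utf8ToInt("C") + 1L]
    lut[utf8ToInt("O") + 1L] <- lut[utf8ToInt("K") + 1L]
  }
  lut
}

#' Neutral monoisotopic peptide mass
#'
#' Computes the neutral (uncharged) monoisotopic mass of one or more
#' peptide sequences: the sum of residue masses plus one water, with any
#' static modifications applied per residue.
#'
#' @param peptides Character vector of uppercase peptide sequences.
#' @param staticMods Named numeric vector of static modification deltas
#'   (Da), default none.
#' @param ambiguity Policy for non-canonical residues (B/J/O/U/X/Z):
#'   `"reject"` (default here) raises an error naming the residue and its
#'   position; `"map"` folds U to C and O to K (other ambiguity codes
#'   still yield `NA`); `"skip"` returns `NA` for any peptide containing
#'   an undefined residue.
#' @return Numeric vector of neutral masses in Da (`NA` where the skip
#'   policy applies).
#' @export
#' @examples
#' computeMonoisotopicMass("GG")
#' computeMonoisotopicMass("C", staticMods = c(C = 57.02146))
computeMonoisotopicMass <- function(peptides, staticMods = NULL,
                                    ambiguity = c("reject", "map", "skip")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(peptides))
  lut <- .massLookup(staticMods, if (ambiguity == "map") "map" else "skip")
  out <- vapply(peptides, function(p) {
    if (is.na(p) || !nzchar(p)) stop("empty peptide sequence")
    v <- lut[utf8ToInt(p) + 1L]
    if (anyNA(v)) {
      if (ambiguity == "skip") return(NA_real_)
      i <- which(is.na(v))[1L]
      stop(sprintf("residue '%s' at position %d of '%s' has no defined mass",
                   substr(p, i, i), i, p))
    }
    sum(v) + .WATER_MONO
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Discretize a neutral mass to a fixed-point integer key
#'
#' Mass keys group peptides sharing (to 0.1 mDa) the same monoisotopic
#' mass: `round(mass * 1e4)`.  The grid is fine enough that a 10 ppm
#' precursor window at any tryptic mass spans many keys, so no candidates
#' are lost to discretization, while identical sequences always collide
#' onto one key.
#'
#' @param mass Numeric vector of neutral masses in Da, all non-negative.
#' @return Integer vector of mass keys.
#' @export
#' @examples
#' discretizeMass(132.05349)  # 1320535
discretizeMass <- function(mass) {
  stopifnot(is.numeric(mass))
  if (any(mass < 0, na.rm = TRUE)) stop("negative mass cannot be discretized")
  as.integer(round(mass * 1e4))
}
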