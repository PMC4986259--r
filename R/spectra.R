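#' Read tandem mass spectra from MS2 or MGF files
#'
#' Parses centroided MS/MS scans. MS2 `Z` lines and MGF `CHARGE` fields
#' are honored (several `Z` lines give several candidate charges); scans
#' carrying no charge assignment receive candidate charges 2+ and 3+ and
#' are flagged `charge_known = FALSE`. Scans with an empty peak list are
#' skipped with a warning.
#'
#' @param path Path to a spectrum file (plain or gzip).
#' @param format `"auto"` (from extension), `"ms2"` or `"mgf"`.
#' @return A [SpectrumSet].
#' @export
readSpectra <- function(path, format = c("auto", "ms2", "mgf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    ext <- tolower(tools::file_ext(base))
    format <- switch(ext, ms2 = "ms2", mgf = "mgf",
                     stop("cannot infer spectrum format from extension: ", ext))
  }
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path,
                     warn = FALSE)
  scans <- if (format == "ms2") .parseMs2(lines) else .parseMgf(lines)
  empty <- vapply(scans, function(s) nrow(s$peaks) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("skipping %d scan(s) with empty peak list", sum(empty)))
    scans <- scans[!empty]
  }
  new("SpectrumSet", scans = scans, source = path)
}

.finishScan <- function(scan) {
  pk <- matrix(scan$pk, ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("mz", "intensity")))
  if (any(!is.finite(pk)) || any(pk[, 2] < 0))
    stop("non-finite or negative peak data in scan ", scan$scan_id)
  pk <- pk[order(pk[, 1]), , drop = FALSE]
  charges <- unique(as.integer(scan$charges))
  charge_known <- length(charges) > 0L
  if (!charge_known) charges <- c(2L, 3L)
  list(scan_id = scan$scan_id, precursor_mz = scan$precursor_mz,
       charges = charges, charge_known = charge_known, peaks = pk)
}

.parseMs2 <- function(lines) {
  scans <- list()
  cur <- NULL
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(ln)) next
    c1 <- substr(ln, 1, 1)
    if (c1 == "H" || c1 == "I" || c1 == "D") next
    if (c1 == "S") {
      if (!is.null(cur)) scans[[length(scans) + 1L]] <- .finishScan(cur)
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) < 4)
        stop(sprintf("malformed S line at line %d: '%s'", k, ln))
      cur <- list(scan_id = as.integer(f[2]),
                  precursor_mz = as.numeric(f[4]),
                  charges = integer(), pk = numeric())
    } else if (c1 == "Z") {
      if (is.null(cur)) stop(sprintf("Z line before any S line at line %d", k))
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      cur$charges <- c(cur$charges, as.integer(f[2]))
    } else {
      if (is.null(cur))
        stop(sprintf("peak data before any S line at line %d", k))
      f <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]]))
      if (length(f) < 2 || anyNA(f[1:2]))
        stop(sprintf("malformed peak line at line %d (scan %s): '%s'",
                     k, cur$scan_id, ln))
      cur$pk <- c(cur$pk, f[1], f[2])
    }
  }
  if (!is.null(cur)) scans[[length(scans) + 1L]] <- .finishScan(cur)
  scans
}

.parseMgf <- function(lines) {
  scans <- list()
  cur <- NULL
  nblock <- 0L
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (!is.null(cur)) stop(sprintf("nested BEGIN IONS at line %d", k))
      nblock <- nblock + 1L
      cur <- list(scan_id = nblock, precursor_mz = NA_real_,
                  charges = integer(), pk = numeric())
    } else if (ln == "END IONS") {
      if (is.null(cur)) stop(sprintf("END IONS without BEGIN at line %d", k))
      if (is.na(cur$precursor_mz))
        stop(sprintf("scan ending at line %d has no PEPMASS", k))
      scans[[length(scans) + 1L]] <- .finishScan(cur)
      cur <- NULL
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) next  # file-level parameter
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") {
        cur$precursor_mz <- as.numeric(strsplit(trimws(val), "[ \t]+")[[1]][1])
      } else if (key == "CHARGE") {
        ch <- suppressWarnings(as.integer(gsub("[+ ]", "",
                                               strsplit(val, "and|,")[[1]])))
        cur$charges <- c(cur$charges, ch[!is.na(ch)])
      } else if (key == "SCANS") {
        sc <- suppressWarnings(as.integer(val))
        if (!is.na(sc)) cur$scan_id <- sc
      }
    } else {
      if (is.null(cur))
        stop(sprintf("peak data outside BEGIN/END IONS at line %d", k))
      f <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(f) < 2 || anyNA(f[1:2]))
        stop(sprintf("malformed peak line at line %d: '%s'", k, ln))
      cur$pk <- c(cur$pk, f[1], f[2])
    }
  }
  if (!is.null(cur)) stop("unterminated BEGIN IONS block at end of file")
  scans
}

#' Write a SpectrumSet (or simulated run) as an MS2 file
#'
#' @param spectra A [SpectrumSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMs2 <- function(spectra, path) {
  stopifnot(is(spectra, "SpectrumSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("H\tCreationDate\t1970-01-01",
               "H\tExtractor\ttrypsearch"), con)
  for (s in spectra@scans) {
    writeLines(sprintf("S\t%d\t%d\t%.5f", s$scan_id, s$scan_id,
                       s$precursor_mz), con)
    if (s$charge_known)
      for (z in s$charges)
        writeLines(sprintf("Z\t%d\t%.5f", z,
                           s$precursor_mz * z - (z - 1) * .PROTON_MASS), con)
    writeLines(sprintf("%.5f %.2f", s$peaks[, 1], s$peaks[, 2]), con)
  }
  invisible(path)
}

#' @describeIn SpectrumSet Number of scans.
#' @param x A `SpectrumSet`.
#' @export
nScans <- function(x) length(x@scans)

#' @describeIn SpectrumSet Extract one scan (a list).
#' @param i Scan position.
#' @export
getScan <- function(x, i) x@scans[[i]]

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet of %d scan(s) from %s\n", length(object@scans),
              object@source))
})
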