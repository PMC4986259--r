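#' Read a protein FASTA file into a protein-record table
#'
#' Parses a (possibly gzipped) multi-line FASTA into the protein-record
#' table used by [buildIndex()]. Records receive sequential 0-based
#' `protein_id` in file order; sequences are uppercased with whitespace
#' and line wrapping removed; a record is flagged as decoy when its
#' defline starts with `decoyPrefix`.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param decoyPrefix Defline prefix marking decoy records.
#' @return A `data.table` with columns `protein_id`, `defline`,
#'   `sequence`, `is_decoy`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKRPA"), f)
#' readFasta(f)
readFasta <- function(path, decoyPrefix = "Reversed_") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ## cheap structural pre-check so malformed input fails with a line number
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  firstLine <- 0L
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) break
    firstLine <- firstLine + 1L
    if (nzchar(trimws(ln))) {
      if (!startsWith(trimws(ln), ">")) {
        close(con)
        stop(sprintf(
          "malformed FASTA: sequence data before first header at line %d",
          firstLine))
      }
      break
    }
  }
  close(con)
  if (firstLine == 0L ||
      !length(ss <- Biostrings::readBStringSet(path, format = "fasta"))) {
    warning("empty FASTA file: ", path)
    return(data.table(protein_id = integer(), defline = character(),
                      sequence = character(), is_decoy = logical()))
  }
  deflines <- trimws(names(ss))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(ss)))
  if (any(!nzchar(seqs)))
    stop("FASTA record(s) with empty sequence: ",
         paste(head(deflines[!nzchar(seqs)], 3), collapse = ", "))
  data.table(protein_id = seq_along(deflines) - 1L, defline = deflines,
             sequence = unname(seqs), is_decoy = startsWith(deflines, decoyPrefix))
}

#' Append reversed decoys to a target protein collection
#'
#' For every target record, emits one decoy whose sequence is the full
#' character reversal of the target sequence and whose defline is
#' `prefix` + the original defline, after all targets. Output therefore
#' holds exactly twice the input records, giving the concatenated
#' target-decoy database used for FDR estimation.
#'
#' @param records Protein-record table from [readFasta()]; must contain
#'   no records already carrying `prefix`.
#' @param prefix Decoy defline prefix.
#' @return A protein-record `data.table` with targets then decoys and
#'   renumbered sequential `protein_id`.
#' @export
#' @examples
#' recs <- data.table::data.table(protein_id = 0L, defline = "p1",
#'   sequence = "ABCK", is_decoy = FALSE)
#' appendDecoys(recs)
appendDecoys <- function(records, prefix = "Reversed_") {
  records <- as.data.table(records)
  if (!nrow(records)) return(copy(records))
  if (any(records$is_decoy) || any(startsWith(records$defline, prefix)))
    stop("input already contains decoy records; refusing to double-decoy")
  decoys <- data.table(
    protein_id = nrow(records) + seq_len(nrow(records)) - 1L,
    defline    = paste0(prefix, records$defline),
    sequence   = stringi::stri_reverse(records$sequence),
    is_decoy   = TRUE)
  out <- rbind(records, decoys)
  out$protein_id <- seq_len(nrow(out)) - 1L
  out
}

#' Write a protein-record table as FASTA
#'
#' @param records Protein-record table.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 60L) {
  ss <- Biostrings::BStringSet(setNames(records$sequence, records$defline))
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}
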