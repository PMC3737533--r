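#' Read a FASTA file of transcript or genomic sequences
#'
#' Sequences are returned as a named character vector in the orientation in
#' which they are stored. `U`/`u` are normalized to `T`/`t` so that RNA and
#' DNA input behave identically downstream; case is preserved because
#' lowercase letters carry the conventional repeat-masking signal used by
#' [scan_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "UCAU"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) abort(sprintf("empty FASTA file: %s", path))
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    abort(sprintf("malformed FASTA header at line %d of %s",
                  nonempty[1], path))
  }
  bad <- grepl("^>\\s*$", trimws(lines))
  if (any(bad)) {
    abort(sprintf("malformed FASTA header (empty id) at line %d of %s",
                  which(bad)[1], path))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    abort(sprintf("duplicate sequence id in %s: %s", path,
                  names(seqs)[duplicated(names(seqs))][1]))
  }
  ok <- grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]*$", seqs)
  if (!all(ok)) {
    abort(sprintf("sequence '%s' contains non-IUPAC characters",
                  names(seqs)[!ok][1]))
  }
  chartr("Uu", "Tt", seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con,
               sep = "\n")
  }
  invisible(path)
}
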