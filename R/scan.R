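IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC-degenerate consensus into its exact word set
#'
#' Cartesian expansion of the per-position letter sets, minus any excluded
#' words. `U` is normalized to `T`. For example the Mbnl consensus `YGCY`
#' with `CGCC` excluded yields `TGCT`, `TGCC`, `CGCT`.
#'
#' @param consensus IUPAC pattern string (length >= 3).
#' @param exclude Character vector of exact words (same length) to remove.
#' @return Character vector of exact words.
#' @export
#' @examples
#' expand_consensus("YCAY")
#' expand_consensus("YGCY", exclude = "CGCC")
expand_consensus <- function(consensus, exclude = character()) {
  stopifnot(is.character(consensus), length(consensus) == 1)
  pat <- toupper(chartr("Uu", "Tt", consensus))
  if (nchar(pat) < 3) abort("consensus must be at least 3 nt long")
  letters <- strsplit(pat, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% names(IUPAC_MAP))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC letter '%s' at position %d of '%s'",
                  letters[bad[1]], bad[1], consensus))
  }
  words <- do.call(paste0, expand.grid(IUPAC_MAP[letters],
                                       stringsAsFactors = FALSE,
                                       KEEP.OUT.ATTRS = FALSE))
  exclude <- toupper(chartr("Uu", "Tt", exclude))
  if (length(exclude) > 0 && !all(exclude %in% words)) {
    abort(sprintf("excluded word '%s' does not match the consensus",
                  setdiff(exclude, words)[1]))
  }
  sort(setdiff(words, exclude))
}

# Regex matching one consensus position set, e.g. Y -> [CT].
consensus_regex <- function(consensus, exclude = character()) {
  words <- expand_consensus(consensus, exclude)
  if (length(exclude) == 0) {
    letters <- strsplit(toupper(chartr("Uu", "Tt", consensus)), "")[[1]]
    paste0(vapply(letters, function(l) {
      s <- IUPAC_MAP[[l]]
      if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
    }, ""), collapse = "")
  } else {
    paste0("(?:", paste(words, collapse = "|"), ")")
  }
}

#' Scan one sequence for all (possibly overlapping) consensus matches
#'
#' Every start position is tested; overlapping matches are all reported (the
#' HMM's spacing feature, not the scanner, handles tight packing). Matching
#' is case-insensitive; a site with at least one lowercase (repeat-masked)
#' base is flagged `is_repetitive`.
#'
#' @param seq Sequence string (U already normalized to T; see [read_fasta()]).
#' @param consensus IUPAC pattern.
#' @param exclude Excluded exact words.
#' @param seq_id Sequence id recorded on each site.
#' @return Tibble of motif sites: `seq_id`, `start`, `end` (0-based
#'   half-open), `strand`, `word` (uppercase matched word), `is_repetitive`,
#'   `ordinal` (1-based index along the sequence).
#' @export
scan_sequence <- function(seq, consensus, exclude = character(),
                          seq_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1)
  k <- nchar(consensus)
  rx <- paste0("(?=(", consensus_regex(consensus, exclude), "))")
  up <- toupper(seq)
  m <- gregexpr(rx, up, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), word = character(),
                  is_repetitive = logical(), ordinal = integer()))
  }
  starts0 <- as.integer(m) - 1L                       # 0-based
  raw <- substring(seq, starts0 + 1L, starts0 + k)
  tibble(
    seq_id = seq_id,
    start = starts0,
    end = starts0 + as.integer(k),
    strand = "+",
    word = toupper(raw),
    is_repetitive = raw != toupper(raw),
    ordinal = seq_along(starts0)
  )
}

#' Scan a set of sequences, optionally restricted to a mask
#'
#' A site is kept only if it lies fully inside the union of the mask
#' intervals for its sequence; ordinals are reassigned per sequence after
#' filtering. Mask records on unknown sequence ids are skipped with a
#' warning.
#'
#' @param seqs Named character vector of sequences.
#' @param consensus IUPAC pattern.
#' @param exclude Excluded exact words.
#' @param mask Optional tibble `(seq_id, start, end)`; `NULL` scans
#'   everything.
#' @return Tibble of motif sites across sequences (see [scan_sequence()]).
#' @export
scan_region_set <- function(seqs, consensus, exclude = character(),
                            mask = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  sites <- purrr::imap(seqs, function(s, id) {
    scan_sequence(s, consensus, exclude, seq_id = id)
  }) |> bind_rows()
  if (!is.null(mask)) {
    assert_intervals(mask, "mask")
    unknown <- setdiff(unique(mask$seq_id), names(seqs))
    if (length(unknown) > 0) {
      warn(sprintf("mask refers to unknown sequence id(s): %s; skipped",
                   paste(unknown, collapse = ", ")))
      mask <- mask[!mask$seq_id %in% unknown, , drop = FALSE]
    }
    keep <- iv_within_union(sites$seq_id, sites$start, sites$end, mask)
    sites <- sites[keep, , drop = FALSE]
  }
  sites |>
    distinct(.data$seq_id, .data$start, .keep_all = TRUE) |>
    arrange(.data$seq_id, .data$start) |>
    group_by(.data$seq_id) |>
    mutate(ordinal = row_number()) |>
    ungroup()
}
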