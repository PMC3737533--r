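#' Read a per-base accessibility track (bedGraph or fixed-step WIG)
#'
#' The track stores, per base, the probability that the base lies in
#' single-stranded (unpaired) RNA; values must be in `[0, 1]`. Positions not
#' covered by any record are missing and handled by the `missing_policy` of
#' [compute_accessibility()].
#'
#' @param path Path to a bedGraph file (4 columns: seq, start, end, value;
#'   0-based half-open) or a fixed-step WIG file.
#' @return Tibble `(seq_id, start, end, value)`, sorted, non-overlapping.
#' @export
read_accessibility <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|#)", lines)]
  if (length(lines) == 0) abort(sprintf("empty track file: %s", path))
  if (any(grepl("^fixedStep", lines))) {
    out <- parse_fixedstep_wig(lines, path)
  } else {
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 4)) {
      abort(sprintf("%s line %d: expected 4 bedGraph columns",
                    path, which(lengths(f) < 4)[1]))
    }
    out <- tibble(
      seq_id = vapply(f, `[[`, "", 1L),
      start = bed_int(vapply(f, `[[`, "", 2L), 2L, path),
      end = bed_int(vapply(f, `[[`, "", 3L), 3L, path),
      value = as.numeric(vapply(f, `[[`, "", 4L))
    )
  }
  bed_check_interval(out$start, out$end, path)
  if (anyNA(out$value) || any(out$value < 0 | out$value > 1)) {
    abort(sprintf("%s: accessibility values must be numbers in [0, 1]", path))
  }
  out <- arrange(out, .data$seq_id, .data$start)
  ov <- out |>
    group_by(.data$seq_id) |>
    summarise(bad = any(.data$start[-1] < .data$end[-dplyr::n()]),
              .groups = "drop")
  if (nrow(out) > 1 && any(ov$bad, na.rm = TRUE)) {
    abort(sprintf("%s: overlapping track records", path))
  }
  out
}

parse_fixedstep_wig <- function(lines, path) {
  hdr_idx <- grep("^fixedStep", lines)
  pieces <- list()
  for (k in seq_along(hdr_idx)) {
    h <- lines[hdr_idx[k]]
    get <- function(key, default = NA) {
      m <- regmatches(h, regexec(paste0(key, "=([^ \t]+)"), h))[[1]]
      if (length(m) < 2) default else m[2]
    }
    chrom <- get("chrom")
    wig_start <- as.integer(get("start"))   # WIG is 1-based
    step <- as.integer(get("step", "1"))
    span <- as.integer(get("span", "1"))
    if (is.na(chrom) || is.na(wig_start)) {
      abort(sprintf("%s: malformed fixedStep header '%s'", path, h))
    }
    to <- if (k < length(hdr_idx)) hdr_idx[k + 1] - 1L else length(lines)
    vals <- as.numeric(lines[seq.int(hdr_idx[k] + 1L, to)])
    starts <- (wig_start - 1L) + step * (seq_along(vals) - 1L)
    pieces[[k]] <- tibble(seq_id = chrom, start = starts,
                          end = starts + span, value = vals)
  }
  bind_rows(pieces)
}

#' Write an accessibility track as bedGraph
#'
#' @param track Tibble `(seq_id, start, end, value)`.
#' @param path Output path.
#' @param digits Decimal places for values.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(track, path, digits = 4L) {
  assert_intervals(track, "accessibility track")
  lines <- paste(track$seq_id, track$start, track$end,
                 formatC(track$value, format = "f", digits = digits),
                 sep = "\t")
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
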