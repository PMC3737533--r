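# BED family readers/writers. Coordinates are kept 0-based half-open
# throughout, exactly as stored on disk.

bed_read_raw <- function(path, min_cols) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, col_names = FALSE,
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, comment = "#")
  if (nrow(x) == 0) abort(sprintf("empty BED file: %s", path))
  if (ncol(x) < min_cols) {
    abort(sprintf("%s: expected at least %d tab-separated columns, found %d",
                  path, min_cols, ncol(x)))
  }
  x
}

bed_int <- function(x, col, path) {
  ok <- grepl("^-?[0-9]+$", x)
  if (!all(ok)) {
    abort(sprintf("%s line %d: non-integer value '%s' in column %d",
                  path, which(!ok)[1], x[!ok][1], col))
  }
  as.integer(x)
}

bed_check_interval <- function(start, end, path) {
  bad <- which(start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid interval [%d, %d)",
                  path, bad[1], start[bad[1]], end[bad[1]]))
  }
}

#' Read a BED file of intervals, CLIP tag clusters or motif-site clusters
#'
#' All variants are BED6-based with 0-based half-open coordinates, preserved
#' exactly. Records are returned sorted by `(seq_id, start)`.
#'
#' * `kind = "interval"`: plain BED6 (name/score/strand kept).
#' * `kind = "clip"`: BED6+2; column 7 is the peak position (0-based
#'   coordinate of the maximum unique-tag depth) and column 8 the peak height
#'   `ph` (number of unique CLIP tags at the peak).
#' * `kind = "cluster"`: BED6+2 as written by [write_bed()] for cluster
#'   calls; column 7 is the member site count and column 8 a comma-separated
#'   list of member site start coordinates. The score column is the cluster
#'   log-likelihood-ratio score.
#'
#' @param path Path to a BED file.
#' @param kind One of `"interval"`, `"clip"`, `"cluster"`.
#' @return A tibble; columns depend on `kind`.
#' @export
read_bed <- function(path, kind = c("interval", "clip", "cluster")) {
  kind <- match.arg(kind)
  x <- bed_read_raw(path, if (kind == "interval") 6L else 8L)
  out <- tibble(
    seq_id = x[[1]],
    start = bed_int(x[[2]], 2L, path),
    end = bed_int(x[[3]], 3L, path),
    name = x[[4]],
    score = suppressWarnings(as.numeric(x[[5]])),
    strand = x[[6]]
  )
  bed_check_interval(out$start, out$end, path)
  bad <- which(!out$strand %in% c("+", "-", "."))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: invalid strand '%s'",
                  path, bad[1], out$strand[bad[1]]))
  }
  if (kind == "clip") {
    out$peak <- bed_int(x[[7]], 7L, path)
    out$ph <- bed_int(x[[8]], 8L, path)
    bad <- which(out$peak < out$start | out$peak >= out$end)
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: peak %d outside cluster interval",
                    path, bad[1], out$peak[bad[1]]))
    }
    bad <- which(out$ph < 1L)
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: peak height must be >= 1", path, bad[1]))
    }
  } else if (kind == "cluster") {
    out$n_sites <- bed_int(x[[7]], 7L, path)
    out$members <- lapply(strsplit(x[[8]], ",", fixed = TRUE), as.integer)
    bad <- which(out$n_sites != lengths(out$members))
    if (length(bad) > 0) {
      abort(sprintf("%s line %d: n_sites disagrees with member list",
                    path, bad[1]))
    }
  }
  arrange(out, .data$seq_id, .data$start, .data$end)
}

#' Write intervals, CLIP clusters or cluster calls to BED
#'
#' Inverse of [read_bed()]. Output is tab-separated with Unix newlines;
#' cluster scores are printed with two decimals.
#'
#' @param x Tibble as returned by [read_bed()] (or with the same columns).
#' @param path Output path.
#' @param kind One of `"interval"`, `"clip"`, `"cluster"`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, kind = c("interval", "clip", "cluster")) {
  kind <- match.arg(kind)
  assert_intervals(x, "BED table")
  name <- if ("name" %in% names(x)) x$name else "."
  strand <- if ("strand" %in% names(x)) x$strand else "+"
  score <- if ("score" %in% names(x)) x$score else 0
  score_txt <- if (kind == "cluster") sprintf("%.2f", score) else
    format(score, trim = TRUE, scientific = FALSE)
  base <- paste(x$seq_id, x$start, x$end, name, score_txt, strand, sep = "\t")
  lines <- switch(kind,
    interval = base,
    clip = paste(base, x$peak, x$ph, sep = "\t"),
    cluster = paste(base, x$n_sites,
                    vapply(x$members, paste, "", collapse = ","), sep = "\t")
  )
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Each record is one transcript: `thickStart`/`thickEnd` delimit the CDS
#' (equal values mean non-coding), block fields give the exon structure.
#'
#' @param path Path to a BED12 file.
#' @return Tibble with one row per transcript: `tx_id`, `seq_id`, `start`,
#'   `end`, `strand`, `cds_start`, `cds_end` (NA for non-coding) and an
#'   `exons` list-column of `(start, end)` tibbles in genomic order.
#' @export
read_bed12 <- function(path) {
  x <- bed_read_raw(path, 12L)
  start <- bed_int(x[[2]], 2L, path)
  end <- bed_int(x[[3]], 3L, path)
  bed_check_interval(start, end, path)
  thick_start <- bed_int(x[[7]], 7L, path)
  thick_end <- bed_int(x[[8]], 8L, path)
  n_blocks <- bed_int(x[[10]], 10L, path)
  sizes <- strsplit(sub(",$", "", x[[11]]), ",", fixed = TRUE)
  offs <- strsplit(sub(",$", "", x[[12]]), ",", fixed = TRUE)
  exons <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    sz <- as.integer(sizes[[i]])
    of <- as.integer(offs[[i]])
    if (length(sz) != n_blocks[i] || length(of) != n_blocks[i] ||
        anyNA(sz) || anyNA(of)) {
      abort(sprintf("%s line %d: inconsistent block fields", path, i))
    }
    es <- start[i] + of
    ee <- es + sz
    if (is.unsorted(es, strictly = TRUE) || any(ee[-length(ee)] > es[-1])) {
      abort(sprintf("%s line %d: exon blocks overlap or are unsorted",
                    path, i))
    }
    if (ee[length(ee)] != end[i] || es[1] != start[i]) {
      abort(sprintf("%s line %d: blocks do not span the record", path, i))
    }
    exons[[i]] <- tibble(start = es, end = ee)
  }
  coding <- thick_end > thick_start
  tibble(
    tx_id = x[[4]],
    seq_id = x[[1]],
    start = start,
    end = end,
    strand = x[[6]],
    cds_start = ifelse(coding, thick_start, NA_integer_),
    cds_end = ifelse(coding, thick_end, NA_integer_),
    exons = exons
  ) |>
    arrange(.data$seq_id, .data$start)
}

#' Write gene models to BED12
#'
#' @param tx Tibble as returned by [read_bed12()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(tx, path) {
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    coding <- !is.na(tx$cds_start[i])
    paste(tx$seq_id[i], tx$start[i], tx$end[i], tx$tx_id[i], 0,
          tx$strand[i],
          if (coding) tx$cds_start[i] else tx$start[i],
          if (coding) tx$cds_end[i] else tx$start[i],
          "0", nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - tx$start[i], collapse = ","), ","),
          sep = "\t")
  }, "")
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
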