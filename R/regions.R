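#' Partition a gene body and its flanks into typed segments
#'
#' Produces the region typing used to stratify conservation. For each
#' transcript the interval `[start - ext, end + ext)` (clipped at 0) is tiled
#' without gaps or overlaps by segments typed `FLANK`, `FIVE_UTR`, `CDS`,
#' `THREE_UTR`, `NONCODING_EXON` or `INTRON`. UTR sides follow the strand;
#' non-coding transcripts get `NONCODING_EXON` exons, which (like `FLANK`)
#' map to the intron conservation stratum downstream.
#'
#' @param tx Transcript tibble as returned by [read_bed12()].
#' @param ext Flank width in nt (default 1000, i.e. "exon + ext1k").
#' @return Tibble `(tx_id, seq_id, start, end, strand, type)`, one row per
#'   segment, tiled in genomic order per transcript.
#' @export
build_region_segments <- function(tx, ext = 1000L) {
  stopifnot(ext >= 0)
  out <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    coding <- !is.na(tx$cds_start[i])
    if (coding &&
        (tx$cds_start[i] < tx$start[i] || tx$cds_end[i] > tx$end[i] ||
         tx$cds_start[i] >= tx$cds_end[i])) {
      abort(sprintf("transcript %s: CDS bounds outside transcript",
                    tx$tx_id[i]))
    }
    segs <- list()
    add <- function(s, e, type) {
      if (e > s) segs[[length(segs) + 1L]] <<- c(s, e, type)
    }
    left <- max(0L, tx$start[i] - as.integer(ext))
    add(left, tx$start[i], "FLANK")
    for (j in seq_len(nrow(ex))) {
      if (j > 1) add(ex$end[j - 1], ex$start[j], "INTRON")
      if (!coding) {
        add(ex$start[j], ex$end[j], "NONCODING_EXON")
      } else {
        cs <- tx$cds_start[i]; ce <- tx$cds_end[i]
        utr_left <- if (tx$strand[i] == "+") "FIVE_UTR" else "THREE_UTR"
        utr_right <- if (tx$strand[i] == "+") "THREE_UTR" else "FIVE_UTR"
        add(ex$start[j], min(ex$end[j], cs), utr_left)
        add(max(ex$start[j], cs), min(ex$end[j], ce), "CDS")
        add(max(ex$start[j], ce), ex$end[j], utr_right)
      }
    }
    add(tx$end[i], tx$end[i] + as.integer(ext), "FLANK")
    m <- do.call(rbind, segs)
    out[[i]] <- tibble(
      tx_id = tx$tx_id[i], seq_id = tx$seq_id[i],
      start = as.integer(m[, 1]), end = as.integer(m[, 2]),
      strand = tx$strand[i], type = m[, 3]
    )
  }
  bind_rows(out)
}

#' Exon + extN mask of a transcript set
#'
#' The union of exons, the first and last `ext` nt of each intron, and the
#' `ext`-nt flanks on each side of the gene: the region class used to build
#' training sets ("exon + ext1k" for `ext = 1000`). Short introns are wholly
#' inside the mask when `2 * ext` exceeds their length.
#'
#' @param tx Transcript tibble as returned by [read_bed12()].
#' @param ext Extension in nt into each intron / beyond the gene.
#' @param per_gene If `TRUE`, keep a `tx_id` column and do not merge across
#'   transcripts (needed by the "gene with no CLIP tags" negative rule).
#' @return Tibble `(seq_id, start, end)` (plus `tx_id` if `per_gene`), merged.
#' @export
exon_ext_mask <- function(tx, ext = 1000L, per_gene = FALSE) {
  ext <- as.integer(ext)
  pieces <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    ivs <- list(tibble(start = ex$start, end = ex$end))
    if (nrow(ex) > 1) {
      istart <- ex$end[-nrow(ex)]
      iend <- ex$start[-1]
      ivs <- c(ivs, list(
        tibble(start = istart, end = pmin(istart + ext, iend)),
        tibble(start = pmax(iend - ext, istart), end = iend)
      ))
    }
    ivs <- c(ivs, list(tibble(
      start = c(max(0L, tx$start[i] - ext), tx$end[i]),
      end = c(tx$start[i], tx$end[i] + ext)
    )))
    p <- bind_rows(ivs)
    p <- p[p$end > p$start, , drop = FALSE]
    p$seq_id <- tx$seq_id[i]
    p$tx_id <- tx$tx_id[i]
    pieces[[i]] <- p
  }
  x <- bind_rows(pieces)
  if (per_gene) {
    x |>
      group_by(.data$tx_id) |>
      dplyr::group_modify(function(d, g) iv_merge(d)) |>
      ungroup() |>
      select("tx_id", "seq_id", "start", "end")
  } else {
    iv_merge(x[c("seq_id", "start", "end")])
  }
}
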