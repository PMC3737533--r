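# Small interval helpers on 0-based half-open tibbles (seq_id, start, end).
# All package coordinates follow the BED convention: 0-based, half-open,
# end > start.

assert_intervals <- function(x, what = "interval table") {
  stopifnot(is.data.frame(x))
  need <- c("seq_id", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s must have columns seq_id, start, end", what))
  }
  if (nrow(x) > 0 && any(x$start >= x$end)) {
    abort(sprintf("%s contains records with start >= end", what))
  }
  invisible(x)
}

# Union of intervals: merge overlapping *and* adjacent records so that
# coverage questions ("is [a,b) fully inside the union?") reduce to a single
# containing record.
iv_merge <- function(x) {
  assert_intervals(x)
  if (nrow(x) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer()))
  }
  x |>
    arrange(.data$seq_id, .data$start, .data$end) |>
    group_by(.data$seq_id) |>
    mutate(
      run = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                            default = dplyr::first(.data$start)))
    ) |>
    group_by(.data$seq_id, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("seq_id", "start", "end") |>
    arrange(.data$seq_id, .data$start)
}

# TRUE for each query interval fully contained in the union of `mask`.
iv_within_union <- function(seq_id, start, end, mask) {
  m <- iv_merge(mask)
  out <- logical(length(seq_id))
  if (nrow(m) == 0 || length(seq_id) == 0) return(out)
  for (sid in unique(seq_id)) {
    idx <- which(seq_id == sid)
    ms <- m[m$seq_id == sid, , drop = FALSE]
    if (nrow(ms) == 0) next
    pos <- findInterval(start[idx], ms$start)
    ok <- pos >= 1L
    ok[ok] <- end[idx][ok] <= ms$end[pos[ok]]
    out[idx] <- ok
  }
  out
}

# TRUE for each query interval overlapping (>= 1 nt) any interval in `other`.
iv_overlaps_any <- function(seq_id, start, end, other) {
  out <- logical(length(seq_id))
  if (nrow(other) == 0 || length(seq_id) == 0) return(out)
  o <- iv_merge(other)
  for (sid in unique(seq_id)) {
    idx <- which(seq_id == sid)
    os <- o[o$seq_id == sid, , drop = FALSE]
    if (nrow(os) == 0) next
    # merged + sorted: the only candidate is the last interval starting
    # before the query end
    j <- findInterval(end[idx] - 1L, os$start)
    hit <- j >= 1L
    hit[hit] <- os$end[j[hit]] > start[idx][hit]
    out[idx] <- hit
  }
  out
}

# Total number of bases covered by the union.
iv_union_width <- function(x) {
  m <- iv_merge(x)
  sum(m$end - m$start)
}
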