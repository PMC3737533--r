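# Cassette-exon regional scores and target ranking. Six splice-site-anchored
# regions organize the clusters around an alternative exon: the upstream
# intron's 5' and 3' ends (UI5ss, UI3ss), the exon's two ends (E3ss, E5ss)
# and the downstream intron's 5' and 3' ends (DI5ss, DI3ss).

SPLICE_REGIONS <- c("UI5ss", "UI3ss", "E3ss", "E5ss", "DI5ss", "DI3ss")

#' Derive cassette-exon events from transcript models
#'
#' Every internal exon of a transcript with >= 3 exons becomes one candidate
#' event: upstream exon, cassette exon, downstream exon ("upstream" in
#' transcript orientation, i.e. swapped on the minus strand).
#'
#' @param tx Transcript tibble from [read_bed12()].
#' @return Event tibble: `event_id`, `seq_id`, `strand`, and genomic
#'   `(start, end)` of `ue` (upstream exon), `ce` (cassette), `de`
#'   (downstream exon).
#' @export
cassette_events <- function(tx) {
  out <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    if (nrow(ex) < 3) next
    for (j in 2:(nrow(ex) - 1)) {
      lo <- j - 1L; hi <- j + 1L
      if (tx$strand[i] == "-") { tmp <- lo; lo <- hi; hi <- tmp }
      out[[length(out) + 1L]] <- tibble(
        event_id = sprintf("%s_ce%d", tx$tx_id[i], j),
        seq_id = tx$seq_id[i], strand = tx$strand[i],
        ue_start = ex$start[lo], ue_end = ex$end[lo],
        ce_start = ex$start[j], ce_end = ex$end[j],
        de_start = ex$start[hi], de_end = ex$end[hi]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(event_id = character(), seq_id = character(),
                  strand = character(), ue_start = integer(),
                  ue_end = integer(), ce_start = integer(),
                  ce_end = integer(), de_start = integer(),
                  de_end = integer()))
  }
  bind_rows(out)
}

# Genomic anchor coordinate and eligible genomic region of each of the six
# splice-site regions for one event. Intronic anchors take intron-side
# clusters; exonic anchors take exon-internal clusters.
event_anchor_regions <- function(ev) {
  plus <- ev$strand != "-"
  ui <- if (plus) c(ev$ue_end, ev$ce_start) else c(ev$ce_end, ev$ue_start)
  di <- if (plus) c(ev$ce_end, ev$de_start) else c(ev$de_end, ev$ce_start)
  ce <- c(ev$ce_start, ev$ce_end)
  # anchor = the splice-site boundary coordinate of each region
  tibble(
    region = SPLICE_REGIONS,
    anchor = if (plus) c(ui[1], ui[2], ce[1], ce[2], di[1], di[2])
             else c(ui[2], ui[1], ce[2], ce[1], di[2], di[1]),
    reg_start = c(ui[1], ui[1], ce[1], ce[1], di[1], di[1]),
    reg_end = c(ui[2], ui[2], ce[2], ce[2], di[2], di[2])
  )
}

#' Distance-weighted regional cluster scores around cassette exons
#'
#' For each of the six splice-site regions, clusters overlapping the region
#' (upstream intron / cassette exon / downstream intron) and lying within
#' `window` nt of the region's anchor contribute
#' `score * exp(-dist / tau)`, where `dist` is the distance from the anchor
#' to the nearest cluster edge (0 for clusters covering the anchor). The
#' regional score is the maximum contribution (0 if none); the summarized
#' score — used to rank candidate regulated exons — is the maximum of the
#' six.
#'
#' @param events Event tibble from [cassette_events()].
#' @param clusters Scored cluster calls.
#' @param window Maximum anchor distance in nt (default 1000).
#' @param tau Exponential decay length in nt (default 500).
#' @return `events` with columns `s_UI5ss` ... `s_DI3ss`, `summarized` and
#'   `argmax_region`.
#' @export
regional_scores <- function(events, clusters, window = 1000, tau = 500) {
  need <- c("ue_start", "ue_end", "ce_start", "ce_end", "de_start", "de_end")
  if (!all(need %in% names(events))) abort("malformed event table")
  if (nrow(events) > 0 && any(events$ce_start >= events$ce_end)) {
    abort("malformed event: cassette exon with start >= end")
  }
  scores <- matrix(0, nrow(events), 6,
                   dimnames = list(NULL, paste0("s_", SPLICE_REGIONS)))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    cl <- clusters[clusters$seq_id == ev$seq_id, , drop = FALSE]
    if (nrow(cl) == 0) next
    anch <- event_anchor_regions(ev)
    for (k in seq_len(6)) {
      lo <- anch$reg_start[k]; hi <- anch$reg_end[k]
      if (hi <= lo) next
      ov <- cl$start < hi & cl$end > lo
      if (!any(ov)) next
      p <- anch$anchor[k]
      s <- cl$start[ov]; e <- cl$end[ov]
      dist <- ifelse(s <= p & p < e, 0,
                     ifelse(p < s, s - p, p - (e - 1L)))
      keep <- dist <= window
      if (!any(keep)) next
      scores[i, k] <- max(cl$score[ov][keep] * exp(-dist[keep] / tau))
    }
  }
  out <- bind_cols(events, as_tibble(scores))
  out$summarized <- do.call(pmax, as.list(as_tibble(scores)))
  out$argmax_region <- SPLICE_REGIONS[max.col(scores, ties.method = "first")]
  out$argmax_region[out$summarized <= 0] <- NA_character_
  out
}

#' Rank events and call targets above a score threshold
#'
#' Events are sorted by summarized score (descending, ties by event id);
#' those at or above `threshold` are called targets, each annotated with its
#' best-scoring region (e.g. `DI5ss` = 5' end of the downstream intron).
#'
#' @param scored_events Output of [regional_scores()].
#' @param threshold Summarized-score threshold (a user choice; score scales
#'   depend on the log base and training data).
#' @return List with `ranked` (all events, sorted) and `targets` (the calls).
#' @export
rank_and_call_targets <- function(scored_events, threshold) {
  ranked <- scored_events |>
    arrange(desc(.data$summarized), .data$event_id)
  list(ranked = ranked,
       targets = ranked |> filter(.data$summarized >= threshold))
}

#' Positional cluster-score profile around the four cassette splice sites
#'
#' For each offset in `[-flank, flank]` around the four splice sites
#' (upstream-exon 5'ss, cassette 3'ss, cassette 5'ss, downstream-exon 3'ss),
#' the sum over events of scores of clusters covering that position,
#' optionally divided by the number of events. Offsets are in transcript
#' orientation (positive = downstream). A simple positional aggregation —
#' not a normalized complexity map.
#'
#' @param events Event tibble.
#' @param clusters Scored cluster calls.
#' @param flank Half-window in nt.
#' @param normalize Divide by the number of events.
#' @return Tibble `(splice_site, offset, value)` with
#'   `splice_site` in `UE5ss`, `CE3ss`, `CE5ss`, `DE3ss`.
#' @export
positional_profile <- function(events, clusters, flank = 500L,
                               normalize = TRUE) {
  if (nrow(events) == 0) abort("no events")
  sites <- c("UE5ss", "CE3ss", "CE5ss", "DE3ss")
  offs <- seq.int(-flank, flank)
  acc <- matrix(0, length(sites), length(offs),
                dimnames = list(sites, NULL))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    plus <- ev$strand != "-"
    anchors <- if (plus) c(ev$ue_end, ev$ce_start, ev$ce_end, ev$de_start)
               else c(ev$ue_start - 1L, ev$ce_end - 1L, ev$ce_start - 1L,
                      ev$de_end - 1L)
    cl <- clusters[clusters$seq_id == ev$seq_id, , drop = FALSE]
    if (nrow(cl) == 0) next
    sgn <- if (plus) 1L else -1L
    for (k in seq_along(sites)) {
      pos <- anchors[k] + sgn * offs
      for (j in seq_len(nrow(cl))) {
        covered <- pos >= cl$start[j] & pos < cl$end[j]
        acc[k, covered] <- acc[k, covered] + cl$score[j]
      }
    }
  }
  if (normalize) acc <- acc / nrow(events)
  tibble(
    splice_site = factor(rep(sites, each = length(offs)), levels = sites),
    offset = rep(offs, times = length(sites)),
    value = as.vector(t(acc))
  )
}

#' Overlap of predicted targets with a reference positive set
#'
#' 2x2 contingency table over a fixed event universe and the two-sided
#' Fisher exact p-value (via [stats::fisher.test()]).
#'
#' @param predicted Character vector of predicted target event ids.
#' @param reference Character vector of reference positive event ids.
#' @param universe Character vector of all candidate event ids.
#' @return One-row tibble: `n_both`, `n_pred_only`, `n_ref_only`,
#'   `n_neither`, `odds_ratio`, `p_value`.
#' @export
target_overlap_table <- function(predicted, reference, universe) {
  predicted <- unique(predicted); reference <- unique(reference)
  universe <- unique(universe)
  if (!all(c(predicted, reference) %in% universe)) {
    abort("universe must contain every predicted and reference event")
  }
  n11 <- length(intersect(predicted, reference))
  n10 <- length(setdiff(predicted, reference))
  n01 <- length(setdiff(reference, predicted))
  n00 <- length(universe) - n11 - n10 - n01
  ft <- fisher.test(matrix(c(n11, n10, n01, n00), 2, byrow = TRUE))
  tibble(n_both = n11, n_pred_only = n10, n_ref_only = n01, n_neither = n00,
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
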