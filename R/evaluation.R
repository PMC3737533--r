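# CLIP-footprint evaluation: footprints, sampled negatives, ROC/AUC,
# two-fold cross-validation, score-bin overlap summaries.

#' CLIP footprints around tag-cluster peaks
#'
#' The region +/- `half_width` nt around the peak of each qualifying CLIP
#' tag cluster ("footprint"), the surrogate true-positive regions of the
#' ROC evaluation. The inclusive +/-50 window becomes the half-open interval
#' `[peak - 50, peak + 51)`, width 101.
#'
#' @param clip CLIP cluster tibble (with `peak`, `ph`).
#' @param ph_min Minimum peak height.
#' @param half_width Half-width in nt (default 50).
#' @param location_mask Optional tibble `(seq_id, start, end)`: keep only
#'   clusters whose peak lies inside the union (e.g. internal exons + 1 kb).
#' @param seq_lengths Optional named vector of sequence lengths; footprints
#'   extending past a sequence end are truncated with a warning.
#' @return Footprint tibble `(seq_id, start, end, peak, ph)`.
#' @export
make_footprints <- function(clip, ph_min = 15L, half_width = 50L,
                            location_mask = NULL, seq_lengths = NULL) {
  fp <- clip |> filter(.data$ph >= ph_min)
  if (!is.null(location_mask)) {
    keep <- iv_within_union(fp$seq_id, fp$peak, fp$peak + 1L, location_mask)
    fp <- fp[keep, , drop = FALSE]
  }
  out <- tibble(
    seq_id = fp$seq_id,
    start = fp$peak - as.integer(half_width),
    end = fp$peak + as.integer(half_width) + 1L,
    peak = fp$peak, ph = fp$ph
  )
  trunc_low <- out$start < 0
  out$start[trunc_low] <- 0L
  if (!is.null(seq_lengths)) {
    lim <- unname(seq_lengths[out$seq_id])
    trunc_high <- !is.na(lim) & out$end > lim
    out$end[trunc_high] <- as.integer(lim[trunc_high])
    if (any(trunc_low | trunc_high)) {
      warn(sprintf("%d footprint(s) truncated at sequence ends",
                   sum(trunc_low | trunc_high)))
    }
  } else if (any(trunc_low)) {
    warn(sprintf("%d footprint(s) truncated at sequence start",
                 sum(trunc_low)))
  }
  arrange(out, .data$seq_id, .data$start)
}

#' Sample fixed-length background windows from tag-free regions
#'
#' Uniform over all eligible placements (every offset of every region long
#' enough), without replacement, reproducible under the seed.
#'
#' @param regions Tibble `(seq_id, start, end)` of CLIP-tag-free sequence.
#' @param length Window length (default 100 nt).
#' @param n Number of windows.
#' @param seed Integer seed (mandatory).
#' @return Tibble `(seq_id, start, end)` of sampled windows.
#' @export
sample_negative_windows <- function(regions, length = 100L, n, seed) {
  assert_intervals(regions, "regions")
  win <- as.integer(length)
  elig <- regions |> filter(.data$end - .data$start >= win)
  placements <- elig$end - elig$start - win + 1L
  n_place <- sum(placements)
  if (n_place < n) {
    abort(sprintf("insufficient eligible space: %d windows requested, %d placements available",
                  n, n_place))
  }
  offsets <- c(0L, cumsum(placements))
  picks <- withr::with_seed(seed, sample.int(n_place, n))
  # map each pick to its region by cumulative placement counts
  ridx <- findInterval(picks, offsets, left.open = TRUE)
  starts <- elig$start[ridx] + (picks - offsets[ridx] - 1L)
  tibble(seq_id = elig$seq_id[ridx], start = starts, end = starts + win) |>
    arrange(.data$seq_id, .data$start)
}

# Max cluster score overlapping each example interval (-Inf if none).
overlap_max_score <- function(examples, clusters) {
  out <- rep(-Inf, nrow(examples))
  if (nrow(clusters) == 0) return(out)
  for (sid in unique(examples$seq_id)) {
    eidx <- which(examples$seq_id == sid)
    cl <- clusters[clusters$seq_id == sid, , drop = FALSE]
    if (nrow(cl) == 0) next
    for (i in eidx) {
      ov <- cl$start < examples$end[i] & cl$end > examples$start[i]
      if (any(ov)) out[i] <- max(cl$score[ov])
    }
  }
  out
}

#' ROC of cluster predictions against footprints and background windows
#'
#' Each example's score is the maximum score of any cluster overlapping it
#' by >= 1 nt (`-Inf` if none — equivalent to the "an overlapping cluster
#' above the threshold exists" rule at every threshold). The AUC is the
#' Mann-Whitney statistic; sensitivities at specificity 0.85 and 0.99 are
#' reported alongside.
#'
#' @param clusters Scored cluster calls ([predict_clusters()]).
#' @param positives Footprint tibble ([make_footprints()]).
#' @param negatives Background window tibble ([sample_negative_windows()]).
#' @param at_specificity Specificities at which to report sensitivity.
#' @return An object of class `roc_eval`: list with `points` (threshold,
#'   sensitivity, specificity), `auc`, `sens_at`, `n_pos`, `n_neg`.
#' @export
roc_from_overlap <- function(clusters, positives, negatives,
                             at_specificity = c(0.85, 0.99)) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    abort("ROC needs non-empty positive and negative example sets")
  }
  sp <- overlap_max_score(positives, clusters)
  sn <- overlap_max_score(negatives, clusters)
  P <- length(sp); N <- length(sn)
  r <- rank(c(sp, sn))                      # midranks: ties counted 1/2
  auc <- (sum(r[seq_len(P)]) - P * (P + 1) / 2) / (P * N)
  thr <- sort(unique(c(sp, sn)), decreasing = TRUE)
  pts <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(sp >= t), 0),
    specificity = vapply(thr, function(t) mean(sn < t), 0)
  )
  sens_at <- tibble(
    specificity = at_specificity,
    sensitivity = vapply(at_specificity, function(s) {
      ok <- pts$specificity >= s
      if (any(ok)) max(pts$sensitivity[ok]) else 0
    }, 0)
  )
  structure(list(points = pts, auc = auc, sens_at = sens_at,
                 n_pos = P, n_neg = N),
            class = "roc_eval")
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("<roc_eval: AUC = %.4f (%d pos, %d neg)>\n",
              x$auc, x$n_pos, x$n_neg))
  for (i in seq_len(nrow(x$sens_at))) {
    cat(sprintf("  sensitivity %.3f at specificity %.2f\n",
                x$sens_at$sensitivity[i], x$sens_at$specificity[i]))
  }
  invisible(x)
}

#' Two-fold cross-validation of cluster scores
#'
#' Splits genes randomly into two halves, trains a model on the training
#' regions of each half and predicts clusters on the other, then compares
#' the pooled out-of-fold cluster scores with the scores of a model trained
#' on everything, matched by exact cluster coordinates. The squared Pearson
#' correlation of the shared clusters summarizes model stability.
#'
#' @param feats Featurized sites for all genes (one scan sequence per gene).
#' @param clip CLIP clusters.
#' @param tx Transcripts (gene level; the split is by transcript so no
#'   gene's sites straddle folds).
#' @param repeats Optional repeat intervals.
#' @param config A [training_config()].
#' @param feature_set Model feature set.
#' @param seed Integer seed for the split.
#' @param min_sites Cluster-call filter.
#' @return List: `r_squared`, `matched` (tibble of shared clusters with
#'   `score_full`, `score_cv`), `folds` (tibble tx_id/fold), `full_model`.
#' @export
crossval_two_fold <- function(feats, clip, tx, repeats = NULL,
                              config = training_config(),
                              feature_set = c("d", "c", "a"), seed = 1L,
                              min_sites = 3L) {
  genes <- tx$tx_id
  if (length(genes) < 2) abort("cross-validation needs at least 2 genes")
  shuffled <- withr::with_seed(seed, sample(genes))
  half <- floor(length(genes) / 2)
  folds <- tibble(tx_id = shuffled,
                  fold = rep(c(1L, 2L), c(half, length(genes) - half)))
  fit_on <- function(ids) {
    sub_tx <- tx |> filter(.data$tx_id %in% ids)
    sub_feats <- feats |> filter(.data$seq_id %in% sub_tx$seq_id)
    sub_clip <- clip |> filter(.data$seq_id %in% sub_tx$seq_id)
    ts <- build_training_sets(sub_clip, sub_tx, repeats, config)
    train_model(label_training_sites(sub_feats, ts, config$D_cens),
                feature_set = feature_set, config = config)
  }
  preds <- list()
  for (f in 1:2) {
    train_ids <- folds$tx_id[folds$fold == f]
    test_ids <- folds$tx_id[folds$fold != f]
    m <- fit_on(train_ids)
    test_seqs <- tx$seq_id[tx$tx_id %in% test_ids]
    preds[[f]] <- predict_clusters(m, feats |>
                                     filter(.data$seq_id %in% test_seqs),
                                   min_sites = min_sites)
  }
  cv <- bind_rows(preds)
  full_model <- fit_on(genes)
  full <- predict_clusters(full_model, feats, min_sites = min_sites)
  matched <- dplyr::inner_join(
    full |> select("seq_id", "start", "end", score_full = "score"),
    cv |> select("seq_id", "start", "end", score_cv = "score"),
    by = c("seq_id", "start", "end")
  )
  r2 <- if (nrow(matched) >= 3) cor(matched$score_full, matched$score_cv)^2
        else NA_real_
  list(r_squared = r2, matched = matched, folds = folds,
       full_model = full_model)
}

#' Footprint overlap as a function of cluster score
#'
#' Bins clusters by score and reports, per bin, the fraction overlapping any
#' CLIP footprint (>= 1 nt), plus the cumulative number of clusters above
#' each bin's lower edge — higher-scoring clusters should overlap CLIP
#' support more often.
#'
#' @param clusters Scored cluster calls.
#' @param footprints Footprint tibble.
#' @param bin_edges Numeric score bin edges (left-closed; last bin
#'   right-closed).
#' @return List of class `score_bin_overlap`: `bins` tibble (`bin`, `lower`,
#'   `upper`, `n`, `n_overlap`, `fraction` — `NA` for empty bins) and
#'   `cumulative` tibble (`lower`, `n_at_or_above`).
#' @export
score_bin_overlap <- function(clusters, footprints, bin_edges) {
  stopifnot(length(bin_edges) >= 3)
  hit <- iv_overlaps_any(clusters$seq_id, clusters$start, clusters$end,
                         footprints[c("seq_id", "start", "end")])
  idx <- cut(clusters$score, breaks = bin_edges, include.lowest = TRUE,
             right = FALSE, labels = FALSE)
  B <- length(bin_edges) - 1L
  n <- tabulate(idx, nbins = B)
  n_ov <- tabulate(idx[hit], nbins = B)
  bins <- tibble(
    bin = seq_len(B),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    n = n, n_overlap = n_ov,
    fraction = ifelse(n > 0, n_ov / n, NA_real_)
  )
  cumulative <- tibble(
    lower = bins$lower,
    n_at_or_above = rev(cumsum(rev(bins$n)))
  )
  structure(list(bins = bins, cumulative = cumulative),
            class = "score_bin_overlap")
}
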