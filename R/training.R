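# Supervised training: positive/negative site sets from CLIP clusters and
# tag-free background, nonparametric emissions, transition MLEs. No
# Baum-Welch: labels come from CLIP overlap.

#' Training configuration
#'
#' @param ph_min Minimum CLIP cluster peak height for positives (15 was used
#'   for Nova, 7 for Mbnl).
#' @param ext Flank width defining the exon+ext mask (default 1000 nt).
#' @param exclude_repetitive_positives Drop positive clusters overlapping
#'   repeat intervals by >= 1 nt.
#' @param D_cens Spacing censoring threshold (nt).
#' @param bins_c,bins_a Number of equal-width bins on `[0, 1]` for the
#'   conservation / accessibility histograms.
#' @param pseudocount Laplace smoothing pseudocount for all histograms and
#'   transition counts.
#' @return A list of class `training_config`.
#' @export
training_config <- function(ph_min = 15L, ext = 1000L,
                            exclude_repetitive_positives = TRUE,
                            D_cens = 30L, bins_c = 20L, bins_a = 20L,
                            pseudocount = 1) {
  stopifnot(ph_min >= 1, pseudocount > 0, D_cens >= 1)
  structure(list(ph_min = as.integer(ph_min), ext = as.integer(ext),
                 exclude_repetitive_positives = exclude_repetitive_positives,
                 D_cens = as.integer(D_cens), bins_c = as.integer(bins_c),
                 bins_a = as.integer(bins_a), pseudocount = pseudocount),
            class = "training_config")
}

#' Build positive and negative training regions
#'
#' Positives are CLIP tag cluster intervals with peak height `>= ph_min`,
#' fully inside the exon+ext mask and (optionally) free of repeat overlap.
#' Negatives are the exon+ext regions of genes in whose mask **no** CLIP tag
#' cluster falls at all, regardless of peak height — a gene with even one
#' weak tag cluster is excluded from the background.
#'
#' @param clip CLIP clusters tibble (see [read_bed()] with `kind = "clip"`).
#' @param tx Transcript tibble from [read_bed12()].
#' @param repeats Optional repeat intervals tibble.
#' @param config A [training_config()].
#' @return List with tibbles `positive` (`region_id, seq_id, start, end`) and
#'   `negative` (same columns); errors if either is empty.
#' @export
build_training_sets <- function(clip, tx, repeats = NULL,
                                config = training_config()) {
  mask_gene <- exon_ext_mask(tx, ext = config$ext, per_gene = TRUE)
  mask_all <- iv_merge(mask_gene[c("seq_id", "start", "end")])
  pos <- clip |> filter(.data$ph >= config$ph_min)
  keep <- iv_within_union(pos$seq_id, pos$start, pos$end, mask_all)
  pos <- pos[keep, , drop = FALSE]
  if (!is.null(repeats) && config$exclude_repetitive_positives &&
      nrow(pos) > 0) {
    rep_hit <- iv_overlaps_any(pos$seq_id, pos$start, pos$end, repeats)
    pos <- pos[!rep_hit, , drop = FALSE]
  }
  # genes with any CLIP tag at all (even outside the mask) are not tag-free
  extent <- tibble(tx_id = tx$tx_id, seq_id = tx$seq_id,
                   start = pmax(0L, tx$start - config$ext),
                   end = tx$end + config$ext)
  tagged <- extent |>
    mutate(hit = iv_overlaps_any(.data$seq_id, .data$start, .data$end,
                                 clip[c("seq_id", "start", "end")]))
  neg_genes <- tagged$tx_id[!tagged$hit]
  neg <- mask_gene |> filter(.data$tx_id %in% neg_genes)
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("untrainable: empty positive or negative training set")
  }
  list(
    positive = tibble(region_id = sprintf("pos_%d", seq_len(nrow(pos))),
                      seq_id = pos$seq_id, start = pos$start, end = pos$end),
    negative = tibble(region_id = sprintf("neg_%s", neg$tx_id),
                      seq_id = neg$seq_id, start = neg$start, end = neg$end)
  )
}

#' Label featurized sites with their training region
#'
#' Every motif site fully inside a positive CLIP cluster interval is labeled
#' `pos`; sites inside negative regions are labeled `neg`. Sites in
#' CLIP-positive genes but outside clusters belong to neither set and are
#' dropped (they would contaminate the background with near-cluster sites).
#' Spacing is recomputed within each training region, whose first site takes
#' the `d = 0` start sentinel.
#'
#' @param feats Featurized sites ([featurize_sites()]).
#' @param training_sets Output of [build_training_sets()].
#' @param D_cens Spacing censoring threshold.
#' @return Labeled feature tibble with `region_id` and `label` columns,
#'   ordered by region and start.
#' @export
label_training_sites <- function(feats, training_sets, D_cens = 30L) {
  tag <- function(regions, label) {
    hits <- list()
    for (i in seq_len(nrow(regions))) {
      inside <- feats$seq_id == regions$seq_id[i] &
        feats$start >= regions$start[i] & feats$end <= regions$end[i]
      if (any(inside)) {
        h <- feats[inside, , drop = FALSE]
        h$region_id <- regions$region_id[i]
        h$label <- label
        hits[[length(hits) + 1L]] <- h
      }
    }
    bind_rows(hits)
  }
  labeled <- bind_rows(tag(training_sets$positive, "pos"),
                       tag(training_sets$negative, "neg"))
  if (nrow(labeled) == 0) abort("no training sites inside training regions")
  labeled |>
    arrange(.data$region_id, .data$start) |>
    group_by(.data$region_id) |>
    group_modify_keep(function(d0) {
      d0$d <- c(0L, pmin(diff(d0$start), as.integer(D_cens)))
      d0
    }) |>
    arrange(.data$region_id, .data$start)
}

# Map per-region label vectors to the unique state path they induce.
labels_to_states <- function(labels) {
  n <- length(labels)
  states <- character(n)
  states[1] <- if (labels[1] == "pos") "S_PLUS" else "S_MINUS"
  if (n > 1) {
    for (i in 2:n) {
      states[i] <- if (labels[i] == "pos") {
        if (labels[i - 1] == "pos") "PLUS" else "I_PLUS"
      } else {
        if (labels[i - 1] == "neg") "MINUS" else "I_MINUS"
      }
    }
  }
  states
}

#' Estimate transition and initial probabilities from labeled sequences
#'
#' Labels induce a unique state path per training region (first site maps to
#' a start state; a label change maps to an internal initiator). Counts on
#' the allowed edges, plus a pseudocount on each, are normalized per source
#' state; the initial distribution over `{S+, S-}` is estimated the same
#' way.
#'
#' @param labeled Labeled feature tibble ([label_training_sites()]) — only
#'   `region_id` and `label` are used.
#' @param pseudocount Smoothing pseudocount.
#' @return List with `trans` (6x6 probability matrix) and `init` (named
#'   probabilities of the two start states).
#' @export
estimate_transitions <- function(labeled, pseudocount = 1) {
  allow <- allowed_transitions()
  counts <- matrix(0, 6, 6, dimnames = dimnames(allow))
  init_counts <- c(S_MINUS = 0, S_PLUS = 0)
  for (labs in split(labeled$label, labeled$region_id)) {
    states <- labels_to_states(labs)
    init_counts[states[1]] <- init_counts[states[1]] + 1
    if (length(states) > 1) {
      for (i in 2:length(states)) {
        stopifnot(allow[states[i - 1], states[i]])
        counts[states[i - 1], states[i]] <- counts[states[i - 1], states[i]] + 1
      }
    }
  }
  trans <- matrix(0, 6, 6, dimnames = dimnames(allow))
  for (s in HMM_STATES) {
    tgt <- which(allow[s, ])
    k <- counts[s, tgt] + pseudocount
    trans[s, tgt] <- k / sum(k)
  }
  init <- (init_counts + pseudocount) / (sum(init_counts) + 2 * pseudocount)
  list(trans = trans, init = c(S_MINUS = unname(init["S_MINUS"]),
                               S_PLUS = unname(init["S_PLUS"])))
}

#' Train the six-state HMM from labeled sites
#'
#' Assembles the emission table from the `pos`/`neg` feature histograms
#' (conservation stratified by region on both sides), estimates transitions
#' and initial probabilities, and records the feature set. The spacing
#' components are estimated from succeeding sites only (`d >= 1`); start
#' sentinels carry no information. A conservation stratum with no positive
#' (or no negative) sites falls back to the region-pooled distribution for
#' that side, with a warning.
#'
#' @param labeled Labeled feature tibble ([label_training_sites()]).
#' @param feature_set Any of `"d"`, `"d c"`, `"d a"`, `"d c a"` as a
#'   character vector; must contain `"d"`.
#' @param config A [training_config()].
#' @param log_base Base for reported cluster scores.
#' @return A fitted [hmm_model()].
#' @export
train_model <- function(labeled, feature_set = c("d", "c", "a"),
                        config = training_config(), log_base = 2) {
  stopifnot("d" %in% feature_set)
  pc <- config$pseudocount
  pos <- labeled |> filter(.data$label == "pos")
  neg <- labeled |> filter(.data$label == "neg")
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort("training requires sites on both sides")
  }
  emis <- list()
  est_d <- function(x) {
    v <- x$d[x$d >= 1]
    if (length(v) == 0) v <- config$D_cens  # degenerate corpus: flat-ish
    estimate_distribution(v, "d", pseudocount = pc, D_cens = config$D_cens)
  }
  emis$d <- list(pos = est_d(pos), neg = est_d(neg))
  if ("c" %in% feature_set) {
    est_c <- function(x, stratum, pool) {
      v <- x$c[as.character(x$region) == stratum]
      if (length(v) == 0) {
        warn(sprintf("no %s training sites in stratum %s; using the pooled distribution",
                     x$label[1], stratum))
        v <- pool
      }
      estimate_distribution(v, "c", bins = config$bins_c, pseudocount = pc,
                            stratum = stratum)
    }
    emis$c <- list(
      pos = lapply(stats::setNames(REGION_TYPES, REGION_TYPES),
                   function(r) est_c(pos, r, pos$c)),
      neg = lapply(stats::setNames(REGION_TYPES, REGION_TYPES),
                   function(r) est_c(neg, r, neg$c))
    )
  }
  if ("a" %in% feature_set) {
    est_a <- function(x) {
      v <- x$a[!is.na(x$a)]
      if (length(v) == 0) v <- 0.5
      estimate_distribution(v, "a", bins = config$bins_a, pseudocount = pc)
    }
    emis$a <- list(pos = est_a(pos), neg = est_a(neg))
  }
  tr <- estimate_transitions(labeled, pseudocount = pc)
  hmm_model(
    init = tr$init, trans = tr$trans, emis = emis,
    feature_set = feature_set, D_cens = config$D_cens, log_base = log_base,
    config = list(training = unclass(config),
                  n_pos_sites = nrow(pos), n_neg_sites = nrow(neg),
                  n_pos_regions = dplyr::n_distinct(pos$region_id),
                  n_neg_regions = dplyr::n_distinct(neg$region_id))
  )
}
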