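# High-level wrappers chaining the standard stages: scan -> featurize ->
# train -> predict. The CLI and the vignette are thin layers over these.

#' Scan and featurize a dataset bundle
#'
#' Scans every sequence for the consensus (restricted to the exon+ext mask),
#' then attaches spacing, conservation, accessibility and region stratum.
#'
#' @param ds Dataset bundle ([simulate_dataset()] / [load_dataset()]).
#' @param consensus,exclude Motif consensus (defaults to the simulation
#'   spec's when present).
#' @param config A [training_config()].
#' @param slop,missing_policy Passed to the feature steps.
#' @return Featurized site tibble.
#' @export
featurize_dataset <- function(ds, consensus = NULL, exclude = NULL,
                              config = training_config(), slop = 0L,
                              missing_policy = "drop_feature") {
  consensus <- consensus %||% ds$spec$consensus
  exclude <- exclude %||% ds$spec$exclude %||% character()
  if (is.null(consensus)) abort("consensus required (bundle has no spec)")
  segments <- build_region_segments(ds$tx, ext = config$ext)
  mask <- exon_ext_mask(ds$tx, ext = config$ext)
  # clip the mask to the actual sequence bounds
  lens <- nchar(ds$seqs)
  mask <- mask |>
    mutate(end = pmin(.data$end, unname(lens[.data$seq_id])),
           start = pmax(.data$start, 0L)) |>
    filter(.data$end > .data$start)
  scan_region_set(ds$seqs, consensus, exclude, mask = mask) |>
    featurize_sites(ds$maf, ds$tree, ds$ref_species, ds$track, segments,
                    consensus, exclude, D_cens = config$D_cens, slop = slop,
                    missing_policy = missing_policy)
}

#' Train a model from a dataset bundle
#'
#' Builds training sets from the bundle's CLIP clusters and annotation,
#' labels the featurized sites and fits the HMM.
#'
#' @param feats Featurized sites ([featurize_dataset()]).
#' @param ds Dataset bundle.
#' @param feature_set Model feature subset (must contain `"d"`).
#' @param config A [training_config()].
#' @param repeats Optional repeat intervals.
#' @return A fitted `hmm_model`.
#' @export
fit_dataset <- function(feats, ds, feature_set = c("d", "c", "a"),
                        config = training_config(), repeats = NULL) {
  ts <- build_training_sets(ds$clip, ds$tx, repeats, config)
  labeled <- label_training_sites(feats, ts, config$D_cens)
  train_model(labeled, feature_set = feature_set, config = config)
}
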