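# Footprints, background sampling, ROC, score-bin overlap, cross-validation.

mk_clip <- function(seq_id, peak, ph, half = 25L) {
  tibble::tibble(seq_id = seq_id, start = as.integer(peak - half),
                 end = as.integer(peak + half), name = "c", score = 0,
                 strand = "+", peak = as.integer(peak), ph = as.integer(ph))
}

test_that("footprints are +/- 50 nt around qualifying peaks", {
  clip <- mk_clip("g1", c(1000, 2000), c(20, 14))
  fp <- make_footprints(clip, ph_min = 15L)
  expect_identical(nrow(fp), 1L)               # PH 14 excluded
  expect_identical(fp$start, 950L)
  expect_identical(fp$end, 1051L)
  expect_identical(fp$end - fp$start, 101L)

  expect_warning(fp2 <- make_footprints(mk_clip("g1", 20, 20, half = 10L),
                                        ph_min = 15L,
                                        seq_lengths = c(g1 = 60L)),
                 "truncated")
  expect_identical(c(fp2$start, fp2$end), c(0L, 60L))
})

test_that("negative window sampling is reproducible and well contained", {
  regions <- tibble::tibble(seq_id = c("a", "b"), start = c(0L, 50L),
                            end = c(500L, 400L))
  w1 <- sample_negative_windows(regions, length = 100L, n = 20L, seed = 9L)
  w2 <- sample_negative_windows(regions, length = 100L, n = 20L, seed = 9L)
  expect_identical(w1, w2)
  expect_true(all(w1$end - w1$start == 100L))
  expect_true(all(motifclust:::iv_within_union(w1$seq_id, w1$start, w1$end, regions)))

  one <- tibble::tibble(seq_id = "a", start = 10L, end = 110L)
  w3 <- sample_negative_windows(one, length = 100L, n = 1L, seed = 1L)
  expect_identical(c(w3$start, w3$end), c(10L, 110L))   # single placement
  expect_error(sample_negative_windows(one, length = 100L, n = 2L, seed = 1L),
               "insufficient eligible space")
})

test_that("sampled negatives never intersect excluded (tagged) regions", {
  # regions are constructed tag-free by the caller; verify containment logic
  regions <- tibble::tibble(seq_id = "g", start = c(0L, 300L),
                            end = c(200L, 600L))
  tagged <- tibble::tibble(seq_id = "g", start = 200L, end = 300L)
  w <- sample_negative_windows(regions, length = 50L, n = 40L, seed = 3L)
  expect_false(any(motifclust:::iv_overlaps_any(w$seq_id, w$start, w$end, tagged)))
})

test_that("overlap ROC: example scores, AUC, and the pairwise oracle", {
  clusters <- tibble::tibble(
    seq_id = "g", start = c(100L, 400L), end = c(150L, 460L),
    score = c(10, 3)
  )
  pos <- tibble::tibble(seq_id = "g", start = c(90L, 390L), end = c(120L, 420L))
  neg <- tibble::tibble(seq_id = "g", start = c(700L, 800L), end = c(750L, 850L))
  roc <- roc_from_overlap(clusters, pos, neg)
  expect_equal(roc$auc, 1.0)                          # perfect separation
  expect_equal(max(roc$points$sensitivity[roc$points$specificity == 1]), 1)

  expect_error(roc_from_overlap(clusters, pos[0, ], neg), "non-empty")

  # pairwise-comparison oracle on random score assignments
  auc_oracle <- function(sp, sn) {
    mean(outer(sp, sn, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  set.seed(91)
  for (rep in 1:10) {
    npos <- sample(3:15, 1); nneg <- sample(3:15, 1)
    pos_iv <- tibble::tibble(seq_id = "g",
                             start = seq(0L, by = 100L, length.out = npos))
    pos_iv$end <- pos_iv$start + 50L
    neg_iv <- tibble::tibble(seq_id = "g",
                             start = seq(10000L, by = 100L, length.out = nneg))
    neg_iv$end <- neg_iv$start + 50L
    cl <- dplyr::bind_rows(pos_iv, neg_iv) |>
      dplyr::mutate(score = sample(c(-Inf, 0, 1, 2, 3, 4), dplyr::n(),
                                   replace = TRUE),
                    n_sites = 3L)
    cl <- cl[is.finite(cl$score), ]
    r <- roc_from_overlap(cl, pos_iv, neg_iv)
    sp <- motifclust:::overlap_max_score(pos_iv, cl)
    sn <- motifclust:::overlap_max_score(neg_iv, cl)
    expect_equal(r$auc, auc_oracle(sp, sn), tolerance = 1e-12)
    expect_true(all(diff(r$points$sensitivity) >= 0 |
                      diff(r$points$specificity) <= 0))
  }
})

test_that("uninformative scores give AUC near one half", {
  set.seed(92)
  n <- 400
  pos <- tibble::tibble(seq_id = "g", start = seq(0L, by = 60L, length.out = n))
  pos$end <- pos$start + 50L
  neg <- tibble::tibble(seq_id = "g",
                        start = seq(100000L, by = 60L, length.out = n))
  neg$end <- neg$start + 50L
  cl <- dplyr::bind_rows(pos, neg) |> dplyr::mutate(score = rnorm(2 * n))
  r <- roc_from_overlap(cl, pos, neg)
  expect_lt(abs(r$auc - 0.5), 0.05)
})

test_that("score-bin overlap reports fractions, empty bins and cumulatives", {
  clusters <- tibble::tibble(seq_id = "g",
                             start = c(0L, 100L, 200L, 300L),
                             end = c(50L, 150L, 250L, 350L),
                             score = c(1, 2, 11, 12))
  fp <- tibble::tibble(seq_id = "g", start = 0L, end = 400L)
  sb <- score_bin_overlap(clusters, fp, bin_edges = c(0, 5, 10, 15))
  expect_equal(sb$bins$fraction, c(1, NA, 1))          # all overlap; empty bin
  expect_identical(sb$bins$n, c(2L, 0L, 2L))
  expect_identical(sb$cumulative$n_at_or_above, c(4L, 2L, 2L))

  far <- tibble::tibble(seq_id = "g", start = 5000L, end = 5100L)
  sb2 <- score_bin_overlap(clusters, far, bin_edges = c(0, 5, 10, 15))
  expect_equal(sb2$bins$fraction, c(0, NA, 0))
})

test_that("two-fold cross-validation splits genes cleanly and correlates", {
  sim <- shared_sim()
  cv <- suppressWarnings(crossval_two_fold(sim$feats, sim$ds$clip, sim$ds$tx,
                                           seed = 5L))
  expect_setequal(cv$folds$tx_id, sim$ds$tx$tx_id)     # union = all genes
  expect_identical(anyDuplicated(cv$folds$tx_id), 0L)  # disjoint
  expect_identical(sort(unique(cv$folds$fold)), c(1L, 2L))
  expect_gt(nrow(cv$matched), 5)
  expect_gt(cv$r_squared, 0.8)
  expect_error(crossval_two_fold(sim$feats, sim$ds$clip, sim$ds$tx[1, ],
                                 seed = 1L), "at least 2")
})
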