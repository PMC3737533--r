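# Training-set construction, histogram estimation, transition MLEs.

test_that("positive clusters are filtered by peak height, mask and repeats", {
  tx <- dplyr::bind_rows(
    toy_tx(exons = list(c(0L, 500L)), seq_id = "g1"),
    toy_tx(tx_id = "t2", exons = list(c(0L, 500L)), seq_id = "g2")
  )
  clip <- tibble::tibble(
    seq_id = "g1", start = c(10L, 110L, 210L), end = c(60L, 160L, 260L),
    name = "c", score = 0, strand = "+",
    peak = c(30L, 130L, 230L), ph = c(3L, 15L, 40L)
  )
  cfg <- training_config(ph_min = 15L, ext = 50L)
  ts <- build_training_sets(clip, tx, config = cfg)
  expect_identical(nrow(ts$positive), 2L)       # PH 15 and 40 pass

  reps <- tibble::tibble(seq_id = "g1", start = 159L, end = 180L)
  ts2 <- build_training_sets(clip, tx, repeats = reps, config = cfg)
  expect_identical(nrow(ts2$positive), 1L)      # 1-nt repeat overlap excluded
})

test_that("a gene with any CLIP tag anywhere is not negative-eligible", {
  tx <- dplyr::bind_rows(
    toy_tx(tx_id = "gA", seq_id = "gA",
           exons = list(c(0L, 100L), c(2000L, 2100L)), cds = NULL),
    toy_tx(tx_id = "gB", seq_id = "gB", exons = list(c(0L, 500L))),
    toy_tx(tx_id = "gC", seq_id = "gC", exons = list(c(0L, 500L)))
  )
  clip <- tibble::tibble(
    seq_id = c("gA", "gC"), start = c(1000L, 10L), end = c(1020L, 60L),
    name = "c", score = 0, strand = "+", peak = c(1010L, 30L),
    ph = c(2L, 20L)
  )
  # gA's tag is in the deep intron, outside the exon+ext mask — but the
  # gene is not tag-free, so only gB qualifies as negative
  ts <- build_training_sets(clip, tx, config = training_config(ext = 100L))
  expect_identical(unique(sub("neg_", "", ts$negative$region_id)), "gB")
})

test_that("untrainable configurations raise errors", {
  tx <- toy_tx(exons = list(c(0L, 500L)), seq_id = "g1")
  clip <- tibble::tibble(seq_id = "g1", start = 10L, end = 60L, name = "c",
                         score = 0, strand = "+", peak = 30L, ph = 20L)
  # no tag-free gene -> empty negatives
  expect_error(build_training_sets(clip, tx, config = training_config()),
               "untrainable")
})

test_that("histogram estimation applies Laplace smoothing exactly", {
  fd <- estimate_distribution(c(1, 1, 3), "d", pseudocount = 1, D_cens = 3L)
  expect_equal(fd$mass, c(3 / 6, 1 / 6, 2 / 6))
  expect_equal(sum(fd$mass), 1, tolerance = 1e-12)

  fd2 <- estimate_distribution(rep(0.5, 10), "c", bins = 4L, pseudocount = 1)
  expect_true(all(fd2$mass > 0))                # empty bins keep mass
  expect_equal(sum(fd2$mass), 1, tolerance = 1e-12)
  expect_identical(which.max(fd2$mass), 3L)     # 0.5 falls in bin 3 of 4

  expect_error(estimate_distribution(c(0, 2), "d", D_cens = 3L), "integers")
  expect_error(estimate_distribution(1.5, "c"), "\\[0, 1\\]")
  expect_error(estimate_distribution(numeric(), "c"), "at least one")
})

test_that("label sequences map to the unique induced state path", {
  labs <- c("neg", "neg", "pos", "pos", "neg")
  expect_identical(motifclust:::labels_to_states(labs),
                   c("S_MINUS", "MINUS", "I_PLUS", "PLUS", "I_MINUS"))
  labeled <- tibble::tibble(region_id = "r1", label = labs)
  tr <- estimate_transitions(labeled, pseudocount = 1)
  # counts: S- -> -, - -> I+, I+ -> +, + -> I-, each once
  expect_equal(tr$trans["S_MINUS", "MINUS"], 2 / 3)
  expect_equal(tr$trans["MINUS", "I_PLUS"], 2 / 3)
  expect_equal(tr$trans["I_PLUS", "PLUS"], 2 / 3)
  expect_equal(tr$trans["PLUS", "I_MINUS"], 2 / 3)
  expect_equal(tr$init[["S_MINUS"]], 2 / 3)
  # rows sum to 1 on allowed edges, 0 elsewhere
  expect_equal(unname(rowSums(tr$trans)), rep(1, 6))
  expect_true(all(tr$trans[!motifclust:::allowed_transitions()] == 0))
})

test_that("degenerate label corpora estimate sensibly", {
  allneg <- tibble::tibble(region_id = rep(sprintf("r%d", 1:50), each = 20),
                           label = "neg")
  tr <- estimate_transitions(allneg, pseudocount = 1)
  expect_gt(tr$init[["S_MINUS"]], 0.95)
  expect_gt(tr$trans["MINUS", "MINUS"], 0.99)

  single <- tibble::tibble(region_id = "r1", label = "pos")
  tr2 <- estimate_transitions(single, pseudocount = 1)
  expect_equal(tr2$init[["S_PLUS"]], 2 / 3)      # one sequence, smoothed
  expect_equal(tr2$trans["PLUS", "PLUS"], 0.5)   # pseudocounts only
})

test_that("identical positive and negative corpora give ~zero scores", {
  set.seed(61)
  base <- random_feats(40, D = 30L, na_frac = 0)
  labeled <- dplyr::bind_rows(
    base |> dplyr::mutate(region_id = "pos_1", label = "pos"),
    base |> dplyr::mutate(region_id = "neg_1", label = "neg")
  )
  m <- suppressWarnings(train_model(labeled, config = training_config()))
  sc <- score_cluster(m, base, 5:9)
  expect_equal(sc, 0, tolerance = 1e-9)
  # and decoding prefers background everywhere (tie-break)
  v <- viterbi(m, base)
  expect_true(all(v$states %in% c("S_MINUS", "MINUS")))
})

test_that("a distance-only model ignores conservation and accessibility", {
  set.seed(62)
  sim <- shared_sim()
  m_d <- suppressWarnings(fit_dataset(sim$feats, sim$ds, feature_set = "d"))
  f2 <- sim$feats |>
    dplyr::mutate(c = stats::runif(dplyr::n()), a = stats::runif(dplyr::n()))
  v1 <- viterbi(m_d, sim$feats[sim$feats$seq_id == sim$feats$seq_id[1], ])
  v2 <- viterbi(m_d, f2[f2$seq_id == f2$seq_id[1], ])
  expect_identical(v1$states, v2$states)
  expect_equal(v1$log_prob, v2$log_prob, tolerance = 1e-12)
})

test_that("stratum fallback warns and region-pools when a stratum is empty", {
  set.seed(63)
  base <- random_feats(60, D = 30L)
  base$region <- factor("INTRON", levels = REGION_TYPES)
  labeled <- dplyr::bind_rows(
    base[1:30, ] |> dplyr::mutate(region_id = "pos_1", label = "pos"),
    base[31:60, ] |> dplyr::mutate(region_id = "neg_1", label = "neg")
  )
  w <- capture_warnings(train_model(labeled, config = training_config()))
  # one warning per empty stratum and side
  expect_true(all(grepl("pooled distribution", w)))
  expect_length(w, 6)
})
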