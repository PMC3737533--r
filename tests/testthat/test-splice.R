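# Regional scores around cassette exons, target ranking, profiles, overlap
# tables.

mk_event <- function(strand = "+") {
  tibble::tibble(
    event_id = "e1", seq_id = "g", strand = strand,
    ue_start = 0L, ue_end = 100L,
    ce_start = 1100L, ce_end = 1200L,
    de_start = 2200L, de_end = 2300L
  )
}

mk_cluster <- function(start, end, score) {
  tibble::tibble(seq_id = "g", start = as.integer(start),
                 end = as.integer(end), score = score, n_sites = 3L)
}

test_that("a cluster on the DI5'ss anchor scores at full weight", {
  ev <- mk_event()
  cl <- mk_cluster(1200, 1235, 12)   # starts on the DI5ss anchor base
  rs <- regional_scores(ev, cl)
  expect_equal(rs$s_DI5ss, 12.0)
  expect_equal(rs$summarized, 12.0)
  expect_identical(rs$argmax_region, "DI5ss")

  # a boundary-straddling cluster covers the anchor from both sides: full
  # weight in the exonic E5ss region as well as DI5ss
  rs2 <- regional_scores(ev, mk_cluster(1195, 1230, 12))
  expect_equal(rs2$s_DI5ss, 12.0)
  expect_equal(rs2$s_E5ss, 12.0)
  expect_equal(rs2$summarized, 12.0)
})

test_that("distance weighting decays as exp(-dist/tau)", {
  ev <- mk_event()
  # cluster 500 nt into the downstream intron (dist = tau from DI5ss)
  cl <- mk_cluster(1200 + 500, 1200 + 540, 12)
  rs <- regional_scores(ev, cl, window = 1000, tau = 500)
  expect_equal(rs$s_DI5ss, 12 * exp(-1), tolerance = 1e-9)
  # the same cluster is ~exp(-500/500) from DI5 but also within 1000 of
  # DI3ss: dist = 2200 - 1 - 1739
  expect_equal(rs$s_DI3ss, 12 * exp(-(2200 - (1740 - 1)) / 500),
               tolerance = 1e-9)
  expect_equal(rs$summarized, max(rs$s_UI5ss, rs$s_UI3ss, rs$s_E3ss,
                                  rs$s_E5ss, rs$s_DI5ss, rs$s_DI3ss))
})

test_that("events with no nearby clusters score zero in all six regions", {
  ev <- mk_event()
  rs <- regional_scores(ev, mk_cluster(9000, 9100, 50))
  expect_true(all(as.matrix(rs[paste0("s_", motifclust:::SPLICE_REGIONS)]) == 0))
  expect_equal(rs$summarized, 0)
})

test_that("exonic regions take exon-internal clusters only", {
  ev <- mk_event()
  cl <- mk_cluster(1120, 1160, 8)    # inside the cassette exon
  rs <- regional_scores(ev, cl)
  expect_gt(rs$s_E3ss, 0)
  expect_gt(rs$s_E5ss, 0)
  expect_equal(rs$s_UI5ss, 0)
  # intron-only cluster contributes nothing to exonic regions
  cl2 <- mk_cluster(1300, 1340, 8)
  rs2 <- regional_scores(ev, cl2)
  expect_equal(rs2$s_E3ss, 0)
  expect_gt(rs2$s_DI5ss, 0)
})

test_that("summarized = max of the six and is monotone in cluster score", {
  set.seed(93)
  ev <- mk_event()
  for (rep in 1:10) {
    cl <- dplyr::bind_rows(lapply(1:4, function(i) {
      s <- sample(0:2250, 1)
      mk_cluster(s, s + 40, runif(1, 0, 20))
    }))
    rs <- regional_scores(ev, cl)
    six <- as.numeric(rs[paste0("s_", motifclust:::SPLICE_REGIONS)])
    expect_equal(rs$summarized, max(six), tolerance = 1e-12)
    rs2 <- regional_scores(ev, cl |> dplyr::mutate(score = score * 2))
    expect_gte(rs2$summarized + 1e-12, rs$summarized)
  }
})

test_that("targets are ranked by summarized score with reported argmax", {
  ev <- dplyr::bind_rows(
    mk_event() |> dplyr::mutate(event_id = "e1"),
    mk_event() |> dplyr::mutate(event_id = "e2"),
    mk_event() |> dplyr::mutate(event_id = "e3")
  )
  scored <- ev |>
    dplyr::mutate(s_UI5ss = 0, s_UI3ss = 0, s_E3ss = 0, s_E5ss = 0,
                  s_DI5ss = c(12, 9, 10), s_DI3ss = c(1, 2, 3),
                  summarized = c(12, 9, 10),
                  argmax_region = "DI5ss")
  res <- rank_and_call_targets(scored, threshold = 10)
  expect_identical(res$targets$event_id, c("e1", "e3"))
  expect_identical(res$ranked$event_id[1], "e1")
  # argmax agrees with a brute-force max over the six fields
  six <- as.matrix(scored[paste0("s_", motifclust:::SPLICE_REGIONS)])
  expect_identical(scored$argmax_region,
                   motifclust:::SPLICE_REGIONS[apply(six, 1, which.max)])
})

test_that("positional profiles aggregate scores linearly around splice sites", {
  ev <- mk_event()
  cl <- mk_cluster(1200, 1300, 5)     # [0, 100) after the cassette 5'ss
  pr <- positional_profile(ev, cl, flank = 200L)
  ce5 <- pr[pr$splice_site == "CE5ss", ]
  expect_equal(ce5$value[ce5$offset >= 0 & ce5$offset < 100], rep(5, 100))
  expect_equal(ce5$value[ce5$offset < 0 | ce5$offset >= 100], rep(0, 301))

  pr2 <- positional_profile(ev, cl |> dplyr::mutate(score = score * 2),
                            flank = 200L)
  expect_equal(pr2$value, 2 * pr$value)

  expect_error(positional_profile(ev[0, ], cl), "no events")
})

test_that("target overlap tables match the hypergeometric oracle", {
  u <- sprintf("e%02d", 1:20)
  res <- target_overlap_table(u[1:10], u[1:10], u)
  # exhaustive tail: only the two extreme tables are as extreme
  p_oracle <- 2 * stats::dhyper(10, 10, 10, 10)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(res$p_value, 1.082509e-05, tolerance = 1e-4)

  res2 <- target_overlap_table(character(), u[1:5], u)
  expect_equal(res2$p_value, 1)
  expect_identical(res2$n_both, 0L)

  expect_error(target_overlap_table("zz", u[1:5], u), "universe")
})

test_that("cassette events derive from internal exons with strand handling", {
  tx <- toy_tx(exons = list(c(0L, 100L), c(1100L, 1200L), c(2200L, 2300L)))
  ev <- cassette_events(tx)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$ce_start, 1100L)
  expect_identical(ev$ue_end, 100L)

  txm <- toy_tx(strand = "-",
                exons = list(c(0L, 100L), c(1100L, 1200L), c(2200L, 2300L)))
  evm <- cassette_events(txm)
  expect_identical(evm$ue_start, 2200L)    # upstream in transcript orientation
  expect_identical(evm$de_end, 100L)

  expect_identical(nrow(cassette_events(toy_tx())), 0L)
})
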