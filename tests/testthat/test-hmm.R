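# Six-state HMM: emission table semantics, Viterbi vs exhaustive oracle,
# cluster extraction and scoring.

lmass <- motifclust:::fd_logmass

# c+a log-ratio of a one-row feature table under a model
ca_diff_of <- function(m, f) {
  r <- as.character(f$region)
  out <- lmass(m$emis$c$pos[[r]], f$c) - lmass(m$emis$c$neg[[r]], f$c)
  if (!is.na(f$a)) {
    out <- out + lmass(m$emis$a$pos, f$a) - lmass(m$emis$a$neg, f$a)
  }
  out
}

test_that("emission components follow the state table", {
  set.seed(71)
  m <- random_model()
  f1 <- random_feats(1, na_frac = 0)         # single site, d = 0
  eS <- vapply(c("S_PLUS", "S_MINUS"), function(s) emission_logprob(m, s, f1),
               0)
  # start states share the degenerate d-term: their difference comes from
  # c and a only
  expect_equal(eS[["S_PLUS"]] - eS[["S_MINUS"]], ca_diff_of(m, f1),
               tolerance = 1e-12)

  fmid <- random_feats(3, na_frac = 0)[3, ]  # succeeding site, d >= 1
  # internal cluster initiators take the background distance component
  dI <- emission_logprob(m, "I_PLUS", fmid) - emission_logprob(m, "I_MINUS", fmid)
  expect_equal(dI, ca_diff_of(m, fmid), tolerance = 1e-12)

  m_d <- random_model(feature_set = "d")
  dPM <- emission_logprob(m_d, "PLUS", fmid) - emission_logprob(m_d, "MINUS", fmid)
  expect_equal(dPM, lmass(m_d$emis$d$pos, fmid$d) -
                 lmass(m_d$emis$d$neg, fmid$d), tolerance = 1e-12)
})

test_that("missing accessibility drops the a-term symmetrically", {
  set.seed(72)
  m <- random_model()
  f <- random_feats(2)[2, ]
  f$a <- NA_real_
  diff_na <- emission_logprob(m, "PLUS", f) - emission_logprob(m, "MINUS", f)
  expect_equal(diff_na,
               (lmass(m$emis$d$pos, f$d) - lmass(m$emis$d$neg, f$d)) +
                 (lmass(m$emis$c$pos[[as.character(f$region)]], f$c) -
                    lmass(m$emis$c$neg[[as.character(f$region)]], f$c)),
               tolerance = 1e-12)
})

test_that("a symmetric model decodes everything as background (tie-break)", {
  set.seed(73)
  m <- symmetric_model()
  f <- random_feats(6)
  v <- viterbi(m, f)
  expect_identical(v$states[1], "S_MINUS")
  expect_true(all(v$states[-1] == "MINUS"))
})

test_that("strong cluster-side emission advantage decodes as a cluster", {
  set.seed(74)
  m <- separated_model()
  f <- random_feats(3, D = 10L, na_frac = 0)
  f$d <- c(0L, 2L, 2L); f$c <- c(0.95, 0.9, 0.99); f$a <- c(0.9, 0.95, 0.85)
  v <- viterbi(m, f)
  expect_identical(v$states, c("S_PLUS", "PLUS", "PLUS"))
  b <- brute_force_decode(m, f)
  expect_equal(v$log_prob, b$log_prob, tolerance = 1e-12)
})

test_that("Viterbi matches the exhaustive oracle on random instances", {
  set.seed(75)
  for (rep in 1:200) {
    m <- random_model()
    f <- random_feats(sample(1:8, 1))
    v <- viterbi(m, f)
    b <- brute_force_decode(m, f)
    expect_equal(v$log_prob, b$log_prob, tolerance = 1e-9)
    # legality of the decoded path
    expect_true(v$states[1] %in% c("S_MINUS", "S_PLUS"))
    if (length(v$states) > 1) {
      allow <- motifclust:::allowed_transitions()
      idx <- cbind(match(v$states[-length(v$states)], HMM_STATES),
                   match(v$states[-1], HMM_STATES))
      expect_true(all(allow[idx]))
    }
  }
})

test_that("cluster runs are extracted as (S+|I+)(+)* with filters", {
  set.seed(76)
  m <- symmetric_model()
  f <- random_feats(7)
  path <- structure(list(states = c("S_MINUS", "MINUS", "I_PLUS", "PLUS",
                                    "PLUS", "I_MINUS", "MINUS"),
                         log_prob = 0), class = "state_path")
  calls <- call_clusters(m, f, path = path, min_sites = 3L)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_sites, 3L)
  expect_identical(calls$start, f$start[3])
  expect_identical(calls$end, f$end[5])

  expect_identical(nrow(call_clusters(m, f, path = path, min_sites = 4L)), 0L)

  # two clusters separated by one background site are never merged
  path2 <- structure(list(states = c("S_PLUS", "PLUS", "PLUS", "I_MINUS",
                                     "I_PLUS", "PLUS", "PLUS"),
                          log_prob = 0), class = "state_path")
  calls2 <- call_clusters(m, f, path = path2, min_sites = 3L)
  expect_identical(nrow(calls2), 2L)
})

test_that("cluster scores: symmetry, additivity, initiating-site distance", {
  set.seed(77)
  m_sym <- symmetric_model()
  f <- random_feats(6)
  expect_equal(score_cluster(m_sym, f, 2:5), 0, tolerance = 1e-12)

  m <- random_model()
  f2 <- random_feats(6, na_frac = 0)
  base <- score_cluster(m, f2, 2:4)
  ext <- score_cluster(m, f2, 2:5)
  site5_ratio <- (lmass(m$emis$d$pos, f2$d[5]) -
                    lmass(m$emis$d$neg, f2$d[5])) + ca_diff_of(m, f2[5, ])
  trans_inc <- m$log_trans["PLUS", "PLUS"] - m$log_trans["MINUS", "MINUS"]
  expect_equal(ext, base + (site5_ratio + trans_inc) / log(2),
               tolerance = 1e-9)

  # the initiating site's distance term cancels exactly: change its d
  f3 <- f2
  f3$d[2] <- 5L
  expect_equal(score_cluster(m, f2, 2:4), score_cluster(m, f3, 2:4),
               tolerance = 1e-12)

  # invariance to sites outside the member run
  f4 <- f2
  f4$c[1] <- 0.123; f4$a[6] <- 0.9; f4$d[6] <- 3L
  expect_equal(score_cluster(m, f2, 2:4), score_cluster(m, f4, 2:4),
               tolerance = 1e-12)

  expect_error(score_cluster(m, f2, c(2, 4)), "contiguous")
})

test_that("decoded paths and scores are invariant to censored-gap size", {
  set.seed(78)
  sim <- shared_sim()
  m <- suppressWarnings(fit_dataset(sim$feats, sim$ds))
  sid <- sim$feats$seq_id[1]
  f <- sim$feats[sim$feats$seq_id == sid, ]
  # push every censored gap to a much larger raw distance and re-censor
  starts2 <- f$start + cumsum(ifelse(f$d >= 30L, 970L, 0L))
  f2 <- f |> dplyr::mutate(start = starts2, end = starts2 + 4L) |>
    dplyr::select(-d) |> compute_spacing(D_cens = 30L)
  v1 <- viterbi(m, f); v2 <- viterbi(m, f2)
  expect_identical(v1$states, v2$states)
  expect_identical(v1$log_prob, v2$log_prob)
  c1 <- call_clusters(m, f, path = v1); c2 <- call_clusters(m, f2, path = v2)
  expect_identical(c1$score, c2$score)
  expect_identical(c1$n_sites, c2$n_sites)
})

test_that("models survive a JSON round-trip bit-for-bit in behaviour", {
  set.seed(79)
  m <- random_model(D = 30L)
  f <- random_feats(6, D = 30L)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(viterbi(m2, f)$log_prob, viterbi(m, f)$log_prob,
               tolerance = 1e-12)
  expect_identical(viterbi(m2, f)$states, viterbi(m, f)$states)
  expect_equal(score_cluster(m2, f, 2:4), score_cluster(m, f, 2:4),
               tolerance = 1e-12)
})
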