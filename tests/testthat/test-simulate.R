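# Synthetic-data generator: determinism, planted truth, feature
# self-consistency, recovery metrics.

test_that("the same seed reproduces the dataset byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- sim_spec(seed = 99L, n_genes = 6L)
  simulate_dataset(spec, out_dir = d1)
  simulate_dataset(spec, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed differs
  simulate_dataset(sim_spec(seed = 100L, n_genes = 6L), out_dir = d2)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d2, "genome.fa"))))
})

test_that("written datasets load back into an equivalent bundle", {
  d <- withr::local_tempdir()
  ds <- simulate_dataset(sim_spec(seed = 17L, n_genes = 5L), out_dir = d)
  back <- load_dataset(d)
  expect_identical(back$seqs, ds$seqs)
  expect_identical(back$maf$rows, ds$maf$rows)
  expect_equal(total_branch_length(back$tree), total_branch_length(ds$tree),
               tolerance = 1e-9)
  expect_identical(back$clip$ph, ds$clip$ph)
  expect_identical(back$truth$members, ds$truth$members)
  expect_identical(back$tx$exons, ds$tx$exons)
})

test_that("scanning recovers exactly the planted sites", {
  ds <- shared_sim()$ds
  sites <- scan_region_set(ds$seqs, ds$spec$consensus, ds$spec$exclude)
  expect_identical(paste(sites$seq_id, sites$start),
                   paste(ds$site_labels$seq_id, ds$site_labels$start))
})

test_that("planted clusters respect the min-site and separation contracts", {
  ds <- shared_sim()$ds
  expect_true(all(ds$truth$n_sites >= 3L))
  seps <- ds$truth |>
    dplyr::group_by(seq_id) |>
    dplyr::summarise(min_gap = if (dplyr::n() < 2) Inf else
      min(start[-1] - end[-dplyr::n()]), .groups = "drop")
  expect_true(all(seps$min_gap >= ds$spec$cluster_min_separation))
})

test_that("full per-species conservation gives BLS 1 on planted sites", {
  ds <- simulate_dataset(sim_spec(seed = 31L, n_genes = 6L, p_keep_pos = 1,
                                  p_keep_neg = 1, noise_subst = 0))
  feats <- suppressWarnings(featurize_dataset(ds))
  expect_true(all(abs(feats$c - 1) < 1e-12))
})

test_that("per-label feature distributions separate as specified", {
  sim <- shared_sim()
  lab <- dplyr::inner_join(sim$feats, sim$ds$site_labels,
                           by = c("seq_id", "start"))
  agg <- lab |>
    dplyr::group_by(label) |>
    dplyr::summarise(c = mean(c), a = mean(a), .groups = "drop")
  expect_gt(agg$c[agg$label == "pos"], agg$c[agg$label == "neg"] + 0.2)
  expect_gt(agg$a[agg$label == "pos"], agg$a[agg$label == "neg"] + 0.15)
})

test_that("recovery metrics: identity, no calls, and the matching oracle", {
  truth <- tibble::tibble(seq_id = c("g1", "g1", "g2"),
                          start = c(100L, 700L, 50L),
                          end = c(180L, 760L, 120L))
  calls_same <- truth |> dplyr::mutate(score = c(5, 4, 3))
  rep1 <- recovery_report(truth, calls_same)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)

  rep0 <- recovery_report(truth, calls_same[0, ])
  expect_true(is.na(rep0$precision))
  expect_equal(rep0$recall, 0)

  # maximum-bipartite-matching oracle on random non-pathological fixtures
  max_matching <- function(adj) {
    # adj: logical calls x truth; Kuhn's augmenting-path algorithm
    nt <- ncol(adj)
    match_t <- rep(0L, nt)
    n <- 0L
    for (i in seq_len(nrow(adj))) {
      seen <- rep(FALSE, nt)
      aug <- function(u) {
        for (j in which(adj[u, ])) {
          if (!seen[j]) {
            seen[j] <<- TRUE
            if (match_t[j] == 0L || aug(match_t[j])) {
              match_t[j] <<- u
              return(TRUE)
            }
          }
        }
        FALSE
      }
      if (aug(i)) n <- n + 1L
    }
    n
  }
  set.seed(101)
  for (rep in 1:10) {
    nt <- sample(3:8, 1)
    t_start <- cumsum(sample(200:400, nt))
    truth <- tibble::tibble(seq_id = "g", start = t_start,
                            end = t_start + sample(40:80, nt, replace = TRUE))
    keep <- runif(nt) < 0.8
    calls <- truth[keep, ] |>
      dplyr::mutate(start = start + sample(-10:10, sum(keep), replace = TRUE),
                    end = end + sample(-10:10, sum(keep), replace = TRUE),
                    score = runif(sum(keep), 1, 10))
    extra_start <- max(truth$end) + cumsum(sample(300:400, 2))
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      seq_id = "g", start = extra_start, end = extra_start + 50L,
      score = c(1, 2)))
    got <- recovery_report(truth, calls, min_overlap = 0.5)
    adj <- matrix(FALSE, nrow(calls), nt)
    for (i in seq_len(nrow(calls))) {
      inter <- pmin(truth$end, calls$end[i]) - pmax(truth$start, calls$start[i])
      ro <- pmin(inter / (calls$end[i] - calls$start[i]),
                 inter / (truth$end - truth$start))
      adj[i, ] <- inter > 0 & ro >= 0.5
    }
    expect_identical(got$tp, max_matching(adj))
  }
})

test_that("generator pmf helpers are proper distributions", {
  expect_equal(sum(spacing_pmf(8, 4, 30)), 1, tolerance = 1e-12)
  expect_equal(sum(spacing_pmf(80, 4, 30)), 1, tolerance = 1e-12)
  expect_true(all(spacing_pmf(8, 4, 30)[1:3] == 0))
  tr <- toy_tree()
  expect_equal(sum(bls_pmf(tr, "A", 0.7, bins = 10)), 1, tolerance = 1e-12)
  expect_equal(sum(beta_pmf(c(8, 2), 20)), 1, tolerance = 1e-9)
  # p_keep = 1 puts all BLS mass in the top bin
  pm <- bls_pmf(tr, "A", 1, bins = 10)
  expect_equal(pm[10], 1, tolerance = 1e-12)
})
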