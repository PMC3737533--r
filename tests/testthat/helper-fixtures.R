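# Shared fixtures: tiny trees, random models/feature sequences, toy
# transcript models. Everything is built in code at test time.

toy_tree <- function() {
  ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.4);")
}

# A feature distribution with given (or random) masses, bypassing
# estimation; used to assemble models with known emissions.
fd_fixed <- function(feature, mass, stratum = "ALL", D_cens = NULL) {
  mass <- mass / sum(mass)
  breaks <- if (feature == "d") seq(0.5, length(mass) + 0.5, by = 1) else
    seq(0, 1, length.out = length(mass) + 1)
  structure(list(feature = feature, breaks = breaks, mass = mass,
                 n = length(mass), pseudocount = 1, stratum = stratum,
                 D_cens = if (feature == "d") length(mass) else NULL),
            class = "feature_distribution")
}

strata_fds <- function(make) {
  stats::setNames(lapply(REGION_TYPES, function(r) make(r)), REGION_TYPES)
}

# Random six-state model over D spacing bins and B value bins.
random_model <- function(D = 6L, B = 5L, feature_set = c("d", "c", "a")) {
  allow <- motifclust:::allowed_transitions()
  tr <- matrix(0, 6, 6, dimnames = dimnames(allow))
  for (s in rownames(allow)) {
    p <- rexp(2)
    tr[s, which(allow[s, ])] <- p / sum(p)
  }
  p0 <- rexp(2)
  rand_fd <- function(feature, stratum = "ALL") {
    fd_fixed(feature, rexp(if (feature == "d") D else B), stratum)
  }
  emis <- list(d = list(pos = rand_fd("d"), neg = rand_fd("d")))
  if ("c" %in% feature_set) {
    emis$c <- list(pos = strata_fds(function(r) rand_fd("c", r)),
                   neg = strata_fds(function(r) rand_fd("c", r)))
  }
  if ("a" %in% feature_set) {
    emis$a <- list(pos = rand_fd("a"), neg = rand_fd("a"))
  }
  hmm_model(init = c(S_MINUS = p0[1] / sum(p0), S_PLUS = p0[2] / sum(p0)),
            trans = tr, emis = emis, feature_set = feature_set, D_cens = D)
}

# Symmetric model: identical pos/neg components everywhere, uniform
# transitions; every log-likelihood ratio is exactly 0.
symmetric_model <- function(D = 6L, B = 5L) {
  allow <- motifclust:::allowed_transitions()
  tr <- matrix(0, 6, 6, dimnames = dimnames(allow))
  for (s in rownames(allow)) tr[s, which(allow[s, ])] <- 0.5
  mk_d <- fd_fixed("d", rep(1, D))
  mk_v <- function(stratum = "ALL") fd_fixed("c", seq_len(B), stratum)
  emis <- list(
    d = list(pos = mk_d, neg = mk_d),
    c = list(pos = strata_fds(mk_v), neg = strata_fds(mk_v)),
    a = list(pos = fd_fixed("a", rep(1, B)), neg = fd_fixed("a", rep(1, B)))
  )
  hmm_model(init = c(S_MINUS = 0.5, S_PLUS = 0.5), trans = tr, emis = emis,
            D_cens = D)
}

# Random feature sequence compatible with random_model(D, B).
random_feats <- function(n, D = 6L, na_frac = 0.15, seq_id = "s") {
  gaps <- sample(seq_len(D), max(n - 1, 0), replace = TRUE)
  start <- cumsum(c(0L, gaps)) * 4L
  tibble::tibble(
    seq_id = seq_id, start = start, end = start + 4L, strand = "+",
    d = c(0L, gaps),
    c = runif(n),
    a = ifelse(runif(n) < na_frac, NA_real_, runif(n)),
    region = factor(sample(REGION_TYPES, n, replace = TRUE),
                    levels = REGION_TYPES)
  )
}

# A model whose cluster side is strongly favoured on every feature.
separated_model <- function(D = 10L, B = 8L, strength = 6) {
  allow <- motifclust:::allowed_transitions()
  tr <- matrix(0, 6, 6, dimnames = dimnames(allow))
  for (s in rownames(allow)) tr[s, which(allow[s, ])] <- 0.5
  up <- exp(strength * seq(0, 1, length.out = B))     # mass on high values
  down <- rev(up)
  d_pos <- exp(-seq_len(D))                            # tight spacing
  d_neg <- rev(d_pos)
  emis <- list(
    d = list(pos = fd_fixed("d", d_pos), neg = fd_fixed("d", d_neg)),
    c = list(pos = strata_fds(function(r) fd_fixed("c", up, r)),
             neg = strata_fds(function(r) fd_fixed("c", down, r))),
    a = list(pos = fd_fixed("a", up), neg = fd_fixed("a", down))
  )
  hmm_model(init = c(S_MINUS = 0.5, S_PLUS = 0.5), trans = tr, emis = emis,
            D_cens = D)
}

# Toy transcript tibble; exons as (start,end) pairs, optional CDS.
toy_tx <- function(tx_id = "t1", seq_id = "chr1", strand = "+",
                   exons = list(c(100L, 200L), c(300L, 400L)),
                   cds = NULL) {
  ex <- tibble::tibble(start = vapply(exons, `[`, 1L, 1),
                       end = vapply(exons, `[`, 2L, 2))
  tibble::tibble(
    tx_id = tx_id, seq_id = seq_id, start = min(ex$start), end = max(ex$end),
    strand = strand,
    cds_start = if (is.null(cds)) NA_integer_ else cds[1],
    cds_end = if (is.null(cds)) NA_integer_ else cds[2],
    exons = list(ex)
  )
}

# Independent edge-enumeration oracle for the minimal spanning subtree
# length: an edge is counted iff it lies on the path between two members.
spanning_length_oracle <- function(tree, species) {
  tips <- match(species, tree$tip.label)
  if (length(tips) < 2) return(0)
  edges_on_paths <- integer()
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (j <= i) next
      np <- ape::nodepath(tree, tips[i], tips[j])
      for (k in seq_len(length(np) - 1)) {
        e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                   (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
        edges_on_paths <- c(edges_on_paths, e)
      }
    }
  }
  sum(tree$edge.length[unique(edges_on_paths)])
}

# Small simulated bundle reused by several test files (computed once).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_spec(seed = 424, n_genes = 25))
      feats <- suppressWarnings(featurize_dataset(ds))
      cache <<- list(ds = ds, feats = feats)
    }
    cache
  }
})
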