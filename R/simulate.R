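# Synthetic transcriptome generator: genes with planted motif-site clusters
# whose spacing, per-species conservation and accessibility follow declared
# distributions, plus CLIP-like peaks over planted clusters. Everything is
# deterministic under the mandatory seed, so training, decoding and
# evaluation are testable end to end without downloads.

#' Specification of a synthetic dataset
#'
#' Defaults emulate the statistical structure of the study conditions:
#' in-cluster spacing much tighter than background (geometric with mean 8 vs
#' 80, conditioned on >= motif length so planted 4-mers never collide,
#' censoring at 30 downstream), conservation much higher for bound sites
#' (per-species motif retention 0.9 vs 0.3), bound sites more accessible
#' (Beta(8,2) vs Beta(2,2)), and CLIP peak heights proportional to cluster
#' size so that weak clusters sometimes lack a qualifying footprint.
#'
#' @param seed Integer seed (mandatory; every draw depends on it).
#' @param n_genes Number of genes (one sequence per gene).
#' @param consensus,exclude Motif consensus to plant and scan.
#' @param n_species Number of aligned species (including the reference).
#' @param tree Optional `phylo`; generated randomly (under the seed) if
#'   `NULL`. Leaves are renamed `sp1..spK`; `sp1` is the reference.
#' @param n_exons Exons per gene.
#' @param exon_len,intron_len Length ranges (uniform) in nt.
#' @param frac_noncoding Fraction of genes without a CDS.
#' @param clusters_per_gene Poisson mean of planted clusters per gene.
#' @param cluster_min_separation Minimum nt between planted clusters, so
#'   that planted clusters are distinct entities: with background spacing
#'   around 80 nt, 400 nt guarantees several genuine background sites
#'   between neighbouring clusters (closer plantings would form one
#'   contiguous high-affinity region, not two clusters).
#' @param cluster_edge_margin Minimum nt between a planted cluster and the
#'   sequence ends, so that every cluster sits in background context on both
#'   sides (real scan sequences are genes with kilobases of flank; a cluster
#'   flush against a sequence end would let decoding absorb the short tail
#'   for free).
#' @param sites_per_cluster_min,sites_per_cluster_extra Sites per cluster =
#'   min + Poisson(extra).
#' @param spacing_mean_pos,spacing_mean_neg Geometric spacing means
#'   (start-to-start, conditioned on >= motif length).
#' @param p_keep_pos,p_keep_neg Per-species probability that a planted site
#'   retains its motif, by site label (i.i.d. across species).
#' @param acc_pos,acc_neg Beta shape pairs for per-site accessibility.
#' @param acc_background Accessibility fill outside motif sites.
#' @param ph_per_site Mean CLIP peak height per member site: peak height is
#'   drawn as NegBin(mu = ph_per_site * n_sites, size = ph_dispersion).
#' @param ph_dispersion Negative-binomial size of peak heights. CLIP tag
#'   counts are strongly overdispersed (they compound binding affinity with
#'   transcript abundance), so conditioning on cluster size still leaves
#'   wide peak-height spread; small `size` captures that.
#' @param false_peak_rate Per-gene probability of one spurious weak peak.
#' @param ph_false_mean Mean (minus 1) of spurious peak heights.
#' @param peak_jitter SD of Gaussian jitter on peak positions (0 = peaks
#'   exactly at cluster midpoints).
#' @param noise_subst Per-base substitution rate in non-reference species
#'   outside motif sites.
#' @param ext Flank used downstream when masking/training.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(seed,
                     n_genes = 60L,
                     consensus = "YCAY", exclude = character(),
                     n_species = 8L, tree = NULL,
                     n_exons = 3L, exon_len = c(150L, 350L),
                     intron_len = c(250L, 600L),
                     frac_noncoding = 0.2,
                     clusters_per_gene = 1,
                     cluster_min_separation = 400L,
                     cluster_edge_margin = 300L,
                     sites_per_cluster_min = 3L,
                     sites_per_cluster_extra = 4,
                     spacing_mean_pos = 8, spacing_mean_neg = 80,
                     p_keep_pos = 0.9, p_keep_neg = 0.3,
                     acc_pos = c(8, 2), acc_neg = c(2, 2),
                     acc_background = 0.5,
                     ph_per_site = 5, ph_dispersion = 2,
                     false_peak_rate = 0.05,
                     ph_false_mean = 5, peak_jitter = 0,
                     noise_subst = 0.01,
                     ext = 1000L) {
  if (missing(seed)) abort("sim_spec: a seed is mandatory")
  stopifnot(p_keep_pos >= 0, p_keep_pos <= 1, p_keep_neg >= 0,
            p_keep_neg <= 1, sites_per_cluster_min >= 1,
            spacing_mean_pos >= nchar(consensus) / 2)
  as.list(environment()) |> structure(class = "sim_spec")
}

# Spacing sampler/pmf: geometric (support 1, 2, ...) with the given mean,
# conditioned on >= min_d (memorylessness: min_d - 1 + geometric).
sample_spacing <- function(n, mean, min_d) {
  (min_d - 1L) + rgeom(n, 1 / mean) + 1L
}

#' Exact censored pmf of the generator's spacing distribution
#'
#' Bin masses on the unit bins `1 ... D_cens` (last bin censored) for the
#' conditioned geometric spacing used by [simulate_dataset()]; the reference
#' truth for emission-recovery checks.
#'
#' @param mean Geometric mean parameter.
#' @param min_d Minimum spacing (motif length).
#' @param D_cens Censoring threshold.
#' @return Numeric vector of `D_cens` masses summing to 1.
#' @export
spacing_pmf <- function(mean, min_d, D_cens = 30L) {
  p <- 1 / mean
  d <- seq_len(D_cens)
  pmf <- ifelse(d >= min_d, stats::dgeom(d - min_d, p), 0)
  pmf[D_cens] <- ifelse(D_cens >= min_d, 1 - stats::pgeom(D_cens - min_d - 1, p), 0)
  pmf
}

#' Exact binned pmf of the generator's branch length score distribution
#'
#' Enumerates all subsets of non-reference species (kept i.i.d. with
#' probability `p_keep`) and accumulates the exact probability mass of each
#' BLS bin.
#'
#' @param tree `phylo` tree.
#' @param ref_species Reference leaf (always conserved).
#' @param p_keep Per-species retention probability.
#' @param bins Number of equal bins on `[0, 1]`.
#' @return Numeric vector of `bins` masses summing to 1.
#' @export
bls_pmf <- function(tree, ref_species, p_keep, bins = 20L) {
  others <- setdiff(tree$tip.label, ref_species)
  if (length(others) > 14) abort("bls_pmf enumerates subsets; use <= 15 species")
  mass <- numeric(bins)
  for (code in 0:(2^length(others) - 1)) {
    keep <- as.logical(bitwAnd(code, 2^(seq_along(others) - 1)))
    pr <- prod(ifelse(keep, p_keep, 1 - p_keep))
    cval <- spanning_branch_length(tree, c(ref_species, others[keep]))
    b <- min(floor(cval * bins) + 1, bins)
    mass[b] <- mass[b] + pr
  }
  mass
}

#' Exact binned pmf of a Beta accessibility distribution
#'
#' @param shape Length-2 vector of Beta shapes.
#' @param bins Number of equal bins on `[0, 1]`.
#' @return Numeric vector of `bins` masses summing to 1.
#' @export
beta_pmf <- function(shape, bins = 20L) {
  edges <- seq(0, 1, length.out = bins + 1)
  diff(pbeta(edges, shape[1], shape[2]))
}

BASES <- c("A", "C", "G", "T")

# Mutate one position of `chars` inside [s0+1, s0+k] so the window no longer
# matches the consensus; positions in `protected` are untouchable.
break_window <- function(chars, s0, letters_sets, protected, rx) {
  k <- length(letters_sets)
  offs <- sample(seq_len(k))
  for (off in offs) {
    pos <- s0 + off
    if (pos %in% protected) next
    allowed <- letters_sets[[off]]
    forbidden <- setdiff(BASES, allowed)
    if (length(forbidden) == 0) next
    chars[pos] <- sample(forbidden, 1)
    win <- paste(chars[(s0 + 1):(s0 + k)], collapse = "")
    if (!grepl(rx, win)) return(chars)
  }
  chars
}

# Remove every consensus match from `chars` except at `planted` starts
# (0-based); bases inside planted spans are protected.
scrub_matches <- function(chars, consensus, exclude, planted = integer(),
                          motif_len = nchar(consensus), max_iter = 50L) {
  rx <- consensus_regex(consensus, exclude)
  rx_look <- paste0("(?=", rx, ")")
  letters_sets <- IUPAC_MAP[strsplit(toupper(chartr("Uu", "Tt", consensus)),
                                     "")[[1]]]
  protected <- unique(unlist(lapply(planted, function(s) (s + 1):(s + motif_len))))
  for (iter in seq_len(max_iter)) {
    seqstr <- paste(chars, collapse = "")
    m <- gregexpr(rx_look, seqstr, perl = TRUE)[[1]]
    starts0 <- if (m[1] == -1) integer() else as.integer(m) - 1L
    extra <- setdiff(starts0, planted)
    if (length(extra) == 0) break
    for (s0 in extra) {
      chars <- break_window(chars, s0, letters_sets, protected, rx)
    }
  }
  chars
}

#' Generate a synthetic dataset with planted motif clusters
#'
#' See [sim_spec()] for the generating process. When `out_dir` is given the
#' seven standard files are written there (`genome.fa`, `aln.maf`,
#' `tree.nwk`, `acc.bedgraph`, `genes.bed12`, `clip.bed`, `truth.bed`);
#' output is byte-identical under the same spec and seed.
#'
#' @param spec A [sim_spec()].
#' @param out_dir Optional output directory.
#' @return List of class `sim_dataset`: `seqs`, `maf`, `tree`, `track`,
#'   `tx`, `clip`, `truth` (planted clusters with `members`), `site_labels`
#'   (per planted site: `seq_id`, `start`, `label`), `spec`, and `paths`
#'   when files were written.
#' @export
simulate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  k <- nchar(spec$consensus)
  words <- expand_consensus(spec$consensus, spec$exclude)
  withr::with_seed(spec$seed, {
    tree <- spec$tree
    if (is.null(tree)) {
      tree <- ape::rtree(spec$n_species, br = function(n) runif(n, 0.05, 0.5))
      tree$tip.label <- paste0("sp", seq_len(spec$n_species))
    }
    validate_tree(tree, "simulation tree")
    ref_species <- tree$tip.label[1]
    species <- tree$tip.label
    seqs <- list(); maf_rows <- list(); track_rows <- list()
    tx_rows <- list(); clip_rows <- list(); truth_rows <- list()
    label_rows <- list()
    for (g in seq_len(spec$n_genes)) {
      sid <- sprintf("g%03d", g)
      exl <- sample(spec$exon_len[1]:spec$exon_len[2], spec$n_exons,
                    replace = TRUE)
      inl <- sample(spec$intron_len[1]:spec$intron_len[2], spec$n_exons - 1,
                    replace = TRUE)
      if (2L * spec$ext < max(inl)) {
        abort("infeasible spec: intron longer than twice the mask extension")
      }
      L <- sum(exl) + sum(inl)
      if (L < 40L * k) abort("infeasible spec: gene too short for planting")
      chars <- sample(BASES, L, replace = TRUE)
      chars <- scrub_matches(chars, spec$consensus, spec$exclude)
      # plant clusters
      n_c <- rpois(1, spec$clusters_per_gene)
      spans <- matrix(numeric(0), ncol = 2)
      cluster_sites <- list()
      for (ci in seq_len(n_c)) {
        n_s <- spec$sites_per_cluster_min + rpois(1, spec$sites_per_cluster_extra)
        gaps <- sample_spacing(n_s - 1, spec$spacing_mean_pos, k)
        rel <- c(0L, cumsum(gaps))
        span_w <- rel[n_s] + k
        placed <- FALSE
        lo <- spec$cluster_edge_margin
        hi <- L - span_w - spec$cluster_edge_margin
        for (try in seq_len(if (hi >= lo) 20L else 0L)) {
          s0 <- sample(lo:hi, 1)
          if (nrow(spans) == 0 ||
              all(s0 > spans[, 2] + spec$cluster_min_separation |
                  s0 + span_w < spans[, 1] - spec$cluster_min_separation)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) next
        starts <- s0 + rel
        spans <- rbind(spans, c(starts[1], starts[n_s] + k))
        cluster_sites[[length(cluster_sites) + 1L]] <- starts
      }
      # background sites over cluster-free sequence
      bg <- integer()
      pos <- sample_spacing(1, spec$spacing_mean_neg, k)
      while (pos + k <= L) {
        clash <- nrow(spans) > 0 &&
          any(pos + k > spans[, 1] - k & pos < spans[, 2] + k)
        if (!clash) bg <- c(bg, pos)
        pos <- pos + sample_spacing(1, spec$spacing_mean_neg, k)
      }
      all_sites <- tibble(
        start = c(unlist(cluster_sites), bg),
        label = c(rep("pos", length(unlist(cluster_sites))),
                  rep("neg", length(bg)))
      ) |> arrange(.data$start)
      # plant words, then repair any accidental extra matches
      for (i in seq_len(nrow(all_sites))) {
        w <- sample(words, 1)
        chars[(all_sites$start[i] + 1):(all_sites$start[i] + k)] <-
          strsplit(w, "")[[1]]
      }
      chars <- scrub_matches(chars, spec$consensus, spec$exclude,
                             planted = all_sites$start, motif_len = k)
      refseq <- paste(chars, collapse = "")
      # species rows: background substitution noise outside sites, motif
      # retained per species with p_keep by label
      site_cols <- unlist(lapply(all_sites$start, function(s) (s + 1):(s + k)))
      letters_sets <- IUPAC_MAP[strsplit(toupper(spec$consensus), "")[[1]]]
      rx <- consensus_regex(spec$consensus, spec$exclude)
      texts <- character(length(species))
      texts[1] <- refseq
      for (sj in seq_along(species)[-1]) {
        sc <- chars
        elig <- setdiff(which(runif(L) < spec$noise_subst), site_cols)
        if (length(elig) > 0) {
          sc[elig] <- vapply(sc[elig], function(b) sample(setdiff(BASES, b), 1), "")
        }
        p_keep <- ifelse(all_sites$label == "pos", spec$p_keep_pos,
                         spec$p_keep_neg)
        lost <- runif(nrow(all_sites)) >= p_keep
        for (i in which(lost)) {
          sc <- break_window(sc, all_sites$start[i], letters_sets,
                             integer(), rx)
        }
        # noise may have created stray matches; they only matter inside
        # site windows, which noise never touches, so leave them
        texts[sj] <- paste(sc, collapse = "")
      }
      seqs[[sid]] <- refseq
      maf_rows[[g]] <- tibble(
        seq_id = sid, start = 0L, end = L, ref_species = ref_species,
        rows = list(tibble(species = species, text = texts))
      )
      # accessibility
      av <- rep(spec$acc_background, L)
      if (nrow(all_sites) > 0) {
        draws <- ifelse(all_sites$label == "pos",
                        rbeta(nrow(all_sites), spec$acc_pos[1], spec$acc_pos[2]),
                        rbeta(nrow(all_sites), spec$acc_neg[1], spec$acc_neg[2]))
        draws <- round(draws, 4)
        for (i in seq_len(nrow(all_sites))) {
          av[(all_sites$start[i] + 1):(all_sites$start[i] + k)] <- draws[i]
        }
      }
      r <- rle(av)
      ends <- cumsum(r$lengths)
      track_rows[[g]] <- tibble(seq_id = sid,
                                start = as.integer(ends - r$lengths),
                                end = as.integer(ends), value = r$values)
      # annotation
      ex_start <- cumsum(c(0L, (exl + c(inl, 0))[-spec$n_exons]))
      ex <- tibble(start = as.integer(ex_start),
                   end = as.integer(ex_start + exl))
      coding <- runif(1) >= spec$frac_noncoding
      tx_rows[[g]] <- tibble(
        tx_id = sprintf("tx%03d", g), seq_id = sid, start = 0L,
        end = as.integer(L), strand = "+",
        cds_start = if (coding) as.integer(ex$start[1] + exl[1] %/% 2) else NA_integer_,
        cds_end = if (coding) as.integer(ex$start[spec$n_exons] + exl[spec$n_exons] %/% 2) else NA_integer_,
        exons = list(ex)
      )
      # CLIP peaks over planted clusters; occasional weak false peak
      for (ci in seq_along(cluster_sites)) {
        st <- cluster_sites[[ci]]
        span <- c(st[1], st[length(st)] + k)
        peak <- (span[1] + span[2]) %/% 2
        if (spec$peak_jitter > 0) {
          peak <- peak + as.integer(round(stats::rnorm(1, 0, spec$peak_jitter)))
          peak <- max(span[1], min(span[2] - 1L, peak))
        }
        clip_rows[[length(clip_rows) + 1L]] <- tibble(
          seq_id = sid, start = as.integer(span[1]), end = as.integer(span[2]),
          name = sprintf("clip_%s_%d", sid, ci), score = 0, strand = "+",
          peak = as.integer(peak),
          ph = as.integer(max(1, stats::rnbinom(1, size = spec$ph_dispersion,
                                                mu = spec$ph_per_site * length(st))))
        )
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          seq_id = sid, start = as.integer(span[1]), end = as.integer(span[2]),
          name = sprintf("truth_%s_%d", sid, ci), score = 0, strand = "+",
          n_sites = length(st), members = list(as.integer(st))
        )
      }
      if (runif(1) < spec$false_peak_rate) {
        p <- sample.int(L - 50L, 1) + 20L
        free <- nrow(spans) == 0 || all(p < spans[, 1] | p >= spans[, 2])
        if (free) {
          clip_rows[[length(clip_rows) + 1L]] <- tibble(
            seq_id = sid, start = as.integer(max(0L, p - 20L)),
            end = as.integer(min(L, p + 20L)),
            name = sprintf("clipfp_%s", sid), score = 0, strand = "+",
            peak = as.integer(p), ph = as.integer(1 + rpois(1, spec$ph_false_mean))
          )
        }
      }
      if (nrow(all_sites) > 0) {
        label_rows[[g]] <- tibble(seq_id = sid,
                                  start = as.integer(all_sites$start),
                                  label = all_sites$label)
      }
    }
    ds <- structure(list(
      seqs = unlist(seqs),
      maf = bind_rows(maf_rows),
      tree = tree,
      ref_species = ref_species,
      track = bind_rows(track_rows),
      tx = bind_rows(tx_rows),
      clip = if (length(clip_rows)) bind_rows(clip_rows) |>
        arrange(.data$seq_id, .data$start) else
          tibble(seq_id = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character(),
                 peak = integer(), ph = integer()),
      truth = if (length(truth_rows)) bind_rows(truth_rows) |>
        arrange(.data$seq_id, .data$start) else
        tibble(seq_id = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character(),
               n_sites = integer(), members = list()),
      site_labels = bind_rows(label_rows),
      spec = spec
    ), class = "sim_dataset")
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "genome.fa"),
      maf = file.path(out_dir, "aln.maf"),
      tree = file.path(out_dir, "tree.nwk"),
      track = file.path(out_dir, "acc.bedgraph"),
      annotation = file.path(out_dir, "genes.bed12"),
      clip = file.path(out_dir, "clip.bed"),
      truth = file.path(out_dir, "truth.bed")
    )
    write_fasta(ds$seqs, paths$fasta)
    write_maf(ds$maf, paths$maf, src_sizes = nchar(ds$seqs))
    write_newick(ds$tree, paths$tree)
    write_accessibility(ds$track, paths$track)
    write_bed12(ds$tx, paths$annotation)
    write_bed(ds$clip, paths$clip, kind = "clip")
    write_bed(ds$truth, paths$truth, kind = "cluster")
    ds$paths <- paths
  }
  ds
}

#' Load a dataset directory written by [simulate_dataset()]
#'
#' @param dir Directory containing the seven standard files.
#' @return A `sim_dataset`-shaped list (without truth labels if absent).
#' @export
load_dataset <- function(dir) {
  tree <- read_newick(file.path(dir, "tree.nwk"))
  structure(list(
    seqs = read_fasta(file.path(dir, "genome.fa")),
    maf = read_maf(file.path(dir, "aln.maf")),
    tree = tree,
    ref_species = tree$tip.label[1],
    track = read_accessibility(file.path(dir, "acc.bedgraph")),
    tx = read_bed12(file.path(dir, "genes.bed12")),
    clip = read_bed(file.path(dir, "clip.bed"), kind = "clip"),
    truth = if (file.exists(file.path(dir, "truth.bed")))
      read_bed(file.path(dir, "truth.bed"), kind = "cluster") else NULL
  ), class = "sim_dataset")
}

#' Sample labeled site sequences from a known transition structure
#'
#' Simulates state paths of the six-state chain (given initial and
#' transition probabilities on the allowed edges) and returns the induced
#' label sequences — the ground truth for transition-estimation recovery
#' checks.
#'
#' @param trans 6x6 transition probability matrix (allowed edges only).
#' @param init Named initial probabilities of `S_MINUS`/`S_PLUS`.
#' @param n_seqs Number of sequences.
#' @param len Sites per sequence.
#' @param seed Integer seed.
#' @return Tibble `(region_id, label)` in sequence order.
#' @export
sample_hmm_labels <- function(trans, init, n_seqs, len, seed) {
  withr::with_seed(seed, {
    out <- vector("list", n_seqs)
    for (i in seq_len(n_seqs)) {
      states <- character(len)
      states[1] <- sample(c("S_MINUS", "S_PLUS"), 1,
                          prob = c(init[["S_MINUS"]], init[["S_PLUS"]]))
      for (t in seq_len(len - 1)) {
        p <- trans[states[t], ]
        states[t + 1] <- sample(HMM_STATES, 1, prob = p)
      }
      out[[i]] <- tibble(
        region_id = sprintf("r%05d", i),
        label = ifelse(states %in% CLUSTER_STATES, "pos", "neg")
      )
    }
    bind_rows(out)
  })
}

#' Precision/recall of cluster calls against planted truth
#'
#' A call matches a planted cluster when their reciprocal overlap is at
#' least `min_overlap`; matching is one-to-one, greedy by descending call
#' score.
#'
#' @param truth Truth tibble (planted clusters).
#' @param calls Scored cluster calls.
#' @param min_overlap Minimum reciprocal overlap fraction.
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision` (`NA` when there
#'   are no calls), `recall`, `f1`.
#' @export
recovery_report <- function(truth, calls, min_overlap = 0.5) {
  if (nrow(calls) == 0) {
    return(tibble(tp = 0L, fp = 0L, fn = nrow(truth),
                  precision = NA_real_, recall = 0, f1 = NA_real_))
  }
  calls <- calls |> arrange(desc(.data$score))
  matched_truth <- rep(FALSE, nrow(truth))
  tp <- 0L
  for (i in seq_len(nrow(calls))) {
    cand <- which(!matched_truth & truth$seq_id == calls$seq_id[i])
    if (length(cand) == 0) next
    inter <- pmin(truth$end[cand], calls$end[i]) -
      pmax(truth$start[cand], calls$start[i])
    ro <- pmin(inter / (calls$end[i] - calls$start[i]),
               inter / (truth$end[cand] - truth$start[cand]))
    ro[inter <= 0] <- 0
    j <- which.max(ro)
    if (ro[j] >= min_overlap) {
      matched_truth[cand[j]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(calls) - tp
  fn <- nrow(truth) - tp
  precision <- tp / nrow(calls)
  recall <- if (nrow(truth) > 0) tp / nrow(truth) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1)
}
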