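# Site features consumed by the HMM: censored spacing d, branch length score
# conservation c (region-stratified), accessibility a.

#' Censored spacing to the preceding motif site
#'
#' Adds a column `d`: the start-to-start distance to the preceding site on
#' the same scan sequence, censored at `D_cens` nt (the implicit limit on
#' spacing allowed inside a cluster). The first site of each sequence gets
#' the sentinel `d = 0`, consumed only by the sequence-initial HMM states
#' whose distance emission is degenerate at 0; real inter-site distances are
#' >= 1, so the sentinel never collides.
#'
#' @param sites Site tibble (see [scan_sequence()]), sorted by start within
#'   each `seq_id`; an error is raised otherwise.
#' @param D_cens Censoring threshold in nt (default 30).
#' @return `sites` with a `d` column.
#' @export
compute_spacing <- function(sites, D_cens = 30L) {
  stopifnot(D_cens >= 1)
  if (nrow(sites) == 0) return(mutate(sites, d = integer()))
  sites |>
    group_by(.data$seq_id) |>
    group_modify_keep(function(d0) {
      if (is.unsorted(d0$start, strictly = TRUE)) {
        abort("sites must be strictly sorted by start within each sequence")
      }
      d0$d <- c(0L, pmin(diff(d0$start), as.integer(D_cens)))
      d0
    })
}

# group_modify that keeps the grouping column; avoids repeating boilerplate.
group_modify_keep <- function(grouped, f) {
  grouped |>
    dplyr::group_modify(function(d, g) f(d)) |>
    ungroup()
}

#' Branch length score of a set of species on a tree
#'
#' Total branch length of the minimal subtree spanning `species`, divided by
#' the total branch length of the tree. Zero by convention when fewer than
#' two species are given or the tree has zero total length.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param species Character vector of leaf names.
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:0.1,B:0.2):0.1,C:0.4);")
#' spanning_branch_length(tr, c("A", "B"))   # 0.3 / 0.8
spanning_branch_length <- function(tree, species) {
  ctx <- bls_context(tree)
  idx <- match(species, tree$tip.label)
  if (anyNA(idx)) {
    abort(sprintf("species not in tree: %s",
                  paste(species[is.na(idx)], collapse = ", ")))
  }
  subtree_length_ctx(ctx, sort(unique(idx))) / max(ctx$total, .Machine$double.eps) *
    (ctx$total > 0)
}

# Precompute, per edge, the set of tips below it; memoize subtree lengths
# per species subset.
bls_context <- function(tree) {
  validate_tree(tree)
  nt <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- i
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  list(
    tree = tree,
    total = sum(tree$edge.length),
    edge_below = lapply(tree$edge[, 2], function(ch) below[[ch]]),
    edge_len = tree$edge.length,
    n_tips = nt,
    cache = new.env(parent = emptyenv())
  )
}

# Minimal spanning subtree length for tip indices `idx` (sorted, unique).
# An edge belongs to the subtree iff it separates two members.
subtree_length_ctx <- function(ctx, idx) {
  if (length(idx) < 2) return(0)
  key <- paste(idx, collapse = ",")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- length(idx)
  len <- 0
  for (k in seq_along(ctx$edge_below)) {
    inb <- sum(ctx$edge_below[[k]] %in% idx)
    if (inb > 0 && inb < m) len <- len + ctx$edge_len[k]
  }
  ctx$cache[[key]] <- len
  len
}

#' Branch length score conservation of motif sites
#'
#' For each site, the species whose aligned orthologous window (the site
#' span +/- `slop` reference nt, gaps removed) still contains an exact
#' consensus match form the conserved set `S` (the reference species is
#' always a member). `c` is the branch length of the minimal subtree of the
#' tree spanning `S`, divided by the total branch length. Sites not fully
#' covered by a single alignment block, or trees with zero total length,
#' give `c = 0`; species absent from a block are absent from `S`.
#'
#' @param sites Site tibble.
#' @param maf Alignment blocks as returned by [read_maf()].
#' @param tree `phylo` tree whose leaves cover the alignment species.
#' @param ref_species Reference species (must be a tree leaf).
#' @param consensus,exclude Consensus definition used to test presence.
#' @param slop Extra reference nt allowed on each side of the site window.
#' @return `sites` with a `c` column in `[0, 1]`.
#' @export
compute_bls <- function(sites, maf, tree, ref_species, consensus,
                        exclude = character(), slop = 0L) {
  if (!ref_species %in% tree$tip.label) {
    abort(sprintf("reference species '%s' is not a leaf of the tree",
                  ref_species))
  }
  ctx <- bls_context(tree)
  rx <- consensus_regex(consensus, exclude)
  cvals <- numeric(nrow(sites))
  if (nrow(sites) == 0) return(mutate(sites, c = numeric()))
  for (sid in unique(sites$seq_id)) {
    sidx <- which(sites$seq_id == sid)
    bl <- maf[maf$seq_id == sid, , drop = FALSE]
    if (nrow(bl) == 0) next
    bi <- findInterval(sites$start[sidx], bl$start)
    covered <- bi >= 1L & bi <= nrow(bl)
    covered[covered] <- sites$end[sidx][covered] <= bl$end[bi[covered]]
    for (b in unique(bi[covered])) {
      here <- sidx[covered & bi == b]
      rows <- bl$rows[[b]]
      if (rows$species[1] != bl$ref_species[b]) {
        abort("first alignment row is not the reference")
      }
      ref_chars <- strsplit(rows$text[1], "", fixed = TRUE)[[1]]
      notgap <- ref_chars != "-"
      col_of_u <- which(notgap)              # column of k-th ungapped base
      size <- length(col_of_u)
      rel_s <- pmax(sites$start[here] - bl$start[b] - as.integer(slop), 0L)
      rel_e <- pmin(sites$end[here] - bl$start[b] + as.integer(slop), size)
      lo <- col_of_u[rel_s + 1L]
      hi <- col_of_u[rel_e]
      present <- matrix(FALSE, length(here), nrow(rows))
      for (j in seq_len(nrow(rows))) {
        win <- substring(rows$text[j], lo, hi)
        win <- toupper(gsub("-", "", win, fixed = TRUE))
        present[, j] <- grepl(rx, win)
      }
      sp_idx <- match(rows$species, tree$tip.label)
      if (anyNA(sp_idx)) {
        abort(sprintf("alignment species missing from tree: %s",
                      paste(rows$species[is.na(sp_idx)], collapse = ", ")))
      }
      ref_tip <- match(ref_species, tree$tip.label)
      for (r in seq_along(here)) {
        members <- unique(c(ref_tip, sp_idx[present[r, ]]))
        cvals[here[r]] <- if (ctx$total > 0) {
          subtree_length_ctx(ctx, sort(members)) / ctx$total
        } else 0
      }
    }
  }
  mutate(sites, c = pmin(pmax(cvals, 0), 1))   # guard float round-off
}

#' Accessibility of motif sites
#'
#' Adds a column `a`: the mean per-base single-strandedness probability over
#' the site span. With `missing_policy = "drop_feature"` (default) a site
#' with any uncovered base gets `a = NA`, and the accessibility term is
#' omitted from its emissions symmetrically across all states;
#' `"mean_of_present"` averages the covered bases instead.
#'
#' @param sites Site tibble.
#' @param track Accessibility track (see [read_accessibility()]), or `NULL`
#'   for the uniform 0.5 fallback that keeps pipelines runnable without a
#'   track.
#' @param missing_policy `"drop_feature"` or `"mean_of_present"`.
#' @return `sites` with an `a` column (`NA` = missing).
#' @export
compute_accessibility <- function(sites, track,
                                  missing_policy = c("drop_feature",
                                                     "mean_of_present")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(sites) == 0) return(mutate(sites, a = numeric()))
  if (is.null(track)) return(mutate(sites, a = 0.5))
  k <- max(sites$end - sites$start)
  vals <- matrix(NA_real_, nrow(sites), k)
  for (sid in unique(sites$seq_id)) {
    sidx <- which(sites$seq_id == sid)
    tr <- track[track$seq_id == sid, , drop = FALSE]
    if (nrow(tr) == 0) next
    for (off in seq_len(k) - 1L) {
      pos <- sites$start[sidx] + off
      inside <- pos < sites$end[sidx]
      j <- findInterval(pos, tr$start)
      ok <- inside & j >= 1L
      ok[ok] <- pos[ok] < tr$end[j[ok]]
      vals[sidx[ok], off + 1L] <- tr$value[j[ok]]
    }
  }
  widths <- sites$end - sites$start
  n_present <- rowSums(!is.na(vals))
  a <- rowMeans(vals, na.rm = TRUE)
  a[n_present == 0] <- NA_real_
  if (missing_policy == "drop_feature") {
    a[n_present < widths] <- NA_real_
  }
  mutate(sites, a = a)
}

#' Assign each site to a conservation stratum
#'
#' The region of the base at the site start decides (sites may straddle
#' boundaries, e.g. exon/intron). When overlapping transcripts disagree, the
#' priority is CDS > 3' UTR > 5' UTR > intron. Flanks and non-coding exons
#' map to the intron stratum; sites outside every segment are mapped to
#' intron with a warning.
#'
#' @param sites Site tibble.
#' @param segments Segment tibble from [build_region_segments()].
#' @return `sites` with a `region` factor column (levels [REGION_TYPES]).
#' @export
assign_region <- function(sites, segments) {
  if (nrow(sites) == 0) {
    return(mutate(sites, region = factor(character(), levels = REGION_TYPES)))
  }
  seg <- segments |>
    mutate(region = segment_to_region(.data$type),
           prio = match(as.character(.data$region),
                        c("CDS", "THREE_UTR", "FIVE_UTR", "INTRON")),
           seg_end_incl = .data$end - 1L)
  hit <- sites |>
    mutate(.site = row_number()) |>
    select(".site", "seq_id", pos = "start") |>
    left_join(seg |> select("seq_id", "start", "seg_end_incl", "region",
                            "prio"),
              by = join_by("seq_id", between(x$pos, y$start, y$seg_end_incl))) |>
    group_by(.data$.site) |>
    arrange(.data$prio, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.site)
  region <- as.character(hit$region)
  if (anyNA(region)) {
    warn(sprintf("%d site(s) outside all annotated segments; assigned to the intron stratum",
                 sum(is.na(region))))
    region[is.na(region)] <- "INTRON"
  }
  mutate(sites, region = factor(region, levels = REGION_TYPES))
}

#' Attach the full feature triple to motif sites
#'
#' Convenience wrapper running [compute_spacing()], [compute_bls()],
#' [compute_accessibility()] and [assign_region()] in order.
#'
#' @param sites Site tibble from [scan_region_set()].
#' @param maf,tree,ref_species Conservation inputs (see [compute_bls()]).
#' @param track Accessibility track or `NULL`.
#' @param segments Region segments from [build_region_segments()].
#' @param consensus,exclude Consensus definition.
#' @param D_cens Spacing censoring threshold.
#' @param slop,missing_policy Passed through.
#' @return Site tibble with columns `d`, `c`, `a`, `region`.
#' @export
featurize_sites <- function(sites, maf, tree, ref_species, track, segments,
                            consensus, exclude = character(), D_cens = 30L,
                            slop = 0L,
                            missing_policy = "drop_feature") {
  sites |>
    compute_spacing(D_cens = D_cens) |>
    compute_bls(maf, tree, ref_species, consensus, exclude, slop = slop) |>
    compute_accessibility(track, missing_policy = missing_policy) |>
    assign_region(segments)
}
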