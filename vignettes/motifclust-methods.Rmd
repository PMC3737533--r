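---
title: "Predicting clustered RBP motif sites with a six-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting clustered RBP motif sites with a six-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifclust)
library(dplyr)
```

## The problem

Many RNA-binding proteins (RBPs) recognize short, degenerate elements —
Nova binds YCAY (Y = C/U), Mbnl binds YGCY — whose individual occurrences
carry almost no information: a random transcriptome position matches YCAY
about once every 64 nt. What distinguishes functional binding regions is
not any single element but the *arrangement*: several elements packed
closely together, sitting in accessible (single-stranded) RNA, and
conserved across species. `motifclust` models exactly those three signals
and decodes *clusters* of motif sites, trained supervised on in vivo
binding evidence (HITS-CLIP tag clusters) against tag-free background.

## The observation model

Scanning a transcript (in sense orientation, exons plus flanking intronic
sequence) yields an ordered list of motif sites. Each site $i$ is an
observation with three features:

* **Spacing** $d_i$ — the start-to-start distance to the preceding site,
  censored at 30 nt. Censoring imposes an implicit limit on the spacing
  allowed within a cluster: all gaps of 30 nt or more are equivalent, which
  the test suite verifies bit-for-bit (decoded paths and scores are
  invariant to the raw size of censored gaps). The first site of a scan
  sequence carries the sentinel $d_1 = 0$, consumed only by the degenerate
  start states; true inter-site distances are $\ge 1$, so the sentinel
  never collides. Start-to-start is used (rather than gap length) because
  it remains positive for overlapping sites.
* **Conservation** $c_i$ — the branch length score (BLS): the fraction of
  the phylogeny's total branch length spanned by the species whose aligned
  orthologous window still contains an exact consensus match (any word of
  the consensus counts; the motif may "move" only within the site window,
  `slop = 0` by default, configurable). Because baseline conservation
  differs drastically between 5' UTR, CDS, 3' UTR and intron, the $c$
  distributions are estimated separately per stratum; flanks and
  non-coding exons are pooled into the intron stratum, the least biased
  default for sequence without UTR/CDS identity.
* **Accessibility** $a_i$ — the probability that the site lies in
  single-stranded RNA, averaged over the site's bases from a per-base
  track. Genome-scale tracks are sparse, so the missing-data policy is
  explicit: by default a site with any uncovered base drops its $a$ term
  from the emission in *every* state symmetrically (`drop_feature`), which
  is neutral for classification; `mean_of_present` averages what is there.
  Without any track a uniform 0.5 placeholder keeps pipelines runnable.

All emission components are nonparametric: binned histograms with Laplace
smoothing, $\mathrm{mass}_b = (n_b + \alpha)/(N + B\alpha)$, so every bin
keeps strictly positive mass. Spacing uses unit bins $1..30$ (the last bin
absorbing censored values); $c$ and $a$ use 20 equal bins on $[0, 1]$;
$\alpha = 1$. These are declared defaults, all exposed in
`training_config()`.

## The six-state chain

Each site is an observation of one of six hidden states: the first site of
a scan sequence is `S+` or `S-` (cluster / background); a site continuing
the current regime is `+` or `-`; a site *switching* regime is `I+` (first
site of an internal cluster) or `I-` (first background site after a
cluster). The emission components per state:

| state | $\Pr(d\,|\,s)$ | $\Pr(c\,|\,s),\ \Pr(a\,|\,s)$ |
|-------|-----------------|-------------------------------|
| `S+`  | degenerate, $\Pr(0)=1$ | bound |
| `S-`  | degenerate, $\Pr(0)=1$ | background |
| `+`   | bound           | bound |
| `-`   | background      | background |
| `I+`  | background      | bound |
| `I-`  | background      | background |

The one subtlety is `I+`: a cluster-initiating site is conserved and
accessible like a bound site, but its *distance* was generated by the
preceding background gap, so it takes the background spacing component.
The allowed transitions follow from the state definitions — from any
cluster-side state to `+` (stay) or `I-` (leave); from any background-side
state to `-` (stay) or `I+` (start a cluster); start states are never
re-entered. Decoding is by the Viterbi algorithm per scan sequence, with
ties broken in the fixed order `S- < - < I- < S+ < + < I+`: background is
preferred, so a completely uninformative model predicts nothing. An
exhaustive-enumeration oracle (`brute_force_decode()`, sequences of up to
8 sites) checks decoding optimality on a thousand random models in the
test suite.

## Training

Training is fully supervised — no Baum–Welch. Positive regions are CLIP
tag cluster intervals with peak height above a threshold (15 was used for
Nova, 7 for Mbnl; `ph_min` here), inside the exon+ext mask (exons, the
first/last `ext` nt of each intron, and the gene flanks; `ext` = 1000 nt)
and free of repeat overlap. Negative regions are the exon+ext masks of
genes with *no* CLIP tag anywhere — a single weak tag cluster anywhere in
the gene, even outside the mask, disqualifies it. Sites fully inside a
positive cluster are labeled `+`; sites in negative genes `-`; sites in
CLIP-positive genes but outside clusters are *excluded* rather than used
as background, to avoid contaminating the background with near-cluster
sites. Labels induce a unique state path per region, so transitions and
the initial distribution are maximum-likelihood counts with a pseudocount
on each allowed edge. Because training regions are label-pure, the
cross-regime edges (`- → I+`, `+ → I-`) are estimated essentially from
their pseudocounts: their probability shrinks as the training corpus
grows, which acts as the prior odds against starting or ending a cluster.

## Cluster calls and scores

Maximal decoded runs of cluster-side states — necessarily of the form
`(S+|I+)(+)*` — become candidate clusters, kept when they contain at least
3 sites (the canonical minimal requirement for functional binding; the
filter is exposed). Each call is scored by the log-likelihood ratio
$\log[P(x\,|\,\text{cluster})/P(x\,|\,\text{background})]$, computed
term-by-term against the homologous background path: the per-site emission
log-ratios plus, for each within-cluster transition, $\log P(+\!\to\!+) -
\log P(-\!\to\!-)$. Including the transition term (switchable via
`include_transitions`) makes longer, tightly spaced clusters score higher
even under flat emissions, which matches the central role of clustering;
the initiating site's distance term cancels exactly by the component table
above, so the score does not depend on how far the cluster is from the
previous site. Scores are reported in log base 2 by default; the base is a
model option, so printed thresholds are not portable constants between
bases or training corpora.

## Evaluation protocol

`make_footprints()` takes ±50 nt around the peak of each robust CLIP
cluster (PH ≥ 15) as surrogate positives; `sample_negative_windows()`
draws 100-nt windows uniformly from tag-free exon+ext sequence.
`roc_from_overlap()` scores an example by the maximum score of any
overlapping cluster (≥ 1 nt; no overlapping cluster means $-\infty$) — an
existence test at every threshold is equivalent to thresholding the
maximum — and reports the ROC, its AUC, and sensitivity at specificities
0.85 and 0.99. `crossval_two_fold()` splits *genes* into random halves (so
one gene's sites never straddle folds), trains on each half, predicts on
the other, and compares pooled out-of-fold cluster scores with full-model
scores matched by exact coordinates. `score_bin_overlap()` bins clusters
by score and reports per-bin footprint-overlap fractions with cumulative
counts. Around cassette exons, `regional_scores()` summarizes clusters
into six splice-site-anchored regional scores with exponential distance
weighting $e^{-\mathrm{dist}/\tau}$ ($\tau$ = 500 nt, window 1000 nt,
both exposed) — the weighting only needs to be smooth, monotone and
anchor-local, so an exponential decay is declared as the default; the
summarized score is the maximum of the six (and the regional
score is likewise a max, paralleling that convention). Fisher tests of
target overlap use `stats::fisher.test`.

## The synthetic transcriptome

`simulate_dataset()` generates everything needed to exercise the pipeline
without downloads: per gene, a background sequence scrubbed of accidental
consensus matches, background sites planted at geometric spacing (mean
80 nt), clusters of 3 + Poisson(4) sites at geometric spacing (mean 8 nt),
per-species alignment rows in which each planted site retains its motif
i.i.d. with probability 0.9 (cluster sites) or 0.3 (background), per-site
accessibility Beta(8, 2) vs Beta(2, 2) rasterized over the site span on a
0.5 background, a 3-exon gene model (20% non-coding), and CLIP peaks at
cluster midpoints with negative-binomial peak heights
(mu = 5 · sites, size = 2) plus occasional weak false peaks. All outputs
are byte-identical under the same seed.

Choices worth spelling out:

* Planted 4-mers cannot overlap unless jointly consistent with the
  consensus, so spacing is the geometric law conditioned on ≥ motif
  length (memorylessness: a constant shift). The exact censored pmfs
  (`spacing_pmf()`, `bls_pmf()`, `beta_pmf()`) are what the
  emission-recovery tests compare against.
* Planted clusters keep ≥ 400 nt between each other and ≥ 300 nt from the
  sequence ends. Closer plantings are not two distinct clusters under a
  30-nt spacing-censored model but one contiguous high-affinity region,
  and a cluster flush against a sequence end would let decoding absorb
  the short tail without ever paying the exit transition; real scan
  sequences (genes plus kilobases of flank) have neither geometry.
* Peak heights are overdispersed on purpose: CLIP tag counts compound
  binding strength with transcript abundance, so conditioning on cluster
  size must still leave wide spread — this is also what makes the
  score-vs-overlap calibration informative rather than saturated.
* Species loss is i.i.d. given the label; phylogenetically correlated
  loss is out of scope. That is sufficient to make BLS informative, but
  it means the synthetic conservation signal is *easier* than real
  alignments (no lineage-specific loss, no alignment error), so passing
  recovery tests bounds what the method can do on clean signal, not on
  real genomes. The same caveat applies to accessibility (no folding
  model, just Beta draws) and to the absence of indels by default.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_spec(seed = 1, n_genes = 60))
feats <- featurize_dataset(ds)
model <- fit_dataset(feats, ds)
clusters <- predict_clusters(model, feats, min_sites = 3)
recovery_report(ds$truth, clusters)
glance(model)
autoplot(model)         # emission histograms, bound vs background
```

Problem sizes in the shipped tests and acceptance script (chosen to keep a
full run in minutes on one core): training replicates of 120 genes,
evaluation replicates of 60, calibration/cross-validation sets of
150–250 genes, 50 000-site corpora for distribution recovery, and 1000
random models for the decoding oracle.

## Numerical conventions and degenerate inputs

Coordinates are 0-based half-open everywhere, BED-native; minus-strand MAF
reference rows are flipped on read. All probability arithmetic is in
natural logs internally; only reported scores are rebased. A value of
exactly 1.0 falls in the top histogram bin. BLS is clamped to $[0, 1]$
against float round-off; a tree with zero total length, a site covered by
no alignment block, or a single-species set all give BLS 0 by convention.
A conservation stratum with no training sites on one side falls back to
that side's pooled distribution with a warning. Empty scan results,
all-background decodes and empty prediction sets flow through as empty
tibbles; `recovery_report()` reports precision `NA` when there are no
calls.

## Limitations

The model scores motif sites only — it cannot propose binding where no
consensus match exists, and its resolution is the site list, not the
nucleotide. Supervised training inherits every bias of the CLIP input
(expression-dependent coverage, peak-height thresholds). The cross-regime
transition probabilities are pseudocount-driven by construction
(label-pure training regions), so absolute cluster scores depend on
training corpus size; scores are comparable within a trained model, not
across models. Genome-scale runs are architecturally supported (per-gene
decoding, streaming-friendly I/O) but not exercised here.
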