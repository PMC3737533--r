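# motifclust

Clustered RNA-binding-protein motif site prediction with a six-state
hidden Markov model.

## The problem

Splicing regulators such as Nova (YCAY) and Mbnl (YGCY) bind short,
degenerate RNA elements that occur by chance every few dozen nucleotides —
individually they predict nothing. Functional binding regions are instead
marked by *clusters*: several elements with tight spacing, in accessible
(single-stranded) RNA, conserved across species. `motifclust` scans
transcripts for IUPAC-consensus matches and models the ordered site list
with a six-state HMM whose states distinguish sites inside an RBP-bound
cluster from background sites, and whose emissions are nonparametric
histograms of three per-site features:

* `d` — start-to-start spacing to the preceding site, censored at 30 nt;
* `c` — branch length score (BLS) conservation: the fraction of the
  phylogeny's branch length spanned by species whose aligned window still
  contains a consensus match, estimated separately for 5' UTR / CDS /
  3' UTR / intron;
* `a` — probability of lying in single-stranded RNA.

Training is supervised: positive sites come from CLIP tag clusters with
peak height above a threshold, negatives from genes without any CLIP tag.
Viterbi decoding yields maximal cluster runs (kept at ≥ 3 sites), each
scored by the log-likelihood ratio
`log2[P(x | cluster) / P(x | background)]`. The package also implements
the downstream protocol: CLIP-footprint ROC evaluation with feature
ablation, two-fold cross-validation, score-bin overlap calibration,
distance-weighted regional scores around cassette exons for target-exon
ranking, and a fully synthetic data generator with planted clusters that
makes the whole pipeline testable offline. It is intended for
computational biologists studying RBP target networks, and as a
reference implementation of the clustered-site HMM.

## Worked example

Everything below runs in about half a minute from a bare R session; the
dataset is simulated, so the numbers are exactly reproducible. (Training
may warn that a sparse conservation stratum fell back to the pooled
distribution — expected at this scale.)

```r
library(motifclust)

ds      <- simulate_dataset(sim_spec(seed = 1, n_genes = 60))
feats   <- featurize_dataset(ds)            # scan + d/c/a/region per site
model   <- fit_dataset(feats, ds)           # supervised HMM fit
clusters <- predict_clusters(model, feats)  # Viterbi + >=3-site calls

clusters
#> # A tibble: 54 x 8
#>   seq_id start   end name           score strand n_sites members
#>   <chr>  <int> <int> <chr>          <dbl> <chr>    <int> <list>
#> 1 g001     789   861 cluster_g001_1  40.3 +            6 <int [6]>
#> 2 g003     362   499 cluster_g003_1  51.2 +            7 <int [7]>
#> 3 g003    1326  1389 cluster_g003_2  73.3 +            9 <int [9]>
#> 4 g004     501   532 cluster_g004_1  40.1 +            4 <int [4]>
#> # 50 more rows

recovery_report(ds$truth, clusters)
#> # A tibble: 1 x 6
#>      tp    fp    fn precision recall    f1
#>   <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1    52     2     2     0.963  0.963 0.963
```

Each cluster call spans its member motif sites; `score` is the log2
likelihood ratio of the bound vs background explanation of those sites
(larger = more cluster-like spacing, conservation and accessibility), and
the recovery report matches calls to planted truth at ≥ 50% reciprocal
overlap. `autoplot(model)` shows the fitted emission histograms (bound vs
background per feature); `glance(model)` and `tidy(model)` expose the
fitted parameters broom-style.

A command-line interface wraps the same functions stage by stage
(`simulate`, `scan`, `featurize`, `train`, `predict`, `evaluate`,
`summarize-exons`); it is installed as `exec/motifclust`:

```sh
motifclust scan --fasta genome.fa --consensus YGCY --exclude CGCC --out sites.bed
```

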