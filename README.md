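# loopdyn

Downstream analysis of time-course HiChIP chromatin loops and matched
multi-omics signal around an acute transcription-factor stimulation — the
androgen receptor (AR) in prostate cells being the motivating system. Most
gene promoters contact many cis-regulatory elements (CREs) at once, so
`loopdyn` asks the multi-enhancer questions: how does the contact frequency
(CF) of pre-existing loops change over a stimulation time course, which
summary of a promoter's contacts best explains expression, and is the
contact distribution unbalanced enough that a single **dominant** loop
carries the signal?

The package is aimed at computational genomicists working downstream of
peak and loop callers: inputs are narrowPeak/BED peak sets, BEDPE loop
tables with per-timepoint counts, bedGraph coverage tracks and a transcript
expression TSV — never reads.

## What it computes

* **CRE annotation** — fixed ±2.5 kb windows around accessibility summits
  pooled over time points; active promoters from the highest-expressed
  isoform per gene; AR/FOXA1 binding by any-timepoint peak overlap.
* **Regulatory network** — CREs as nodes, mark-specific reference loops
  (H3K27ac enhancer-centric, H3K4me3 promoter-centric) as undirected edges
  with one TMM-normalized weight per time point.
* **Bootstrapped CF fold change** — from promoter and enhancer viewpoints,
  per iteration *i* and time point *t*:

  ```
  FC_i(t) = mean CF(query loops, t) / mean CF(reference loops_i, t)
  ```

  with n = 100 promoters drawn per iteration (b = 1000, seed 7), reference
  draws stratified to match the query's expression quartiles, and empirical
  p-values from a matched null in which the query is itself a reference
  draw.
* **Multi-enhancer models** — average / maximum / sum of a promoter's
  first-degree CFs against expression, binned into k = 25 equal-size
  expression bins, compared by bin-level Spearman rho and by
  permutation importance of a random-forest regressor.
* **Dominant loops** — per promoter and time point, min–max scaled CFs with
  a > 0.8 dominance threshold ("any timepoint" aggregate policy), plus the
  Gini inequality index of the promoter's contact distribution:

  ```
  G = Σ_i Σ_j |x_i − x_j| / (2 n² x̄)
  ```

* **Nascent time groups** — maximal Start-seq-style TSS signal (±500 bp,
  strand-aware), upregulation at log2 fold change > 1 vs 0 m, and
  assignment of each upregulated transcript to its maximal-expression time
  point (30 m / 4 h / 16 h / 72 h).
* **Synthetic data with planted truth** — a generator emulating the whole
  multi-omics structure (boosted E+AR→P+AR loops peaking at 16 h, ChIP
  signal peaking at 4 h, Dirichlet-unbalanced contact allocation, additive
  expression), so every stage is testable offline, plus `score_recovery()`
  to compare pipeline output against the planted truth.

## Worked example

```r
library(loopdyn)

## synthesize the default study: 2,000 genes, 5 time points, 2 marks
sim <- generate_dataset(sim_config(seed = 7), dir = "ds")

## enhancer-centric network with TMM-normalized weights
net <- build_network(tmm_normalize_loops(sim$loops$H3K27ac), sim$cres)
net
#> <loop_network> 32469 nodes, 73196 edges (H3K27ac=73196), timepoints 0m,30m,4h,16h,72h

## contact-frequency fold change of AR-bound-enhancer loops to
## AR-regulated promoters, vs quartile-matched background loops
genes  <- sim$genes
strata <- setNames(genes$quartile, genes$promoter)
fc <- bootstrap_fc_enhancer_view(
  net, sim$cres, selector = "E+AR->P+AR",
  query_promoters     = genes$promoter[genes$class == "up"],
  reference_promoters = genes$promoter[genes$class == "independent"],
  strata = strata)
fc
#> <bootstrap_result> b=1000 n=100 seed=7; peak 16h (p=0.000999)
#>  timepoint mean_fc  ci_lo ci_hi    p_two
#>         0m  0.8381 0.8008 0.883 0.001998
#>        30m  1.0037 0.9585 1.057 0.911089
#>         4h  1.3397 1.2807 1.412 0.001998
#>        16h  1.8612 1.7778 1.961 0.001998
#>        72h  1.2617 1.2048 1.329 0.001998
```

The loops of AR-bound enhancers gain contact frequency after stimulation
and peak at 16 h — the planted kinetic — while the 30 m point sits at 1
(matched baselines; the 0 m offset is the sampling error of a ~260-loop
query set with heavy-tailed allocation weights).

```r
## dominant loops and contact inequality
calls <- call_dominant_loops(net, sim$cres, threshold = 0.8, policy = "any")
calls
#> <dominance_calls> 2000 promoters, 55207 loops, 3024 dominant (mark H3K27ac, threshold 0.80, policy any)
#>   mean Gini at 16h: 0.495

## which summary of multi-enhancer contact explains expression?
map  <- data.frame(gene = genes$gene, cre_id = genes$promoter)
summ <- summarize_models(net, map, mark = "H3K27ac", timepoint = "16h")
for (m in c("avg", "max", "sum"))
  print(bin_and_correlate(summ, genes, m, timepoint = "16h"))
#> <model_fit> avg @ 16h: bin-level rho=0.561 (p=0.00355), gene-level rho=0.115, n=2000, k=25
#> <model_fit> max @ 16h: bin-level rho=0.979 (p=1.93e-17), gene-level rho=0.607, n=2000, k=25
#> <model_fit> sum @ 16h: bin-level rho=0.992 (p=2.25e-22), gene-level rho=0.801, n=2000, k=25
```

A mean per-promoter Gini near 0.5 says contact is strongly unbalanced, and
the additive (sum) model correlates best with expression, the maximum model
close behind — the signature of dominant loops.

The full pipeline and recovery scoring run in one call each (or via the
`exec/loopdyn` command line: `loopdyn synthesize|run|score`):

```r
run_pipeline("ds", "out")            # writes cres.tsv, net.json, fc_*.tsv,
                                     # dominance*.tsv, models.tsv, ...
score_recovery("out", "ds/truth.json")
```

## File formats

Loop tables are BEDPE with a header: six coordinate columns, `name`,
`mark`, then one numeric column per time point named `cf_<label>`
(`cf_0m cf_30m cf_4h cf_16h cf_72h`) — per-timepoint contact frequencies
have no standard BEDPE home, so the dialect is pinned here. Coordinates are
0-based half-open everywhere. The dataset directory layout consumed by
`run_pipeline()` is exactly what `generate_dataset()` writes:
`atac_peaks_<tp>.narrowPeak`, `ar_peaks_*.bed`, `foxa1_peaks_*.bed`,
`loops_<mark>.bedpe`, `signal_<assay>_<tp>.bedgraph`, `expression.tsv`,
`nascent_{fwd,rev}_<tp>.bedgraph`, `hallmark_genes.txt` and (optionally)
`truth.json`.

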