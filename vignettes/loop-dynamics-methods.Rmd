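---
title: "Methods: contact-frequency dynamics and multi-enhancer dominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-frequency dynamics and multi-enhancer dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopdyn)
```

## The problem

Ligand-activated transcription factors such as the androgen receptor (AR)
bind thousands of cis-regulatory elements (CREs), most of them enhancers
connected to target promoters through chromatin loops. A single promoter
typically contacts on the order of fifteen CREs, so the question of how
individual enhancers contribute to expression cannot be answered one loop at
a time. `loopdyn` implements the downstream analysis layer for a
five-time-point stimulation experiment (0 m, 30 m, 4 h, 16 h, 72 h) that
measures accessibility, factor binding, histone marks, mark-specific HiChIP
loops and nascent transcription: it builds a CRE-level regulatory network,
quantifies how loop contact frequency (CF) changes over the time course,
asks which summary of a promoter's multi-enhancer contacts best explains
expression, and scores the inequality of a promoter's contact distribution
to call *dominant* loops.

Everything operates downstream of alignment, peak calling and loop calling:
inputs are peak/loop tables and coverage tracks, not reads.

## CRE annotation

CREs are fixed windows of +/- `half_width` (default 2500 bases) around
accessibility summits pooled over all time points. A summit falling inside a
window accepted earlier (earlier time point, or earlier coordinate within
the same time point) is absorbed into that window, so re-called peaks never
duplicate a CRE. The merge rule is deterministic and order-independent after
coordinate sorting; it is our choice at a point where only the merged
outcome, not the rule, is conventionally reported.

Active promoters come from expression: per gene, the isoform with the
highest expression at any time point (ties broken toward the
lexicographically smallest transcript id) contributes a strand-aware TSS
window of the same width; a CRE overlapping it by at least one base is that
gene's promoter, with maximal overlap deciding among several candidates.
Genes with no overlapping CRE are excluded from promoter-anchored analyses
and counted. A CRE is AR-bound (or FOXA1-bound) if it overlaps a
corresponding ChIP peak at *any* time point; non-promoter CREs are
enhancers, split into E+AR and E-AR by that flag. A promoter may be AR-bound
without changing class.

Gene sets: hallmark (pathway) membership marks AR-regulated genes;
downregulated genes satisfy `log2((e16h + eps)/(e0m + eps)) < -1` with
`eps = 0.01` TPM (the pseudocount is ours; steady-state TPM is used, since
nothing in the inputs distinguishes the alternative); expression quartiles
(Q1 highest) come from the maximum expression over time.

## The regulatory network

Nodes are all CREs; edges are loops from a *reference* loop set per mark
(H3K27ac enhancer-centric, H3K4me3 promoter-centric), called once from
pooled time points, with one weight per time point. Loop anchors map to the
CRE of maximal overlap (ties to the leftmost CRE); loops with an unmapped
anchor or both anchors on one CRE are skipped and counted, and parallel
loops collapsing onto one CRE pair have their counts summed — with 5 kb
anchor bins and 5 kb CRE windows, several called bin pairs can legitimately
describe one element pair, and summation preserves total contact mass. The
network is undirected and is stored as a plain edge table (one weight column
per time point); `as_igraph()` exports any single mark/time-point layer.

Per-timepoint counts are TMM-normalized across time points before
comparison (`tmm_normalize()`, 30% trim on log-ratios, 5% on intensity,
precision weights, reference column by upper quartile — the method's
published defaults, computed by edgeR). Note that every fold-change ratio
below compares a numerator and denominator at the *same* time point, so the
analysis is exactly invariant to this per-column scaling; normalization
matters for cross-timepoint displays such as signal kinetics and temporal
SDs.

Mean assay coverage per CRE uses the length-weighted mean of the bedGraph
track over the window, with uncovered bases counted as zero (bedGraph
sparsity convention).

## Bootstrapped contact-frequency fold change

For a query set of promoters (e.g. hallmark-gene promoters) the statistic at
time point *t* is

    FC_i(t) = mean CF(query loops, t) / mean CF(reference loops_i, t)

where iteration *i* draws `n` promoters (default 100) without replacement
from a reference pool and collects all their loops; the default is `b` =
1000 iterations with seed 7. The enhancer viewpoint restricts loop sets to
enhancer-promoter edges matching a selector (E+AR->P+AR, E-AR->P+AR,
E-AR->P-AR) against a reference of AR-free-enhancer loops of highly
expressed independent promoters, and subsamples the query promoters to `n`
per iteration when there are more.

Two design choices deserve emphasis:

* **Expression matching.** Reference promoters are drawn stratified by
  expression quartile to match the query's composition. Expression and
  total contact are correlated, so an unmatched highly-expressed reference
  would bias FC below 1 even with no effect present; matching keeps the
  null centered at 1 (this is the package's realization of comparing
  regulated genes with "similarly expressed" backgrounds).
* **Significance.** The null procedure behind the reported stars is not
  conventionally standardized, so the package defines one: in every
  iteration an additional pseudo-query of `n` reference promoters is drawn,
  giving a matched null FC distribution. Per time point a two-sided
  empirical p is reported, plus a one-sided (greater) p at the time point
  of maximal mean FC. Empirical p-values use the add-one rule
  `(1 + #{null >= obs}) / (1 + b)` and therefore never reach zero.

Iterations whose reference mean is zero are discarded and counted; a
discard rate above 5% raises a warning. Intervals are the 2.5/97.5
percentiles of the per-iteration FCs. Because the query is one fixed gene
set, its sampling error (a few percent at 100 genes) is visible as a common
offset of the whole FC curve; calibration statements therefore aggregate
over datasets, while within one dataset the *shape* of the curve (peak time
point) is the meaningful signal.

## Temporal dynamics and perturbation

`temporal_sd_profile()` computes the sample SD (n - 1) of any per-item
feature across the five time points and min-max normalizes it within a
comparison group (e.g. per gene across its enhancers); a single-item group
is assigned 1 by convention and logged. `correlate_perturbation()` reports
the Spearman correlation (t-approximation p, as everywhere in the package)
between per-CRE perturbation effects, such as CRISPRi knockdown of
stimulated expression, and the temporal SD of the CRE's contact frequency;
the sign is reported, not assumed.

## Multi-enhancer models

For every gene with a promoter, the first-degree contact frequencies at one
time point are summarized three ways: `avg` (all contacts contribute
equally), `max` (one strong contact), `sum` (additive contribution). Genes
are sorted by expression, split into `k = 25` contiguous equal-size bins
(remainder on the first bins), and each bin contributes its mean
`log(expression + 0.01)` and mean summary. The reported correlation is
Spearman's rho over the 25 bin means, mirroring a binned-scatter reading; a
gene-level rho is also returned. A random forest is trained on the three
binned features to predict binned expression with `random state` 0, and
features are ranked by permutation importance: the mean drop in training
R^2 over 10 seeded shuffles of one feature at a time. All features are
considered at every split (`mtry` = 3): with three strongly collinear
features a per-split random subset of one makes the trees indifferent to
feature quality and the importance ranking arbitrary, whereas considering
all features lets the best-associated summary dominate the splits. The
10-shuffle/seed-0/training-R^2 convention is a reporting choice, not a
claim about any particular external default.

## Dominant loops and the Gini index

At every time point the contact frequencies of a promoter's first-degree
CREs are min-max scaled to [0, 1]; neighbors above 0.8 (exclusive) are
dominant at that time point. The aggregate call is *dominant at any time
point* (dominant loops tend to pre-exist stimulation, so a fixed-time-point
policy would miss primed loops; a named-time-point policy is available and
per-timepoint flags are always retained). Degenerate neighborhoods follow
two conventions: a single neighbor is dominant (scaled value 1), and a
neighborhood with all-equal CFs yields no call and a `balanced` flag —
inequality is the concept being scored, and a flat neighborhood has none.

Inequality itself is quantified by the Gini index of the promoter's raw CF
distribution at a configurable time point (default 16 h):

    G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))

i.e. the relative mean absolute difference over all ordered pairs,
implemented via the sorted-vector identity and verified against a literal
double loop. G is scale-invariant, 0 for perfect equality and bounded by
(n-1)/n < 1.

`compare_dominant_dynamics()` contrasts the temporal SD of dominant (D+)
versus non-dominant (D-) loops with a two-sided Mann-Whitney U (exact by
enumeration when the pooled size is at most 12 without ties, normal
approximation with tie and continuity correction otherwise), and
`dominant_proximity_fraction()` reports how often a dominant CRE is also the
genomically closest one (gap distance, 0 when windows overlap).

## Nascent transcription groups

TSS-proximal nascent signal is the maximum track value within +/-500 bases
of the TSS on the strand-appropriate track (forward for plus-strand
transcripts, reverse for minus; a base exactly 500 away counts, 501 does
not). Upregulation means `log2((s_t + eps)/(s_0m + eps)) > 1` at any
stimulated time point with `eps = 0.5` — a heavier pseudocount than for TPM
because nascent coverage is sparse and zero-TSS transcripts must not
produce unstable ratios (both pseudocounts are configurable). Each
upregulated transcript's five-point vector is z-scored per transcript
(mean 0, sample SD 1) and the transcript joins the group of its maximal z.
z-scoring never changes the argmax (asserted property), so the grouping is
equivalently the raw argmax; the z profile is retained for display. Ties
break toward the earlier time point; transcripts peaking at 0 m, or with
constant signal, are dropped from grouping and counted — the groups are
30 m / 4 h / 16 h / 72 h with no untreated class.

## The synthetic data generator

`sim_config()` / `generate_dataset()` produce a complete plain-text bundle
(peaks, two BEDPE loop tables, per-assay bedGraphs, expression TSV,
strand-specific nascent tracks, hallmark list, `truth.json`) with planted
ground truth. Defaults encode the study conditions the package is designed
around:

* **Genome model.** One synthetic chromosome per 250 genes; each gene has a
  promoter and `K` enhancers on a 10 kb lattice with +/-1 kb jitter, so loop
  spans stay within the 5 kb–3 Mb window of the loop caller. `K` is
   2 + NB(mean 13, size 2): a long-tailed contact-count distribution (median
  near the ~15 contacts per gene typical of such data) whose spread is what
  separates the `avg` model from the others.
* **Contact structure.** A promoter's total contact is `K_g * L_g` with
  `L_g` a log-normal per-loop intensity (sd 0.2), split across enhancers by
  a symmetric Dirichlet with concentration 0.3. The factorization keeps the
  per-loop mean CF independent of `K`, which keeps bootstrap-FC sampling
  error near 3% at n = 100; the low concentration plants strong allocation
  inequality (mean per-promoter Gini ~0.5–0.7, estimated by an independent
  Monte-Carlo of Dirichlet draws before the generator was built).
* **Kinetics.** E+AR loops of upregulated genes are multiplied by a boost
  profile peaking at 16 h (2.2x); AR/FOXA1/H3K27ac signal at AR-bound CREs
  peaks at 4 h; accessibility peaks at 16 h; H3K4me3 is static;
  downregulated genes decay in expression (bottom 0.2x at 16 h) without any
  CF change. Both marks share the E-P topology with loop-level mark noise
  (sd 0.15); mark-specific E-E and P-P loops are added to match the
  reported class compositions (H3K27ac enhancer-centric, H3K4me3
  promoter-centric).
* **Expression.** `log(expr) = intercept + gain * log(sum of first-degree
  CF) + N(0, 0.3)` per gene and time point — expression is additive in the
  summed contact frequency by construction.
* **Noise.** Observed CFs carry log-normal measurement noise of sd 0.03 per
  loop and time point, representing deep pooled reference-set
  quantification; nascent signal carries sd 0.2. These levels were fixed
  from pre-build simulations as the regime in which the planted structure
  is recoverable (recovery of planted dominants and groups at the stated
  thresholds), and are not revisited per run.
* **Truth.** `truth.json` records gene classes and quartiles, boosted loop
  keys with baseline CFs, planted dominant loops (computed by applying the
  exact calling rule to the noiseless CFs), and planted nascent groups —
  everything `score_recovery()` needs, without duplicating the ~125k-loop
  tables that the BEDPE files already carry.

`plant_null_dataset()` is the same generator with every effect off; it is
the calibration control for the bootstrap machinery.

What the generator does *not* emulate: read-level noise, peak- and
loop-calling artifacts, genomic sequence context, distance-dependent
contact decay beyond the span window, inter-chromosomal contacts, eRNA
transcription at enhancers, and biological expression variance beyond the
planted additive law (the additive law is deliberately tight so that model
discrimination reflects structure, not luck). Passing tests therefore
demonstrate that the machinery recovers planted structure at realistic
noise, not that real data satisfy the additive model.

## Problem sizes and determinism

The default study scale is 2,000 genes (~32,000 CREs, ~125,000 loops across
two marks, five time points); unit tests use 300-gene datasets and
bootstrap settings of 200 iterations x 50 promoters, while calibration and
recovery checks run at the full default scale (200 null datasets for
coverage, 5 seeds for dominance recovery) — sizes chosen as the smallest
that make the statistical statements stable. All randomness flows through
named seeds (`sim_config(seed=)`, `bootstrap_config(seed=)`, the
random-forest seed) via a private RNG stream that restores the caller's
state, so reruns are byte-identical, which `run_pipeline()`'s manifest
(input checksums, stage counts, no timestamps) makes checkable.

## Known limitations

* Per-timepoint loop significance calling is out of scope; "presence" of a
  loop at a time point is CF > 0 on the reference set.
* The hypergeometric loop test is exposed as a generic tail probability;
  the population/success mapping is the caller's.
* No multiple-testing correction is applied anywhere; all p-values are raw,
  and downstream users should correct as appropriate for their query sets.
* CLI configuration files are YAML.
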