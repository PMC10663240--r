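---
title: "Mining insulator-like intergenic elements: methods and design notes"
author: "insulatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining insulator-like intergenic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulatr)
```

## The problem

Stacked transgene cassettes interfere with each other: a strong
constitutive enhancer next to a normally silent promoter will activate it.
Insulator (enhancer-blocking) elements placed between cassettes prevent
this, but few short, well-characterised insulators exist for plants. One
productive place to look for them is a compact genome: when genes sit very
close together, the intergenic sequence between two neighbours that
maintain sharply different expression levels is a natural candidate for an
element that blocks regulatory crosstalk. `insulatr` implements that
screen as a reusable, fully testable pipeline: candidate mining from gene
models and expression, microsynteny evidence across related genomes,
unmethylated-region (UMR) evidence from bisulfite data, candidate ranking,
and the dual-reporter statistic used for in vivo validation.

All coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
and allc files (1-based positions) are converted at the I/O boundary. This
matches BED and makes every length a plain `end - start`.

## Candidate mining

For each pair of genes with consecutive positional ranks on a sequence,
the region between the left gene's end and the right gene's start is an
intergenic region, provided the genes do not overlap (overlapping or
nested pairs yield no region, and do not block the next consecutive pair).
Orientation is a pure function of the two strands: head-to-head `(-,+)`
pairs are *divergent*, tail-to-tail `(+,-)` pairs *convergent*, co-oriented
pairs *tandem*.

A region passes the core filter iff all of the following hold
(`miner_params()` defaults in brackets; all bounds inclusive):

* length within `[min_len, max_len]` [50 bp, 20 kb] — wide enough to
  exclude trivial spacers and regions long enough to hide transposon
  insertions;
* orientation divergent or convergent — tandem pairs may owe their
  expression contrast to read-through or shared terminators;
* FPKM fold change `max(f1,f2)/min(f1,f2) >= min_fc` [1.5], a deliberately
  loose contrast threshold;
* the higher-expressed gene lies in the top `top_fraction` [50%] of all
  transcripts, where the cutoff is the `ceiling(f * n)`-th largest FPKM
  and ties at the cutoff count as "in";
* convergent pairs additionally need *exactly one* flanking gene in that
  top set. The divergent class requires only that either gene be the
  higher expressed, so a divergent pair with both genes highly expressed
  still passes; this asymmetry follows the screen's published wording.

Zero expression gets no pseudo-count: a zero lower FPKM against a positive
higher one gives an infinite fold change (passes any threshold); a pair
with both FPKM zero never passes. `filter_short()` keeps passing
candidates at most `short_max` [1 kb] long, the subset practical for
synthetic constructs.

## Microsynteny

For each candidate and each subject genome, every pair of BLAST hits
(left-flank hit × right-flank hit) on one subject sequence with at most
`max_between` [5] intervening genes is admissible; the same ceiling is
checked on the query side, which is trivially satisfied for adjacent
pairs but keeps the scanner correct for general pairs. Among admissible
pairs the scanner selects the one minimising the intervening count, then
the summed e-value, then lexicographic subject gene ids — a fully
deterministic choice that considers *all* hits rather than best-hit-only,
since a best-hit heuristic can miss conserved pairs.

Classification compares the *relative* configuration: each gene's
direction along the axis running from the left-flank ortholog to the
right-flank ortholog. Absolute strand is meaningless across assemblies, so
when the subject pair runs against its chromosome's coordinates both
subject strands are flipped before comparison; reversing an entire subject
chromosome therefore changes no call (a tested invariant). With the
orientation conserved and intervening counts equal the call is
`high_quality`; orientation conserved but counts different, `indel`;
exactly one gene flipped with counts equal, `inversion`; anything else —
including both genes flipped — `none`. E-values are filtered inclusively
(`<= 1e-5`); inclusivity at a floating-point boundary is practically
irrelevant but has to be fixed one way.

High-confidence candidates are at most 1 kb long, show a strictly
greater than 10-fold expression contrast, and have a `high_quality` call
in at least one genome. Validation shortlists take the top `k` [9] by fold
change (infinite fold changes first, ordered by the high gene's FPKM) and
the top `k` by synteny breadth, both ignoring orientation class, with ties
broken by length then region id.

## UMR calling

Methylation is summarised in 100-bp non-overlapping tiles per context
(CG, CHG, CHH), as weighted levels (read sums, not site averages). A tile
is `missing` when it has fewer than `min_cytosines` [2] cytosines **or**
mean coverage below `min_coverage` [5×]. The published rule joins the two
clauses with "and", which reads naturally as either condition being
disqualifying: a single cytosine cannot represent a tile's methylation at
any depth. We therefore default to the OR reading but expose
`missing_rule = "and"` so both readings are switchable. Coverage is the
mean total read count per cytosine with at least one read, since per-base
genome coverage is not recoverable from site records.

A non-missing tile is `unmethylated` when every context present in the
tile has a level strictly below `max_level` [10%]; a context with no
cytosines in the tile passes vacuously. Maximal runs of unmethylated and
missing tiles are trimmed of flanking missing tiles — so UMR boundaries
are always supported by data — and kept as UMRs when they span at least
`min_span` [300 bp] with a missing-tile fraction of at most
`max_missing_frac` [1/3, inclusive]. All three context levels must be low
simultaneously in each tile; we do not call per-context UMRs and union
them. Candidate/UMR overlap requires at least one shared base (half-open:
abutting intervals do not overlap).

## Reporter statistic

For construct $i$ with per-replicate ratios $r_{ij} = \mathrm{GFP}_{ij} /
\mathrm{mCherry}_{ij}$ and construct mean $\bar r_i$, the fold change
against the 21-bp spacer control is

$$\mathrm{FC}_i = \frac{\bar r_i - \bar r_0}{\bar r_0},$$

so FC is 0 for spacer-like behaviour and −1 for complete GFP silencing.
We average per-replicate ratios rather than taking a ratio of summed
channels; with three biological replicates per construct this is the
variance-safer estimator and keeps replicates exchangeable. Ratios are
GFP/mCherry everywhere — the direction the FC formula uses — and output
columns are labelled explicitly since display conventions sometimes invert
the ratio. Replicates with zero mCherry have no defined ratio and are
dropped with a warning.

Group comparison is a one-way ANOVA on per-replicate ratios followed by
all-pairs Tukey HSD at `alpha` [0.05]. The compact letter display is
computed by insert-and-absorb over the significance graph, with letters
assigned to sets ordered by their best member mean: two constructs share
no letter iff their Tukey comparison is significant, and the labelling is
deterministic.

## What the generators emulate — and what they do not

The synthetic genome is built from two-gene *units* separated by gaps
above the miner's length ceiling, so every inter-unit locus is a
deterministic negative. Each unit is planted either as a passing divergent
or convergent candidate or as a *single-rule negative*: tandem
orientation, fold change below 1.5, neither gene highly expressed, gap
below 50 bp, or gap above 20 kb. Expression values occupy two separated
pools (top ≥ 8 FPKM, bottom ≤ 4) with exactly half of all genes in the top
pool — balanced by pairing the all-top (`lowfc`) and all-bottom
(`bothlow`) negative classes — so the empirical top-50% cutoff always
falls between the pools and planted intent is realised exactly. Defaults
(4 chromosomes × 25 units = 200 genes, 20 divergent + 20 convergent
planted) are the conditions under which recovery is tested; planted
candidate gaps are ≤ 1 kb with probability 0.427, the short-region share
reported for the real screen. Gene and gap lengths are log-normal —
heavy-tailed and strictly positive, the shape compact plant genomes show.

Subject genomes copy the query gene order and apply one action per planted
locus (intact, one-gene strand flip, 1–3 inserted genes, one flanking gene
deleted, or 6 inserted genes), then emit one hit per surviving ortholog
with optional dropout. The methylome draws Poisson(20×) coverage and
binomial methylated counts at per-context background levels of
0.60/0.45/0.40 against 0.01 inside planted, tile-aligned UMRs. The assay
draws log-normal mCherry and multiplies a unit-mean log-normal noise (CV
0.05 by default; 0 gives exact recovery `FC = s − 1`). Default strengths
include the two validated insulators' measured ratios (0.155 and 0.261 of
control).

These generators plant *clean, separable* truth: real data have ambiguous
expression contrasts near the cutoff, tandem duplications that blur
orthology, partially methylated and low-coverage regions, and replicate
structure beyond multiplicative noise. Passing the planted-truth suite
shows the rules are implemented exactly as stated, not that the screen's
biological yield on real data is reproduced; genome-scale counts from the
published screen derive from ~100 Mb of accession data and 45 external
genomes and are reproduced here only as report arithmetic from their
printed numerators and denominators.

## Numerical choices and degenerate inputs

* All rule thresholds are inclusive except the two the screen states
  strictly: tile levels must be `< 0.10`, and high-confidence fold change
  `> 10`.
* Zero-length intergenic regions (abutting genes) are kept pre-filter and
  removed by the 50-bp floor.
* Quantile ties: genes exactly at the expression cutoff are in the top
  set (deterministic and monotone).
* `1/3` is compared exactly (same double on both sides), so a 3-tile run
  with one missing tile is retained.
* Scan tie-breaks (intervening count, summed e-value, lexicographic ids)
  make multi-hit resolution reproducible across platforms.
* Empty inputs: an empty sequence yields no regions; an empty region list
  writes an empty BED; a genome without subject genomes yields an empty
  matrix with zero breadths; a construct losing all replicates is an
  error rather than a silent NA.

## Problem sizes used by the tests

The test and acceptance suites run entirely on generated data: 200-gene
genomes for recovery, 200-instance brute-force equivalence sweeps for the
miner and the scanner (up to 100 genes / 50 hits per instance), 50-kb
methylomes over 10 seeds for UMR Jaccard, and 3-replicate assays. These
sizes give exact planted-truth checks and tight stochastic estimates while
keeping the whole suite in well under a minute of compute.

## Known limitations

* The miner consumes one FPKM per gene; multi-tissue tables are collapsed
  by `max` at read time. Which pooled aggregate fed the original screen is
  not recoverable, and `max` favours genes active in any tissue.
* The scanner classifies only the configurations the screen enumerates;
  a pair with both orientations flipped is `none`, not an inversion.
* UMR calling has no access to per-base coverage and approximates the 5×
  rule with mean per-cytosine coverage.
* The genome-wide "methylated fraction" style statistics are not
  implemented; their definitions are not recoverable from the screen's
  description.
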