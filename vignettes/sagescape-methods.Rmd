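---
title: "sagescape: models, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sagescape: models, conventions, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sagescape implements an end-to-end pipeline for tag-based expression
profiling of multiplexed deepSAGE libraries, together with a simulator
that generates every input the pipeline consumes. This vignette records
the models, the parameter conventions and their defaults, the numerical
choices made where several readings were defensible, and — because the
package is validated against its own simulator — exactly what a green
test does and does not establish.

## 1. The library geometry model

`library_layout()` captures the sequence arithmetic of one library
construct. The biology behind the numbers: NlaIII cuts at `CATG`,
defining the anchor; oligo(dT) capture retains the 3'-terminal NlaIII
fragment of each transcript; EcoP15I, whose recognition site sits in the
5' linker, cuts 25 nt away on one strand and 27 nt on the other, leaving
a two-base 5' overhang. Hence the hard invariants enforced by the
constructor:

* `anchor(4) + tag(19) + degenerate(2) == 25` (the short cut distance);
* `long cut == short cut + 2` (the overhang);
* `linker5(47) + 25 + linker3(47) == 119` (the gel-purified product);
* a 50 bp read covers `barcode(6) + degenerate(2) + anchor(4) + tag(19)`.

Two conventions are worth stating. First, the two degenerate overhang
bases are placed *between barcode and anchor in the read*; physically the
overhang sits at the EcoP15I cut, but the read-orientation convention is
what the extraction step ("digital removal") sees, and it is configurable
in the layout. Second, the 47/47 linker lengths are chosen solely to
satisfy the 119 bp construct; the real linker oligo sequences are not
modelled, and `build_construct()`/`simulate_reads()` use an arbitrary
fixed fill. Neither choice affects tags, counts, or any downstream
statistic.

## 2. The synthetic world

The simulator's defaults are a single stated world, fixed before any test
outcome was observed, and not tuned afterwards:

* **Transcriptome** — lengths uniform on 400–2000 nt, GC 0.5, 2%
  untaggable controls (anchor-free). Lengths only need to exceed
  anchor + tag; the range is an ordinary mRNA ballpark.
* **Expression** — each cluster of transcripts is high (fold 8) in its
  block of tissues over a basal mean of 10, with multiplicative lognormal
  replicate noise, sdlog 0.3 (0.2 in the planted-recovery tests that
  state it). The noise model is a choice — the data source does not
  dictate one — and lognormal multiplicative noise is the standard
  assumption for expression magnitudes. The canonical configuration is 10
  clusters x 50 transcripts across 28 tissues with 8 replicates each
  (224 samples), matching the scale of the tissue-atlas design the
  package targets.
* **Reads** — per sample, tags are drawn from one multinomial
  proportional to the expression of taggable transcripts; substitution
  errors apply to the tag at `error_rate`; qualities are uniform Q35 with
  an optional fraction of uniformly poor (Q2) reads to exercise the
  filter. No PCR bias, size-selection artifacts, or paired-end mode.
* **Promoters** — i.i.d. composition at the target GC; each foreground
  sequence receives at most one planted PWM-sampled site, uniform
  position, random strand. Background sequences are exchangeable with
  unplanted foreground ones by construction.

A green test on this world establishes internal consistency (geometry,
accounting, statistical calibration, recovery of planted structure). It
does *not* establish performance on real reads, whose error and quality
profiles, adapter content, and expression dispersion are all richer than
the simulator's.

## 3. Tag reference and extraction conventions

The tag of a transcript is the 19 bases immediately 3' of the **3'-most**
anchor occurrence. The 3'-most site is the one the chemistry retains
(poly(A)-side capture); whether the original tag-assignment software used
the 3'-most or all sites is not documented, so the package commits to the
3'-most rule in one internal function shared by the simulator and
`build_tag_reference()`, making simulator truth and reference agree by
construction. Transcripts without an anchor, with fewer than 19 bases
after the last anchor, or with an ambiguous base in the tag region are
"untaggable"; every transcript lands in exactly one bucket (a tested
partition invariant). Lookup is exact-match — tag counting is exact in
this protocol, and sequencing-error rescue is deliberately out of scope.

Extraction applies, in order: the quality filter, demultiplexing, anchor
check. Conventions:

* *"poor score < 0.5"* is read on the **accuracy** scale: a base is poor
  when `1 - 10^(-Q/10) < 0.5`, i.e. Phred < ~3. The threshold is a
  parameter because the original scale is ambiguous.
* *"more than 20%"* is a strict inequality: exactly 20% poor passes.
* The anchor must match exactly; one mismatch in `CATG` discards the
  read. Rescuing near-anchors would trade unambiguous extraction for
  little yield at realistic error rates.
* Demultiplexing tolerates `max_mismatch = 0` by default; with a
  tolerance, ties go to "unassigned" (a value, not an error).
* Accounting is exact: per sample,
  `reads_total == reads_failed_quality + reads_no_barcode +
  reads_no_anchor + tags_emitted`. Reads failing quality or
  demultiplexing belong to no sample, so they appear in a `__run__` row;
  sample rows carry zeros in those columns.

## 4. Quantification

Multi-mapped tags are split evenly: a tag mapping to *k* transcripts
contributes `count/k` to each. The alternative reading ("assign the full
count to every transcript") was rejected because it violates mass
conservation — with the even split,
`assigned + unmatched == counted` holds to 1e-9 and is asserted.

Quantile normalization forces every column's sorted values onto the mean
of sorted columns. Ties within a column receive the **mean of the
reference values their ranks span** (so a 3-way tie takes the mean of
three reference values, not an interpolation at the average rank). The
operation is idempotent and, on tie-free input, agrees with
`limma::normalizeQuantiles` to machine precision (tested). The log2
transform uses pseudocount 1, the conventional choice when the source
does not state one.

## 5. Rarefaction

Classical subsampling without replacement; "size fractionation" is
treated as evaluation on a depth grid (default: 20 log-spaced points), not
as fragment-size modelling. The Monte-Carlo curve is validated against
the closed form `E[discovered at d] = sum_t [1 - C(N - n_t, d)/C(N, d)]`
(`expected_discovered()`, cross-checked against `vegan::rarefy`). The
`saturation_index()` operationalizes "near-saturation" as discovered at
half depth over discovered at full depth, linearly interpolating when the
half depth is off the grid. No Chao/ACE extrapolation: only observed
curves are reported.

## 6. Moderated-t tissue-specific calling

Each tissue is contrasted against **all remaining samples** (not a
mean of per-tissue means) with a two-group linear model per transcript on
log2 quantile-normalized values: effect = difference of group means,
pooled residual variance on `n - 2` df. The empirical-Bayes prior
`(d0, s0^2)` is fitted by method of moments on `log(s2)` using the
log-chi-square/scaled-F theory; the finite-`d0` branch is
formula-identical to `limma::fitFDist` and the whole pipeline reproduces
`limma::eBayes` t and p to 1e-8 on heterogeneous-variance data (tested
against limma as an independent oracle).

Two conventions in the degenerate branches:

* **Homogeneous limit.** When the empirical variance of `log(s2)` does
  not exceed its sampling term, `d0 = Inf` and `s0^2` is the geometric
  mean of the variances, so all-equal variances `v` recover `s0^2 = v`
  exactly.
* **`d0 = Inf` means no moderation.** The statistic uses each
  transcript's own `s2` on `df` degrees of freedom, i.e. it reduces
  exactly to the classical pooled-variance t. The continuous-limit
  alternative (shrink fully to `s0^2`, normal reference) was rejected as
  the package's convention because it either breaks the pooled-t
  reduction or, combined with t-distribution quantiles on `df`, makes
  null p-values conservative; the chosen convention keeps global-null
  p-values exactly uniform in both branches (tested by calibration and
  Kolmogorov–Smirnov).

The stringent filter is applied on raw p-values — fold change > 5 and
p < 1e-6, two-sided, in at least one tissue — because that is the
selection rule this class of atlas analysis uses; BH q-values are
reported alongside but do not gate the default filter. Whether the
upstream values should be quantile-normalized log2 counts (assumed here)
or a count-model transform is an open modelling question; the package
standardizes on the former.

## 7. Clustering

Rows are adjusted by median-centering then scaling to unit Euclidean
norm ("median center and normalization"); unit-norm scaling is the
standard heatmap reading of "normalization" and makes the adjustment
idempotent. Constant rows are dropped with a warning.

BF98 seeding: `S` subsamples (10% of rows each, floored at K) are each
clustered by K-means; the pooled `S*K` centroids form a candidate set;
K-means over the candidate set is started from each subsample's solution
and the lowest-distortion solution — distortion measured **on the
candidate set**, the convention adopted here since the variant is
under-specified — provides the initial seeds. The final Lloyd run
(Euclidean, convergence at centroid shift < 1e-6 or 300 iterations)
asserts per iteration that the objective never increases and repairs
empty clusters by re-seeding from the farthest point. Duplicated seeded
runs are executed (default 2) and their pairwise adjusted Rand index is
reported; at the default `S = 400` the planted-structure tests require
ARI >= 0.99 between runs, matching the observation that large subsample
counts make duplicated runs consistent. `K = 10, S = 400` are the
package defaults — the configuration selected for the tissue atlas this
package models; `cluster_sweep()` exposes the (K, S) grid with
within-SS and stability per cell, with no automatic chooser, since the
original selection was made by visual inspection.

Within-cluster substructure uses average-linkage agglomeration on
`1 - Pearson correlation` across samples — the heatmap convention —
validated against a brute-force average-linkage recomputation on small
instances, and exported as Newick via ape.

PCA is column-mean-centered SVD of sample profiles with explained
variance fractions; `pca_excluding()` refits after dropping named
samples, supporting the iterative "remove the separated groups and
recompute" workflow.

## 8. Motif over-representation

Scoring follows the Clover family: at every position and strand the
likelihood ratio `prod_j pwm[j, base]/bg[base]` is computed (ambiguous
bases contribute a factor 1), `avg_lr` is the arithmetic mean over all
sites of both strands, and the set-level **raw score** is
`sum over sequences of ln(avg_lr)` — additive, exactly 0 for an
uninformative PWM, and negative when a motif is depleted. The exact
recursion of the original tool is not restated anywhere accessible, so
this additive, sign-bearing aggregation is the package's committed
reading.

Randomization p-values use the add-one estimator
`p = (1 + #{random >= observed})/(1 + n_rand)`, so p is never 0 and never
below `1/(n_rand + 1)` (reported as such rather than "0"). Two of the
classical randomization controls are implemented: drawing
foreground-sized sets from the GC-matched background pool (default; the
design the promoter workflow implies) and mononucleotide shuffling of
the foreground. `n_rand` defaults to 1000 and must be >= 19 to resolve
p <= 0.05.

Site calls (`occurrence`, `gene_count`) use a likelihood-ratio threshold
of `2^6` (6 bits over background) — a configuration default, since no
site-call cutoff is documented for the original analysis; overlapping
sites count independently, so `occurrence >= gene_count` always. The
report gates significance on BH FDR <= alpha (default 0.05) while also
emitting raw p, since the two were conflated in the workflow this
mirrors. JASPAR matrices are read with a 0.375 per-cell pseudocount
before row normalization. Promoter retrieval is upstream of the package:
promoters arrive as FASTA.

## 9. Known limitations

* The simulator's quality strings are two-level (Q35/Q2); real quality
  profiles decay along the read.
* No fuzzy tag matching: sequencing errors in the tag region become
  unmatched mass rather than being rescued.
* BF98 K-means is pure R; at the default scale (500 x 224, S = 400) a
  full duplicated run takes about a minute, and very large S or matrices
  will scale linearly in S.
* The randomization test's draw strategy presumes the background pool is
  genuinely exchangeable with an unenriched foreground; GC matching is
  the only composition control applied.
* `d0 = Inf` disables moderation entirely (see §6); on genuinely
  homogeneous-variance data this forgoes the power gain full shrinkage
  would give, in exchange for exact pooled-t behaviour and calibration.
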