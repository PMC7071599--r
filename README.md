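# sagescape

Simulation and analysis of multiplexed deepSAGE expression profiles.

Tag-based serial analysis of gene expression (SAGE) measures transcript
abundance by counting short sequence tags instead of whole reads: each mRNA
is anchored at the 3'-most NlaIII site (`CATG`), and the type III enzyme
EcoP15I, cutting 25/27 nt downstream of its recognition site, releases a
fragment whose **19 bp tag** identifies the transcript. Barcoded linkers
let many samples share one sequencing run (the full library construct is
47 + 25 + 47 = 119 bp; a 50 bp single-end read covers
`barcode(6) + 2 degenerate bases + CATG + tag(19)`).

sagescape provides, as tested R code:

- a **seeded simulator** of every pipeline input: transcriptome FASTA,
  block-structured per-tissue expression with lognormal replicate noise,
  multiplexed FASTQ reads with the exact library geometry, and promoter
  sets with planted binding sites;
- the **virtual tag reference** (transcript → 19 bp tag, tag → transcript
  set) and **extraction**: Phred quality filter (poor-base accuracy < 0.5
  in more than 20% of bases fails a read), barcode demultiplexing, digital
  removal of the two degenerate bases, exact anchor check;
- **quantification**: tag counting, even-split assignment of multi-mapped
  tags (a tag shared by *k* transcripts contributes count/*k* to each, so
  mass is conserved), quantile normalization, log2 transform;
- the downstream **atlas statistics**: rarefaction/saturation curves with
  a closed-form hypergeometric reference, sample PCA with iterative
  exclusion, tissue-vs-rest **moderated-t** calling (empirical-Bayes
  variance shrinkage: `s2_tilde = (d0*s0^2 + df*s^2)/(d0 + df)`, p-values
  on `df + d0` degrees of freedom) with the stringent
  fold-change > 5, p < 1e-6 filter, **BF98 bootstrap-refined K-means**
  (K = 10, S = 400 defaults) with within-cluster average-linkage
  dendrograms and duplicated-run consistency (adjusted Rand index), and
  **Clover-style PWM over-representation** (raw score = sum of
  ln(average likelihood ratio) per sequence, randomization p-values
  against a GC-matched background pool, BH FDR).

## Worked example

```r
library(sagescape)
layout <- library_layout()
layout
#> deepSAGE library layout
#>   read: barcode(6) + degenerate(2) + CATG + tag(19), read_len 50
#>   EcoP15I cut 25/27 nt; construct 119 bp

# 1. simulate a multiplexed run: 6 tissues x 4 replicates, 20k reads each
tx     <- simulate_transcriptome(300, untaggable_frac = 0.02, seed = 1)
design <- cluster_design(n_clusters = 6, n_tissues = 6,
                         transcripts_per_cluster = 40, n_null = 60)
expr   <- simulate_expression(design, reps_per_tissue = 4, sigma = 0.2, seed = 2)
sheet  <- make_sample_sheet(colnames(expr$expression), expr$tissue_of,
                            layout, seed = 3)
run    <- simulate_reads(expr$expression, tx$tag_of, sheet, layout,
                         depth = 20000, seed = 4)

# 2. extract and quantify
res <- extract_tags(run$reads, sheet, layout)
tail(res$stats, 1)
#>    sample_id reads_total reads_failed_quality reads_no_barcode reads_no_anchor tags_emitted
#> 25   __run__      480000                    0                0               0       480000
ref <- build_tag_reference(tx$sequences, layout)
ref
#> TagReference: 294 tags over 300 transcripts (6 untaggable), 19 bp tags after CATG
asg <- assign_to_transcripts(count_tags(res$tags), ref)
l2  <- log2_transform(quantile_normalize(asg$expression))

# 3. rarefaction: is one sample sequenced to saturation?
rc <- rarefy(count_tags(res$tags)[, 1], n_reps = 10, seed = 5)
saturation_index(rc)
#> [1] 1          # every transcript already discovered by half depth

# 4. tissue-specific transcripts, then co-expression clusters
de   <- tissue_de(l2, expr$tissue_of)
hits <- apply_filter(de, fc_cut = 5, p_cut = 1e-6)
length(hits)
#> [1] 233        # of the 240 planted tissue-specific transcripts
fit <- kmeans_bf98(adjust_rows(l2[hits, ]), K = 6, S = 50, seed = 6)
fit
#> BF98-seeded K-means: K = 6, S = 50, within-SS = 20.8634
#> cluster sizes: 40 40 39 40 34 40
#> duplicated-run ARI: 1.0000
adjusted_rand_index(fit$assignment, expr$cluster_of[names(fit$assignment)])
#> [1] 1          # planted cluster structure recovered exactly

# 5. motif over-representation in a promoter cluster
motifs <- read_jaspar(system.file("extdata", "example_motifs.jaspar",
                                  package = "sagescape"))
pr <- simulate_promoters(n_fore = 25, n_back = 100, length = 1000,
                         pwm = motifs[["SYN0001.1"]], plant_rate = 0.8,
                         gc = 0.45, seed = 7)
enrichment_report(list(cluster1 = pr$foreground), motifs, pr$background,
                  n_rand = 499, seed = 8)
#>    cluster jaspar_id tf_name occurrence gene_count raw_score     p   fdr
#> 1 cluster1 SYN0001.1 SYNRUNT         70         24     22.49 0.002 0.006
#> 2 cluster1 SYN0002.1 SYNEBOX        210         25     -3.53 0.702 0.702
#> 3 cluster1 SYN0003.1  SYNZIP         71         24    -10.78 0.682 0.702
```

The planted motif (SYN0001.1) is ranked first by raw score and is the only
significant one; the bundled PWMs are synthetic examples, not real JASPAR
entries.

## Command line

A thin CLI over the pipeline stages ships in
`inst/scripts/sagescape.R` (subcommands `extract`, `quantify`, `cluster`);
see the header of that file for usage.

## Documentation

`vignettes/sagescape-methods.Rmd` describes the models, parameter
conventions, numerical choices, and what the synthetic world does and does
not establish.
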