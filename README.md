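# cotx — exon-biased occupancy analysis of co-transcriptional ChIP-seq

`cotx` is an R package for the downstream analysis of ChIP-seq and
nascent RNA-seq coverage tracks of proteins that travel with elongating
RNA polymerase II.  It answers two questions about such a protein's
footprint on transcription units:

1. **Where along genes does it sit?**  Metagene profiles: 500 bp
   per-base flanks around a gene body scaled to 16 bins, averaged over
   genes, stratified by expression class (RPKM < 1 inactive, ≥ 1
   active, > 5 high), each dataset normalised to its per-million
   sequencing depth.
2. **Does it prefer exons over introns on the nascent transcript?**
   For every exon–intron–exon triplet (introns strictly longer than
   100 bp), the mean ChIP coverage of each feature is divided by the
   mean input coverage, and the exon and intron populations are
   compared with a two-sided unpaired Wilcoxon rank-sum test:

   `norm(feature) = (chip_mean / chip_depth) / (input_mean / input_depth)`,
   with `U = Σ rank(x) − n₁(n₁+1)/2`, exact p for small samples and a
   tie-corrected normal approximation otherwise.

Inputs are Bedgraph coverage tracks (ChIP, input, optionally a second
ChIP track), a refGene-style annotation table, and optionally BED read
alignments for RPKM stratification.  A seeded simulator generates all
of these with known ground truth (gene structures, expression,
fragment-pileup coverage with an exon occupancy multiplier and a
TSS-proximal peak), so every stage of the pipeline is validated by
parameter recovery.  The methods vignette
(`vignettes/exon-intron-occupancy.Rmd`) documents the models and design
choices.

## Worked example

Simulate a 120-gene dataset with a 3-fold exonic occupancy bias, filter
the annotation, and run the enrichment analysis:

```r
library(cotx)

spec  <- simulation_spec(seed = 7, n_genes = 120)   # f_exon = 3 by default
sim   <- simulate_dataset(spec)
genes <- filter_genes(sim$genes)
trip  <- derive_features(genes)$triplets
enr   <- triplet_enrichment(sim$chip_upf1, sim$input, trip)
exon_vs_intron_summary(enr)
#> Exon vs intron enrichment summary (n = 421 triplets)
#>   left_vs_intron   p = 1.377e-30 (U = 129187)
#>   right_vs_intron  p = 7.3e-31 (U = 129380)
#>   left_vs_right    p = 0.9234 (U = 88280.5)
#>   median exon/intron ratio: left 3.033, right 3.022
```

Both flanking exons are far more enriched than the intron between them
(p ≈ 10⁻³⁰), the two exons are indistinguishable from each other
(p = 0.92), and the median input-normalised exon/intron ratio recovers
the simulated 3-fold multiplier.  The expression pathway on the same
dataset:

```r
expr <- expression_table(sim$rna_reads, genes,
                         total_mapped = spec$rna_total_mapped)
table(expr$activity_class)
#> inactive   active     high
#>       48       42       30
cor(attr(sim$genes, "true_rpkm")[genes$name], expr$rpkm,
    method = "spearman")
#> [1] 0.98
```

And the correlation of per-exon coverage between the two simulated ChIP
tracks (both driven by the same expression field):

```r
exon_correlation(sim$chip_upf1, sim$chip_pol2, genes)
#> Exon correlation over 593 exons: Pearson(log10) = 0.8927, Spearman = 0.9099
```

An end-to-end run (`run_pipeline()`, or `Rscript inst/scripts/cotx.R
run --config run.yaml`) writes `rpkm.tsv`, `metagene_*.tsv`,
`enrichment.tsv`, `percent_profile.tsv`, `exon_correlation.tsv`, a
`summary.json` and a reproducibility `manifest.json`; identical configs
produce byte-identical summaries.

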