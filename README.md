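# h1blocks

Linker histones of the H1 family stabilize nucleosomal linker DNA and
compact chromatin. In differentiated human cells, the H1.5 subtype does not
bind diffusely: it accumulates in broad, multi-kilobase *blocks* of
enrichment that preferentially cover clustered gene families (olfactory
receptors, late cornified envelope genes, and similar tandem arrays) and
are associated with transcriptional repression. `h1blocks` is an R package
for mapping and characterizing such blocks from ChIP-seq coverage
summarized in fixed 100-bp windows, and for relating them to gene families
and expression. It is aimed at epigenomics analysts who have windowed
ChIP/input counts, a gene annotation, a gene-family catalog, and per-gene
expression tables.

## The statistics at its core

**Windowed Poisson enrichment.** For each 100-bp window with ChIP count
*k* and input count *m*, the expected ChIP count under no enrichment is the
library-scaled local input,

    lambda = max( m * Nc/Ni , mean(m) * Nc/Ni )

where *Nc* and *Ni* are the ChIP and input library sizes and the
genome-wide mean input floors the rate so zero-input windows cannot produce
spurious calls. The one-sided p-value is P(X >= k) for X ~ Poisson(lambda);
a **peak** is a single window with p < 0.001 (raw, unmerged). Block
structure is profiled by averaging the -log10 p scores in non-overlapping
5-kb windows and comparing the histogram against a shuffled-score control.

**Targets.** A *genic region* is a gene body extended 3 kb beyond both
ends; a *distal intergenic region* is at least 3 kb from every gene. A
region with >= 1 peak per kb is a *target locus*; a *target gene* is bound
in its genic region, flanks a target intergenic region, or both.

**Families and clusters.** A *cluster* is a run of >= 3 adjacent genes of
one family. Enrichment of family membership (and of clustered membership)
among target genes is an exact binomial upper tail against the genome-wide
background proportion. Family-by-sample binding is summarized as z-scores
(mean window score over the family's genic regions, standardized across
families per sample) with hierarchical ordering (1 - Pearson r, average
linkage).

**Expression.** Binding and expression are related through 2000-gene bins
and a gene-level Pearson correlation on log1p expression; knockdown
deregulation uses a 1.5-fold rule on pseudocounted values, broken down by
target, family, and cluster status. Exclusivity of a peak set against
another interval set (e.g. DNase hypersensitive sites) is assessed by a
permutation test that relocates peaks uniformly within chromosomes.

A seeded synthetic-data generator (`sim_config()`, `simulate_dataset()`)
plants enrichment blocks over clustered families with coupled repression,
so the full pipeline is testable end to end.

## Worked example

```r
library(h1blocks)

sim   <- simulate_dataset(sim_config(seed = 1))   # 2-Mb genome, planted blocks
pv    <- poisson_enrichment(sim$counts)
peaks <- call_peaks(pv, alpha = 0.001)
nrow(peaks)
#> [1] 3762

gen <- peak_density(genic_regions(sim$annotation), peaks)
itg <- peak_density(intergenic_regions(sim$annotation), peaks)
tt  <- classify_targets(sim$annotation, gen, itg)
summarize_targets(tt)
#> $counts
#>      genic intergenic       both       none
#>         59          4         25        212
#> $n_targets
#> [1] 88
```

88 of 300 genes are targets: 59 bound only in their genic regions, 4 only
next to bound intergenic regions, 25 both. Family enrichment among targets:

```r
catalog <- family_catalog(as.data.frame(sim$annotation))
fe <- family_enrichment(tt, catalog, sim$annotation, sim$clusters)
fe$family$percent;  fe$family$p
#> [1] 76
#> [1] 5.96e-12
fe$clustered$percent;  fe$clustered$p
#> [1] 91
#> [1] 1.86e-12
```

76% of target genes are family members (genome background 40%), and 91% of
those are clustered (background 51%) — the planted preference of blocks for
clustered families, recovered with binomial p ~ 1e-12. Binding represses:

```r
binding <- gene_binding_scores(pv, sim$annotation)
ctrl <- setNames(sim$expression$control, sim$expression$gene_id)
bc <- binding_expression_curve(binding, ctrl, bin = 30)
round(bc$r, 3)
#> [1] -0.818

kd    <- setNames(sim$expression$kd, sim$expression$gene_id)
calls <- classify_deregulated(ctrl, kd)          # 1.5-fold rule
bd    <- deregulation_breakdown(calls, tt, catalog, sim$clusters)
c(bd$all$total, bd$all$percent_up, bd$targets$percent_up)
#> [1] 20 95 100
```

The gene-level binding-expression correlation is strongly negative, and of
the 20 deregulated genes after the simulated knockdown, 95% are
up-regulated (100% among targets) — the planted de-repression of
non-clustered target genes. `run_pipeline(pipeline_config())` performs all
of the above in one call and writes BED/bedGraph/TSV outputs plus a
manifest that makes the run bit-identical on re-execution.

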