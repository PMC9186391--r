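# nucfrac

Analysis of nuclear–cytoplasmic fractionation RNA-seq, for labs asking
which transcripts depend on a given factor for nuclear export. Starting
from gene-level count tables of total, nuclear, and cytoplasmic libraries
in wild-type (WT) and knockout (KO) cells, the package computes per-gene
localization shifts, relates them to transcript features (GC content, exon
structure, splicing efficiency), and integrates CLIP binding data. A fully
seeded synthetic-data generator with a planted GC-dependent export
impairment makes every stage verifiable against a known truth table.

## The statistics

Counts are normalized to FPKM
(`FPKM_g = count_g * 1e9 / (length_g * library_size)`, longest isoform per
gene), averaged across replicates (3 WT, 4 KO per fraction), and filtered
to genes with FPKM > 1 in all three fractions of both genotypes. For each
detected gene:

```
L_g = log2(FPKM_KO_nuc / FPKM_KO_cyto) - log2(FPKM_WT_nuc / FPKM_WT_cyto)
E_g = log2(FPKM_KO_total / FPKM_WT_total)
```

`L_g > 1` (strictly) calls a gene nuclear-enriched; detected genes are
ranked by descending `L_g`. Per-intron splicing efficiency is
`ee / (ee + (ei_donor + ei_acceptor)/2)` from junction-spanning reads,
computed only for introns with every junction covered by ≥ 10 reads.
Features are Pearson-correlated with `L` (pairwise complete, BH-adjusted
q-values alongside raw p). CLIP peaks are annotated by majority overlap
(CDS > 5'UTR > 3'UTR > noncoding exon > intron), target-versus-nontarget
localization shifts are tested with a two-sample Kolmogorov–Smirnov test,
metagene CLIP/input profiles are built over the scaled exonic gene body,
and peak GC enrichment is tested with Wilcoxon rank-sum tests.

## Worked example

Simulate a full experiment (2000 genes, 21 libraries, CLIP tracks) and run
every stage through the on-disk formats:

```r
library(nucfrac)
res <- run_pipeline("all", out_dir = "demo", seed = 1)
#> simulate: 2000 genes, 21 samples -> demo/sim
#> splice: 1718/1857 transcripts with a covered intron
#> features: 2000 genes
#> localize: 1942/2000 genes retained, 206 nuclear-enriched
#> clip: 300 peaks, 300 targets, KS D = 0.174

subset(res$correlation$correlations, feature == "gc_content")
#>      feature    n         r            p            q constant
#> 1 gc_content 1942 0.2551361 3.110086e-30 2.799077e-29    FALSE
```

Reading the output: 1942 of 2000 simulated genes pass the FPKM > 1
detection filter; 206 of them shift more than twofold toward the nucleus
in the knockout (`L > 1`), and GC content is the feature most correlated
with that shift (r = 0.26) — the planted effect, attenuated by counting
noise. The CLIP targets, designated with a GC bias by the generator, show
a clear localization shift versus nontargets (KS D = 0.174,
p ≈ 7.7e-7), and peak GC (median 0.80) far exceeds the background
transcript GC (median 0.53). All tables are written under `demo/`
(`localization.tsv`, `correlations.tsv`, `peak_annotation.tsv`,
`metagene.tsv`, ...) together with a `manifest.json` recording the
configuration, seed, and input checksums.

A command-line front end with the same subcommands lives at
`inst/scripts/nucfrac-pipeline.R`.

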