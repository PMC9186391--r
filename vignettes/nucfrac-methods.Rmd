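---
title: "Quantifying RNA nuclear export from fractionation RNA-seq"
author: "nucfrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNA nuclear export from fractionation RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a nuclear-export factor is lost, its substrate RNAs accumulate in the
nucleus and are often degraded there by the nuclear exosome. A standard way
to find those substrates genome-wide is nuclear–cytoplasmic fractionation
RNA-seq: cells of the wild-type (WT) and knockout (KO) genotypes are
fractionated, and total, nuclear, and cytoplasmic RNA from each are
sequenced as separate libraries with biological replicates (here 3 WT and 4
KO per fraction). `nucfrac` implements the downstream analysis of such an
experiment — from gene-level count tables to per-gene localization shifts,
transcript-feature correlations (most importantly GC content), and the
integration of CLIP binding data — together with a seeded synthetic-data
generator that plants a known GC-dependent export impairment, so that every
stage of the pipeline can be verified against a truth table.

## The localization and expression statistics

Counts are normalized to FPKM,

$$\mathrm{FPKM}_g = \frac{c_g \cdot 10^9}{\ell_g \cdot N},$$

with $c_g$ the read count of gene $g$, $\ell_g$ the exonic length of its
longest isoform, and $N$ the library's total mapped reads (taken from the
design table, because mapped totals include reads outside the counted gene
set). FPKM is averaged arithmetically across replicates within each
(genotype, fraction) cell. A gene is *detected* when its averaged FPKM is
strictly greater than 1 in all three fractions; by default this is required
in **both** genotypes, which guarantees strictly positive arguments to every
logarithm below without any pseudocount. (An `either`-genotype mode is
available; with it, a gene can carry an undefined statistic if one genotype
fails the floor, so the default is the safer reading.)

For each detected gene the **relative localization** is

$$L_g = \log_2\frac{\mathrm{FPKM}^{KO}_{nuc}}{\mathrm{FPKM}^{KO}_{cyto}}
      - \log_2\frac{\mathrm{FPKM}^{WT}_{nuc}}{\mathrm{FPKM}^{WT}_{cyto}},$$

positive when the gene shifts toward the nucleus upon knockout, and the
**relative expression** is

$$E_g = \log_2\frac{\mathrm{FPKM}^{KO}_{total}}{\mathrm{FPKM}^{WT}_{total}}.$$

A gene is called *nuclear-enriched* when $L_g > 1$ strictly (a greater than
twofold increase of its nuclear:cytoplasmic ratio), and detected genes are
ranked by descending $L_g$ with ties broken by gene id, so rank 1 is the
most nuclear-enriched gene. Both thresholds are configuration values, not
constants in stage logic.

## Transcript features

Seven covariates are computed per gene from the genome and annotation,
using the longest isoform (greatest exonic length; ties broken by the
lexicographically smallest transcript id so selection is deterministic):

* **GC content** of the mature (spliced) sequence, case-insensitive, with
  ambiguous bases excluded from numerator and denominator. A separate
  gene-body GC over the genomic span is also emitted for track-style
  displays; which one enters the correlation analysis is a configuration
  switch (`exonic` by default, since the other features are defined at the
  exon level).
* **exon count**, **transcript length** (exons only), **longest exon
  length**, **exon density** (exonic length / genomic gene length), and
  **gene length** (genomic span).
* **splicing efficiency** (SE), from junction-spanning read counts. For an
  intron with $ee$ exon–exon reads and $ei_d, ei_a$ reads over the two
  exon–intron boundaries,
  $$SE = \frac{ee}{ee + (ei_d + ei_a)/2}.$$
  The two boundary counts are averaged because one unspliced molecule
  offers a read opportunity at *both* boundaries, so summing them would
  weight the unspliced form twice; a literal-sum mode is provided
  (`ei_mode = "sum"`). SE is only computed for introns whose junctions are
  each covered by at least 10 spanning reads; by default the coverage of a
  boundary counts reads spanning it in either spliced or unspliced form
  ($ee + ei_d \ge 10$ and $ee + ei_a \ge 10$), with a stricter per-category
  mode available. Per transcript, SE is summarized as the mean, maximum,
  and minimum over covered introns; transcripts with no covered intron
  (including all single-exon transcripts) carry undefined summaries, which
  propagate as missing values — never as zeros — into the correlations.

Each feature is Pearson-correlated with $L$ over detected genes using
pairwise-complete observations. Raw two-sided p-values are reported, with
Benjamini–Hochberg q-values alongside (added, not substituted). GC content
additionally gets least-squares regressions of $L$ and of $E$.
Biotype composition is tabulated for the detected set and for the
nuclear-enriched subset.

## CLIP integration

CLIP peaks (BED6, stranded) are assigned to the gene with maximal
same-strand overlap and to a functional category by majority overlap within
that gene, with priority CDS > 5'UTR > 3'UTR > noncoding exon > intron on
ties; peaks overlapping no same-strand gene are intergenic. A gene hosting
at least one assigned peak is a *CLIP target*.

The metagene profile scales each target gene body to a fixed number of bins
(100 by default) after projecting read midpoints into exonic
(mature-transcript) coordinates — intronic positions are removed because
binding is expected on processed transcripts; a genomic-span mode exists.
Per gene, CLIP and input bin counts each receive a one-read-equivalent
pseudocount and are normalized to the gene's own total before their ratio
is taken; the profile is the mean ratio across genes. The pseudocount is
applied symmetrically to both tracks: this keeps the profile exactly 1.0 in
every bin when CLIP and input coincide, which is the natural calibration of
a relative-to-input display (an input-only pseudocount would bias every bin
of the identity comparison away from 1).

The localization shift of CLIP targets versus nontargets is tested on their
$L$ values with the two-sided two-sample Kolmogorov–Smirnov test
(`stats::ks.test`, which switches to the exact null distribution for small
groups), and empirical CDF coordinates are exported for plotting. GC
enrichment compares peak sequences, exonic sequences of peak-hosting
transcripts, and background transcripts with pairwise two-sided Wilcoxon
rank-sum tests, summarized as median, 25–75 box, and 10–90 whiskers.

## The synthetic-data generator

`simulate_dataset()` draws, per gene: exon count (uniform 1–15), exon and
intron lengths (log-normal, medians 150 and 400 nt), a GC target
(Beta(5,5) rescaled to [0.30, 0.80]), a wild-type total abundance
(log-normal FPKM, median 15), and a wild-type nuclear:cytoplasmic ratio
$r_g$ (log-normal, log-SD 0.5). The knockout ratio is
$r_g \cdot 2^{\Delta_g}$ with the planted shift

$$\Delta_g = \beta\,(GC_g - \overline{GC}) + \varepsilon_g,\qquad
\varepsilon_g \sim N(0, 0.5),\ \beta = 3,$$

and the knockout total abundance is scaled by
$2^{-\gamma \max(0, \Delta_g)}$ with $\gamma = 1$, coupling nuclear
trapping to expression loss (so that GC correlates positively with $L$ and
negatively with $E$, mirroring the direction of the biological effect).
Counts for every library (3 WT + 4 KO replicates x 3 fractions, $10^7$
mapped reads each) are negative binomial with mean
$\mathrm{FPKM}\cdot\ell\cdot N/10^9$ and dispersion $\phi = 0.1$
(variance $\mu + \phi\mu^2$). The three fractions are simulated as
independent libraries — no shared cell-level noise — which is a documented
simplification.

The genome is one synthetic chromosome: exonic bases are G/C with the
gene's target probability, introns and intergenic spacers sit at a 0.40
background, and the realized exonic GC of each gene is written back into
the truth table. Coding genes receive a CDS over the central 70% of the
mature transcript so UTRs exist for peak annotation. Junction counts per
intron draw a Poisson depth proportional to abundance (50 reads at average
abundance), split the spliced fraction binomially by the intron's true SE,
and divide the remainder across the two boundaries. CLIP targets (300 of
2000 genes) are designated by GC-biased sampling (weight $e^{25\,GC_g}$,
chosen so that the planted target-versus-nontarget localization shift is
clearly detectable by the KS test at this scale); each target's single
peak occupies the highest-GC window of its mature sequence that lies
within one exon, and CLIP read density is 10-fold enriched over input
inside the peak.

All draws flow from one master seed through named substreams (truth,
genome, counts, junctions, CLIP), so a fixed seed reproduces every emitted
file byte for byte and any one stage can be regenerated in isolation.

### What the generator does and does not emulate

It reproduces the statistical structure the analysis is sensitive to:
replicate design, NB counting noise, a GC-driven localization shift with
coupled expression loss, junction-limited SE estimation, and GC-targeted
CLIP binding. It does not emulate alignment artifacts, multimapping,
fragment-level (FASTQ) data, isoform mixtures, batch effects, or correlated
fraction libraries. Tests passing on synthetic data therefore establish the
correctness and calibration of the computations, not robustness to every
artifact of real libraries.

### Calibration facts worth knowing

With the defaults above, the count-sampling noise on $\hat L_g$ has
variance $\approx 2(\phi/3 + \phi/4)/\ln^2 2 \approx 0.24$ (SD
$\approx 0.5$ log2 units), because four log-FPKM terms enter $L$ and the NB
dispersion dominates at these depths. Two consequences, verified by the
test suite: under an exact null (knockout generatively identical to wild
type) about 2–3% of genes still exceed $L > 1$ from sampling noise alone;
and the pipeline-recovered correlation $r(GC, \hat L)$ is attenuated by a
factor $\approx \sigma_\Delta/\sqrt{\sigma_\Delta^2 + 0.24} \approx 0.75$
relative to the truth-table correlation $r(GC, \Delta) \approx 0.41$.
Detecting the planted effect (sign and significance) is essentially
certain at $n = 2000$; recovering the attenuation-free correlation value is
not possible from these counts alone.

## Numerical and design choices

* Internal coordinates are GRanges (1-based, closed) throughout; BED input
  and output is converted at the boundary by rtracklayer. One internal
  convention removes off-by-one drift between the GTF (1-based) and BED
  (0-based) worlds.
* No pseudocounts in the localization statistics: the strict detection
  filter guarantees positivity.
* Longest-isoform ties, enrichment ranking ties, and peak-assignment ties
  all break lexicographically, so every output is reproducible under
  permutation of the input.
* A feature that is constant across genes yields an undefined correlation
  and is flagged rather than aborting the report.
* Degenerate CLIP inputs (a gene with no input reads) are excluded from the
  metagene and counted; groups of fewer than two genes make the KS test
  refuse explicitly.
* Problem sizes in the test suite are desk-scale by design: formula oracles
  run on thousands of randomized fixtures; Monte Carlo calibration uses 50
  seeds at 1000 genes; parameter recovery uses the default 2000-gene
  simulation and 100 seeds of the counts-only chain.

## Known limitations

* `library_size` is taken from the design table; whether the original
  mapped-read totals counted all mapped reads or feature-assigned reads is
  a documented configuration concern for real data.
* The analysis is gene-level: isoform mixtures and alternative splicing
  quantification (PSI) are out of scope.
* The junction generator splits each unspliced molecule's read between the
  two boundaries, so the averaged-boundary SE estimator is upward biased at
  low SE under the generator's own model; the literal-sum mode is unbiased
  there. On real data the averaged mode remains the recommended default
  because boundary reads from one molecule are not independent
  observations.
* Peaks spanning exon–exon junctions in transcript space are emitted as a
  single exonic window by the generator; the annotator handles multi-block
  peaks but the simulator does not produce them.
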