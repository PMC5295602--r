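---
title: "Pool-seq F_ST and heterozygosity: models, filters and design choices"
author: "poolpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq F_ST and heterozygosity: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolpopgen)
library(data.table)
```

# Scope and model

`poolpopgen` analyses exon-enriched pooled sequencing of population
samples. In pool-seq, DNA from many individuals is pooled before library
preparation, so a site's allele frequency is estimated as a read-coverage
ratio rather than from genotypes. Two design features drive everything
downstream:

1. **Replicate pools.** Each collection is sequenced as at least two
   independently prepared pooled libraries. Sites whose allele frequencies
   disagree between replicates beyond sampling noise are unreliable
   (alignment artefacts, collapsed paralogs, contamination) and are
   discarded by a per-site heterogeneity χ² test.
2. **Mosquito counts, not read counts, set the information limit.** The
   F~ST~ estimator uses the number of pooled individuals (n~i~, n~j~) in
   its sampling corrections; read depth only enters through the precision
   of the frequency estimates and the pooled-frequency weighting.

## The F~ST~ decomposition

For SNP *s* between collections *i* and *j*:

$$\alpha_{i,s} = 2\,\hat p_{i,s}(1-\hat p_{i,s}), \qquad
b_s = \frac{n_i\,\alpha_{i,s} + n_j\,\alpha_{j,s}}{n_i+n_j-1}$$

$$a_s = \frac{4 n_i (\hat p_{i,s}-\hat p_s)^2 +
              4 n_j (\hat p_{j,s}-\hat p_s)^2 - b_s}
             {2\,[\,2 n_i n_j/(n_i+n_j)\,]}, \qquad
F_{ST}(s) = \frac{a_s}{a_s+b_s}$$

with $\hat p_s$ the coverage-weighted pooled frequency. The gene-level
value is the **ratio of sums** $\sum a_s / \sum (a_s+b_s)$, which weights
informative SNPs more than a mean of per-SNP ratios would and is the
quantity whose expectation matches the divergence parameter of the
simulation model.

The grouping of the $a_s$ numerator and denominator is fixed by two limit
requirements that any correct transcription must satisfy, and which the
test suite enforces: a fixed difference ($p_i=1$, $p_j=0$) must give
$b_s=0$ and $F_{ST}=1$, and identical frequencies must give $a_s \le 0$,
hence $F_{ST} \le 0$. A second, independently written transcription of the
equations is kept in the test helpers and compared to the vectorised
implementation to 1e-12 on 1000 random sites.

**Bi-allelic reduction.** The formulas use one frequency per site. The
tracked allele is the reference allele among reference + alternate
coverage, the alternate being the second most common allele over the
pooled coverage of both collections (ties broken by the lexicographically
smallest token). Third alleles are excluded from the frequency but still
count toward *nid*. If the reference allele itself carries no coverage,
the major allele stands in for it.

## Filter cascade

Per library: sites with total coverage below `min_cov = 15` are removed
(a site with exactly 15 reads is retained); sites above `max_cov = 2000`
are **excluded** by default — the cap exists to remove collapsed
repetitive regions, and exclusion serves that purpose directly. A
`truncate` policy (proportional scaling to 2000) is available for users
who prefer the literal cap. `min_cov` applies per library, before
replicate summing.

Per collection: replicate libraries are intersected (a SNP must occur in
every replicate) and tested for concordance. The test is a plain Pearson
χ² on the 2 × *nid* table of allele counts with *nid* − 1 degrees of
freedom, no continuity correction. Indel alleles are first-class tokens
contributing to *nid* and to the table; a flag excludes them if a
nucleotide-only reading is wanted. Because the screen is per-SNP, no
multiple-testing correction is applied; `alpha = 0.05` is the per-SNP
false-discard rate and is configurable. Tables with any expected cell
below 1 are retained with a `flag_lowexp` marker rather than tested — the
statistic is meaningless there and discarding on it would silently bias
against low-coverage minor alleles. Replicate counts of retained sites
are summed, and the mosquito count entering the estimator is the sum over
replicates.

## Annotation

Gene models are read from GTF (`exon` + `CDS` rows) with the genome
FASTA. UTRs are derived as exon minus CDS span (strand-aware), introns as
gaps between exons, and the 5′NTR/3′NTR as 600 bp nontranscribed flanks
upstream/downstream of the transcript on the coding strand, truncated at
contig edges and flagged rather than dropped. CDS frames are recomputed
in coding order; transcripts whose CDS length is not a multiple of 3 are
flagged incomplete and excluded from consequence calls only. Nonsense
changes count as replacement — the output's silent/replacement binary has
no stop category.

Coordinates are **1-based inclusive everywhere internally** — the native
convention of GTF, IRanges and the rest of the R genomics stack — with
conversion only at the BED boundary (handled by `rtracklayer`). A single
convention end to end is what prevents off-by-one drift; in R that
convention is 1-based.

Overlapping genes: a position inside two gene windows is tracked once per
gene (duplicated records), which keeps the gene-centric SNPID scheme
consistent. Overlapping transcripts of one gene are reconciled by a
canonical transcript — the longest complete CDS, ties broken by
transcript id — for gene-level reporting; per-transcript classification
is available via `classify_region(all_transcripts = TRUE)` since the
choice between once-per-gene and once-per-transcript reporting is
genuinely open in this kind of pipeline.

SNPIDs order positions hierarchically: chromosome assignment (1, 2, 3,
unmapped, from a contig-to-chromosome map), supercontig, gene position in
the supercontig, offset within the gene window. Each gene gets a base
offset equal to the cumulative length of all earlier gene windows, making
the id monotone within and across genes.

## Distribution comparisons

Per-gene statistics are binned at width 0.01 (F~ST~ from −0.05 to 1,
H~exp~ from 0 to 1; left-closed bins, the last bin closed). Histograms
are compared **bin by bin**: for each bin, a k × 2 heterogeneity χ² of
in-bin versus out-of-bin gene counts with k − 1 degrees of freedom, and
LOD = −log~10~ p. LOD is computed from `pchisq(log.p = TRUE)`, so very
strong signals do not underflow. The per-bin (rather than omnibus k × B)
design is what lets the profile be plotted as a function of the statistic
and read as "where the distributions differ". A bin empty in all
distributions has LOD 0 by convention, and exact zeros are protected
against floating-point dust. LOD = 3 (p = 10⁻³) is used as the stringent
per-bin cutoff.

Tails take the `floor(0.01 n)` extreme genes per direction after ranking,
ties at the cutoff broken by gene id; each collection's tail is taken on
its own gene set. The mode of a continuous distribution is reported as
the midpoint of the most populated 0.01 bin; the 5%/95% cutoffs use
linear-interpolation quantiles (R type 7) with nearest-rank available by
argument.

# The synthetic-data generator

The generator exists so that every downstream stage can be exercised, and
the estimator validated for **parameter recovery**, without any sequence
download. It emulates the study design it stands in for: two or more
collections, each as replicate pooled libraries of a fixed number of
individuals, over an exome-like annotation.

* **Reference**: `n_genes` two-exon genes (UTRs 20–40 bp, one intron
  40–80 bp, CDS length a multiple of 3) on both strands, five genes per
  supercontig, supercontigs assigned round-robin to chromosomes 1–3 and
  an unmapped class; 600 bp flanks; CDS-only capture BED.
* **Divergence**: Balding–Nichols. A segregating site's ancestral minor
  allele frequency is uniform on `ancestral_maf_range` (default
  0.05–0.5); each collection's frequency is
  Beta(p(1−θ)/θ, (1−p)(1−θ)/θ), so θ is the expected F~ST~ — a known
  target the acceptance suite can demand back. θ can be overridden per
  chromosome (`theta_chrom`) to plant, e.g., sex-linked divergence on
  chromosome 1 only.
* **Two-stage pooling**: per collection, 2·n individuals' chromosomes are
  drawn binomially from the true frequency once — replicate libraries
  share this pool frequency — then each replicate samples reads at
  negative-binomial coverage (mean 100, size 10 by default; NB rather
  than Poisson so the coverage cap is exercised realistically) with
  miscalls at `error_rate = 0.001` spread over the other bases.
  Individuals and read depth are therefore separately controllable,
  mirroring the estimator's use of mosquito counts.
* **Nuisance structure**: `repeat_fraction` of sites get 10–100× inflated
  coverage (the cap's target); `indel_rate` of segregating sites carry an
  indel allele; `triallelic_fraction` a second alternate. `snp_density`
  (default 0.05) sets the fraction of window sites segregating, chosen to
  match the ~5–8% polymorphism of real exon-enriched data. The default
  pool size of 12 individuals per replicate matches the sequenced
  replicate libraries the design emulates.

All draws derive from one integer seed with a fixed split (reference:
seed; frequencies: seed + 1; library *k*: seed + 100 + *k*), so every
output file is bit-reproducible.

**What the generator does not model** — and what passing tests therefore
do not show about real data: linkage between sites (sites are
independent), capture bias and coverage autocorrelation along the genome,
unequal DNA contribution per pooled individual, mapping error structure,
and base-quality variation. In particular, with symmetric sequencing
error almost every deep site shows a stray read, so simulated
percent-polymorphic values (~20% at coverage 100) are far above the 5–8%
of quality-filtered real data; the printed-table worked examples, not the
simulation, anchor that statistic.

# Validation and problem sizes

```{r recovery, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 60, theta = 0.2,
                  collections = list(collection_spec("A", 12),
                                     collection_spec("B", 12)))
st  <- simulate_study(cfg, tempfile("recovery"))
res <- run_pipeline(st$config_file)
median(res$comparisons[[1]]$genes$fst)   # targets 0.2
```

The acceptance suite runs the full pipeline — generation, parsing,
trimming, concordance filtering, intersection, annotation, estimation —
at θ ∈ {0.05, 0.1, 0.2, 0.4} and requires the median per-gene F~ST~ to be
monotone in θ and within ±0.05 of θ at 0.2; at θ = 0 at least 95% of gene
values must fall below 0.05. The sex-divergence scenario plants θ = 0.3
on chromosome 1 with θ = 0 elsewhere and requires the chromosome-1
distribution to be right-shifted with per-bin LOD > 3 while a uniform
control stays below 3 everywhere.

Problem sizes are the package's own choice: 60 genes (~110k sites per
library) per recovery run and 160 genes for the sex scenarios give the
median-of-genes estimate and the LOD signature comfortable margins —
observed recovery error at θ = 0.2 is below 0.01, against the 0.05
acceptance band — while keeping a full validation run in the minutes
range on a single core.

Numerical conventions collected in one place: Pearson χ² without
continuity correction everywhere; expected-cell < 1 tables retained with
a flag; per-SNP F~ST~ undefined (NA, excluded from gene sums) when
a + b = 0; histograms clamp out-of-range values into end bins with a
warning; alt-allele ties broken lexicographically; tail ties broken by
gene id; quantiles type 7.

# Known limitations

* Replicate folding for more than two replicates intersects pairwise in
  file order; the concordance test is only ever applied to pairs.
* Gene-level H~exp~ averages over **all** retained sites by default
  (monomorphic included), which is what pushes genome-wide H~exp~
  distributions toward zero; `polymorphic_only = TRUE` gives the other
  reading, since the site universe for gene averages is a genuine
  reporting choice.
* No confidence intervals on F~ST~ are produced, and no LD-aware
  statistics; the per-bin LOD profile is a descriptive comparison, not a
  test with genome-wide error control.
* The analysis path is fully deterministic; all randomness lives in the
  generator.
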