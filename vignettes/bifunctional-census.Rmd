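---
title: "Counting bifunctional gene loci and what array probes can(not) see"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting bifunctional gene loci and what array probes can(not) see}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Many human gene loci produce both protein-coding and non-coding transcript
isoforms — via alternative promoters, alternative splicing, or intron-hosted
small RNAs. RefSeq curation encodes the distinction in the accession prefix:
`NM_` for validated protein-coding transcripts, `NR_` for validated
non-coding ones (`XM_`/`XR_` for their predicted counterparts). Grouping
curated transcripts by gene symbol therefore yields a simple, reproducible
census: loci with only `NM_` isoforms, only `NR_` isoforms, or both
("bifunctional" loci).

The census matters practically because short expression-array probes
interrogate 25-nt windows of spliced transcripts. A probe lying on an exon
shared between a coding and a non-coding isoform of the same locus reports
their summed signal and cannot attribute expression to either class. bifscan
quantifies that limitation: it rebuilds spliced isoform sequences from the
genome, matches probes exactly, classifies each probe as coding-specific,
noncoding-specific or ambiguous, compares expression between
exclusively-coding and exclusively-non-coding probe groups with a rank-sum
test, and checks gene lists for overrepresentation in gene-set libraries.

## The pipeline model

1. **Locus partition.** The locus key is the gene symbol, exactly as in
   Venn-style comparisons of annotation content "by gene name"; no
   coordinate-overlap merging is attempted. Symbol collisions (distinct loci
   sharing a symbol) are a known limitation of that convention. The coding
   flag of a transcript follows the explicit CDS in the file when present
   (`cdsStart == cdsEnd` means non-coding); the accession prefix is a
   cross-check that warns on contradiction. Predicted (`XM_`/`XR_`) models
   are excluded by default: the census is about curated content, and mixing
   predicted models in would inflate the bifunctional class with unvalidated
   isoforms. Percentages are computed as `100 * count / total` and rounded
   half away from zero to one decimal — the convention that reproduces
   60.2 / 30.6 / 9.2 from counts 16,879 / 8,583 / 2,586 (total 28,048).

2. **Probe discriminability.** The hybridization model is an exact,
   ungapped, full-length match of the probe (and/or its reverse complement;
   the default `sense_mode = "both"` keeps the tool agnostic about whether a
   platform stores probe sequences sense or antisense to the mRNA) against
   spliced transcript sequences. Exact matching is a deliberate,
   conservative choice: no public mismatch/thermodynamics model would be
   reproducible, and perfect-match probe design makes the exact hit set the
   natural primary object. Matching is done with a preprocessed dictionary
   (Aho–Corasick) over all probes, scanning each transcript once per
   orientation; a naive full-scan oracle in the test suite guarantees the
   indexed path finds exactly the same hit set. A probe hitting at least one
   coding and at least one non-coding transcript is *ambiguous*. At gene
   level both headline numbers are reported: genes with *any* ambiguous
   probe and genes with *all* probes ambiguous, because summaries in the
   literature mix the two readings. The unit of the probe census is the
   individual probe; probes with no hit are excluded from the
   percent-ambiguous denominator and counted separately.

3. **Expression comparison.** `select_groups()` forms a coding and a
   non-coding group either from bifunctional loci whose probes are
   exclusively coding- or exclusively noncoding-specific (default, the
   "exclusively coding / exclusively non-coding genes" reading) or simply
   from coding-only vs non-coding-only loci. Per-probe values are the median
   across samples by default (`mean` and `none` = pool all probe-by-sample
   values are provided, since published figures rarely state the reduction).
   The Wilcoxon–Mann–Whitney test is implemented in the package: midranks,
   tie-corrected variance
   $\sigma^2 = \frac{n_1 n_2}{12}\left[(N+1) - \frac{\sum_t (t^3-t)}{N(N-1)}\right]$,
   continuity-corrected normal approximation, and full enumeration of rank
   assignments when $\binom{N}{n_1} \le 2\times10^5$ (the cap keeps exact
   enumeration under a second; above it the normal approximation is
   accurate to well under 0.01 at the sizes involved). Two-sided p-values
   throughout; all-tied input is flagged degenerate with p = 1.

4. **Overrepresentation.** The enrichment statistic is the one-sided
   hypergeometric upper tail (Fisher-exact enrichment), computed in log
   space, with Benjamini–Hochberg adjustment across sets and deterministic
   tie-breaking by set name. This is an intentional substitution for
   web-service combined scores whose rank-based backgrounds cannot be
   reproduced offline. The default universe is the union of library genes;
   an explicit universe (e.g. all genes on the array) is the statistically
   proper background for platform-constrained questions and is supported via
   the `universe` argument.

## The synthetic-data generator

Because the real inputs (a dated annotation snapshot, a vendor probe table,
a public expression panel) are versioned external resources, every stage is
exercised against generated data with known ground truth.

Bifunctional loci are realized with the alternative-isoform architecture:
two shared exons flank one coding-specific and one noncoding-specific exon;
the `NM_` isoform splices shared–coding–shared and the `NR_` isoform
shared–noncoding–shared. Probes placed on shared exons are ambiguous by
construction; probes on the middle exons are class-specific. The other two
bifunctionality architectures (a single molecule with both functions; an
intron-hosted small RNA) do not produce distinct `NM_`/`NR_` census entries
— a single-molecule bifRNA is one `NM_` record, and a snoRNA host appears as
an `NM_` plus a separate small `NR_` — so the generator focuses on the
architecture that the census can actually detect.

Defaults encode the study conditions the package is built around: class
fractions 0.602 / 0.306 / 0.092 (coding-only / non-coding-only /
bifunctional), 11 probes of 25 nt per locus, 60 expression samples,
log-scale intensities with per-gene baseline Normal(7, 1), per-value noise
SD 0.5, and **no** coding-versus-noncoding shift (`delta = 0`), reflecting
the observation that coding and non-coding isoforms of the same loci show
comparable expression. Exon lengths 120–300 bp and introns 60–200 bp are
compact but realistic enough to host 25-nt probes away from boundaries.

Probe placement is **correlated within a locus**: a bifunctional gene's
whole probe set is placed on shared exons with probability
`frac_probes_on_shared_exons` (default 0.667) or on a specific exon
otherwise (coding-specific with probability 0.871). A probe set interrogates
one target region of one transcript, so per-probe independent placement
would be unrealistic — and would make loci whose probes are *exclusively*
coding- or noncoding-specific (the groups the expression comparison needs)
vanishingly rare, which contradicts the observed abundance of such loci.
With correlated placement the same parameter is simultaneously the expected
per-probe ambiguity fraction and the per-gene fraction of all-ambiguous
loci.

Ground truth records each gene's class, each probe's intended verdict, its
host transcript and spliced offset, and its expression group;
`synth_verify()` re-runs the pipeline and enumerates any disagreement. A
single seeded generator drives everything; one seed gives byte-identical
files.

What the generator does **not** emulate: cross-hybridization and mismatch
tolerance, hybridization noise models, sequence composition bias,
overlapping genes and shared symbols, NA patterns in expression data, and
annotation errors. Passing tests on synthetic data therefore demonstrate
correctness of the computations, not robustness to the messiness of real
annotation snapshots.

## Statistical notes

* **The locus is the independent unit for expression inference.** Probes of
  one locus share its baseline, so probe-level values are clustered; a
  rank test treating probes as independent units is anticonservative (its
  null rejection rate can far exceed the nominal level). The package's
  verification therefore compares one summary value per locus when checking
  that the equal-means regime is non-significant; probe-level output remains
  available because it is what published figures typically plot, but
  p-values computed on clustered probe values should be read with that
  caveat.
* Type-I error and power of the rank test are checked by simulation:
  at $\alpha = 0.05$ the empirical rejection rate on identically distributed
  groups is nominal, and a one-pooled-SD shift at $n = 100$ per group is
  detected essentially always.
* The hypergeometric tail is validated against exhaustive enumeration for
  all universes up to size 12 and against the standard distribution
  function; its pmf is normalized to within $10^{-12}$ in log space.

## Problem sizes used in validation

The packaged checks run the census recovery at 28,048 loci
(annotation only), the probe pipeline at 600–2,000 loci, the matcher-oracle
comparison at 200 probes against 50 transcripts, 1,000 replicate rank tests
for the type-I rate, and rank-test enumeration for all group sizes with
$\binom{N}{n_1} \le 10^4$. These sizes are the package's own validation
choices: large enough for the binomial/permutation bounds being asserted,
small enough to re-run routinely.

## Known limitations

* Gene symbols are taken at face value; no alias resolution or
  coordinate-based locus merging.
* GFF3 and BED12 are not read; use genePred/refFlat or GTF.
* No microarray normalization is performed; the expression input is assumed
  already on a log scale.
* Enrichment reproduces the hypergeometric component of web-service
  analyses, not their combined rank-corrected scores.
* Exact probe matching ignores near-matches; cross-hybridization makes real
  discriminability worse than the exact-match census suggests, so the
  ambiguous fraction reported here is a lower bound in that respect.

## A worked example

```{r, eval = FALSE}
library(bifscan)

sim <- synth_generate(synth_config(n_genes = 500, rng_seed = 1))
part <- partition_loci(sim$transcripts)
summarize_census(part)

reports <- match_probes(sim$probes, sim$transcripts, sim$genome)
gd <- gene_discriminability(reports, part)
gd$summary$percent_ambiguous

groups <- select_groups(sim$exprs, reports, part, rule = "locus_class")
mann_whitney(groups$coding, groups$noncoding)

amb <- gd$genes$gene_symbol[gd$genes$any_ambiguous]
head(enrich(amb, sim$library))
```
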