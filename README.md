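# bifscan

Many gene loci produce both protein-coding and non-coding transcript
isoforms. In RefSeq nomenclature the two classes carry distinct accession
prefixes — `NM_` for validated coding transcripts, `NR_` for validated
non-coding ones — so grouping curated transcripts by gene symbol gives a
direct census of loci that are coding-only, non-coding-only, or
*bifunctional* (both). bifscan builds that census and then asks the question
that matters for anyone analysing expression-array data: **can a short
perfect-match probe even tell the two isoform classes of a locus apart?**

For transcriptomics practitioners, the package provides:

* **Locus census** — partition loci by isoform content and summarize counts
  and percentages (`partition_loci()`, `summarize_census()`,
  `census_from_counts()`).
* **Probe discriminability** — reconstruct spliced isoform sequences from a
  genome FASTA, match 25-nt probes exactly (indexed Aho–Corasick scan,
  proven equal to a naive full scan), and call each probe
  coding-specific, noncoding-specific or *ambiguous*
  (`spliced_sequence()`, `match_probes()`, `gene_discriminability()`).
* **Expression comparison** — compare probes of exclusively-coding versus
  exclusively-non-coding loci with a self-contained Wilcoxon–Mann–Whitney
  test: midranks, tie-corrected variance
  `n1*n2/12 * ((N+1) - sum(t^3-t)/(N*(N-1)))`, exact enumeration for small
  groups, continuity-corrected normal approximation otherwise
  (`select_groups()`, `mann_whitney()`, `boxplot_summary()`).
* **Overrepresentation** — one-sided hypergeometric (Fisher-exact
  enrichment) of a gene list against a GMT library, log-space tail,
  Benjamini–Hochberg across sets (`read_gmt()`, `enrich()`,
  `hypergeom_tail()`).
* **Synthetic data with ground truth** — a seeded generator emitting genome,
  genePred/refFlat annotation, probe table, expression matrix and GMT
  library whose classes, probe verdicts and expression groups are known
  exactly (`synth_config()`, `synth_generate()`, `synth_verify()`).

Inputs are standard formats: genePred/refFlat or GTF annotation, genome
FASTA, TSV probe table (`probe_id probeset_id gene sequence`), TSV
expression matrix, GMT gene sets. A thin command-line wrapper with
`census` / `probes` / `express` / `enrich` / `synth` subcommands is
installed at `inst/scripts/bifscan`.

## Worked example

```r
library(bifscan)

# census arithmetic on published Venn counts
census_from_counts(16879, 8583, 2586)
#> Locus census over 28048 gene loci
#>   coding_only        16879  (60.2%)
#>   noncoding_only      8583  (30.6%)
#>   bifunctional        2586  (9.2%)

# a fully ground-truthed synthetic dataset
sim  <- synth_generate(synth_config(n_genes = 500, rng_seed = 1))
part <- partition_loci(sim$transcripts)
summarize_census(part)
#> Locus census over 500 gene loci
#>   coding_only          313  (62.6%)
#>   noncoding_only       136  (27.2%)
#>   bifunctional          51  (10.2%)

reports <- match_probes(sim$probes, sim$transcripts, sim$genome)
gd <- gene_discriminability(reports, part)
gd$summary$percent_ambiguous
#> [1] 76.5

groups <- select_groups(sim$exprs, reports, part, rule = "locus_class")
mann_whitney(groups$coding, groups$noncoding)
#> Wilcoxon-Mann-Whitney: n1 = 3443, n2 = 1496, U = 2564994.0, z = -0.225
#>   two-sided p = 0.8218 (normal_approx)

amb <- gd$genes$gene_symbol[gd$genes$any_ambiguous & gd$genes$class %in% "bifunctional"]
head(enrich(amb, sim$library), 3)
#>             set   N  m  n  k      p_hyper         q_bh
#> 26 ENRICHED_BIF 500 40 39 23 6.898008e-19 1.793482e-17
#> 10       SET_10 500 38 39  5 1.639429e-01 9.223995e-01
#> 15       SET_15 500 41 39  5 2.059309e-01 9.223995e-01
```

Reading the output: 51 of the 500 simulated loci (10.2%) carry both `NM_`
and `NR_` isoforms; 76.5% of the probes interrogating those loci sit on
shared exons and cannot attribute signal to either isoform class; expression
of probes from coding-only versus non-coding-only loci shows no significant
difference (p = 0.82, as planted — the generator draws both classes from the
same distribution); and the gene set deliberately seeded with bifunctional
loci is recovered as the top enrichment hit (q ≈ 2e-17).

## The methods vignette

`vignettes/bifunctional-census.Rmd` documents the model and its assumptions:
the locus-by-symbol convention, the exact-match hybridization model, the
rank-test and enrichment formulas, what the synthetic generator does and
does not emulate, and why the locus (not the probe) is the independent unit
for expression inference.
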