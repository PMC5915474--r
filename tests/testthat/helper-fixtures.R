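# Shared fixtures, built in code. A small simulated dataset is generated once
# per test run and reused across files.

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- synth_generate(
      synth_config(n_genes = 120, n_samples = 20, rng_seed = 101))
  }
  .fixture_env$sim
}

# read a transcript table from genePred/refFlat text lines
tx_from_lines <- function(lines, format = "auto") {
  f <- withr::local_tempfile(fileext = ".genePred", .local_envir = parent.frame())
  writeLines(lines, f)
  read_genepred(f, format = format)
}

# hand fixture on a 200 bp chromosome:
#   geneA bifunctional — shared exons [0,30) and [80,110); the NM isoform
#     additionally splices in exon [40,70) (CDS core), the NR isoform only
#     joins the shared exons;
#   geneB coding-only (NM, exons [120,150) [160,200));
#   geneC non-coding with exactly geneB's exon structure, so a probe across
#     that splice junction hits one NM_ and one NR_ transcript.
hand_fixture <- function(seed = 5) {
  withr::with_seed(seed, {
    genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                             collapse = ""))
  })
  lines <- c(
    "geneA\tNM_000001.1\tchr1\t+\t0\t110\t5\t105\t3\t0,40,80,\t30,70,110,",
    "geneA\tNR_000001.1\tchr1\t+\t0\t110\t110\t110\t2\t0,80,\t30,110,",
    "geneB\tNM_000002.1\tchr1\t+\t120\t200\t125\t195\t2\t120,160,\t150,200,",
    "geneC\tNR_000002.1\tchr1\t+\t120\t200\t200\t200\t2\t120,160,\t150,200,"
  )
  list(genome = genome, transcripts = tx_from_lines(lines))
}
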