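#' Spliced transcript sequence
#'
#' Concatenates exon substrings of the chromosome in genomic order and, for
#' minus-strand transcripts, reverse-complements the concatenation, yielding
#' the mature (spliced) transcript sequence in transcription order. Length
#' equals the sum of exon lengths. `N` bases are permitted (exact probe
#' matches never cross an `N`).
#'
#' @param transcripts transcript data.frame (one or more rows).
#' @param genome named character vector from [read_genome_fasta()].
#' @return named character vector of spliced sequences (names = accessions).
#' @export
spliced_sequence <- function(transcripts, genome) {
  validate_transcripts(transcripts, genome)
  out <- vapply(seq_len(nrow(transcripts)), function(i) {
    ch <- genome[[transcripts$chrom[i]]]
    es <- transcripts$exon_starts[[i]]
    ee <- transcripts$exon_ends[[i]]
    s <- paste(substring(ch, es + 1L, ee), collapse = "")
    if (transcripts$strand[i] == "-") revcomp(s) else s
  }, character(1))
  names(out) <- transcripts$accession
  out
}

#' Read a probe table
#'
#' Tab-separated with header `probe_id probeset_id gene sequence`. Probe ids
#' must be unique; probes containing non-ACGT characters are skipped with a
#' warning (perfect-match array probes are ACGT-only).
#'
#' @param path file path.
#' @return data.frame `probe_id`, `probeset_id`, `gene`, `sequence`.
#' @export
read_probes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("probe_id", "probeset_id", "gene", "sequence")
  if (!all(need %in% names(df))) {
    stop("probe table must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in probe table")
  }
  df$sequence <- toupper(df$sequence)
  df
}

#' Match probes exactly against spliced transcript sequences
#'
#' A hit is an exact, ungapped, full-length occurrence of the probe sequence
#' (and/or its reverse complement, per `sense_mode`) within a spliced
#' transcript sequence. Matching uses a preprocessed dictionary index
#' (Aho-Corasick via [Biostrings::PDict]) over all probes of each length, so
#' each transcript is scanned once per orientation; results are identical to a
#' naive full scan. Each probe's verdict summarizes the coding status of the
#' transcripts it hits: `ambiguous` means it cannot distinguish coding from
#' non-coding isoforms.
#'
#' @param probes data.frame from [read_probes()].
#' @param transcripts transcript data.frame.
#' @param genome named character vector.
#' @param sense_mode `"both"` (default; array probes are conventionally
#'   antisense to the mRNA, matching both orientations keeps the tool
#'   annotation-agnostic), `"sense"`, or `"antisense"`.
#' @return data.frame with one row per retained probe: `probe_id`,
#'   `probeset_id`, `gene`, `n_hits`, `hit_coding`, `hit_noncoding`, `verdict`
#'   (`coding_specific` / `noncoding_specific` / `ambiguous` / `no_hit`).
#'   Attribute `"hits"` holds the per-hit table (`probe_id`, `accession`,
#'   `gene_hit`, `coding`, `offset` 0-based within the spliced sequence,
#'   `orientation`); attribute `"sense_mode"` records the mode.
#' @export
match_probes <- function(probes, transcripts, genome,
                         sense_mode = c("both", "sense", "antisense")) {
  sense_mode <- match.arg(sense_mode)
  bad <- grepl("[^ACGT]", probes$sequence) | !nzchar(probes$sequence)
  if (any(bad)) {
    warning(sum(bad), " probe(s) with non-ACGT sequence skipped", call. = FALSE)
    probes <- probes[!bad, , drop = FALSE]
  }
  seqs <- spliced_sequence(transcripts, genome)
  orientations <- switch(sense_mode,
                         both = c("sense", "antisense"),
                         sense = "sense", antisense = "antisense")
  # one scan per orientation and probe width: transcripts are concatenated
  # with runs of N (probes are ACGT-only, so no exact match can straddle a
  # spacer) and global hit positions are mapped back to transcripts
  hit_list <- list()
  for (ori in orientations) {
    qseq <- if (ori == "sense") probes$sequence else revcomp(probes$sequence)
    for (w in unique(nchar(qseq))) {
      idx <- which(nchar(qseq) == w)
      pd <- Biostrings::PDict(qseq[idx])
      spacer <- strrep("N", w)
      subject <- Biostrings::DNAString(paste(seqs, collapse = spacer))
      tx_start <- cumsum(c(0L, (nchar(seqs) + w)[-length(seqs)]))  # 0-based
      m <- Biostrings::matchPDict(pd, subject)
      st <- Biostrings::startIndex(m)
      nh <- lengths(st)
      if (sum(nh) == 0L) next
      gpos <- unlist(st[nh > 0L]) - 1L
      t_row <- findInterval(gpos, tx_start)
      hit_list[[length(hit_list) + 1L]] <- data.frame(
        probe_row = rep(idx, nh),
        t_row = t_row,
        offset = gpos - tx_start[t_row],
        orientation = ori,
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(hit_list)) do.call(rbind, hit_list) else
    data.frame(probe_row = integer(0), t_row = integer(0),
               offset = integer(0), orientation = character(0))
  # a probe whose sequence equals its own reverse complement would be found
  # twice at the same (transcript, offset); keep one
  hits <- hits[!duplicated(hits[, c("probe_row", "t_row", "offset")]), ,
               drop = FALSE]
  hits_out <- data.frame(
    probe_id = probes$probe_id[hits$probe_row],
    accession = transcripts$accession[hits$t_row],
    gene_hit = transcripts$gene_symbol[hits$t_row],
    coding = transcripts$coding[hits$t_row],
    offset = hits$offset,
    orientation = hits$orientation,
    stringsAsFactors = FALSE
  )
  hc <- tapply(hits_out$coding, factor(hits_out$probe_id, levels = probes$probe_id), any)
  hn <- tapply(!hits_out$coding, factor(hits_out$probe_id, levels = probes$probe_id), any)
  nh <- table(factor(hits_out$probe_id, levels = probes$probe_id))
  hit_coding <- !is.na(hc) & hc
  hit_noncoding <- !is.na(hn) & hn
  verdict <- ifelse(hit_coding & hit_noncoding, "ambiguous",
                    ifelse(hit_coding, "coding_specific",
                           ifelse(hit_noncoding, "noncoding_specific", "no_hit")))
  out <- data.frame(
    probe_id = probes$probe_id,
    probeset_id = probes$probeset_id,
    gene = probes$gene,
    n_hits = as.integer(nh),
    hit_coding = hit_coding,
    hit_noncoding = hit_noncoding,
    verdict = verdict,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "hits") <- hits_out
  attr(out, "sense_mode") <- sense_mode
  out
}

#' Gene-level probe discriminability
#'
#' Rolls per-probe verdicts up to genes and summarizes how well the probes of
#' bifunctional loci separate coding from non-coding isoforms. Probes with no
#' hit are excluded from the percent-ambiguous denominator and counted
#' separately.
#'
#' @param reports data.frame from [match_probes()].
#' @param partition data.frame from [partition_loci()].
#' @param gene_assignment `"declared"` (use the probe table's gene column,
#'   default) or `"by_hit"` (assign each probe to the gene(s) of its hit
#'   transcripts; probes hitting several genes are counted once per gene and
#'   flagged).
#' @return list with `genes` (per gene: `gene_symbol`, `class`, `n_probes`,
#'   `n_ambiguous`, `any_ambiguous`, `all_ambiguous`) and `summary` (counts
#'   over bifunctional loci: probes hitting them, percent ambiguous among
#'   those, genes with any/all probes ambiguous, no-hit and multi-gene probe
#'   counts).
#' @export
gene_discriminability <- function(reports, partition,
                                  gene_assignment = c("declared", "by_hit")) {
  gene_assignment <- match.arg(gene_assignment)
  hitting <- reports[reports$verdict != "no_hit", , drop = FALSE]
  n_multi <- 0L
  if (gene_assignment == "declared") {
    pg <- data.frame(probe_id = hitting$probe_id, gene = hitting$gene,
                     verdict = hitting$verdict, stringsAsFactors = FALSE)
  } else {
    hits <- attr(reports, "hits")
    gl <- tapply(hits$gene_hit, hits$probe_id, function(g) unique(g))
    gl <- gl[hitting$probe_id]
    n_multi <- sum(lengths(gl) > 1L)
    pg <- data.frame(
      probe_id = rep(hitting$probe_id, lengths(gl)),
      gene = unlist(gl, use.names = FALSE),
      verdict = rep(hitting$verdict, lengths(gl)),
      stringsAsFactors = FALSE
    )
  }
  klass <- partition$class[match(unique(pg$gene), partition$gene_symbol)]
  genes <- data.frame(gene_symbol = unique(pg$gene), class = klass,
                      stringsAsFactors = FALSE)
  tab_n <- table(factor(pg$gene, levels = genes$gene_symbol))
  tab_a <- table(factor(pg$gene[pg$verdict == "ambiguous"],
                        levels = genes$gene_symbol))
  genes$n_probes <- as.integer(tab_n)
  genes$n_ambiguous <- as.integer(tab_a)
  genes$any_ambiguous <- genes$n_ambiguous > 0L
  genes$all_ambiguous <- genes$n_probes > 0L & genes$n_ambiguous == genes$n_probes
  genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  row.names(genes) <- NULL
  bif <- genes[!is.na(genes$class) & genes$class == "bifunctional", , drop = FALSE]
  on_bif <- pg[pg$gene %in% bif$gene_symbol, , drop = FALSE]
  n_on_bif <- length(unique(on_bif$probe_id))
  n_amb_bif <- length(unique(on_bif$probe_id[on_bif$verdict == "ambiguous"]))
  summary <- list(
    n_bifunctional_covered = nrow(bif),
    n_probes_on_bifunctional = n_on_bif,
    n_ambiguous_on_bifunctional = n_amb_bif,
    percent_ambiguous = if (n_on_bif > 0L)
      round_half_away(100 * n_amb_bif / n_on_bif, 1L) else NA_real_,
    n_genes_any_ambiguous = sum(bif$any_ambiguous),
    n_genes_all_ambiguous = sum(bif$all_ambiguous),
    n_probes_no_hit = sum(reports$verdict == "no_hit"),
    n_probes_multi_gene = n_multi
  )
  list(genes = genes, summary = summary)
}
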