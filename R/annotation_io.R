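#' Classify a RefSeq-style accession as coding or non-coding
#'
#' RefSeq accession prefixes encode curated coding status: `NM_` marks
#' validated protein-coding transcripts and `NR_` validated non-protein-coding
#' transcripts; `XM_`/`XR_` are the model (predicted) counterparts. Any other
#' prefix is classified `unknown` (a value, not an error). Version suffixes
#' (`".N"`) are irrelevant to the prefix and ignored.
#'
#' @param accession character vector of transcript accessions.
#' @return character vector, one of `"coding"`, `"noncoding"`, `"unknown"`.
#' @examples
#' classify_accession(c("NM_001253764.1", "NR_045586.1", "ENST00000001"))
#' @export
classify_accession <- function(accession) {
  stopifnot(is.character(accession))
  if (any(!nzchar(accession)) || anyNA(accession)) {
    stop("accessions must be non-empty strings")
  }
  out <- rep_len("unknown", length(accession))
  out[startsWith(accession, "NM_") | startsWith(accession, "XM_")] <- "coding"
  out[startsWith(accession, "NR_") | startsWith(accession, "XR_")] <- "noncoding"
  out
}

#' Is an accession a predicted (XM_/XR_) RefSeq model?
#'
#' @param accession character vector of transcript accessions.
#' @return logical vector.
#' @export
is_predicted_accession <- function(accession) {
  startsWith(accession, "XM_") | startsWith(accession, "XR_")
}

# Assemble and validate the transcript table used throughout the package.
# Coordinates are 0-based half-open on the forward strand. `exon_starts` /
# `exon_ends` are list-columns of sorted integer vectors; `cds_start` /
# `cds_end` are NA for non-coding transcripts. The coding flag follows the
# explicit CDS when present (curation proxy: the file's CDS columns outrank
# the accession prefix); contradictions with the prefix are warned about.
transcript_table <- function(accession, gene_symbol, chrom, strand,
                             exon_starts, exon_ends, cds_start, cds_end,
                             context = NULL) {
  n <- length(accession)
  ctx <- context %||% as.character(seq_len(n))
  for (i in seq_len(n)) {
    s <- exon_starts[[i]]; e <- exon_ends[[i]]
    if (length(s) == 0L || length(s) != length(e)) {
      stop("transcript ", accession[i], " (", ctx[i], "): empty or ragged exon list")
    }
    if (any(s >= e)) {
      stop("transcript ", accession[i], " (", ctx[i], "): exon with start >= end")
    }
    if (is.unsorted(s, strictly = TRUE) ||
        any(e[-length(e)] > s[-1L])) {
      stop("transcript ", accession[i], " (", ctx[i],
           "): exons must be sorted and pairwise disjoint")
    }
    if (!is.na(cds_start[i])) {
      if (cds_start[i] >= cds_end[i] ||
          cds_start[i] < s[1L] || cds_end[i] > e[length(e)]) {
        stop("transcript ", accession[i], " (", ctx[i],
             "): CDS outside transcript span")
      }
    }
  }
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  coding <- !is.na(cds_start)
  cls <- classify_accession(accession)
  contra <- (cls == "coding" & !coding) | (cls == "noncoding" & coding)
  if (any(contra)) {
    warning("CDS presence contradicts accession prefix for: ",
            paste(accession[contra], collapse = ", "),
            " (CDS wins for the coding flag)", call. = FALSE)
  }
  # prefix decides only when no CDS information at all is carried by the file;
  # callers that lack CDS columns pass cds_start = NA and may override below.
  df <- data.frame(
    accession = accession,
    gene_symbol = gene_symbol,
    chrom = chrom,
    strand = strand,
    tx_start = vapply(exon_starts, function(x) x[1L], integer(1)),
    tx_end = vapply(exon_ends, function(x) x[length(x)], integer(1)),
    cds_start = cds_start,
    cds_end = cds_end,
    coding = coding,
    predicted = is_predicted_accession(accession),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- exon_starts
  df$exon_ends <- exon_ends
  df
}

#' Read transcript models from a genePred or refFlat file
#'
#' Parses the tab-delimited UCSC genePred table (name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) or its refFlat
#' variant, which prepends a gene-symbol column. Coordinates are kept 0-based
#' half-open. `cdsStart == cdsEnd` signals a non-coding transcript. Trailing
#' commas in the exon lists are tolerated (UCSC convention). The coding flag is
#' taken from CDS presence and cross-checked against the accession prefix; on
#' contradiction a warning is raised and the CDS wins.
#'
#' @param path file path.
#' @param format `"auto"` (detect refFlat by its 11th column), `"genepred"`, or
#'   `"refflat"`.
#' @return data.frame of transcript records with list-columns `exon_starts`,
#'   `exon_ends`, plus `coding` and `predicted` flags.
#' @export
read_genepred <- function(path, format = c("auto", "genepred", "refflat")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (all(nf == 11L)) "refflat" else "genepred"
  }
  want <- if (format == "refflat") 11L else 10L
  bad <- which(nf != want)
  if (length(bad)) {
    stop("line ", bad[1L], ": expected ", want, " tab-separated fields, got ",
         nf[bad[1L]])
  }
  off <- if (format == "refflat") 1L else 0L
  parse_list <- function(x, line) {
    v <- suppressWarnings(as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1L]]))
    if (anyNA(v)) stop("line ", line, ": non-integer exon coordinate")
    v
  }
  n <- length(fields)
  acc <- character(n); gene <- character(n); chrom <- character(n)
  strand <- character(n); cs <- integer(n); ce <- integer(n)
  es <- vector("list", n); ee <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    gene[i] <- if (format == "refflat") f[1L] else NA_character_
    acc[i] <- f[1L + off]
    chrom[i] <- f[2L + off]
    strand[i] <- f[3L + off]
    cs[i] <- as.integer(f[6L + off])
    ce[i] <- as.integer(f[7L + off])
    cnt <- as.integer(f[8L + off])
    es[[i]] <- parse_list(f[9L + off], i)
    ee[[i]] <- parse_list(f[10L + off], i)
    if (length(es[[i]]) != cnt || length(ee[[i]]) != cnt) {
      stop("line ", i, ": exonCount (", cnt, ") does not match exon lists")
    }
    if (is.unsorted(es[[i]], strictly = TRUE)) {
      stop("line ", i, ": exonStarts not sorted ascending")
    }
  }
  noncoding <- cs == ce
  transcript_table(
    accession = acc, gene_symbol = gene, chrom = chrom, strand = strand,
    exon_starts = es, exon_ends = ee,
    cds_start = ifelse(noncoding, NA_integer_, cs),
    cds_end = ifelse(noncoding, NA_integer_, ce),
    context = paste0("line ", seq_len(n))
  )
}

#' Write transcript models as genePred / refFlat
#'
#' Inverse of [read_genepred()]. Non-coding transcripts are written with
#' `cdsStart == cdsEnd == txEnd` (UCSC convention); exon lists carry trailing
#' commas.
#'
#' @param transcripts transcript data.frame as returned by [read_genepred()].
#' @param path output file path.
#' @param format `"refflat"` (leading gene-symbol column, default) or
#'   `"genepred"`.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(transcripts, path, format = c("refflat", "genepred")) {
  format <- match.arg(format)
  fmt_list <- function(v) paste0(paste(v, collapse = ","), ",")
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    t <- transcripts[i, ]
    cs <- if (is.na(t$cds_start)) t$tx_end else t$cds_start
    ce <- if (is.na(t$cds_end)) t$tx_end else t$cds_end
    core <- paste(t$accession, t$chrom, t$strand, t$tx_start, t$tx_end,
                  cs, ce, length(t$exon_starts[[1L]]),
                  fmt_list(t$exon_starts[[1L]]), fmt_list(t$exon_ends[[1L]]),
                  sep = "\t")
    if (format == "refflat") paste(t$gene_symbol, core, sep = "\t") else core
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Imports `exon` and `CDS` features, groups them by `transcript_id`, and
#' converts 1-based closed GTF coordinates to the package's internal 0-based
#' half-open convention, so that a gene model read from GTF is identical to the
#' same model read from genePred. The gene symbol is taken from the
#' `gene_name` attribute when present, else `gene_id`. A CDS feature falling
#' outside the transcript's exon union is a validation error.
#'
#' @param path file path to a GTF 2.2 file.
#' @return data.frame of transcript records, as [read_genepred()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0L) stop("no exon features in GTF: ", path)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    stop("GTF feature without transcript_id attribute")
  }
  gene_attr <- gr$gene_name
  if (is.null(gene_attr)) gene_attr <- gr$gene_id
  gene_attr[is.na(gene_attr)] <- gr$gene_id[is.na(gene_attr)]
  df <- data.frame(
    tid = tid,
    gene = gene_attr %||% NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start0 = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end0 = GenomicRanges::end(gr),
    type = as.character(gr$type),
    stringsAsFactors = FALSE
  )
  ids <- sort(unique(df$tid))
  recs <- lapply(ids, function(id) {
    d <- df[df$tid == id, ]
    ex <- d[d$type == "exon", ]
    if (nrow(ex) == 0L) stop("transcript ", id, ": CDS without exon features")
    o <- order(ex$start0)
    ex <- ex[o, ]
    cds <- d[d$type == "CDS", ]
    cs <- NA_integer_; ce <- NA_integer_
    if (nrow(cds) > 0L) {
      inside <- vapply(seq_len(nrow(cds)), function(j) {
        any(cds$start0[j] >= ex$start0 & cds$end0[j] <= ex$end0)
      }, logical(1))
      if (!all(inside)) stop("transcript ", id, ": CDS outside exon union")
      cs <- min(cds$start0); ce <- max(cds$end0)
    }
    list(accession = id, gene = ex$gene[1L], chrom = ex$chrom[1L],
         strand = ex$strand[1L], es = ex$start0, ee = ex$end0,
         cs = cs, ce = ce)
  })
  transcript_table(
    accession = vapply(recs, `[[`, character(1), "accession"),
    gene_symbol = vapply(recs, `[[`, character(1), "gene"),
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    strand = vapply(recs, `[[`, character(1), "strand"),
    exon_starts = lapply(recs, `[[`, "es"),
    exon_ends = lapply(recs, `[[`, "ee"),
    cds_start = vapply(recs, `[[`, integer(1), "cs"),
    cds_end = vapply(recs, `[[`, integer(1), "ce")
  )
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon and, for coding transcripts, `CDS`
#' features as the per-exon intersection of the genomic CDS span with the exon
#' intervals (1-based closed coordinates).
#'
#' @param transcripts transcript data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  out <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     t$gene_symbol, t$accession, t$gene_symbol)
    es <- t$exon_starts[[1L]]; ee <- t$exon_ends[[1L]]
    out <- c(out, sprintf("%s\tbifscan\texon\t%d\t%d\t.\t%s\t.\t%s",
                          t$chrom, es + 1L, ee, t$strand, attrs))
    if (!is.na(t$cds_start)) {
      ks <- pmax(es, t$cds_start); ke <- pmin(ee, t$cds_end)
      keep <- ks < ke
      out <- c(out, sprintf("%s\tbifscan\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                            t$chrom, ks[keep] + 1L, ke[keep], t$strand, attrs))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' The header token up to the first whitespace is the chromosome name.
#' Sequences are stored uppercase; only `A`, `C`, `G`, `T`, `N` are accepted.
#' Duplicate chromosome names and empty files are errors.
#'
#' @param path FASTA file path.
#' @return named character vector, one uppercase sequence per chromosome.
#' @export
read_genome_fasta <- function(path) {
  ss <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("non-IUPAC character in FASTA: ", path, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  if (length(ss) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN character in chromosome(s): ",
         paste(nm[bad], collapse = ", "))
  }
  names(seqs) <- nm
  seqs
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Check every transcript's chromosome is present and long enough.
validate_transcripts <- function(transcripts, genome) {
  for (i in seq_len(nrow(transcripts))) {
    ch <- transcripts$chrom[i]
    if (!ch %in% names(genome)) {
      stop("transcript ", transcripts$accession[i],
           ": chromosome ", ch, " absent from genome")
    }
    if (transcripts$tx_end[i] > nchar(genome[[ch]])) {
      stop("transcript ", transcripts$accession[i],
           ": exon beyond end of ", ch)
    }
  }
  invisible(TRUE)
}
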