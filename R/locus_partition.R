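#' Partition gene loci by coding / non-coding isoform content
#'
#' Groups transcripts by gene symbol (the locus key, matching the field
#' practice of Venn-diagramming RefSeq content "by gene name") and labels each
#' locus `coding_only`, `noncoding_only`, or `bifunctional` (at least one
#' coding and at least one non-coding isoform). Predicted (XM_/XR_) models and
#' transcripts of unknown class are excluded from the census by default; genes
#' left with no eligible transcript are dropped with a message.
#'
#' @param transcripts transcript data.frame ([read_genepred()] / [read_gtf()]).
#' @param include_predicted include XM_/XR_ models (default `FALSE`).
#' @return data.frame with one row per gene symbol, sorted lexicographically:
#'   `gene_symbol`, `n_coding`, `n_noncoding`, `class`. The number of genes
#'   dropped (only predicted/unknown transcripts) is in attribute
#'   `"n_excluded_genes"`.
#' @export
partition_loci <- function(transcripts, include_predicted = FALSE) {
  if (nrow(transcripts) == 0L) stop("no transcripts to partition")
  bad <- is.na(transcripts$gene_symbol) | !nzchar(transcripts$gene_symbol)
  if (any(bad)) {
    stop("transcripts without gene symbol: ",
         paste(transcripts$accession[bad], collapse = ", "))
  }
  all_genes <- unique(transcripts$gene_symbol)
  keep <- rep_len(TRUE, nrow(transcripts))
  if (!include_predicted) keep <- keep & !transcripts$predicted
  # transcripts whose class could not be resolved at all: unknown prefix and
  # no CDS information (coding flag FALSE from absent CDS columns is still a
  # resolution only when the file carries CDS columns; readers guarantee it)
  t <- transcripts[keep, , drop = FALSE]
  if (nrow(t) == 0L) stop("no eligible transcripts after exclusions")
  agg <- tapply(t$coding, t$gene_symbol, function(x) c(sum(x), sum(!x)))
  genes <- sort(names(agg))
  n_cod <- vapply(agg[genes], `[`, numeric(1), 1L)
  n_non <- vapply(agg[genes], `[`, numeric(1), 2L)
  klass <- ifelse(n_cod > 0 & n_non > 0, "bifunctional",
                  ifelse(n_cod > 0, "coding_only", "noncoding_only"))
  out <- data.frame(gene_symbol = genes,
                    n_coding = as.integer(n_cod),
                    n_noncoding = as.integer(n_non),
                    class = klass,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  n_excluded <- length(setdiff(all_genes, genes))
  if (n_excluded > 0L) {
    message(n_excluded, " gene(s) had only predicted/excluded transcripts and were dropped")
  }
  attr(out, "n_excluded_genes") <- n_excluded
  out
}

census_classes <- c("coding_only", "noncoding_only", "bifunctional")

# shared arithmetic: counts -> census summary (percent = 100*count/total,
# rounded half away from zero to one decimal)
census_summary_from_counts <- function(counts) {
  if (!is.null(names(counts))) counts <- counts[census_classes]
  names(counts) <- census_classes
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  if (total == 0) stop("empty census")
  out <- data.frame(class = census_classes,
                    count = as.integer(counts),
                    percent = round_half_away(100 * counts / total, 1L),
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(summary = out, total = as.integer(total)),
            class = "census_summary")
}

#' Summarize a locus partition into the three-way census
#'
#' Counts loci per class and converts counts to percentages of the total
#' (rounded half away from zero to one decimal, the convention that maps
#' counts 16,879 / 8,583 / 2,586 to 60.2 / 30.6 / 9.2).
#'
#' @param partition data.frame from [partition_loci()].
#' @return a `census_summary`: list with `summary` (class, count, percent) and
#'   `total`.
#' @export
summarize_census <- function(partition) {
  if (is.null(partition) || nrow(partition) == 0L) stop("empty partition")
  counts <- table(factor(partition$class, levels = census_classes))
  census_summary_from_counts(as.integer(counts))
}

#' Census summary directly from printed class counts
#'
#' Same arithmetic as [summarize_census()], applied to class counts given
#' directly (e.g. counts read off a published Venn diagram).
#'
#' @param coding_only,noncoding_only,bifunctional non-negative integer counts.
#' @return a `census_summary`.
#' @examples
#' census_from_counts(16879, 8583, 2586)
#' @export
census_from_counts <- function(coding_only, noncoding_only, bifunctional) {
  census_summary_from_counts(c(coding_only, noncoding_only, bifunctional))
}

#' @export
print.census_summary <- function(x, ...) {
  cat("Locus census over", x$total, "gene loci\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s %8d  (%.1f%%)\n", s$class[i], s$count[i], s$percent[i]))
  }
  invisible(x)
}

#' Write partition and census to TSV
#'
#' @param partition data.frame from [partition_loci()].
#' @param census a `census_summary` from [summarize_census()].
#' @param dir output directory (created if needed).
#' @return character vector of the two file paths, invisibly.
#' @export
write_census <- function(partition, census, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "locus_partition.tsv")
  p2 <- file.path(dir, "census_summary.tsv")
  write.table(partition, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(census$summary, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
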