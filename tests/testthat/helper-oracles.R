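# Independent brute-force oracles. These deliberately avoid the code paths of
# the implementations they check.

# per-base spliced-sequence construction: walk every exon base by base
oracle_spliced <- function(tx_row, genome) {
  ch <- genome[[tx_row$chrom]]
  es <- tx_row$exon_starts[[1L]]
  ee <- tx_row$exon_ends[[1L]]
  chars <- character(0)
  for (e in seq_along(es)) {
    for (p in (es[e] + 1L):ee[e]) chars <- c(chars, substr(ch, p, p))
  }
  s <- paste(chars, collapse = "")
  if (tx_row$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    s <- paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }
  s
}

rc_chr <- function(x) {
  vapply(x, function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# naive full scan: every (probe, transcript, offset) window compared
oracle_match <- function(probes, transcripts, genome, sense_mode = "both") {
  seqs <- spliced_sequence(transcripts, genome)
  oris <- switch(sense_mode, both = c("sense", "antisense"),
                 sense = "sense", antisense = "antisense")
  out <- list()
  for (pi in seq_len(nrow(probes))) {
    for (ori in oris) {
      q <- probes$sequence[pi]
      if (ori == "antisense") q <- rc_chr(q)
      L <- nchar(q)
      for (ti in seq_along(seqs)) {
        s <- seqs[[ti]]
        if (nchar(s) < L) next
        win <- substring(s, 1:(nchar(s) - L + 1L), L:nchar(s))
        at <- which(win == q)
        if (length(at)) {
          out[[length(out) + 1L]] <- data.frame(
            probe_id = probes$probe_id[pi],
            accession = names(seqs)[ti],
            offset = at - 1L,
            orientation = ori,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(0), accession = character(0),
                      offset = integer(0), orientation = character(0)))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("probe_id", "accession", "offset")]), , drop = FALSE]
}

# canonical form of a hit set for equality comparison
hit_key <- function(h) {
  sort(paste(h$probe_id, h$accession, h$offset, sep = "|"))
}

# Mann-Whitney oracle: U by direct pair counting, exact two-sided p by
# enumerating every assignment of pooled values to the first group
oracle_mw_exact <- function(a, b) {
  U_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  mu <- n1 * (N - n1) / 2
  Uobs <- U_of(a, b)
  cmb <- utils::combn(N, n1)
  devs <- apply(cmb, 2L, function(ix) {
    abs(U_of(pooled[ix], pooled[-ix]) - mu)
  })
  list(U = Uobs, p = mean(devs >= abs(Uobs - mu) - 1e-9))
}

# hypergeometric upper tail by exhaustive enumeration of query draws
oracle_hyper <- function(k, m, n, N) {
  universe <- seq_len(N)        # first m elements are "in the set"
  cmb <- utils::combn(N, n)
  overlap <- apply(cmb, 2L, function(ix) sum(ix <= m))
  mean(overlap >= k)
}
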