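#' Read an expression matrix from TSV
#'
#' First column = row ids (probe or probe-set ids), header row = sample names,
#' values = log-scale intensities; missing values as NA. Rows with no non-NA
#' value are dropped with a message.
#'
#' @param path file path.
#' @return numeric matrix with row and column names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a row-id column and >= 1 sample")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample names")
  all_na <- rowSums(!is.na(m)) == 0L
  if (any(all_na)) {
    message(sum(all_na), " all-NA row(s) dropped from expression matrix")
    m <- m[!all_na, , drop = FALSE]
  }
  m
}

#' Write an expression matrix to TSV
#'
#' @param exprs numeric matrix with row and column names.
#' @param path output file path.
#' @param id_name header for the row-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(exprs, path, id_name = "probe_id") {
  df <- data.frame(rownames(exprs), exprs, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select coding vs non-coding expression groups
#'
#' Builds the two value vectors compared in the expression analysis. Under the
#' default `rule = "exclusive"`, a bifunctional locus contributes its probes to
#' the coding group when every one of its hit probes is coding-specific, and to
#' the non-coding group when every one is noncoding-specific (loci with mixed
#' or ambiguous probes contribute nothing) — the "exclusively coding /
#' exclusively non-coding" reading. `rule = "locus_class"` instead takes all
#' hit probes of coding-only vs non-coding-only loci.
#'
#' @param exprs expression matrix ([read_expression()]), rows keyed by probe id.
#' @param reports probe match report ([match_probes()]).
#' @param partition locus partition ([partition_loci()]).
#' @param rule `"exclusive"` (default) or `"locus_class"`.
#' @param reduce per-probe reduction across samples: `"median"` (default),
#'   `"mean"`, or `"none"` (pool all probe-by-sample values).
#' @return list with numeric vectors `coding` and `noncoding`, plus
#'   `n_dropped` (probes selected but absent from the matrix).
#' @export
select_groups <- function(exprs, reports, partition,
                          rule = c("exclusive", "locus_class"),
                          reduce = c("median", "mean", "none")) {
  rule <- match.arg(rule)
  reduce <- match.arg(reduce)
  hitting <- reports[reports$verdict != "no_hit", , drop = FALSE]
  if (rule == "exclusive") {
    klass <- partition$class[match(hitting$gene, partition$gene_symbol)]
    bif <- hitting[!is.na(klass) & klass == "bifunctional", , drop = FALSE]
    per_gene <- split(bif$verdict, bif$gene)
    all_cod <- names(per_gene)[vapply(per_gene, function(v)
      all(v == "coding_specific"), logical(1))]
    all_non <- names(per_gene)[vapply(per_gene, function(v)
      all(v == "noncoding_specific"), logical(1))]
    ids_cod <- bif$probe_id[bif$gene %in% all_cod]
    ids_non <- bif$probe_id[bif$gene %in% all_non]
  } else {
    klass <- partition$class[match(hitting$gene, partition$gene_symbol)]
    ids_cod <- hitting$probe_id[!is.na(klass) & klass == "coding_only"]
    ids_non <- hitting$probe_id[!is.na(klass) & klass == "noncoding_only"]
  }
  pull <- function(ids) {
    present <- ids %in% rownames(exprs)
    vals <- exprs[ids[present], , drop = FALSE]
    list(n_dropped = sum(!present),
         values = switch(reduce,
                         median = apply(vals, 1L, median, na.rm = TRUE),
                         mean = rowMeans(vals, na.rm = TRUE),
                         none = as.vector(vals)[!is.na(as.vector(vals))]))
  }
  a <- pull(ids_cod); b <- pull(ids_non)
  n_dropped <- a$n_dropped + b$n_dropped
  if (n_dropped > 0L) message(n_dropped, " selected probe(s) absent from expression matrix")
  if (length(a$values) == 0L || length(b$values) == 0L) {
    stop("empty expression group; relax the selection ",
         "(e.g. rule = \"locus_class\" or reduce = \"none\")")
  }
  list(coding = a$values, noncoding = b$values, n_dropped = n_dropped)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank test with midrank tie handling. The statistic is
#' \eqn{U = R_1 - n_1(n_1+1)/2} from the midranks of the pooled sample. For
#' small problems (number of group labelings \eqn{C(N, n_1)} at most
#' `exact_cap`) the two-sided p-value is computed by full enumeration of rank
#' assignments (the permutation distribution of U is symmetric about
#' \eqn{n_1 n_2/2}, so the two-sided p is the probability of a deviation at
#' least as large as observed). Otherwise a normal approximation with
#' continuity correction and tie-corrected variance
#' \eqn{n_1 n_2/12 [(N+1) - \sum(t^3-t)/(N(N-1))]} is used. NA values are
#' removed before ranking.
#'
#' @param a,b numeric vectors (each of length >= 1 after NA removal).
#' @param exact_cap enumerate exactly when `choose(n1+n2, n1) <= exact_cap`
#'   (default `2e5`).
#' @return object of class `rank_test`: `n1`, `n2`, `U`, `z`, `p_two_sided`,
#'   `method` (`"exact"` or `"normal_approx"`), `degenerate` (all pooled
#'   values identical; p is 1).
#' @examples
#' mann_whitney(c(1, 2, 3), c(1, 2, 3))
#' @export
mann_whitney <- function(a, b, exact_cap = 2e5) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("values must be finite")
  pooled <- c(a, b)
  N <- n1 + n2
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tt <- table(pooled)
  tie_term <- sum(tt^3 - tt)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  degenerate <- length(tt) == 1L
  z <- if (v > 0) {
    cc <- 0.5 * sign(U - mu)
    (U - mu - cc) / sqrt(v)
  } else 0
  if (choose(N, n1) <= exact_cap) {
    method <- "exact"
    k <- min(n1, n2)
    cmb <- combn(N, k)
    Rk <- colSums(matrix(r[cmb], nrow = k))
    R1s <- if (k == n1) Rk else sum(r) - Rk
    Us <- R1s - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
  } else {
    method <- "normal_approx"
    p <- if (v > 0) min(1, 2 * pnorm(-abs(z))) else 1
  }
  if (degenerate) p <- 1
  structure(list(n1 = n1, n2 = n2, U = U, z = z, p_two_sided = p,
                 method = method, degenerate = degenerate),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney: n1 = %d, n2 = %d, U = %.1f, z = %.3f\n",
              x$n1, x$n2, x$U, x$z))
  cat(sprintf("  two-sided p = %.4g (%s)%s\n", x$p_two_sided, x$method,
              if (x$degenerate) " [degenerate: all values tied]" else ""))
  invisible(x)
}

#' Five-number summary with Tukey fences
#'
#' Quartiles by linear interpolation (type 7); outliers are values beyond
#' 1.5 IQR from the quartile hinges.
#'
#' @param v numeric vector, length >= 1 (NA removed).
#' @return list: `min`, `q1`, `median`, `q3`, `max`, `iqr`, `fences`
#'   (length 2), `outliers`.
#' @export
boxplot_summary <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty vector")
  q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  iqr <- q[4] - q[2]
  fences <- c(q[2] - 1.5 * iqr, q[4] + 1.5 * iqr)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       iqr = iqr, fences = fences,
       outliers = v[v < fences[1] | v > fences[2]])
}
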