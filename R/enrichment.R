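#' Read a gene-set library in GMT format
#'
#' Each line: set name, description, then tab-separated gene symbols. Symbols
#' are uppercased and deduplicated within a set. Duplicate set names and lines
#' with fewer than three fields are errors.
#'
#' @param path file path.
#' @return object of class `gene_set_library`: list with `sets` (named list of
#'   character vectors), `descriptions`, and `universe` (union of all set
#'   genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop("line ", short[1L], ": GMT line with < 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name in GMT: ", nm[duplicated(nm)][1L])
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, character(1), 2L)
  names(desc) <- nm
  structure(list(sets = sets, descriptions = desc,
                 universe = sort(unique(unlist(sets, use.names = FALSE)))),
            class = "gene_set_library")
}

#' Write a gene-set library in GMT format
#'
#' @param lib `gene_set_library` (or named list of character vectors).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  sets <- if (inherits(lib, "gene_set_library")) lib$sets else lib
  desc <- if (inherits(lib, "gene_set_library")) lib$descriptions else
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for the overlap \eqn{X} between a random query of size
#' \eqn{n} and a set of size \eqn{m} drawn from a universe of size \eqn{N}:
#' \eqn{\sum_{i=k}^{\min(m,n)} C(m,i) C(N-m,n-i) / C(N,n)}, accumulated in log
#' space for numerical stability. `k = 0` returns exactly 1.
#'
#' @param k observed overlap (vectorized).
#' @param m set size.
#' @param n query size.
#' @param N universe size.
#' @return numeric vector of probabilities in (0, 1].
#' @export
hypergeom_tail <- function(k, m, n, N) {
  stopifnot(m <= N, n <= N)
  vapply(k, function(kk) {
    lo <- max(0, n + m - N)
    hi <- min(m, n)
    if (kk > hi) return(0)
    if (kk <= lo) return(1)
    i <- kk:hi
    lp <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
    min(1, exp(logsumexp(lp)))
  }, numeric(1))
}

#' Hypergeometric overrepresentation of a gene list in a set library
#'
#' For every set in the library, computes the overlap with the query and the
#' one-sided (upper tail) hypergeometric p-value — the Fisher-exact enrichment
#' probability of seeing at least that overlap by drawing the query uniformly
#' from the universe — then adjusts across sets with Benjamini-Hochberg.
#' The default universe is the union of library genes; pass an explicit
#' `universe` (e.g. all genes on an array) for a platform-constrained
#' background, in which case sets are intersected with it. Query genes outside
#' the universe are dropped with a message; a query disjoint from the universe
#' is an error.
#'
#' @param query character vector of gene symbols (case-insensitive).
#' @param lib `gene_set_library` from [read_gmt()].
#' @param universe optional character vector overriding the background.
#' @return data.frame sorted by p (ties broken by set name): `set`, `N`, `m`,
#'   `n`, `k`, `p_hyper`, `q_bh`.
#' @export
enrich <- function(query, lib, universe = NULL) {
  stopifnot(inherits(lib, "gene_set_library"))
  uni <- if (is.null(universe)) lib$universe else sort(unique(toupper(universe)))
  sets <- lapply(lib$sets, function(s) intersect(s, uni))
  query <- unique(toupper(query))
  dropped <- setdiff(query, uni)
  if (length(dropped) == length(query)) {
    stop("query is disjoint from the universe")
  }
  if (length(dropped)) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  q <- intersect(query, uni)
  N <- length(uni); n <- length(q)
  m <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, q)), integer(1))
  p <- vapply(seq_along(sets), function(i) hypergeom_tail(k[i], m[i], n, N),
              numeric(1))
  out <- data.frame(set = names(sets), N = N, m = as.integer(m), n = n,
                    k = as.integer(k), p_hyper = p,
                    q_bh = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_hyper, out$set), , drop = FALSE]
}
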