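test_that("rank-sum statistic and p-value behave at the boundaries", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  expect_equal(r$p_two_sided, 1)
  expect_equal(r$method, "exact")
  d <- mann_whitney(c(2, 2), c(2, 2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p_two_sided, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  expect_error(mann_whitney(c(1, Inf), c(2, 3)), "finite")
  # NA values are removed before ranking
  expect_equal(mann_whitney(c(1, 3, 5, NA), c(2, 4, 6))$U,
               mann_whitney(c(1, 3, 5), c(2, 4, 6))$U)
})

test_that("exact p equals brute-force enumeration over labelings", {
  o <- oracle_mw_exact(c(1, 3, 5), c(2, 4, 6))
  r <- mann_whitney(c(1, 3, 5), c(2, 4, 6))
  expect_equal(r$U, o$U)
  expect_equal(r$p_two_sided, o$p)
  for (seed in 1:12) {
    dat <- withr::with_seed(seed, {
      n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
      tied <- seed %% 2 == 0
      vals <- if (tied) sample(1:4, n1 + n2, replace = TRUE)
              else rnorm(n1 + n2)
      list(a = vals[1:n1], b = vals[-(1:n1)])
    })
    o <- oracle_mw_exact(dat$a, dat$b)
    r <- mann_whitney(dat$a, dat$b)
    expect_equal(r$U, o$U)
    expect_equal(r$p_two_sided, o$p, info = paste("seed", seed))
  }
})

test_that("rank-sum test matches the standard implementation", {
  # exact, no ties
  a <- withr::with_seed(1, rnorm(7)); b <- withr::with_seed(2, rnorm(9))
  expect_equal(mann_whitney(a, b)$p_two_sided,
               wilcox.test(a, b, exact = TRUE)$p.value)
  expect_equal(mann_whitney(a, b)$U, unname(wilcox.test(a, b)$statistic))
  # normal approximation with ties and continuity correction
  aa <- withr::with_seed(3, sample(1:6, 60, replace = TRUE))
  bb <- withr::with_seed(4, sample(1:6, 70, replace = TRUE))
  expect_equal(mann_whitney(aa, bb, exact_cap = 1)$p_two_sided,
               wilcox.test(aa, bb, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("rank-sum properties: complement, rank invariance, approximations", {
  for (seed in 1:6) {
    dat <- withr::with_seed(seed, list(a = rnorm(8), b = rnorm(8) + 0.5))
    ra <- mann_whitney(dat$a, dat$b)
    rb <- mann_whitney(dat$b, dat$a)
    expect_equal(ra$U + rb$U, ra$n1 * ra$n2)
    # invariant under strictly monotone transforms of the pooled values
    tr <- function(x) exp(x) + x^3
    rt <- mann_whitney(tr(dat$a), tr(dat$b))
    expect_equal(rt$U, ra$U)
    expect_equal(rt$p_two_sided, ra$p_two_sided)
    # exact and normal-approximation p agree closely at n1 = n2 = 8
    rn <- mann_whitney(dat$a, dat$b, exact_cap = 1)
    expect_equal(rn$method, "normal_approx")
    expect_lt(abs(rn$p_two_sided - ra$p_two_sided), 0.01)
  }
})

test_that("the test has high power against a one-SD shift", {
  rejections <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      a <- rnorm(100); b <- rnorm(100) + 1
      mann_whitney(a, b)$p_two_sided < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("expression groups recover planted membership", {
  # scenario with plenty of exclusively-coding and exclusively-non-coding
  # bifunctional loci so both groups are populated
  cfg <- synth_config(n_genes = 300, n_samples = 12, rng_seed = 77,
                      frac_probes_on_shared_exons = 0.4,
                      specific_coding_frac = 0.5)
  sim <- synth_generate(cfg)
  part <- partition_loci(sim$transcripts)
  rep <- match_probes(sim$probes, sim$transcripts, sim$genome)
  g <- select_groups(sim$exprs, rep, part, rule = "exclusive")
  truth <- sim$truth$probes
  expect_setequal(names(g$coding),
                  truth$probe_id[truth$expr_group %in% "coding"])
  expect_setequal(names(g$noncoding),
                  truth$probe_id[truth$expr_group %in% "noncoding"])
  # locus-class rule selects probes of coding-only vs noncoding-only loci
  g2 <- select_groups(sim$exprs, rep, part, rule = "locus_class")
  cls <- sim$truth$genes$class[match(truth$gene, sim$truth$genes$gene_symbol)]
  expect_setequal(names(g2$coding), truth$probe_id[cls == "coding_only"])
  expect_setequal(names(g2$noncoding), truth$probe_id[cls == "noncoding_only"])
  # probes absent from the matrix are dropped with a message
  ex2 <- sim$exprs[-(1:5), , drop = FALSE]
  expect_message(select_groups(ex2, rep, part, rule = "locus_class"), "absent")
  # an impossible selection is a clear error
  few <- rep[rep$verdict == "no_hit", , drop = FALSE]
  expect_error(select_groups(sim$exprs, few, part), "relax")
})

test_that("per-probe reduction modes behave as documented", {
  cfg <- synth_config(n_genes = 100, n_samples = 5, rng_seed = 13)
  sim <- synth_generate(cfg)
  part <- partition_loci(sim$transcripts)
  rep <- match_probes(sim$probes, sim$transcripts, sim$genome)
  gm <- select_groups(sim$exprs, rep, part, rule = "locus_class",
                      reduce = "median")
  expect_equal(unname(gm$coding[1]),
               median(sim$exprs[names(gm$coding)[1], ]))
  gn <- select_groups(sim$exprs, rep, part, rule = "locus_class",
                      reduce = "none")
  expect_length(gn$coding, length(gm$coding) * ncol(sim$exprs))
})

test_that("five-number summary matches direct computation", {
  s <- boxplot_summary(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q1, s$median, s$q3), c(2, 3, 4))
  expect_length(s$outliers, 0)
  cs <- boxplot_summary(rep(7, 10))
  expect_equal(cs$iqr, 0)
  expect_length(cs$outliers, 0)
  v <- withr::with_seed(8, c(rnorm(50), 10))
  s2 <- boxplot_summary(v)
  # direct sort-based type-7 quantiles
  q7 <- function(p) {
    sv <- sort(v); h <- (length(sv) - 1) * p
    sv[floor(h) + 1] + (h - floor(h)) * (sv[min(floor(h) + 2, length(sv))] -
                                           sv[floor(h) + 1])
  }
  expect_equal(s2$q1, q7(0.25))
  expect_equal(s2$q3, q7(0.75))
  expect_equal(s2$median, q7(0.5))
  expect_true(10 %in% s2$outliers)
  expect_equal(s2$min, min(v))
  expect_equal(s2$max, max(v))
})

test_that("expression matrix TSV round-trips", {
  sim <- shared_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$exprs, f)
  m <- read_expression(f)
  expect_equal(m, sim$exprs, tolerance = 1e-12)
  # duplicate ids and all-NA rows are handled
  writeLines(c("probe_id\ts1", "p1\t1", "p1\t2"), f)
  expect_error(read_expression(f), "duplicate")
  writeLines(c("probe_id\ts1\ts2", "p1\t1\t2", "p2\tNA\tNA"), f)
  expect_message(m2 <- read_expression(f), "dropped")
  expect_equal(rownames(m2), "p1")
})
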