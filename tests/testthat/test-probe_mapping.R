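test_that("spliced sequences concatenate exons and honor strand", {
  genome <- c(chr1 = "ACGTACGT")
  plus <- tx_from_lines("g\tNR_1\tchr1\t+\t0\t4\t4\t4\t1\t0,\t4,")
  expect_equal(unname(spliced_sequence(plus, genome)), "ACGT")
  fwd3 <- tx_from_lines("g\tNR_2\tchr1\t+\t0\t3\t3\t3\t1\t0,\t3,")
  expect_equal(unname(spliced_sequence(fwd3, genome)), "ACG")
  rev3 <- tx_from_lines("g\tNR_3\tchr1\t-\t0\t3\t3\t3\t1\t0,\t3,")
  expect_equal(unname(spliced_sequence(rev3, genome)), "CGT")
  # junction joining: two exons vs the brute-force per-base oracle
  two <- tx_from_lines("g\tNR_4\tchr1\t+\t0\t8\t8\t8\t2\t0,5,\t3,8,")
  expect_equal(unname(spliced_sequence(two, genome)), "ACGCGT")
  expect_equal(unname(spliced_sequence(two, genome)), oracle_spliced(two, genome))
  expect_error(
    spliced_sequence(tx_from_lines("g\tNR_5\tchr1\t+\t0\t99\t99\t99\t1\t0,\t99,"),
                     genome), "beyond")
})

test_that("spliced_sequence matches the per-base oracle on random models", {
  sim <- shared_sim()
  tx <- sim$transcripts[seq(1, nrow(sim$transcripts), by = 17), ]
  got <- spliced_sequence(tx, sim$genome)
  for (i in seq_len(nrow(tx))) {
    expect_equal(unname(got[i]), oracle_spliced(tx[i, ], sim$genome))
  }
  # strand involution: flipping the strand reverse-complements the sequence
  flipped <- tx
  flipped$strand <- ifelse(tx$strand == "+", "-", "+")
  expect_equal(unname(spliced_sequence(flipped, sim$genome)),
               rc_chr(unname(got)))
})

test_that("probe verdicts follow the coding status of hit transcripts", {
  hf <- hand_fixture()
  nm_seq <- spliced_sequence(hf$transcripts[1, ], hf$genome)
  nr_seq <- spliced_sequence(hf$transcripts[2, ], hf$genome)
  nm2_seq <- spliced_sequence(hf$transcripts[3, ], hf$genome)
  probes <- data.frame(
    probe_id = c("p_nm_only", "p_shared_exon", "p_junction_shared",
                 "p_whole_nr", "p_none"),
    probeset_id = "ps1",
    gene = c("geneA", "geneA", "geneB", "geneA", "geneA"),
    # 1: inside the NM-specific exon; 2: inside an exon shared by NM and NR
    # isoforms; 3: spanning a splice junction present in both an NM_ and an
    # NR_ transcript; 4: the entire NR spliced sequence; 5: no hit
    sequence = c(substr(nm_seq, 35, 59), substr(nm_seq, 3, 27),
                 substr(nm2_seq, 20, 44), unname(nr_seq), strrep("A", 25)),
    stringsAsFactors = FALSE)
  rep <- match_probes(probes, hf$transcripts, hf$genome, sense_mode = "sense")
  expect_equal(rep$verdict,
               c("coding_specific", "ambiguous", "ambiguous",
                 "noncoding_specific", "no_hit"))
  hits <- attr(rep, "hits")
  expect_setequal(hits$accession[hits$probe_id == "p_shared_exon"],
                  c("NM_000001.1", "NR_000001.1"))
  expect_setequal(hits$accession[hits$probe_id == "p_junction_shared"],
                  c("NM_000002.1", "NR_000002.1"))
  # the NR-junction probe (exon 1 to exon 3) must not match the NM isoform
  expect_setequal(hits$accession[hits$probe_id == "p_whole_nr"],
                  "NR_000001.1")
  # antisense-only probes are found under both and antisense modes
  rc_probes <- probes[1, ]
  rc_probes$sequence <- rc_chr(rc_probes$sequence)
  expect_equal(match_probes(rc_probes, hf$transcripts, hf$genome,
                            sense_mode = "both")$verdict, "coding_specific")
  expect_equal(match_probes(rc_probes, hf$transcripts, hf$genome,
                            sense_mode = "sense")$verdict, "no_hit")
})

test_that("non-ACGT probes are skipped with a warning", {
  hf <- hand_fixture()
  probes <- data.frame(probe_id = c("ok", "bad"), probeset_id = "ps",
                       gene = "geneA",
                       sequence = c(strrep("A", 25), "ACGTNACGTN"),
                       stringsAsFactors = FALSE)
  expect_warning(rep <- match_probes(probes, hf$transcripts, hf$genome),
                 "skipped")
  expect_equal(rep$probe_id, "ok")
})

test_that("indexed matcher equals the naive full-scan oracle", {
  sim <- shared_sim()
  tx <- sim$transcripts[1:30, ]
  probes <- sim$probes[sim$probes$gene %in% tx$gene_symbol, ][1:40, ]
  # add random probes that mostly miss
  rand <- withr::with_seed(42, replicate(10, paste(
    sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")))
  probes <- rbind(probes, data.frame(
    probe_id = paste0("rand", 1:10), probeset_id = "rand", gene = "",
    sequence = rand, stringsAsFactors = FALSE))
  for (mode in c("both", "sense", "antisense")) {
    got <- attr(match_probes(probes, tx, sim$genome, sense_mode = mode), "hits")
    want <- oracle_match(probes, tx, sim$genome, sense_mode = mode)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("verdicts are monotone in the transcript set", {
  sim <- shared_sim()
  tx <- sim$transcripts
  probes <- sim$probes[seq(1, nrow(sim$probes), by = 9), ]
  full <- match_probes(probes, tx, sim$genome)
  sub <- match_probes(probes, tx[seq(1, nrow(tx), by = 2), ], sim$genome)
  # adding transcripts can never turn ambiguous into specific
  was_amb <- sub$verdict == "ambiguous"
  expect_true(all(full$verdict[was_amb] == "ambiguous"))
  # hit flags only ever accumulate
  expect_true(all(full$hit_coding >= sub$hit_coding))
  expect_true(all(full$hit_noncoding >= sub$hit_noncoding))
})

test_that("gene-level roll-up counts ambiguous probes correctly", {
  reports <- data.frame(
    probe_id = paste0("p", 1:5),
    probeset_id = "ps",
    gene = c("g1", "g1", "g1", "g2", "g2"),
    n_hits = c(1L, 2L, 2L, 1L, 0L),
    hit_coding = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    hit_noncoding = c(FALSE, TRUE, TRUE, FALSE, FALSE),
    verdict = c("coding_specific", "ambiguous", "ambiguous",
                "coding_specific", "no_hit"),
    stringsAsFactors = FALSE)
  attr(reports, "hits") <- data.frame(
    probe_id = c("p1", "p2", "p2", "p3", "p3", "p4"),
    accession = c("NM_a", "NM_a", "NR_a", "NM_a", "NR_a", "NM_b"),
    gene_hit = c("g1", "g1", "g1", "g1", "g1", "g2"),
    coding = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    offset = 0L, orientation = "sense", stringsAsFactors = FALSE)
  partition <- data.frame(
    gene_symbol = c("g1", "g2"),
    n_coding = c(1L, 1L), n_noncoding = c(1L, 0L),
    class = c("bifunctional", "coding_only"), stringsAsFactors = FALSE)
  gd <- gene_discriminability(reports, partition)
  g1 <- gd$genes[gd$genes$gene_symbol == "g1", ]
  expect_equal(g1$n_probes, 3L)
  expect_equal(g1$n_ambiguous, 2L)
  expect_true(g1$any_ambiguous)
  expect_false(g1$all_ambiguous)
  expect_equal(gd$summary$n_probes_on_bifunctional, 3L)
  expect_equal(gd$summary$percent_ambiguous, 66.7)
  expect_equal(gd$summary$n_probes_no_hit, 1L)
  expect_equal(gd$summary$n_genes_any_ambiguous, 1L)
  expect_equal(gd$summary$n_genes_all_ambiguous, 0L)
  # a gene whose probes all sit on coding-specific exons is fully specific
  g2 <- gd$genes[gd$genes$gene_symbol == "g2", ]
  expect_false(g2$any_ambiguous)
  # by-hit assignment agrees here (declared genes match hit genes)
  gd2 <- gene_discriminability(reports, partition, gene_assignment = "by_hit")
  expect_equal(gd2$genes$n_ambiguous, gd$genes$n_ambiguous)
})

test_that("ambiguity percentages recover the generator's ground truth", {
  sim <- shared_sim()
  part <- partition_loci(sim$transcripts)
  rep <- match_probes(sim$probes, sim$transcripts, sim$genome)
  gd <- gene_discriminability(rep, part)
  truth <- sim$truth$probes
  bif_genes <- sim$truth$genes$gene_symbol[sim$truth$genes$class == "bifunctional"]
  tb <- truth[truth$gene %in% bif_genes, ]
  expect_equal(gd$summary$n_probes_on_bifunctional, nrow(tb))
  expect_equal(gd$summary$n_ambiguous_on_bifunctional,
               sum(tb$intended_verdict == "ambiguous"))
  # percent invariant under probe input order
  perm <- withr::with_seed(3, sample(nrow(sim$probes)))
  rep2 <- match_probes(sim$probes[perm, ], sim$transcripts, sim$genome)
  gd2 <- gene_discriminability(rep2, part)
  expect_equal(gd2$summary$percent_ambiguous, gd$summary$percent_ambiguous)
})
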