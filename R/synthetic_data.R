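#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the structure the pipeline is designed for: a locus census
#' with 9.2% bifunctional, 60.2% coding-only and 30.6% non-coding-only loci;
#' 11 perfect-match probes of 25 nt per gene (one probe set per locus); a
#' 60-sample expression panel on the log scale with no coding-versus-noncoding
#' mean shift (`delta = 0`, the "not significant" regime); and two-thirds of
#' bifunctional-gene probe sets placed on exons shared by coding and
#' non-coding isoforms.
#'
#' @param n_genes number of gene loci.
#' @param frac_bifunctional,frac_coding_only,frac_noncoding_only class
#'   probabilities (must sum to 1).
#' @param iso_coding_range,iso_noncoding_range integer ranges for the number
#'   of coding / non-coding isoforms per locus (bifunctional loci draw both).
#' @param exon_length_range,intron_length_range,intergenic_gap geometry of the
#'   synthetic gene models, in bp. Minimum exon length must be at least
#'   `probe_length`.
#' @param probe_length probe length in nt (default 25).
#' @param probes_per_gene probes per locus (default 11, a typical probe-set
#'   size).
#' @param frac_probes_on_shared_exons probability that a bifunctional locus's
#'   probe set is placed on shared exons (intended verdict: ambiguous) rather
#'   than on isoform-specific exons. Placement is correlated within a locus —
#'   a probe set interrogates one target region — so this is both the
#'   expected per-probe ambiguity fraction and the per-gene fraction of
#'   all-ambiguous bifunctional loci.
#' @param specific_coding_frac among specific-mode bifunctional loci, the
#'   probability the probe set sits on the coding-specific exon (default
#'   0.871, i.e. 770 of 884 exclusively-resolvable loci).
#' @param probe_orientation emit probes `"antisense"` to the mRNA (array
#'   convention, default) or `"sense"`.
#' @param n_samples expression panel size (default 60).
#' @param expr_mean,expr_gene_sd,expr_noise_sd log-scale expression model:
#'   per-gene baseline ~ Normal(`expr_mean`, `expr_gene_sd`), per-value noise
#'   ~ Normal(0, `expr_noise_sd`).
#' @param delta planted mean shift between coding-specific and
#'   noncoding-specific probes (+delta/2 vs -delta/2; default 0).
#' @param n_sets,set_size_range gene-set library: number of random sets and
#'   their size range; one additional planted set is biased toward
#'   bifunctional loci.
#' @param rng_seed seed for the single random generator used throughout.
#' @return object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 2000,
                         frac_bifunctional = 0.092,
                         frac_coding_only = 0.602,
                         frac_noncoding_only = 0.306,
                         iso_coding_range = c(1L, 2L),
                         iso_noncoding_range = c(1L, 2L),
                         exon_length_range = c(120L, 300L),
                         intron_length_range = c(60L, 200L),
                         intergenic_gap = 100L,
                         probe_length = 25L,
                         probes_per_gene = 11L,
                         frac_probes_on_shared_exons = 0.667,
                         specific_coding_frac = 0.871,
                         probe_orientation = c("antisense", "sense"),
                         n_samples = 60L,
                         expr_mean = 7,
                         expr_gene_sd = 1,
                         expr_noise_sd = 0.5,
                         delta = 0,
                         n_sets = 25L,
                         set_size_range = c(10L, 50L),
                         rng_seed = 1L) {
  probe_orientation <- match.arg(probe_orientation)
  fr <- c(frac_bifunctional, frac_coding_only, frac_noncoding_only)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-8) {
    stop("class fractions must lie in [0,1] and sum to 1")
  }
  stopifnot(n_genes >= 1, probes_per_gene >= 1, probe_length >= 1,
            n_samples >= 1, n_sets >= 0,
            frac_probes_on_shared_exons >= 0, frac_probes_on_shared_exons <= 1,
            specific_coding_frac >= 0, specific_coding_frac <= 1,
            is.finite(delta))
  if (exon_length_range[1L] < max(probe_length, 20L)) {
    stop("minimum exon length must be >= probe_length and >= 20")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    frac_bifunctional = frac_bifunctional,
    frac_coding_only = frac_coding_only,
    frac_noncoding_only = frac_noncoding_only,
    iso_coding_range = as.integer(iso_coding_range),
    iso_noncoding_range = as.integer(iso_noncoding_range),
    exon_length_range = as.integer(exon_length_range),
    intron_length_range = as.integer(intron_length_range),
    intergenic_gap = as.integer(intergenic_gap),
    probe_length = as.integer(probe_length),
    probes_per_gene = as.integer(probes_per_gene),
    frac_probes_on_shared_exons = frac_probes_on_shared_exons,
    specific_coding_frac = specific_coding_frac,
    probe_orientation = probe_orientation,
    n_samples = as.integer(n_samples),
    expr_mean = expr_mean, expr_gene_sd = expr_gene_sd,
    expr_noise_sd = expr_noise_sd, delta = delta,
    n_sets = as.integer(n_sets),
    set_size_range = as.integer(set_size_range),
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# exon subset for the j-th isoform of a simple multi-exon gene
iso_exon_subset <- function(k, j) {
  if (j == 1L) return(seq_len(k))
  if (k >= 3L) {
    drop <- 1L + (j - 1L)              # drop one internal/terminal exon
    if (drop > k) drop <- k
    return(setdiff(seq_len(k), drop))
  }
  if (k == 2L) return(if (j %% 2L == 0L) 1L else 2L)
  seq_len(k)
}

runif_int <- function(n, range) {
  if (range[1L] >= range[2L]) rep.int(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a ground-truthed synthetic dataset
#'
#' Emits (in memory, and optionally as files) a random genome, a transcript
#' annotation, a probe table, an expression matrix and a gene-set library
#' whose joint structure is known exactly. Bifunctional loci follow the
#' alternative-isoform architecture: two shared exons flank one
#' coding-specific and one noncoding-specific exon; the coding isoform (NM_)
#' splices shared-coding-shared, the non-coding isoform (NR_)
#' shared-noncoding-shared, so probes on shared exons cannot distinguish the
#' two classes while probes on the middle exons can. All randomness flows
#' from `config$rng_seed`; the same seed reproduces byte-identical outputs.
#'
#' @param config a [synth_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `annotation.genePred` (refFlat dialect), `probes.tsv`, `expression.tsv`,
#'   `library.gmt`, `truth_genes.tsv`, `truth_probes.tsv`.
#' @param components which artifacts to build: any of `"annotation"`,
#'   `"genome"`, `"probes"`, `"expression"`, `"gmt"`. The annotation is always
#'   built; probes/expression imply the genome.
#' @return list with `config`, `transcripts`, `genome`, `probes`, `exprs`,
#'   `library`, `truth` (list: `genes` with per-gene class, `probes` with
#'   intended verdict, expression group, host transcript and spliced offset),
#'   and `paths` when `out_dir` was given.
#' @export
synth_generate <- function(config,
                           out_dir = NULL,
                           components = c("annotation", "genome", "probes",
                                          "expression", "gmt")) {
  stopifnot(inherits(config, "synth_config"))
  components <- match.arg(components, several.ok = TRUE)
  need_probes <- any(c("probes", "expression") %in% components)
  need_genome <- need_probes || "genome" %in% components
  withr::with_seed(config$rng_seed, {
    n <- config$n_genes
    gene <- sprintf("GENE%05d", seq_len(n))
    klass <- sample(c("bifunctional", "coding_only", "noncoding_only"), n,
                    replace = TRUE,
                    prob = c(config$frac_bifunctional, config$frac_coding_only,
                             config$frac_noncoding_only))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_cod <- ifelse(klass == "noncoding_only", 0L,
                    runif_int(n, config$iso_coding_range))
    n_non <- ifelse(klass == "coding_only", 0L,
                    runif_int(n, config$iso_noncoding_range))

    acc <- list(); gsym <- list(); chl <- list(); stl <- list()
    esl <- list(); eel <- list(); csl <- list(); cel <- list()
    gene_exons <- vector("list", n)   # per gene: starts, ends, roles
    ti <- 0L
    nm_counter <- 0L; nr_counter <- 0L
    cursor <- 0L
    add_tx <- function(a, g, st, es, ee, cs, ce) {
      ti <<- ti + 1L
      acc[[ti]] <<- a; gsym[[ti]] <<- g; chl[[ti]] <<- "chr1"; stl[[ti]] <<- st
      esl[[ti]] <<- es; eel[[ti]] <<- ee; csl[[ti]] <<- cs; cel[[ti]] <<- ce
    }
    nm_acc <- function() { nm_counter <<- nm_counter + 1L
      sprintf("NM_%06d.1", nm_counter) }
    nr_acc <- function() { nr_counter <<- nr_counter + 1L
      sprintf("NR_%06d.1", nr_counter) }

    for (i in seq_len(n)) {
      k_ex <- if (klass[i] == "bifunctional") 4L else
        max(3L, runif_int(1L, c(2L, 4L)))
      lens <- runif_int(k_ex, config$exon_length_range)
      gaps <- runif_int(k_ex, config$intron_length_range)
      starts <- integer(k_ex); ends <- integer(k_ex)
      pos <- cursor + config$intergenic_gap
      for (e in seq_len(k_ex)) {
        starts[e] <- pos
        ends[e] <- pos + lens[e]
        pos <- ends[e] + gaps[e]
      }
      cursor <- ends[k_ex]
      roles <- if (klass[i] == "bifunctional")
        c("shared", "coding_specific", "noncoding_specific", "shared")
      else rep("all", k_ex)
      gene_exons[[i]] <- list(starts = starts, ends = ends, roles = roles)
      if (klass[i] == "bifunctional") {
        nm_ex <- list(c(1L, 2L, 4L), c(2L, 4L))
        nr_ex <- list(c(1L, 3L, 4L), c(1L, 3L))
        for (j in seq_len(n_cod[i])) {
          sel <- nm_ex[[min(j, 2L)]]
          if (j > 2L) sel <- nm_ex[[1L]][seq_len(2L)]  # rare: >2 isoforms
          es <- starts[sel]; ee <- ends[sel]
          add_tx(nm_acc(), gene[i], strand[i], es, ee,
                 es[1L] + 9L, ee[length(ee)] - 9L)
        }
        for (j in seq_len(n_non[i])) {
          sel <- nr_ex[[min(j, 2L)]]
          if (j > 2L) sel <- nr_ex[[1L]][seq_len(2L)]
          add_tx(nr_acc(), gene[i], strand[i], starts[sel], ends[sel],
                 NA_integer_, NA_integer_)
        }
      } else if (klass[i] == "coding_only") {
        for (j in seq_len(n_cod[i])) {
          sel <- iso_exon_subset(k_ex, j)
          es <- starts[sel]; ee <- ends[sel]
          add_tx(nm_acc(), gene[i], strand[i], es, ee,
                 es[1L] + 9L, ee[length(ee)] - 9L)
        }
      } else {
        for (j in seq_len(n_non[i])) {
          sel <- iso_exon_subset(k_ex, j)
          add_tx(nr_acc(), gene[i], strand[i], starts[sel], ends[sel],
                 NA_integer_, NA_integer_)
        }
      }
    }
    transcripts <- transcript_table(
      accession = unlist(acc), gene_symbol = unlist(gsym),
      chrom = unlist(chl), strand = unlist(stl),
      exon_starts = esl[seq_len(ti)], exon_ends = eel[seq_len(ti)],
      cds_start = unlist(csl), cds_end = unlist(cel)
    )
    truth_genes <- data.frame(gene_symbol = gene, class = klass,
                              n_coding = n_cod, n_noncoding = n_non,
                              stringsAsFactors = FALSE)

    genome <- NULL
    if (need_genome) {
      total_len <- cursor + config$intergenic_gap
      genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), total_len,
                                      replace = TRUE), collapse = ""))
    }

    probes <- NULL; truth_probes <- NULL
    if (need_probes) {
      # first isoform of each class per gene hosts the probes
      tx_by_gene <- split(seq_len(nrow(transcripts)), transcripts$gene_symbol)
      L <- config$probe_length
      np <- config$probes_per_gene
      rows <- vector("list", n)
      for (i in seq_len(n)) {
        ge <- gene_exons[[i]]
        idxs <- tx_by_gene[[gene[i]]]
        cod_first <- idxs[transcripts$coding[idxs]][1L]
        non_first <- idxs[!transcripts$coding[idxs]][1L]
        if (klass[i] == "bifunctional") {
          mode <- if (stats::runif(1) < config$frac_probes_on_shared_exons)
            "shared"
          else if (stats::runif(1) < config$specific_coding_frac)
            "spec_coding" else "spec_noncoding"
        } else mode <- "plain"
        target_exon <- switch(mode,
          shared = sample(c(1L, 4L), np, replace = TRUE),
          spec_coding = rep.int(2L, np),
          spec_noncoding = rep.int(3L, np),
          plain = sample(length(ge$starts), np, replace = TRUE))
        host <- switch(mode,
          shared = cod_first, spec_coding = cod_first,
          spec_noncoding = non_first,
          plain = if (klass[i] == "coding_only") cod_first else non_first)
        verdict <- switch(mode,
          shared = "ambiguous", spec_coding = "coding_specific",
          spec_noncoding = "noncoding_specific",
          plain = if (klass[i] == "coding_only") "coding_specific"
                  else "noncoding_specific")
        grp <- switch(mode, spec_coding = "coding",
                      spec_noncoding = "noncoding", NA_character_)
        hes <- transcripts$exon_starts[[host]]
        hee <- transcripts$exon_ends[[host]]
        hlen <- sum(hee - hes)
        pos_in_exon <- vapply(target_exon, function(e) {
          sample.int(ge$ends[e] - ge$starts[e] - L + 1L, 1L) - 1L
        }, integer(1))
        # offset of the probe window within the spliced sequence (sense)
        off_plus <- vapply(seq_len(np), function(j) {
          e <- target_exon[j]
          before <- sum((hee - hes)[hes < ge$starts[e]])
          before + pos_in_exon[j]
        }, integer(1))
        off <- if (strand[i] == "-") hlen - off_plus - L else off_plus
        rows[[i]] <- data.frame(
          probe_id = sprintf("%s_p%02d", gene[i], seq_len(np)),
          probeset_id = paste0(gene[i], "_at"),
          gene = gene[i],
          host = transcripts$accession[host],
          offset = off,
          intended_verdict = verdict,
          expr_group = grp,
          stringsAsFactors = FALSE
        )
      }
      truth_probes <- do.call(rbind, rows)
      host_seqs <- spliced_sequence(
        transcripts[match(unique(truth_probes$host), transcripts$accession), ,
                    drop = FALSE], genome)
      sense_seq <- substring(host_seqs[truth_probes$host],
                             truth_probes$offset + 1L,
                             truth_probes$offset + L)
      emitted <- if (config$probe_orientation == "antisense")
        revcomp(sense_seq) else sense_seq
      probes <- data.frame(
        probe_id = truth_probes$probe_id,
        probeset_id = truth_probes$probeset_id,
        gene = truth_probes$gene,
        sequence = unname(emitted),
        stringsAsFactors = FALSE
      )
    }

    exprs <- NULL
    if ("expression" %in% components) {
      base <- rnorm(n, config$expr_mean, config$expr_gene_sd)
      names(base) <- gene
      shift <- ifelse(truth_probes$intended_verdict == "coding_specific",
                      config$delta / 2,
                      ifelse(truth_probes$intended_verdict == "noncoding_specific",
                             -config$delta / 2, 0))
      mu <- base[truth_probes$gene] + shift
      exprs <- matrix(rnorm(length(mu) * config$n_samples, mean = mu,
                            sd = config$expr_noise_sd),
                      nrow = length(mu), ncol = config$n_samples)
      rownames(exprs) <- truth_probes$probe_id
      colnames(exprs) <- sprintf("SAMPLE%02d", seq_len(config$n_samples))
    }

    lib <- NULL
    if ("gmt" %in% components && config$n_sets > 0L) {
      sizes <- runif_int(config$n_sets, config$set_size_range)
      sizes <- pmin(sizes, n)
      sets <- lapply(seq_len(config$n_sets), function(s)
        sort(sample(gene, sizes[s])))
      names(sets) <- sprintf("SET_%02d", seq_len(config$n_sets))
      bif_genes <- gene[klass == "bifunctional"]
      if (length(bif_genes) >= 5L) {
        sz <- min(40L, n)
        n_bif <- min(length(bif_genes), ceiling(0.8 * sz))
        planted <- sort(c(sample(bif_genes, n_bif),
                          sample(setdiff(gene, bif_genes), sz - n_bif)))
        sets$ENRICHED_BIF <- planted
      }
      desc <- setNames(rep("synthetic", length(sets)), names(sets))
      lib <- structure(list(sets = sets, descriptions = desc,
                            universe = sort(gene)),
                       class = "gene_set_library")
    }

    out <- list(config = config, transcripts = transcripts, genome = genome,
                probes = probes, exprs = exprs, library = lib,
                truth = list(genes = truth_genes, probes = truth_probes))
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      paths <- c(annotation = file.path(out_dir, "annotation.genePred"))
      write_genepred(transcripts, paths[["annotation"]], format = "refflat")
      if (!is.null(genome)) {
        paths[["genome"]] <- file.path(out_dir, "genome.fa")
        write_genome_fasta(genome, paths[["genome"]])
      }
      if (!is.null(probes)) {
        paths[["probes"]] <- file.path(out_dir, "probes.tsv")
        write.table(probes, paths[["probes"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
      }
      if (!is.null(exprs)) {
        paths[["expression"]] <- file.path(out_dir, "expression.tsv")
        write_expression(exprs, paths[["expression"]])
      }
      if (!is.null(lib)) {
        paths[["gmt"]] <- file.path(out_dir, "library.gmt")
        write_gmt(lib, paths[["gmt"]])
      }
      paths[["truth_genes"]] <- file.path(out_dir, "truth_genes.tsv")
      write.table(truth_genes, paths[["truth_genes"]], sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (!is.null(truth_probes)) {
        paths[["truth_probes"]] <- file.path(out_dir, "truth_probes.tsv")
        write.table(truth_probes, paths[["truth_probes"]], sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      out$paths <- paths
    }
    out
  })
}

#' Re-run the pipeline on synthetic data and check it against ground truth
#'
#' Recovers the locus partition (and, when present, probe verdicts, recorded
#' probe offsets and expression-group membership) from the generated artifacts
#' and compares against the generator's ground truth. Any disagreement is
#' enumerated in the returned report rather than raised.
#'
#' @param sim result of [synth_generate()].
#' @return list: `ok` (logical), `class_mismatches`, `verdict_mismatches`,
#'   `offset_mismatches`, `group_mismatches` (data.frames, empty when clean).
#' @export
synth_verify <- function(sim) {
  part <- partition_loci(sim$transcripts)
  tg <- sim$truth$genes
  got <- part$class[match(tg$gene_symbol, part$gene_symbol)]
  cm <- tg[is.na(got) | got != tg$class, , drop = FALSE]
  cm$recovered <- got[is.na(got) | got != tg$class]
  vm <- om <- gm <- data.frame()
  if (!is.null(sim$probes)) {
    reports <- match_probes(sim$probes, sim$transcripts, sim$genome,
                            sense_mode = "both")
    tp <- sim$truth$probes
    gotv <- reports$verdict[match(tp$probe_id, reports$probe_id)]
    vm <- tp[is.na(gotv) | gotv != tp$intended_verdict, , drop = FALSE]
    # recorded offsets must address the emitted probe within the host
    # (hosts missing from a corrupted annotation are themselves mismatches)
    L <- sim$config$probe_length
    present <- tp$host %in% sim$transcripts$accession
    window <- rep(NA_character_, nrow(tp))
    if (any(present)) {
      hosts <- unique(tp$host[present])
      host_seqs <- spliced_sequence(
        sim$transcripts[match(hosts, sim$transcripts$accession), ,
                        drop = FALSE], sim$genome)
      window[present] <- substring(host_seqs[tp$host[present]],
                                   tp$offset[present] + 1L,
                                   tp$offset[present] + L)
    }
    emitted <- sim$probes$sequence[match(tp$probe_id, sim$probes$probe_id)]
    sense <- if (sim$config$probe_orientation == "antisense") revcomp(emitted)
             else emitted
    om <- tp[is.na(window) | window != sense, , drop = FALSE]
    if (!is.null(sim$exprs)) {
      grp <- tryCatch(
        select_groups(sim$exprs, reports, part, rule = "exclusive"),
        error = function(e) NULL)
      if (!is.null(grp)) {
        want_cod <- sort(tp$probe_id[!is.na(tp$expr_group) &
                                       tp$expr_group == "coding"])
        want_non <- sort(tp$probe_id[!is.na(tp$expr_group) &
                                       tp$expr_group == "noncoding"])
        bad_cod <- setdiff(union(names(grp$coding), want_cod),
                           intersect(names(grp$coding), want_cod))
        bad_non <- setdiff(union(names(grp$noncoding), want_non),
                           intersect(names(grp$noncoding), want_non))
        if (length(bad_cod) || length(bad_non)) {
          gm <- data.frame(probe_id = c(bad_cod, bad_non),
                           group = rep(c("coding", "noncoding"),
                                       c(length(bad_cod), length(bad_non))),
                           stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(ok = nrow(cm) == 0L && nrow(vm) == 0L && nrow(om) == 0L &&
         nrow(gm) == 0L,
       class_mismatches = cm, verdict_mismatches = vm,
       offset_mismatches = om, group_mismatches = gm)
}
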