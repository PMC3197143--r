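# Synthetic cohort generator: determinism, frame arithmetic, planted
# effect structure, read fidelity.

test_that("an empty config yields empty outputs", {
  cfg <- sim_config(n_genes = 0, n_pattern1 = 0, n_pattern2 = 0,
                    n_pattern3 = 0, n_skip = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotation$genes), 0L)
  d <- tempfile()
  paths <- write_simulation(sim, d)
  expect_true(file.exists(paths$genome))
})

test_that("identical seeds give byte-identical FASTA, GTF and FASTQ", {
  cfg <- small_config(seed = 21, reads_per_sample = 500)
  d1 <- tempfile(); d2 <- tempfile()
  sim1 <- simulate_genome(cfg); sim2 <- simulate_genome(cfg)
  write_simulation(sim1, d1); write_simulation(sim2, d2)
  for (f in c("genome.fa", "annotation.gtf"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  e1 <- simulate_expression(sim1, cfg); e2 <- simulate_expression(sim2, cfg)
  expect_identical(e1$mass, e2$mass)
  r1 <- simulate_reads(sim1, e1, sample_ids = "P01_T", dir = d1)
  r2 <- simulate_reads(sim2, e2, sample_ids = "P01_T", dir = d2)
  expect_identical(r1, r2)
  expect_identical(readLines(file.path(d1, "P01_T.fastq")),
                   readLines(file.path(d2, "P01_T.fastq")))
})

test_that("every transcript is fully coding with CDS length a multiple of 3", {
  sim <- simulate_genome(small_config())
  tx <- sim$annotation$transcripts
  expect_true(all(tx$cds_length %% 3 == 0))
  expect_true(all(tx$frame_consistent))
  expect_true(all(tx$cds_length == tx$length))
})

test_that("planted skips are frame-preserving: donor end phase equals acceptor start phase", {
  cfg <- small_config(seed = 13)
  sim <- simulate_genome(cfg)
  skips <- sim$roles[sim$roles$role == "skip", ]
  expect_equal(nrow(skips), cfg$n_skip)
  ex <- sim$annotation$exons
  for (i in seq_len(nrow(skips))) {
    d <- ex[ex$exon_id == skips$donor_exon[i], ]
    a <- ex[ex$exon_id == skips$acceptor_exon[i], ]
    expect_equal(d$end_phase, a$start_phase)
    # recompute from the emitted per-transcript CDS lengths
    full_tx <- sprintf("T_%s_full", skips$gene_id[i])
    et <- sim$annotation$exon_tx |>
      dplyr::filter(transcript_id == full_tx) |>
      dplyr::arrange(exon_rank)
    ph <- compute_exon_phases(et$cds_len)
    sp <- cfg$skip_span
    expect_equal(ph$end_phase[min(sp) - 1], ph$start_phase[max(sp) + 1])
  }
})

test_that("an infeasible exon length range is rejected by name", {
  expect_error(sim_config(exon_length = c(20, 40)), "flank")
  expect_error(sim_config(skip_span = 6:10), "acceptor")
})

test_that("zero DEG fraction plants no gene-level effects", {
  cfg <- small_config(deg_fraction = 0, n_pattern1 = 0)
  expr <- simulate_expression(simulate_genome(cfg), cfg)
  expect_equal(sum(expr$truth$genes$is_deg), 0L)
})

test_that("planted DEGs have geometric-mean abundance ratio near the planted fold change", {
  # closed form: the log2 of the tumour/normal molar ratio averages to
  # the planted shift because all noise terms are symmetric in log space
  # (Monte-Carlo over simulated cohorts)
  ratios <- c()
  for (s in 1:30) {
    cfg <- sim_config(seed = s, n_genes = 60, n_pairs = 4,
                      deg_fraction = 0.2, n_pattern1 = 0, n_pattern2 = 0,
                      n_pattern3 = 0, n_skip = 0, reads_per_sample = 0)
    expr <- simulate_expression(simulate_genome(cfg), cfg)
    truth <- expr$truth$genes
    up <- truth$gene_id[truth$is_deg & truth$direction == "up"]
    gm <- expr$molar
    gene_molar <- rowsum(gm, expr$isoforms$gene_id)
    tcols <- expr$design$condition == "tumor"
    lr <- log2(rowMeans(gene_molar[up, tcols, drop = FALSE]) /
                 rowMeans(gene_molar[up, !tcols, drop = FALSE]))
    ratios <- c(ratios, lr)
  }
  expect_equal(mean(ratios), 2, tolerance = 0.1)  # 2^2 = 4-fold
})

test_that("pattern-3 genes have exons with opposite expected shifts", {
  cfg <- small_config(seed = 15)
  expr <- simulate_expression(simulate_genome(cfg), cfg)
  p3 <- expr$truth$genes$gene_id[expr$truth$genes$role == "pattern3"]
  ex <- expr$truth$exons
  for (g in p3) {
    e <- ex[ex$gene_id == g & ex$is_dee, ]
    expect_true(any(e$direction == "up") && any(e$direction == "down"))
  }
  # pattern-2 genes shift in a single direction
  p2 <- expr$truth$genes$gene_id[expr$truth$genes$role == "pattern2"]
  for (g in p2) {
    e <- ex[ex$gene_id == g & ex$is_dee, ]
    expect_gt(nrow(e), 0)
    expect_length(unique(e$direction), 1)
  }
})

test_that("with zero error rate every read is an exact transcript substring", {
  cfg <- small_config(seed = 16, error_rate = 0, reads_per_sample = 200)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim, cfg)
  reads <- simulate_reads(sim, expr, sample_ids = "P01_N")[[1]]
  seqs <- c(transcript_sequences(sim$annotation),
            setNames(sim$novel_isoforms$seq,
                     sim$novel_isoforms$transcript_id))
  meta <- strsplit(names(reads), ":", fixed = TRUE)
  for (i in seq_along(reads)) {
    tx <- meta[[i]][2]
    pos <- as.integer(meta[[i]][3])
    expect_identical(reads[[i]], substr(seqs[[tx]], pos + 1, pos + 36))
  }
  # FASTQ round-trip preserves names and sequences
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(unname(back), unname(reads))
})

test_that("tumour samples of skip genes produce junction-spanning reads", {
  cfg <- small_config(seed = 17, reads_per_sample = 20000)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim, cfg)
  jx <- expr$truth$junctions
  reads <- simulate_reads(sim, expr, sample_ids = "P01_T")[[1]]
  src_tx <- vapply(strsplit(names(reads), ":", fixed = TRUE), `[`, "", 2)
  pos <- as.integer(vapply(strsplit(names(reads), ":", fixed = TRUE),
                           `[`, "", 3))
  for (i in seq_len(nrow(jx))) {
    tx <- jx$novel_tx[i]
    # junction point in skip-isoform coordinates = summed length of
    # retained exons upstream of the acceptor
    ids <- sim$novel_isoforms$exon_ids[[
      match(tx, sim$novel_isoforms$transcript_id)]]
    ex <- sim$annotation$exons
    upstream <- ids[seq_len(match(jx$acceptor_exon[i], ids) - 1)]
    jp <- sum(ex$length[match(upstream, ex$exon_id)])
    spanning <- src_tx == tx & pos <= jp - 8 & pos + 36 >= jp + 8
    expect_gt(sum(spanning), 0)
  }
})
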