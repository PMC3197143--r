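# Multiread counting rules, RPKM/TPM arithmetic, saturation sampling.

hits_tbl <- function(read_id, ref, offset = 0L) {
  tibble::tibble(read_id = read_id, ref = ref, offset = offset,
                 strand = "+", mismatches = 0L)
}

test_that("multireads go to the transcript with the most unique reads; ties break lexicographically", {
  tx2gene <- tibble::tibble(transcript_id = c("T1", "T2", "Ta", "Tb"),
                            gene_id = c("g1", "g2", "g3", "g3"))
  # 10 unique reads on T1, 3 on T2, one multiread hitting both
  h <- dplyr::bind_rows(
    hits_tbl(sprintf("u%d", 1:10), "T1"),
    hits_tbl(sprintf("v%d", 1:3), "T2"),
    hits_tbl("m1", "T1"), hits_tbl("m1", "T2"))
  res <- assign_reads_gene_level(h, tx2gene)
  tc <- setNames(res$transcript_counts$count, res$transcript_counts$transcript_id)
  expect_equal(tc[["T1"]], 11L)
  expect_equal(tc[["T2"]], 3L)
  expect_equal(res$n_assigned, 14L)
  # tie 5 vs 5 between Ta and Tb -> Ta
  h2 <- dplyr::bind_rows(
    hits_tbl(sprintf("a%d", 1:5), "Ta"), hits_tbl(sprintf("b%d", 1:5), "Tb"),
    hits_tbl("mm", "Ta"), hits_tbl("mm", "Tb"))
  res2 <- assign_reads_gene_level(h2, tx2gene)
  tc2 <- setNames(res2$transcript_counts$count, res2$transcript_counts$transcript_id)
  expect_equal(tc2[["Ta"]], 6L)
  # conservation: gene counts sum to aligned reads
  expect_equal(sum(res2$gene_counts$count), 11L)
})

test_that("exon-level fan-out counts every overlapped exon, discards >30-hit reads, and credits junction exons", {
  ann <- four_exon_annotation()
  # one read inside E1 and one multiread hitting E1 and E3 loci
  gh <- dplyr::bind_rows(
    hits_tbl("r1", "chrT", 110L),
    hits_tbl("r2", "chrT", 110L), hits_tbl("r2", "chrT", 510L))
  ec <- assign_reads_exon_level(gh, hits_tbl(character(0), character(0)),
                                ann, build_known_junctions(ann))
  counts <- setNames(ec$count, ec$exon_id)
  expect_equal(counts[["GX.E1"]], 2L)
  expect_equal(counts[["GX.E3"]], 1L)

  # a read with 31 alignment hits contributes nothing
  gh31 <- hits_tbl(rep("rep", 31), "chrT", as.integer(seq(100, 700, 20)))
  ec31 <- assign_reads_exon_level(gh31, hits_tbl(character(0), character(0)),
                                  ann, build_known_junctions(ann))
  expect_equal(sum(ec31$count), 0L)
  gh30 <- hits_tbl(rep("rep", 30), "chrT", as.integer(seq(100, 680, 20)))
  expect_gt(sum(assign_reads_exon_level(
    gh30, hits_tbl(character(0), character(0)), ann,
    build_known_junctions(ann))$count), 0L)

  # a junction read adds one to donor and acceptor exon
  known <- build_known_junctions(ann)
  j <- known$junction_id[known$donor_exon == "GX.E1"]
  jc <- assign_reads_exon_level(
    hits_tbl(character(0), character(0)), hits_tbl("jr", j, 10L), ann, known)
  jcounts <- setNames(jc$count, jc$exon_id)
  expect_equal(jcounts[["GX.E1"]], 1L)
  expect_equal(jcounts[["GX.E2"]], 1L)
})

test_that("RPKM and TPM arithmetic and scale invariance", {
  counts <- tibble::tibble(feature_id = "f", s1 = 100)
  expect_equal(
    compute_rpkm(counts, c(f = 2000), c(s1 = 1e7))$s1, 5.0)
  expect_equal(compute_rpkm(tibble::tibble(feature_id = "f", s1 = 0),
                            c(f = 500), c(s1 = 1e6))$s1, 0)
  expect_equal(compute_tpm(tibble::tibble(feature_id = "f", s1 = 5),
                           c(s1 = 1e6))$s1, 5.0)
  expect_equal(compute_tpm(tibble::tibble(feature_id = "f", s1 = 21),
                           c(s1 = 3e6))$s1, 7.0)
  # doubling counts and totals changes nothing
  expect_equal(
    compute_rpkm(tibble::tibble(feature_id = "f", s1 = 200),
                 c(f = 2000), c(s1 = 2e7))$s1, 5.0)
  expect_error(compute_rpkm(counts, c(f = 2000), c(s1 = 0)), "zero total")
})

test_that("gene RPKM uses the per-sample major transcript length", {
  ann <- toy_annotation()
  # G1: T1 (198 nt) dominant in s1, T2 (135 nt) dominant in s2
  tx_counts <- tibble::tibble(
    transcript_id = c("G1.T1", "G1.T2", "G1.T3", "G2.T1"),
    s1 = c(90, 5, 5, 0), s2 = c(5, 90, 5, 0))
  gene_counts <- tibble::tibble(gene_id = c("G1", "G2"),
                                s1 = c(100, 0), s2 = c(100, 0))
  totals <- c(s1 = 1e6, s2 = 1e6)
  rpkm <- compute_gene_rpkm(gene_counts, tx_counts, ann, totals)
  expect_equal(rpkm$s1[1], 100 * 1e9 / (198 * 1e6))
  expect_equal(rpkm$s2[1], 100 * 1e9 / (135 * 1e6))
  # union mode uses summed exon length
  rpkm_u <- compute_gene_rpkm(gene_counts, tx_counts, ann, totals,
                              method = "union")
  expect_equal(rpkm_u$s1[1], 100 * 1e9 / (198 * 1e6))  # exons sum to 198
})

test_that("saturation curve is monotone in expectation and exact at the extremes", {
  withr::with_seed(3, {
    pool <- 5000
    # 60 genes with geometric-ish read counts; 1500 reads unmapped
    genes <- sprintf("g%02d", 1:60)
    m <- pmax(1, stats::rpois(60, exp(seq(log(1), log(300), length.out = 60))))
    reads <- rep(genes, m)[1:3500]
    rg <- tibble::tibble(read = seq_along(reads), gene_id = reads)
    bins <- c(0, 500, 1000, 2000, 3500, 5000)
    curve <- saturation_curve(rg, pool, bins, n_replicates = 4, seed = 9)
    means <- curve |> dplyr::distinct(bin, mean_detected) |>
      dplyr::arrange(bin)
    expect_equal(means$mean_detected[1], 0)
    expect_true(all(diff(means$mean_detected) >= 0))
    # full pool: every gene with >= 1 mapped read, no sampling variance
    full <- curve |> dplyr::filter(bin == 5000)
    expect_true(all(full$genes_detected == length(unique(reads))))
    # occupancy expectation matches Monte-Carlo within tolerance
    exp_tbl <- saturation_expected(rg, pool, bins)
    cmp <- means |> dplyr::inner_join(exp_tbl, by = "bin")
    expect_true(all(abs(cmp$mean_detected - cmp$expected_detected) <= 3))
    expect_error(saturation_curve(rg, pool, 6000), "exceeds")
  })
})
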