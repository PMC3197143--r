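# Known/novel junction database construction and the overhang rule.


test_that("known junctions: one per adjacent pair, deduplicated, 28-nt flanks", {
  ann <- toy_annotation()  # G1 chain E1-E2-E3 shared by 3 transcripts; G2 2 exons
  known <- build_known_junctions(ann, read_length = 36, min_overhang = 8)
  g1 <- known[known$gene_id == "G1", ]
  expect_equal(nrow(g1), 2L)  # E1-E2, E2-E3 despite 3 transcripts
  expect_equal(nrow(known[known$gene_id == "G2", ]), 1L)
  expect_true(all(known$left_flank == 28 & known$right_flank == 28))
  expect_true(all(nchar(known$seq) == 56))
})

test_that("junction sequence equals donor 3' flank plus acceptor 5' flank", {
  ann <- toy_annotation()
  known <- build_known_junctions(ann)
  g <- as.character(ann$genome[["chrT"]])
  j12 <- known[known$donor_exon == "G1.E1" & known$acceptor_exon == "G1.E2", ]
  expect_equal(j12$seq, paste0(substr(g, 133, 160), substr(g, 201, 228)))
  # minus-strand gene: flanks in transcript orientation
  j <- known[known$gene_id == "G2", ]
  expect_equal(j$donor_exon, "G2.E2")  # transcription starts downstream
  expect_equal(j$seq,
               paste0(revcomp(substr(g, 601, 628)),
                      revcomp(substr(g, 533, 560))))
})

test_that("novel candidates are in-phase ordered pairs minus known junctions", {
  ann <- four_exon_annotation()  # all phases 0 -> every ordered pair in phase
  known <- build_known_junctions(ann)
  novel <- build_novel_junctions(ann, known)
  got <- sort(paste(novel$donor_exon, novel$acceptor_exon))
  expect_equal(got, sort(c("GX.E1 GX.E3", "GX.E1 GX.E4", "GX.E2 GX.E4")))
  expect_true(all(novel$donor_end_phase == novel$acceptor_start_phase))
})

test_that("a two-exon gene yields no novel candidates", {
  ann <- toy_annotation()
  known <- build_known_junctions(ann)
  novel <- build_novel_junctions(ann, known)
  expect_equal(nrow(novel[novel$gene_id == "G2", ]), 0L)
})

test_that("phase filter agrees with brute-force pair enumeration", {
  sim <- simulate_genome(small_config())
  ann <- sim$annotation
  known <- build_known_junctions(ann)
  novel <- build_novel_junctions(ann, known)
  known_keys <- paste(known$donor_exon, known$acceptor_exon)
  expected <- list()
  for (g in ann$genes$gene_id) {
    ex <- splicepatterns:::gene_exon_order(ann, g)
    ex <- ex[ex$coding & !is.na(ex$start_phase) & !is.na(ex$end_phase), ]
    n <- nrow(ex)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ex$end_phase[i] == ex$start_phase[j] &&
          !paste(ex$exon_id[i], ex$exon_id[j]) %in% known_keys)
        expected[[length(expected) + 1]] <-
          paste(ex$exon_id[i], ex$exon_id[j])
    }
  }
  expect_setequal(paste(novel$donor_exon, novel$acceptor_exon),
                  unlist(expected))
  # set-disjointness with the known junctions
  expect_length(intersect(paste(novel$donor_exon, novel$acceptor_exon),
                          known_keys), 0)
})

test_that("every planted frame-preserving skip appears in the novel database", {
  sim <- simulate_genome(small_config())
  expr <- simulate_expression(sim)
  known <- build_known_junctions(sim$annotation)
  novel <- build_novel_junctions(sim$annotation, known)
  jx <- expr$truth$junctions
  expect_gt(nrow(jx), 0)
  expect_true(all(paste(jx$donor_exon, jx$acceptor_exon) %in%
                    paste(novel$donor_exon, novel$acceptor_exon)))
})

test_that("the 8-base overhang rule counts boundary hits and rejects 7-nt overhangs", {
  jdb <- tibble::tibble(
    junction_id = "J1", gene_id = "G", donor_exon = "a",
    acceptor_exon = "b", donor_end_phase = 0L, acceptor_start_phase = 0L,
    left_flank = 28L, right_flank = 28L, seq = strrep("A", 56),
    status = "novel")
  hit <- function(offset) tibble::tibble(
    read_id = paste0("r", offset), ref = "J1", offset = offset,
    strand = "+", mismatches = 0L)
  # offset 20: left overhang 8, right 28 -> counted (8 is inclusive)
  expect_equal(detect_junction_reads(hit(20), jdb)$count, 1L)
  # offset 0: left 28, right 8 -> counted
  expect_equal(detect_junction_reads(hit(0), jdb)$count, 1L)
  # offset 21 would leave a 7-nt left overhang -> rejected
  expect_equal(detect_junction_reads(hit(21), jdb)$count, 0L)
  # exhaustive: exactly 21 valid start offsets for 36-nt reads on 28+28
  valid <- vapply(0:20, function(o)
    detect_junction_reads(hit(o), jdb)$count, 1L)
  expect_equal(sum(valid), 21L)
})
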