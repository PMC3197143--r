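# Counting and normalization: multiread-aware gene/transcript counting,
# exon-level fan-out counting, RPKM/TPM, and saturation analysis.

#' Assign transcriptome hits to transcripts and genes
#'
#' Two-pass multiread resolution: pass 1 counts uniquely mapping reads
#' per transcript; pass 2 assigns each multiread to the hit transcript
#' with the highest pass-1 count, under the assumption that a read more
#' likely originates from the more abundant transcript. Ties break to the
#' lexicographically smallest transcript id, so the assignment is
#' deterministic. Every aligned read contributes exactly once; gene
#' counts are sums over their transcripts.
#'
#' @param hits Hit tibble from [align_reads()] against transcript
#'   references (`ref` = transcript id).
#' @param tx2gene Tibble with columns `transcript_id`, `gene_id`.
#' @return List with `transcript_counts` (tibble `transcript_id`,
#'   `count`), `gene_counts` (tibble `gene_id`, `count`) and `n_assigned`
#'   (number of reads assigned, equal to the number of aligned reads).
#' @export
assign_reads_gene_level <- function(hits, tx2gene) {
  h <- hits |> distinct(.data$read_id, .data$ref)
  n_hits <- h |> count(.data$read_id, name = "n_refs")
  h <- h |> inner_join(n_hits, by = "read_id")

  unique_counts <- h |>
    filter(.data$n_refs == 1) |>
    count(.data$ref, name = "unique_count")

  # pick, per read, the hit transcript with the highest unique count
  # (ties to the lexicographically smallest id): sort once, keep firsts
  assigned <- h |>
    left_join(unique_counts, by = "ref") |>
    mutate(unique_count = ifelse(is.na(.data$unique_count), 0L,
                                 .data$unique_count)) |>
    arrange(.data$read_id, desc(.data$unique_count), .data$ref)
  assigned <- assigned[!duplicated(assigned$read_id), ]

  tx_counts <- assigned |> count(.data$ref, name = "count") |>
    rename(transcript_id = "ref")
  gene_counts <- tx_counts |>
    inner_join(tx2gene, by = "transcript_id") |>
    group_by(.data$gene_id) |>
    summarise(count = sum(.data$count), .groups = "drop")
  list(transcript_counts = tx_counts, gene_counts = gene_counts,
       n_assigned = nrow(assigned))
}

#' Count reads per exon from genome and junction hits
#'
#' A genome-stage read adds one count to every exon it overlaps (any
#' overlap of at least 1 nt), provided its total number of alignment
#' hits is at most `max_hits` (default 30); reads with more hits are
#' discarded entirely, which keeps gene-family multireads while dropping
#' highly repetitive reads. A junction-stage read adds one count to both
#' the donor and the acceptor exon of each junction it spans.
#'
#' @param genome_hits Hits against the genome (`ref` = chromosome,
#'   forward-strand offsets).
#' @param junction_hits Hits against junction references (`ref` =
#'   junction id); may be a tibble combining known and novel stages.
#' @param annotation A `genome_annotation`.
#' @param junctions A `junction_db` covering the junction ids seen in
#'   `junction_hits`.
#' @param read_length Read length in nt.
#' @param max_hits Multiread discard ceiling (reads with more alignment
#'   hits than this contribute nothing).
#' @return Tibble `exon_id`, `count` over all annotated exons.
#' @export
assign_reads_exon_level <- function(genome_hits, junction_hits, annotation,
                                    junctions, read_length = 36,
                                    max_hits = 30) {
  exon_counts <- tibble(exon_id = annotation$exons$exon_id, count = 0L)

  if (nrow(genome_hits) > 0) {
    gh <- genome_hits |>
      distinct(.data$read_id, .data$ref, .data$offset, .data$strand)
    keep_reads <- gh |> count(.data$read_id) |>
      filter(.data$n <= max_hits) |> pull(.data$read_id)
    gh <- gh |> filter(.data$read_id %in% keep_reads)
    if (nrow(gh) > 0) {
      reads_gr <- GenomicRanges::GRanges(
        seqnames = gh$ref,
        ranges = IRanges::IRanges(start = gh$offset + 1L,
                                  width = read_length))
      exons_gr <- GenomicRanges::GRanges(
        seqnames = annotation$exons$chrom,
        ranges = IRanges::IRanges(start = annotation$exons$start + 1L,
                                  end = annotation$exons$end))
      ov <- GenomicRanges::findOverlaps(reads_gr, exons_gr,
                                        ignore.strand = TRUE)
      if (length(ov) > 0) {
        genome_adds <- tibble(
          read_id = gh$read_id[S4Vectors::queryHits(ov)],
          exon_id = annotation$exons$exon_id[S4Vectors::subjectHits(ov)]) |>
          distinct() |>
          count(.data$exon_id, name = "add")
        exon_counts <- exon_counts |>
          left_join(genome_adds, by = "exon_id") |>
          mutate(count = .data$count +
                   ifelse(is.na(.data$add), 0L, .data$add)) |>
          select(-"add")
      }
    }
  }

  if (nrow(junction_hits) > 0) {
    j_adds <- junction_hits |>
      distinct(.data$read_id, .data$ref) |>
      inner_join(junctions |>
                   select("junction_id", "donor_exon", "acceptor_exon"),
                 by = c(ref = "junction_id")) |>
      tidyr::pivot_longer(c("donor_exon", "acceptor_exon"),
                          values_to = "exon_id") |>
      count(.data$exon_id, name = "add")
    exon_counts <- exon_counts |>
      left_join(j_adds, by = "exon_id") |>
      mutate(count = .data$count +
               ifelse(is.na(.data$add), 0L, .data$add)) |>
      select(-"add")
  }
  exon_counts
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (length_nt * total_mapped)`. Doubling all counts
#' and totals leaves the value unchanged.
#'
#' @param counts Tibble with a feature id column followed by one numeric
#'   column per sample.
#' @param lengths Named numeric vector of feature lengths in nt (named by
#'   feature id), or a tibble `feature_id`, `length`.
#' @param totals Named numeric vector of total mapped reads per sample;
#'   default the column sums of `counts`.
#' @return Tibble of the same shape with RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, totals = NULL) {
  id_col <- names(counts)[1]
  samples <- names(counts)[-1]
  if (is.data.frame(lengths))
    lengths <- setNames(lengths[[2]], lengths[[1]])
  len <- unname(lengths[counts[[id_col]]])
  assert_that(all(!is.na(len)) && all(len > 0),
              "every feature needs a positive length")
  if (is.null(totals))
    totals <- vapply(counts[samples], sum, 0)
  assert_that(all(totals[samples] > 0),
              "zero total mapped reads in at least one sample")
  out <- counts
  for (s in samples)
    out[[s]] <- counts[[s]] * 1e9 / (len * totals[[s]])
  out
}

#' Tags per million mapped reads
#'
#' `TPM = count * 1e6 / total_mapped` (the classical tag-count scaling
#' used for junction evidence; not the modern transcripts-per-million).
#'
#' @inheritParams compute_rpkm
#' @param totals Named numeric vector of total mapped reads per sample.
#' @return Tibble of the same shape with TPM values.
#' @export
compute_tpm <- function(counts, totals) {
  id_col <- names(counts)[1]
  samples <- names(counts)[-1]
  assert_that(all(totals[samples] > 0),
              "zero total mapped reads in at least one sample")
  out <- counts
  for (s in samples)
    out[[s]] <- counts[[s]] * 1e6 / totals[[s]]
  out
}

#' Per-sample gene lengths and gene RPKM via the major transcript
#'
#' The gene count is divided by a transcript length; by default the
#' length of the gene's most abundant ("major") transcript in that
#' sample, consistent with the assign-to-most-abundant multiread rule.
#' Alternatively `method = "union"` uses the union-exon length.
#'
#' @param gene_counts Tibble `gene_id` + per-sample counts.
#' @param tx_counts Tibble `transcript_id` + per-sample counts.
#' @param annotation A `genome_annotation`.
#' @param totals Named numeric vector of per-sample total mapped reads.
#' @param method `"major"` (default) or `"union"`.
#' @return Tibble `gene_id` + per-sample RPKM.
#' @export
compute_gene_rpkm <- function(gene_counts, tx_counts, annotation, totals,
                              method = c("major", "union")) {
  method <- match.arg(method)
  samples <- names(gene_counts)[-1]
  tx_meta <- annotation$transcripts |>
    select("transcript_id", "gene_id", "length")
  out <- gene_counts
  if (method == "union") {
    ulen <- annotation$exons |>
      group_by(.data$gene_id) |>
      summarise(length = sum(.data$length), .groups = "drop")
    len <- unname(setNames(ulen$length, ulen$gene_id)[gene_counts$gene_id])
    for (s in samples)
      out[[s]] <- gene_counts[[s]] * 1e9 / (len * totals[[s]])
    return(out)
  }
  tx_long <- tx_counts |>
    tidyr::pivot_longer(-"transcript_id", names_to = "sample",
                        values_to = "count") |>
    inner_join(tx_meta, by = "transcript_id")
  major <- tx_long |>
    group_by(.data$gene_id, .data$sample) |>
    arrange(desc(.data$count), .data$transcript_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("gene_id", "sample", major_length = "length")
  fallback <- tx_meta |>
    group_by(.data$gene_id) |>
    summarise(fallback_length = max(.data$length), .groups = "drop")
  for (s in samples) {
    m <- major |> filter(.data$sample == s)
    len <- unname(setNames(m$major_length, m$gene_id)[gene_counts$gene_id])
    fb <- unname(setNames(fallback$fallback_length,
                          fallback$gene_id)[gene_counts$gene_id])
    len <- ifelse(is.na(len), fb, len)
    out[[s]] <- gene_counts[[s]] * 1e9 / (len * totals[[s]])
  }
  out
}

#' Sequencing-depth saturation analysis
#'
#' Randomly subsamples the raw read pool at increasing bin sizes and
#' reports how many genes are detected (at least one mapped read) per
#' bin, averaged over replicates. Sampling is over raw reads -- unaligned
#' reads occupy their share of each bin. Because whether a read maps to
#' a gene does not depend on the other reads sampled, the pool is
#' aligned once and bins are drawn over read indices; this is exactly
#' equivalent to aligning each bin separately.
#'
#' @param read_genes Tibble `read` (integer index into the raw pool,
#'   `1..pool_size`), `gene_id`: one row per (mapped read, gene) pair.
#' @param pool_size Total number of raw reads in the pool (mapped or
#'   not).
#' @param bins Integer vector of bin sizes; all must be `<= pool_size`.
#' @param n_replicates Random draws per bin (default 3).
#' @param seed Seed; replicate r uses `seed + r`.
#' @return Tibble `bin`, `replicate`, `genes_detected`, plus the
#'   replicate mean per bin in `mean_detected`.
#' @export
saturation_curve <- function(read_genes, pool_size, bins,
                             n_replicates = 3, seed = 1) {
  assert_that(all(bins <= pool_size), "bin size exceeds the read pool")
  assert_that(all(bins >= 0), "bin sizes must be non-negative")
  gene_of <- split(read_genes$gene_id, read_genes$read)
  read_idx <- as.integer(names(gene_of))
  res <- purrr::map(seq_len(n_replicates), function(r) {
    withr::with_seed(seed + r, {
      purrr::map(bins, function(b) {
        if (b == 0)
          return(tibble(bin = 0L, replicate = r, genes_detected = 0L))
        picked <- sample.int(pool_size, b)
        hit <- read_idx %in% picked
        tibble(bin = as.integer(b), replicate = r,
               genes_detected = length(unique(unlist(
                 gene_of[hit], use.names = FALSE))))
      }) |> bind_rows()
    })
  }) |> bind_rows()
  res |>
    group_by(.data$bin) |>
    mutate(mean_detected = mean(.data$genes_detected)) |>
    ungroup()
}

#' Expected gene detection under random subsampling
#'
#' Occupancy expectation `sum_g(1 - (1 - p_g)^n)` where `p_g` is gene
#' g's share of the raw read pool; used as the analytic reference for
#' the saturation curve.
#'
#' @inheritParams saturation_curve
#' @return Tibble `bin`, `expected_detected`.
#' @export
saturation_expected <- function(read_genes, pool_size, bins) {
  m <- read_genes |> distinct(.data$read, .data$gene_id) |>
    count(.data$gene_id)
  p <- m$n / pool_size
  tibble(bin = as.integer(bins),
         expected_detected = vapply(bins, function(n)
           sum(1 - (1 - p)^n), 0))
}
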