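# Genome annotation model: genes -> transcripts -> exons, with per-exon
# coding phases and coordinate-correct sequence extraction.
#
# Internal coordinates are 0-based half-open everywhere; GTF (1-based
# inclusive) is converted at the file boundary.

new_annotation <- function(genes, transcripts, exons, exon_tx, genome) {
  structure(
    list(genes = genes, transcripts = transcripts, exons = exons,
         exon_tx = exon_tx, genome = genome),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %d genes, %d transcripts, %d exons on %d sequence(s)\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), length(x$genome)))
  invisible(x)
}

#' Compute coding-exon phases along a transcript
#'
#' The phase of an exon boundary is the position within a codon at which
#' the boundary falls: phase 0 when the boundary coincides with a codon
#' boundary, phase 1 when it falls between the first and second base of a
#' codon, phase 2 between the second and third. The first coding exon
#' starts at phase 0; each exon's end phase is the cumulative coding
#' length so far modulo 3, and the next coding exon starts at the previous
#' end phase.
#'
#' @param cds_lengths Integer vector of per-exon coding lengths in
#'   transcription order; entries of 0 (or `NA`) mark non-coding exons,
#'   which receive `NA` phases.
#' @return A tibble with columns `cds_length`, `start_phase`, `end_phase`,
#'   one row per input exon, and an attribute `frame_consistent` that is
#'   `FALSE` when the total coding length is not a multiple of 3 (such
#'   transcripts are excluded from phase-based junction pairing).
#' @examples
#' compute_exon_phases(c(50, 70))  # end phases 2, 0
#' @export
compute_exon_phases <- function(cds_lengths) {
  cds <- ifelse(is.na(cds_lengths), 0L, as.integer(cds_lengths))
  assert_that(all(cds >= 0L), "coding lengths must be non-negative")
  n <- length(cds)
  start_phase <- rep(NA_integer_, n)
  end_phase <- rep(NA_integer_, n)
  cum <- 0L
  for (i in seq_len(n)) {
    if (cds[i] > 0L) {
      start_phase[i] <- cum %% 3L
      cum <- cum + cds[i]
      end_phase[i] <- cum %% 3L
    }
  }
  out <- tibble(cds_length = cds, start_phase = start_phase,
                end_phase = end_phase)
  attr(out, "frame_consistent") <- (cum %% 3L) == 0L
  out
}

# Shared constructor used by both the GTF loader and the simulator, so a
# simulated annotation and its reloaded-from-disk counterpart are built
# through identical code.
#
# exon_tx: tibble(gene_id, transcript_id, chrom, start, end, strand,
#                 exon_rank, cds_len, exon_id [optional])
annotation_from_tables <- function(exon_tx, genome) {
  stopifnot(is(genome, "DNAStringSet"))
  if (nrow(exon_tx) == 0) {
    empty_ex <- tibble(exon_id = character(), gene_id = character(),
                       chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       length = integer(), coding = logical(),
                       start_phase = integer(), end_phase = integer())
    return(new_annotation(
      genes = tibble(gene_id = character(), chrom = character(),
                     strand = character(), start = integer(),
                     end = integer(), n_transcripts = integer()),
      transcripts = tibble(transcript_id = character(), gene_id = character(),
                           chrom = character(), strand = character(),
                           n_exons = integer(), length = integer(),
                           cds_length = integer(),
                           frame_consistent = logical()),
      exons = empty_ex,
      exon_tx = tibble(transcript_id = character(), exon_id = character(),
                       exon_rank = integer(), cds_len = integer()),
      genome = genome))
  }

  assert_that(all(exon_tx$start < exon_tx$end),
              "exon start must be strictly less than exon end")
  if (!"exon_id" %in% names(exon_tx)) exon_tx$exon_id <- NA_character_
  exon_tx <- exon_tx |>
    mutate(exon_id = ifelse(
      is.na(.data$exon_id) | .data$exon_id == "",
      sprintf("%s:%d-%d(%s)", .data$chrom, .data$start, .data$end,
              .data$strand),
      .data$exon_id))

  # per-transcript phases in transcription order
  phase_tbl <- exon_tx |>
    arrange(.data$transcript_id, .data$exon_rank) |>
    group_by(.data$transcript_id) |>
    group_modify(function(d, key) {
      ph <- compute_exon_phases(d$cds_len)
      d$start_phase <- ph$start_phase
      d$end_phase <- ph$end_phase
      d$frame_consistent <- attr(ph, "frame_consistent")
      d
    }) |>
    ungroup()

  transcripts <- phase_tbl |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1], n_exons = dplyr::n(),
      length = sum(.data$end - .data$start),
      cds_length = sum(ifelse(is.na(.data$cds_len), 0L, .data$cds_len)),
      frame_consistent = .data$frame_consistent[1],
      .groups = "drop")

  # deduplicate exons across transcripts by genomic identity; phases from
  # frame-consistent transcripts only, conflicting assignments become NA
  exon_phases <- phase_tbl |>
    filter(.data$frame_consistent, !is.na(.data$start_phase)) |>
    distinct(.data$exon_id, .data$start_phase, .data$end_phase) |>
    group_by(.data$exon_id) |>
    summarise(
      start_phase = if (dplyr::n() == 1) .data$start_phase[1] else NA_integer_,
      end_phase = if (dplyr::n() == 1) .data$end_phase[1] else NA_integer_,
      .groups = "drop")

  exons <- exon_tx |>
    distinct(.data$exon_id, .data$gene_id, .data$chrom, .data$start,
             .data$end, .data$strand, .keep_all = FALSE) |>
    distinct(.data$exon_id, .keep_all = TRUE) |>
    mutate(length = .data$end - .data$start,
           coding = .data$exon_id %in%
             exon_tx$exon_id[!is.na(exon_tx$cds_len) & exon_tx$cds_len > 0]) |>
    left_join(exon_phases, by = "exon_id") |>
    mutate(start_phase = ifelse(.data$coding, .data$start_phase, NA_integer_),
           end_phase = ifelse(.data$coding, .data$end_phase, NA_integer_))

  genes <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              n_transcripts = dplyr::n(), .groups = "drop") |>
    left_join(
      exon_tx |> group_by(.data$gene_id) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  .groups = "drop"),
      by = "gene_id") |>
    select("gene_id", "chrom", "strand", "start", "end", "n_transcripts")

  new_annotation(
    genes = genes, transcripts = transcripts, exons = exons,
    exon_tx = exon_tx |>
      arrange(.data$transcript_id, .data$exon_rank) |>
      select("transcript_id", "exon_id", "exon_rank", "cds_len"),
    genome = genome)
}

#' Load a genome annotation from GTF and FASTA
#'
#' Parses exon and CDS features, cross-indexes genes, transcripts and
#' exons, converts GTF 1-based inclusive coordinates to internal 0-based
#' half-open coordinates, deduplicates exons shared across transcripts by
#' genomic identity, and computes per-exon coding phases.
#'
#' @param gtf Path to a GTF file whose records carry `gene_id` and
#'   `transcript_id` attributes and use `exon` / `CDS` feature types.
#' @param genome Path to the genome FASTA, or a
#'   [Biostrings::DNAStringSet]. Chromosome names must match the GTF.
#' @param quiet Suppress the parsed-counts message.
#' @return A `genome_annotation` object: a list of tibbles (`genes`,
#'   `transcripts`, `exons`, `exon_tx`) plus the genome sequences.
#' @details CDS records that fall outside their exon's bounds are rejected
#'   with a warning. A transcript with no exon records is an error.
#'   Transcripts whose total CDS length is not a multiple of 3 are flagged
#'   frame-inconsistent and never contribute to phase-based junction
#'   pairing.
#' @export
load_annotation <- function(gtf, genome, quiet = FALSE) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  empty_tbl <- tibble(gene_id = character(), transcript_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      exon_rank = integer(), cds_len = integer())
  if (is.character(gtf) && file.exists(gtf)) {
    content <- readLines(gtf, warn = FALSE)
    if (!any(nzchar(content) & !startsWith(content, "#")))
      return(annotation_from_tables(empty_tbl, genome))
  }
  gr <- rtracklayer::import(gtf, format = "gtf")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  tab <- tibble(
    type = as.character(meta$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(meta$gene_id),
    transcript_id = as.character(meta$transcript_id),
    exon_id = if ("exon_id" %in% names(meta))
      as.character(meta$exon_id) else NA_character_)

  exons <- tab |> filter(.data$type == "exon")
  cds <- tab |> filter(.data$type == "CDS")

  tx_with_cds_only <- setdiff(unique(cds$transcript_id),
                              unique(exons$transcript_id))
  if (length(tx_with_cds_only) > 0)
    abort(sprintf("transcript(s) with no exon records: %s",
                  paste(tx_with_cds_only, collapse = ", ")))
  if (nrow(exons) == 0)
    return(annotation_from_tables(empty_tbl, genome))

  # transcription order: ascending genomic for +, descending for -
  exons <- exons |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (.data$strand[1] == "-")
      rev(seq_len(dplyr::n())) else seq_len(dplyr::n())) |>
    ungroup()

  # attach coding length: CDS records contained in the exon interval
  cds_len <- rep(0L, nrow(exons))
  if (nrow(cds) > 0) {
    for (i in seq_len(nrow(cds))) {
      j <- which(exons$transcript_id == cds$transcript_id[i] &
                 exons$chrom == cds$chrom[i] &
                 exons$start <= cds$start[i] & exons$end >= cds$end[i])
      if (length(j) == 0) {
        warn(sprintf(
          "CDS record at %s:%d-%d (%s) outside exon bounds; rejected",
          cds$chrom[i], cds$start[i] + 1L, cds$end[i], cds$transcript_id[i]))
      } else {
        cds_len[j[1]] <- cds_len[j[1]] + (cds$end[i] - cds$start[i])
      }
    }
  }
  exons$cds_len <- cds_len

  ann <- annotation_from_tables(
    exons |> select("gene_id", "transcript_id", "chrom", "start", "end",
                    "strand", "exon_rank", "cds_len", "exon_id"),
    genome)
  if (!quiet)
    message(sprintf("parsed %d genes, %d transcripts, %d exons",
                    nrow(ann$genes), nrow(ann$transcripts), nrow(ann$exons)))
  ann
}

#' Extract a genomic subsequence
#'
#' @param genome A [Biostrings::DNAStringSet] or a `genome_annotation`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` returns the forward sequence, `"-"` its reverse
#'   complement.
#' @return A character scalar of length `end - start`.
#' @export
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (inherits(genome, "genome_annotation")) genome <- genome$genome
  assert_that(chrom %in% names(genome),
              sprintf("unknown sequence '%s'", chrom))
  len <- Biostrings::width(genome[chrom])
  assert_that(start >= 0 && end <= len && start <= end,
              sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                      start, end, chrom, len))
  if (start == end) return("")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Spliced transcript sequences
#'
#' Concatenates each transcript's exon sequences in transcription order
#' (reverse-complementing minus-strand transcripts).
#'
#' @param annotation A `genome_annotation`.
#' @param transcript_ids Transcripts to extract; default all.
#' @return Named character vector of cDNA sequences.
#' @export
transcript_sequences <- function(annotation, transcript_ids = NULL) {
  tx <- annotation$transcripts
  if (!is.null(transcript_ids)) tx <- tx |>
      filter(.data$transcript_id %in% transcript_ids)
  if (nrow(tx) == 0) return(setNames(character(0), character(0)))
  chrom_str <- as.character(annotation$genome)
  # exon sequences fetched in one vectorized pass, then spliced per
  # transcript in transcription order
  ex <- annotation$exon_tx |>
    filter(.data$transcript_id %in% tx$transcript_id) |>
    inner_join(annotation$exons |>
                 select("exon_id", "chrom", "start", "end", "strand"),
               by = "exon_id") |>
    arrange(.data$transcript_id, .data$exon_rank)
  seqs <- substr(chrom_str[ex$chrom], ex$start + 1L, ex$end)
  minus <- ex$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  spliced <- vapply(split(seqs, ex$transcript_id), paste, "",
                    collapse = "")
  setNames(spliced[tx$transcript_id], tx$transcript_id)
}

#' Write an annotation back to GTF
#'
#' Emits one `exon` record per transcript exon and one `CDS` record per
#' coding exon, converting internal 0-based half-open coordinates back to
#' GTF 1-based inclusive. Reloading the file reproduces the same internal
#' model.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  et <- annotation$exon_tx |>
    inner_join(annotation$exons |>
                 select("exon_id", "gene_id", "chrom", "start", "end",
                        "strand"),
               by = "exon_id")
  if (nrow(et) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  mk <- function(d, type, phase = NA_integer_) GenomicRanges::GRanges(
    seqnames = d$chrom,
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
    strand = d$strand, type = type, gene_id = d$gene_id,
    transcript_id = d$transcript_id, exon_id = d$exon_id,
    phase = phase)
  cds_rows <- et |>
    filter(!is.na(.data$cds_len), .data$cds_len > 0) |>
    inner_join(annotation$exons |>
                 select("exon_id", "start_phase"), by = "exon_id")
  # GTF frame: bases to skip from the CDS start to the first full codon
  frame <- (3L - cds_rows$start_phase) %% 3L
  frame[is.na(frame)] <- 0L
  gr <- c(mk(et, "exon"), mk(cds_rows, "CDS", frame))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' One-row summary of an annotation
#'
#' @param annotation A `genome_annotation`.
#' @return Tibble with gene/transcript/exon counts.
#' @export
annotation_summary <- function(annotation) {
  tibble(n_genes = nrow(annotation$genes),
         n_transcripts = nrow(annotation$transcripts),
         n_exons = nrow(annotation$exons))
}

# exons of one gene in transcription order (strand-aware genomic order)
gene_exon_order <- function(annotation, gene) {
  e <- annotation$exons |> filter(.data$gene_id == gene)
  if (nrow(e) == 0) return(e)
  if (e$strand[1] == "-") e |> arrange(desc(.data$start)) else
    e |> arrange(.data$start)
}
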