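# Exon-exon junction reference construction (known and phase-compatible
# novel candidates) and junction-spanning read detection.
#
# A junction sequence is the donor exon's 3' flank followed by the
# acceptor exon's 5' flank, both in transcript orientation. With flanks
# of read_length - min_overhang per side, every read satisfying the
# two-sided overhang rule aligns fully inside the junction sequence.

junction_flank <- function(read_length, min_overhang) {
  as.integer(read_length - min_overhang)
}

exon_flank_seqs <- function(annotation, exons) {
  # 3' and 5' flank extraction helpers in transcript orientation
  list(
    three_prime = function(exon_row, flank) {
      f <- min(flank, exon_row$length)
      if (exon_row$strand == "+")
        extract_sequence(annotation, exon_row$chrom, exon_row$end - f,
                         exon_row$end, "+")
      else
        extract_sequence(annotation, exon_row$chrom, exon_row$start,
                         exon_row$start + f, "-")
    },
    five_prime = function(exon_row, flank) {
      f <- min(flank, exon_row$length)
      if (exon_row$strand == "+")
        extract_sequence(annotation, exon_row$chrom, exon_row$start,
                         exon_row$start + f, "+")
      else
        extract_sequence(annotation, exon_row$chrom, exon_row$end - f,
                         exon_row$end, "-")
    })
}

build_junction_records <- function(annotation, pairs, status,
                                   read_length, min_overhang) {
  if (nrow(pairs) == 0) {
    return(tibble(junction_id = character(), gene_id = character(),
                  donor_exon = character(), acceptor_exon = character(),
                  donor_end_phase = integer(),
                  acceptor_start_phase = integer(),
                  left_flank = integer(), right_flank = integer(),
                  seq = character(), status = character()))
  }
  flank <- junction_flank(read_length, min_overhang)
  ex <- annotation$exons
  fl <- exon_flank_seqs(annotation, ex)
  rows <- purrr::pmap(pairs, function(gene_id, donor_exon, acceptor_exon,
                                      ...) {
    d <- ex[ex$exon_id == donor_exon, ]
    a <- ex[ex$exon_id == acceptor_exon, ]
    left <- fl$three_prime(d, flank)
    right <- fl$five_prime(a, flank)
    tibble(
      junction_id = sprintf("%s|%s|%s", gene_id, donor_exon, acceptor_exon),
      gene_id = gene_id, donor_exon = donor_exon,
      acceptor_exon = acceptor_exon,
      donor_end_phase = d$end_phase, acceptor_start_phase = a$start_phase,
      left_flank = nchar(left), right_flank = nchar(right),
      seq = paste0(left, right))
  })
  bind_rows(rows) |> mutate(status = status)
}

#' Build the known exon-exon junction database
#'
#' One record per adjacent exon pair in every transcript, deduplicated
#' across transcripts sharing the same exon chain. Flank length per side
#' is `read_length - min_overhang` (28 nt for 36-nt reads and the
#' 8-base overhang rule), truncated to the exon length when the exon is
#' shorter.
#'
#' @param annotation A `genome_annotation`.
#' @param read_length Read length in nt (default 36).
#' @param min_overhang Minimum junction overhang in nt (default 8).
#' @return A `junction_db` tibble: `junction_id`, `gene_id`,
#'   `donor_exon`, `acceptor_exon`, donor/acceptor phases, flank lengths,
#'   `seq`, `status = "known"`.
#' @export
build_known_junctions <- function(annotation, read_length = 36,
                                  min_overhang = 8) {
  et <- annotation$exon_tx |> arrange(.data$transcript_id, .data$exon_rank)
  pairs <- et |>
    group_by(.data$transcript_id) |>
    reframe(donor_exon = head(.data$exon_id, -1),
            acceptor_exon = .data$exon_id[-1]) |>
    inner_join(annotation$transcripts |>
                 select("transcript_id", "gene_id"),
               by = "transcript_id") |>
    distinct(.data$gene_id, .data$donor_exon, .data$acceptor_exon)
  out <- build_junction_records(annotation, pairs, "known",
                                read_length, min_overhang)
  class(out) <- c("junction_db", class(out))
  out
}

#' Build the phase-compatible novel junction candidate database
#'
#' Candidate junctions are ordered within-gene pairs of coding exons
#' (donor preceding acceptor in transcription order) whose reading-frame
#' phases are compatible -- the donor's end phase equals the acceptor's
#' start phase, so splicing them preserves the reading frame -- and that
#' are absent from the known junction set. Exons without a defined phase
#' (non-coding, phase-conflicted, or from frame-inconsistent transcripts)
#' never participate.
#'
#' @param annotation A `genome_annotation`.
#' @param known A `junction_db` from [build_known_junctions()].
#' @inheritParams build_known_junctions
#' @return A `junction_db` tibble with `status = "novel"`.
#' @export
build_novel_junctions <- function(annotation, known, read_length = 36,
                                  min_overhang = 8) {
  known_keys <- paste(known$donor_exon, known$acceptor_exon)
  pairs <- purrr::map(annotation$genes$gene_id, function(g) {
    ex <- gene_exon_order(annotation, g) |>
      filter(.data$coding, !is.na(.data$start_phase),
             !is.na(.data$end_phase))
    n <- nrow(ex)
    if (n < 2) return(NULL)
    grid <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n)) |>
      filter(.data$i < .data$j)
    tibble(gene_id = g,
           donor_exon = ex$exon_id[grid$i],
           acceptor_exon = ex$exon_id[grid$j],
           donor_end_phase = ex$end_phase[grid$i],
           acceptor_start_phase = ex$start_phase[grid$j])
  }) |> bind_rows()
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      filter(.data$donor_end_phase == .data$acceptor_start_phase,
             !paste(.data$donor_exon, .data$acceptor_exon) %in% known_keys) |>
      distinct(.data$gene_id, .data$donor_exon, .data$acceptor_exon)
  }
  out <- build_junction_records(annotation, pairs, "novel",
                                read_length, min_overhang)
  class(out) <- c("junction_db", class(out))
  out
}

#' Count junction-spanning reads with the two-sided overhang rule
#'
#' A hit on a junction sequence counts as evidence for the splicing event
#' only if the read covers at least `min_overhang` nt on both sides of
#' the junction point. Multiple hits of one read on the same junction
#' count once.
#'
#' @param hits Hit tibble from [align_reads()] whose `ref` values are
#'   junction ids.
#' @param junctions A `junction_db`.
#' @param read_length Read length in nt.
#' @param min_overhang Minimum overhang per side (8 is inclusive: an
#'   exactly-8-base overhang counts).
#' @return Tibble `junction_id`, `count` (junctions with zero spanning
#'   reads included).
#' @export
detect_junction_reads <- function(hits, junctions, read_length = 36,
                                  min_overhang = 8) {
  counted <- hits |>
    inner_join(junctions |> select("junction_id", "left_flank"),
               by = c(ref = "junction_id")) |>
    filter(.data$offset <= .data$left_flank - min_overhang,
           .data$offset + read_length >= .data$left_flank + min_overhang) |>
    distinct(.data$read_id, .data$ref) |>
    count(.data$ref, name = "count")
  junctions |>
    select("junction_id") |>
    left_join(counted, by = c(junction_id = "ref")) |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
}

#' Export junction references as FASTA and a coordinate table
#'
#' @param junctions A `junction_db`.
#' @param fasta Path for the junction FASTA.
#' @param tsv Optional path for a tab-separated junction table.
#' @return `fasta`, invisibly.
#' @export
write_junction_db <- function(junctions, fasta, tsv = NULL) {
  seqs <- Biostrings::DNAStringSet(setNames(junctions$seq,
                                            junctions$junction_id))
  Biostrings::writeXStringSet(seqs, fasta)
  if (!is.null(tsv))
    write.table(junctions |> select(-"seq"), tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

# named vector of junction sequences suitable for build_index()
junction_references <- function(junctions) {
  setNames(junctions$seq, junctions$junction_id)
}
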