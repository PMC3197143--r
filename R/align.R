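# Self-contained short-read aligner: report every placement of a read on
# a reference set with at most `max_mismatch` mismatches, via pigeonhole
# seeding (k = floor(L / (m + 1)) guarantees an exact seed segment).

#' Build a seed index over a reference set
#'
#' Indexes every k-mer occurrence of every reference sequence. With the
#' default seed length 12 and 36-nt reads, any alignment with at most 2
#' mismatches contains at least one exact 12-mer segment, so seed lookup
#' followed by full-length verification is complete.
#'
#' @param references Named character vector or [Biostrings::DNAStringSet]
#'   of reference sequences. Names must be unique.
#' @param k Seed length (default 12); must satisfy
#'   `k <= read_length / (max_mismatch + 1)` for the completeness
#'   guarantee.
#' @return A `seed_index` object.
#' @export
build_index <- function(references, k = 12) {
  if (is(references, "DNAStringSet")) {
    refs <- as.character(references)
    names(refs) <- names(references)
  } else refs <- references
  assert_that(length(refs) > 0, "reference set is empty")
  assert_that(!is.null(names(refs)) && all(nzchar(names(refs))),
              "references must be named")
  if (anyDuplicated(names(refs)))
    abort(sprintf("duplicate reference ids: %s",
                  paste(unique(names(refs)[duplicated(names(refs))]),
                        collapse = ", ")))
  ptr <- cpp_build_index(unname(refs), names(refs), as.integer(k))
  info <- cpp_index_info(ptr)
  structure(
    list(ptr = ptr, k = as.integer(k), ref_names = names(refs),
         ref_lengths = setNames(nchar(unname(refs)), names(refs)),
         n_positions = info$n_positions),
    class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %d reference(s), k = %d, %s indexed positions\n",
              length(x$ref_names), x$k, format(x$n_positions, big.mark = ",")))
  invisible(x)
}

#' Seed-table postings for one k-mer
#'
#' @param index A `seed_index`.
#' @param kmer A string of length `index$k`.
#' @return Tibble of (`ref`, `offset`) occurrences (0-based offsets).
#' @export
query_kmer <- function(index, kmer) {
  d <- cpp_query_kmer(index$ptr, kmer)
  tibble(ref = index$ref_names[d$ref], offset = d$offset)
}

#' Align reads against a seed index
#'
#' Returns exactly the set of (reference, offset) placements with Hamming
#' distance at most `max_mismatch` from each read; `N` bases match
#' nothing and always count as mismatches. Hits are ordered
#' deterministically by (read, reference id, offset). Reads carrying more
#' than `max_mismatch` ambiguous bases are discarded (they cannot satisfy
#' the mismatch bound meaningfully); reads shorter than the seed length
#' are skipped with a warning.
#'
#' @param reads Character vector of reads (named, or `read_ids` given).
#' @param index A `seed_index` from [build_index()].
#' @param max_mismatch Maximum Hamming distance (default 2).
#' @param both_strands Also align the reverse complement of each read;
#'   minus-strand hits are reported in forward reference coordinates with
#'   `strand == "-"`. Used for the genome stage of an unstranded
#'   protocol; transcript and junction references are sense-strand.
#' @param read_ids Read identifiers; defaults to `names(reads)` or
#'   `read_1..n`.
#' @return Tibble: `read_id`, `ref`, `offset` (0-based), `strand`,
#'   `mismatches`.
#' @export
align_reads <- function(reads, index, max_mismatch = 2,
                        both_strands = FALSE, read_ids = NULL) {
  read_ids <- read_ids %||% names(reads) %||%
    sprintf("read_%d", seq_along(reads))
  reads <- toupper(unname(reads))

  short <- nchar(reads) < index$k
  if (any(short)) {
    warn(sprintf("%d read(s) shorter than the seed length skipped",
                 sum(short)))
  }
  many_n <- cpp_count_n(reads) > max_mismatch
  keep <- !short & !many_n
  if (!any(keep)) {
    return(tibble(read_id = character(), ref = character(),
                  offset = integer(), strand = character(),
                  mismatches = integer()))
  }
  sub <- reads[keep]
  ids <- read_ids[keep]

  fw <- cpp_align(index$ptr, sub, as.integer(max_mismatch))
  out <- tibble(read_id = ids[fw$read], ref = index$ref_names[fw$ref],
                offset = fw$offset, strand = "+",
                mismatches = fw$mismatches)
  if (both_strands) {
    rv <- cpp_align(index$ptr, revcomp(sub), as.integer(max_mismatch))
    out <- bind_rows(out,
      tibble(read_id = ids[rv$read], ref = index$ref_names[rv$ref],
             offset = rv$offset, strand = "-",
             mismatches = rv$mismatches))
  }
  out |>
    arrange(match(.data$read_id, ids), .data$ref, .data$offset,
            .data$strand)
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read A single read sequence.
#' @return Tibble of hits as in [align_reads()].
#' @export
align_read <- function(read, index, max_mismatch = 2,
                       both_strands = FALSE) {
  align_reads(setNames(read, "read_1"), index,
              max_mismatch = max_mismatch, both_strands = both_strands)
}

#' Hierarchical alignment through ordered reference stages
#'
#' Each read is consumed by the first stage at which it has at least one
#' hit; only then-unaligned reads proceed to the next stage. Two standard
#' configurations exist: gene-level (transcriptome only) and exon-level
#' (genome, then known junctions, then novel junctions).
#'
#' @param reads Named character vector of reads.
#' @param stages Named list of stages, each a list with elements `index`
#'   (a `seed_index`) and optionally `both_strands` (default `FALSE`).
#' @param max_mismatch Maximum Hamming distance per alignment.
#' @return List with `hits` (named list of per-stage hit tibbles),
#'   `unaligned` (ids of reads unaligned after the last stage), and
#'   `tally` (tibble: stage, n_input, n_aligned, n_remaining).
#' @export
align_hierarchical <- function(reads, stages, max_mismatch = 2) {
  read_ids <- names(reads) %||% sprintf("read_%d", seq_along(reads))
  names(reads) <- read_ids
  remaining <- read_ids
  hits <- list()
  tally <- list()
  for (stage_name in names(stages)) {
    st <- stages[[stage_name]]
    h <- align_reads(reads[remaining], st$index,
                     max_mismatch = max_mismatch,
                     both_strands = isTRUE(st$both_strands))
    aligned_ids <- unique(h$read_id)
    tally[[stage_name]] <- tibble(
      stage = stage_name, n_input = length(remaining),
      n_aligned = length(aligned_ids),
      n_remaining = length(remaining) - length(aligned_ids))
    hits[[stage_name]] <- h
    remaining <- setdiff(remaining, aligned_ids)
  }
  list(hits = hits, unaligned = remaining, tally = bind_rows(tally))
}
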