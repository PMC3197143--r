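# Shared fixtures and independent oracles, built in code.

suppressPackageStartupMessages({
  library(dplyr)
})

# -- tiny hand-made annotation ------------------------------------------

# Two genes on one chromosome; G1 (+, 3 transcripts sharing exon chains)
# and G2 (-, 1 transcript). Coordinates are GTF-style 1-based inclusive
# in this table and written through a real GTF file.
toy_gtf_table <- function() {
  tribble(
    ~gene_id, ~transcript_id, ~start, ~end, ~strand, ~exon_id,
    "G1", "G1.T1", 101, 160, "+", "G1.E1",   # 60 nt
    "G1", "G1.T1", 201, 275, "+", "G1.E2",   # 75 nt
    "G1", "G1.T1", 351, 413, "+", "G1.E3",   # 63 nt
    "G1", "G1.T2", 101, 160, "+", "G1.E1",
    "G1", "G1.T2", 201, 275, "+", "G1.E2",
    "G1", "G1.T3", 101, 160, "+", "G1.E1",
    "G1", "G1.T3", 201, 275, "+", "G1.E2",
    "G1", "G1.T3", 351, 413, "+", "G1.E3",
    "G2", "G2.T1", 501, 560, "-", "G2.E1",   # 60 nt
    "G2", "G2.T1", 601, 660, "-", "G2.E2")   # 60 nt
}

write_toy_gtf <- function(path, cds = TRUE) {
  tab <- toy_gtf_table()
  lines <- c()
  for (i in seq_len(nrow(tab))) {
    attrs <- sprintf(
      'gene_id "%s"; transcript_id "%s"; exon_id "%s";',
      tab$gene_id[i], tab$transcript_id[i], tab$exon_id[i])
    lines <- c(lines, paste("chrT", "toy", "exon", tab$start[i],
                            tab$end[i], ".", tab$strand[i], ".", attrs,
                            sep = "\t"))
    if (cds)
      lines <- c(lines, paste("chrT", "toy", "CDS", tab$start[i],
                              tab$end[i], ".", tab$strand[i], "0", attrs,
                              sep = "\t"))
  }
  writeLines(lines, path)
  path
}

toy_genome <- function(len = 800, seed = 42) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(setNames(
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "chrT"))
  })
}

toy_annotation <- function(seed = 42) {
  gtf <- tempfile(fileext = ".gtf")
  write_toy_gtf(gtf)
  load_annotation(gtf, toy_genome(seed = seed), quiet = TRUE)
}

# 4 coding exons of 90 nt (all phases 0) on one plus-strand gene
four_exon_annotation <- function() {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c()
  for (i in 1:4) {
    s <- 100 + (i - 1) * 200
    attrs <- sprintf(
      'gene_id "GX"; transcript_id "GX.T1"; exon_id "GX.E%d";', i)
    lines <- c(lines,
      paste("chrT", "t", "exon", s, s + 89, ".", "+", ".", attrs, sep = "\t"),
      paste("chrT", "t", "CDS", s, s + 89, ".", "+", "0", attrs, sep = "\t"))
  }
  writeLines(lines, gtf)
  load_annotation(gtf, toy_genome(1200), quiet = TRUE)
}

# -- independent oracles -------------------------------------------------

# brute-force Hamming scan: every window of every reference, both the
# reference for the aligner completeness property
brute_force_hits <- function(read, refs, max_mm = 2) {
  L <- nchar(read)
  rcode <- utf8ToInt(read)
  out <- list()
  for (rn in names(refs)) {
    s <- refs[[rn]]
    n <- nchar(s)
    if (n < L) next
    scode <- utf8ToInt(s)
    n_win <- n - L + 1
    mm <- integer(n_win)
    acgt <- utf8ToInt("ACGT")
    for (j in seq_len(L)) {
      win <- scode[j:(j + n_win - 1)]
      mm <- mm + as.integer(win != rcode[j] |
                              !(rcode[j] %in% acgt) |
                              !(win %in% acgt))
    }
    keep <- which(mm <= max_mm)
    if (length(keep) > 0)
      out[[rn]] <- tibble(ref = rn, offset = keep - 1L,
                          mismatches = mm[keep])
  }
  if (length(out) == 0)
    return(tibble(ref = character(), offset = integer(),
                  mismatches = integer()))
  bind_rows(out)
}

# exact Wilcoxon signed-rank two-sided p by full 2^n enumeration
wilcoxon_enumeration <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(w = 0, p = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(w = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# random reads drawn from a reference with planted mismatches
mutate_read <- function(read, k) {
  if (k == 0) return(read)
  L <- nchar(read)
  pos <- sample.int(L, k)
  r <- strsplit(read, "")[[1]]
  for (p in pos) r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1)
  paste(r, collapse = "")
}

# small simulated cohort shared across tests (cheap, no reads)
small_config <- function(seed = 5, n_pairs = 6, reads_per_sample = 5000,
                         deg_fraction = 0.1, n_pattern1 = 3,
                         n_pattern2 = 3, n_pattern3 = 3, n_skip = 2,
                         ...) {
  sim_config(seed = seed, n_genes = 40, n_pairs = n_pairs,
             reads_per_sample = reads_per_sample,
             n_pattern1 = n_pattern1, n_pattern2 = n_pattern2,
             n_pattern3 = n_pattern3, n_skip = n_skip,
             deg_fraction = deg_fraction, ...)
}
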