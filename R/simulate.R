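# Synthetic cohort generator: a mini genome with phase-consistent coding
# annotation, paired tumour/normal expression with planted differential
# genes, isoform switches (pattern 2/3) and frame-preserving exon-skip
# events, and 36-nt single-end reads with substitution errors.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a matched-pair
#' cohort sequenced single-end at 36 nt, with log-normal baseline
#' expression, patient-level random effects shared within a pair, extra
#' tumour heterogeneity, and planted effects whose ground truth is
#' recorded alongside the data.
#'
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param n_pairs Number of matched tumour/normal pairs (default 10).
#' @param n_genes Number of genes (default 100).
#' @param exons_per_gene Range (min, max) of exons per gene; at least 5
#'   so pattern isoforms have interior exons to switch.
#' @param exon_length Range of exon lengths in nt. The minimum must be at
#'   least `read_length - min_overhang` so junction flanks are full.
#' @param intron_length Range of intron lengths in nt.
#' @param read_length Read length in nt (default 36).
#' @param reads_per_sample Reads simulated per sample (default 200,000).
#' @param error_rate Per-base substitution error rate (default 0.002).
#' @param baseline_log2_sd SD of per-gene baseline log2 expression.
#' @param patient_log2_sd SD of the per-gene patient random effect shared
#'   by the tumour and normal sample of a pair (induces pairing).
#' @param tumor_extra_log2_sd Extra per-gene log2 noise in tumour samples
#'   only, emulating the higher biological heterogeneity of tumours.
#' @param sample_log2_sd Per-gene per-sample log2 noise.
#' @param deg_fraction Fraction of genes planted as whole-gene DEGs.
#'   DEGs are drawn from genes with at-least-median baseline expression:
#'   a fold change planted on an effectively silent gene is not a
#'   recoverable signal at any realistic depth.
#' @param deg_log2fc Absolute planted log2 fold change for DEGs.
#' @param n_pattern1 Number of dedicated planted pattern-1 genes
#'   (whole-gene shift of `deg_log2fc`, planted at elevated baseline so
#'   exon-level recovery is well-powered, mirroring the well-expressed
#'   representative genes such analyses illustrate patterns with). These
#'   genes count as true DEGs as well.
#' @param n_pattern2,n_pattern3 Numbers of planted isoform-switch genes
#'   of pattern 2 (one exon shifts, one direction) and pattern 3 (two
#'   exons shift in opposite directions); planted at elevated baseline
#'   like pattern-1 genes.
#' @param n_skip Number of genes carrying an unannotated frame-preserving
#'   multi-exon skip isoform.
#' @param skip_n_exons Exon count of skip genes (default 10).
#' @param skip_span Transcription-order indices of the skipped exons
#'   (default 6:8, the archetypal exon 6-8 skip).
#' @param skip_inclusion_tumor,skip_inclusion_normal Molar fraction of
#'   the gene's expression carried by the skip isoform per condition.
#' @param skip_gene_share Target share of cohort expression mass per
#'   skip gene; skip genes are planted as highly expressed so that
#'   junction-spanning reads are essentially guaranteed in every sample
#'   at the configured depth.
#' @param pattern_gene_share Target share of cohort expression mass per
#'   planted pattern gene (pattern 1/2/3), giving per-exon counts that
#'   support exon-level testing.
#' @param pattern2_shares,pattern2_shares_tumor Molar shares of the
#'   (full, exon-skipping) isoform pair of pattern-2 genes, per condition.
#' @param pattern3_shares,pattern3_shares_tumor Molar shares of the two
#'   complementary isoforms of pattern-3 genes, per condition.
#' @param minus_strand_fraction Fraction of genes placed on the minus
#'   strand.
#' @param min_overhang Junction overhang used for flank feasibility.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1, n_pairs = 10, n_genes = 2000,
                       exons_per_gene = c(5, 10),
                       exon_length = c(90, 240),
                       intron_length = c(60, 120),
                       read_length = 36, reads_per_sample = 200000,
                       error_rate = 0.002,
                       baseline_log2_sd = 2, patient_log2_sd = 0.6,
                       tumor_extra_log2_sd = 0.3, sample_log2_sd = 0.25,
                       deg_fraction = 0.025, deg_log2fc = 2,
                       n_pattern1 = 8, n_pattern2 = 8, n_pattern3 = 8,
                       n_skip = 5,
                       skip_n_exons = 10, skip_span = 6:8,
                       skip_inclusion_tumor = 1.0,
                       skip_inclusion_normal = 0.0,
                       skip_gene_share = 0.01,
                       pattern_gene_share = 0.002,
                       pattern2_shares = c(0.5, 0.5),
                       pattern2_shares_tumor = c(0.1, 0.9),
                       pattern3_shares = c(0.2, 0.8),
                       pattern3_shares_tumor = c(0.9, 0.1),
                       minus_strand_fraction = 0.2,
                       min_overhang = 8) {
  cfg <- as.list(environment())
  assert_that(deg_fraction >= 0 && deg_fraction <= 1,
              "deg_fraction must lie in [0, 1]")
  assert_that(is.finite(deg_log2fc), "deg_log2fc must be finite")
  assert_that(all(c(skip_inclusion_tumor, skip_inclusion_normal) >= 0) &&
              all(c(skip_inclusion_tumor, skip_inclusion_normal) <= 1),
              "skip inclusion rates must lie in [0, 1]")
  if (n_genes > 0 && exon_length[1] < read_length - min_overhang)
    abort(sprintf(
      paste("infeasible config: minimum exon length %d is below the",
            "junction flank requirement read_length - min_overhang = %d"),
      exon_length[1], read_length - min_overhang))
  if ((cfg$n_pattern2 > 0 || cfg$n_pattern3 > 0) && exons_per_gene[1] < 5)
    abort("infeasible config: pattern genes need at least 5 exons per gene")
  if (n_skip > 0 && skip_n_exons <= max(skip_span))
    abort("infeasible config: skip_span must leave a downstream acceptor exon")
  total_planted <- n_pattern1 + n_pattern2 + n_pattern3 + n_skip +
    round(deg_fraction * n_genes)
  assert_that(n_genes == 0 || total_planted <= n_genes,
              "planted gene sets exceed n_genes")
  structure(cfg, class = "sim_config")
}

exon_name <- function(gene, rank) sprintf("%s.E%d", gene, rank)

#' Generate a mini genome and phase-consistent annotation
#'
#' Lays out `n_genes` multi-exon genes along one synthetic chromosome.
#' Every transcript is fully coding with total CDS length a multiple of
#' 3. Pattern-2 genes receive a second annotated isoform skipping one
#' interior exon; pattern-3 genes receive two complementary annotated
#' isoforms; skip genes carry an *unannotated* isoform lacking
#' `skip_span`, whose skipped block length is forced to a multiple of 3
#' so the donor's end phase equals the acceptor's start phase (the
#' frame-preserving condition).
#'
#' @param config A [sim_config()].
#' @return A `sim_genome` list: `annotation` (a `genome_annotation`),
#'   `roles` (per-gene planted role and the exons involved),
#'   `novel_isoforms` (the unannotated skip transcripts with sequences),
#'   and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(config$seed, 1), {
    n <- config$n_genes
    if (n == 0) {
      ann <- annotation_from_tables(
        tibble(gene_id = character(), transcript_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), exon_rank = integer(),
               cds_len = integer()),
        Biostrings::DNAStringSet())
      return(structure(list(annotation = ann,
                            roles = tibble(gene_id = character(),
                                           role = character()),
                            novel_isoforms = tibble(),
                            config = config),
                       class = "sim_genome"))
    }
    gene_ids <- sprintf("G%04d", seq_len(n))
    role_pool <- sample(gene_ids)
    take <- function(k) {
      out <- role_pool[seq_len(k)]
      role_pool <<- role_pool[-seq_len(k)]
      out
    }
    skip_genes <- if (config$n_skip > 0) take(config$n_skip) else character()
    p2_genes <- if (config$n_pattern2 > 0) take(config$n_pattern2) else character()
    p3_genes <- if (config$n_pattern3 > 0) take(config$n_pattern3) else character()
    p1_genes <- if (config$n_pattern1 > 0) take(config$n_pattern1) else character()

    chrom <- "chrS1"
    cursor <- 200L
    exon_rows <- list()
    role_rows <- list()
    novel_rows <- list()

    for (g in gene_ids) {
      role <- if (g %in% skip_genes) "skip"
        else if (g %in% p2_genes) "pattern2"
        else if (g %in% p3_genes) "pattern3"
        else if (g %in% p1_genes) "pattern1"
        else "null"
      n_ex <- if (role == "skip") config$skip_n_exons else
        sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1)
      lens <- sample(config$exon_length[1]:config$exon_length[2], n_ex,
                     replace = TRUE)
      strand <- sample(c("+", "-"), 1,
                       prob = c(1 - config$minus_strand_fraction,
                                config$minus_strand_fraction))
      # genomic blocks left to right; transcription ranks strand-aware
      ranks <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      if (role == "skip") {
        # skipped block length a multiple of 3 => donor end phase equals
        # acceptor start phase (indices are transcription-order ranks)
        sp_idx <- which(ranks %in% config$skip_span)
        fix <- sp_idx[1]
        lens[fix] <- lens[fix] + (3L - sum(lens[sp_idx]) %% 3L) %% 3L
      }
      # pattern isoforms skip single exons: pad those exons to a
      # multiple of 3 so the annotated switch isoforms preserve frame
      # and exon phases agree across a gene's isoforms
      pat_j <- ceiling(n_ex / 2)
      pat3_j <- max(2, floor(n_ex / 3))
      pat3_k <- min(n_ex - 1, max(pat3_j + 1, floor(2 * n_ex / 3)))
      pad3 <- function(r) {
        i <- which(ranks == r)
        lens[i] <<- lens[i] + (3L - lens[i] %% 3L) %% 3L
      }
      if (role == "pattern2") pad3(pat_j)
      if (role == "pattern3") { pad3(pat3_j); pad3(pat3_k) }
      # total CDS a multiple of 3, adjusted on the last transcribed exon
      last_idx <- which(ranks == n_ex)
      lens[last_idx] <- lens[last_idx] + (3L - sum(lens) %% 3L) %% 3L
      introns <- sample(config$intron_length[1]:config$intron_length[2],
                        max(n_ex - 1, 1), replace = TRUE)

      starts <- integer(n_ex)
      pos <- cursor
      for (i in seq_len(n_ex)) {
        starts[i] <- pos
        pos <- pos + lens[i] + if (i < n_ex) introns[i] else 0L
      }
      cursor <- pos + 150L
      ord <- order(ranks)
      ex_tbl <- tibble(
        exon_rank = ranks[ord], start = starts[ord],
        end = starts[ord] + lens[ord], len = lens[ord]) |>
        arrange(.data$exon_rank) |>
        mutate(exon_id = exon_name(g, .data$exon_rank))

      iso <- list()
      if (role == "pattern2") {
        j <- pat_j
        iso[[sprintf("T_%s_full", g)]] <- seq_len(n_ex)
        iso[[sprintf("T_%s_skip", g)]] <- setdiff(seq_len(n_ex), j)
        role_rows[[g]] <- tibble(gene_id = g, role = role,
                                 exon_down = exon_name(g, j),
                                 exon_up = NA_character_,
                                 donor_exon = NA_character_,
                                 acceptor_exon = NA_character_,
                                 novel_tx = NA_character_)
      } else if (role == "pattern3") {
        j <- pat3_j
        k <- pat3_k
        iso[[sprintf("T_%s_A", g)]] <- setdiff(seq_len(n_ex), k)
        iso[[sprintf("T_%s_B", g)]] <- setdiff(seq_len(n_ex), j)
        role_rows[[g]] <- tibble(gene_id = g, role = role,
                                 exon_down = exon_name(g, k),
                                 exon_up = exon_name(g, j),
                                 donor_exon = NA_character_,
                                 acceptor_exon = NA_character_,
                                 novel_tx = NA_character_)
      } else {
        iso[[sprintf("T_%s_full", g)]] <- seq_len(n_ex)
        if (role == "skip") {
          sp <- config$skip_span
          role_rows[[g]] <- tibble(
            gene_id = g, role = role,
            exon_down = NA_character_, exon_up = NA_character_,
            donor_exon = exon_name(g, min(sp) - 1L),
            acceptor_exon = exon_name(g, max(sp) + 1L),
            novel_tx = sprintf("T_%s_skipnovel", g))
          novel_rows[[g]] <- tibble(
            transcript_id = sprintf("T_%s_skipnovel", g), gene_id = g,
            ranks = list(setdiff(seq_len(n_ex), sp)))
        } else {
          role_rows[[g]] <- tibble(
            gene_id = g, role = role,
            exon_down = NA_character_, exon_up = NA_character_,
            donor_exon = NA_character_, acceptor_exon = NA_character_,
            novel_tx = NA_character_)
        }
      }

      for (tx in names(iso)) {
        rk <- iso[[tx]]
        sub <- ex_tbl |> filter(.data$exon_rank %in% rk) |>
          arrange(.data$exon_rank)
        exon_rows[[paste(g, tx)]] <- tibble(
          gene_id = g, transcript_id = tx, chrom = chrom,
          start = sub$start, end = sub$end, strand = strand,
          exon_rank = seq_len(nrow(sub)), cds_len = sub$len,
          exon_id = sub$exon_id)
      }
      # keep the per-gene exon table for novel isoform splicing
      attr(role_rows[[g]], "ex_tbl") <- ex_tbl |> mutate(strand = strand)
    }

    genome <- Biostrings::DNAStringSet(setNames(random_dna(cursor + 200L),
                                                chrom))
    ann <- annotation_from_tables(bind_rows(exon_rows), genome)

    roles <- bind_rows(role_rows)
    novel_isoforms <- tibble()
    if (length(novel_rows) > 0) {
      novel_isoforms <- bind_rows(purrr::imap(novel_rows, function(nr, g) {
        ex_tbl <- attr(role_rows[[g]], "ex_tbl")
        rk <- nr$ranks[[1]]
        sub <- ex_tbl |> filter(.data$exon_rank %in% rk) |>
          arrange(.data$exon_rank)
        seq <- paste(vapply(seq_len(nrow(sub)), function(i)
          extract_sequence(genome, "chrS1", sub$start[i], sub$end[i],
                           sub$strand[i]), ""), collapse = "")
        tibble(transcript_id = nr$transcript_id, gene_id = g,
               seq = seq, length = nchar(seq),
               exon_ids = list(sub$exon_id))
      }))
    }
    structure(list(annotation = ann, roles = roles,
                   novel_isoforms = novel_isoforms, config = config),
              class = "sim_genome")
  })
}

cond_shares <- function(role, config, condition) {
  tumor <- condition == "tumor"
  switch(role,
    pattern2 = if (tumor) config$pattern2_shares_tumor else
      config$pattern2_shares,
    pattern3 = if (tumor) config$pattern3_shares_tumor else
      config$pattern3_shares,
    skip = {
      inc <- if (tumor) config$skip_inclusion_tumor else
        config$skip_inclusion_normal
      c(1 - inc, inc)
    },
    1)
}

# isoform table (annotated + novel) with per-condition molar shares
isoform_table <- function(sim) {
  cfg <- sim$config
  ann_tx <- sim$annotation$transcripts |>
    select("transcript_id", "gene_id", "length") |>
    mutate(annotated = TRUE)
  if (nrow(sim$novel_isoforms) > 0) {
    ann_tx <- bind_rows(ann_tx,
      sim$novel_isoforms |>
        select("transcript_id", "gene_id", "length") |>
        mutate(annotated = FALSE))
  }
  ann_tx |>
    left_join(sim$roles |> select("gene_id", "role"), by = "gene_id") |>
    group_by(.data$gene_id) |>
    arrange(.data$transcript_id, .by_group = TRUE) |>
    mutate(share_normal = cond_shares(.data$role[1], cfg, "normal"),
           share_tumor = cond_shares(.data$role[1], cfg, "tumor")) |>
    ungroup()
}

#' Generate paired expression profiles with planted truth
#'
#' Produces per-sample expected transcript abundances for a cohort of
#' `n_pairs` matched tumour/normal samples. Planted whole-gene DEGs
#' receive the configured log2 shift in tumour; pattern-2 and pattern-3
#' genes switch molar shares between isoforms while conserving the
#' gene's total molar abundance (so shared exons stay flat and the
#' switched exons carry the signal); skip genes move expression onto an
#' unannotated skip isoform in tumour. Patient-level random effects are
#' shared within each pair.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param config Optional override of `sim$config`.
#' @return A `sim_expression` list: `design` (sample sheet), `isoforms`,
#'   `molar` and `mass` matrices (transcripts x samples; mass =
#'   molar x effective length, i.e. expected read share), and `truth`
#'   (per-gene, per-exon and junction truth tables).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_genome"))
  withr::with_seed(derive_seed(config$seed, 2), {
    design <- tibble(
      patient_id = rep(sprintf("P%02d", seq_len(config$n_pairs)), each = 2),
      condition = rep(c("tumor", "normal"), config$n_pairs)) |>
      mutate(sample_id = paste0(.data$patient_id,
                                ifelse(.data$condition == "tumor",
                                       "_T", "_N"))) |>
      select("sample_id", "patient_id", "condition")

    iso <- isoform_table(sim)
    genes <- sim$roles
    n_g <- nrow(genes)
    n_s <- nrow(design)

    if (n_g == 0) {
      return(structure(list(design = design, isoforms = iso,
                            molar = matrix(0, 0, n_s), mass = matrix(0, 0, n_s),
                            truth = list(genes = tibble(), exons = tibble(),
                                         junctions = tibble())),
                       class = "sim_expression"))
    }

    baseline <- rnorm(n_g, 0, config$baseline_log2_sd)
    # skip genes are planted as highly expressed (a fixed share of the
    # cohort's expression mass) so every tumour sample is essentially
    # guaranteed junction-spanning reads at this depth
    lognormal_mean_log2 <- config$baseline_log2_sd^2 * log(2) / 2
    baseline[genes$role == "skip"] <-
      log2(config$skip_gene_share * n_g) + lognormal_mean_log2
    # isoform-switch and dedicated pattern-1 genes emulate the
    # well-expressed genes exon-level patterns are illustrated with:
    # planted at a fixed cohort-mass share so per-exon counts support
    # exon-level testing at this depth
    pat_roles <- c("pattern1", "pattern2", "pattern3")
    baseline[genes$role %in% pat_roles] <-
      log2(config$pattern_gene_share * n_g) + lognormal_mean_log2

    # whole-gene DEGs: planted on genes with at-least-median baseline
    # (a fold change on a silent gene is not a recoverable signal)
    deg_n <- round(config$deg_fraction * n_g)
    eligible <- which(genes$role == "null" & baseline >= 0)
    deg_idx <- sample(eligible, min(deg_n, length(eligible)))
    role_full <- genes$role
    role_full[deg_idx] <- "deg"
    shifted <- role_full %in% c("deg", "pattern1")
    deg_direction <- rep(NA_character_, n_g)
    deg_direction[shifted] <- rep(c("up", "down"), length.out = sum(shifted))

    patient_eff <- matrix(rnorm(n_g * config$n_pairs, 0,
                                config$patient_log2_sd),
                          n_g, config$n_pairs)
    gene_log2 <- matrix(0, n_g, n_s,
                        dimnames = list(genes$gene_id, design$sample_id))
    # multiplicative log-normal noise is mean-corrected (-sigma^2*ln2/2
    # in log2 units) so that noise redistributes expression without
    # inflating a condition's total mass: non-planted genes then share
    # expectation across conditions exactly
    lnorm_mean <- function(s) -s^2 * log(2) / 2
    for (s in seq_len(n_s)) {
      p <- match(design$patient_id[s],
                 sprintf("P%02d", seq_len(config$n_pairs)))
      tumor <- design$condition[s] == "tumor"
      eff <- baseline + patient_eff[, p] +
        rnorm(n_g, lnorm_mean(config$sample_log2_sd),
              config$sample_log2_sd)
      if (tumor) {
        eff <- eff + rnorm(n_g, lnorm_mean(config$tumor_extra_log2_sd),
                           config$tumor_extra_log2_sd)
        shift <- ifelse(shifted,
                        ifelse(deg_direction == "up", 1, -1) *
                          config$deg_log2fc, 0)
        eff <- eff + ifelse(is.na(shift), 0, shift)
      }
      gene_log2[, s] <- eff
    }

    share <- ifelse(rep(design$condition, each = nrow(iso)) == "tumor",
                    rep(iso$share_tumor, n_s), rep(iso$share_normal, n_s))
    share <- matrix(share, nrow(iso), n_s,
                    dimnames = list(iso$transcript_id, design$sample_id))
    molar <- 2^gene_log2[iso$gene_id, , drop = FALSE] * share
    rownames(molar) <- iso$transcript_id
    eff_len <- pmax(iso$length - config$read_length + 1, 0)
    mass <- molar * eff_len

    # ---- truth tables (closed-form expectations, noise-free) ----
    truth_genes <- genes |>
      mutate(role = role_full,
             is_deg = .data$role %in% c("deg", "pattern1"),
             direction = deg_direction,
             true_log2fc = ifelse(.data$is_deg,
                                  ifelse(.data$direction == "up", 1, -1) *
                                    config$deg_log2fc, 0),
             pattern = dplyr::case_match(.data$role,
                                         c("deg", "pattern1") ~ "1",
                                         c("pattern2", "skip") ~ "2",
                                         "pattern3" ~ "3",
                                         .default = "none")) |>
      select("gene_id", "role", "is_deg", "direction", "true_log2fc",
             "pattern")

    exon_iso <- sim$annotation$exon_tx |>
      select("transcript_id", "exon_id") |>
      bind_rows(if (nrow(sim$novel_isoforms) > 0)
        sim$novel_isoforms |>
          select("transcript_id", "exon_ids") |>
          tidyr::unnest_longer("exon_ids", values_to = "exon_id")
        else NULL)
    cov_tbl <- exon_iso |>
      inner_join(iso |> select("transcript_id", "gene_id", "share_normal",
                               "share_tumor"),
                 by = "transcript_id") |>
      inner_join(truth_genes |> select("gene_id", "true_log2fc"),
                 by = "gene_id") |>
      group_by(.data$exon_id, .data$gene_id) |>
      summarise(cov_normal = sum(.data$share_normal),
                cov_tumor = sum(.data$share_tumor) *
                  2^.data$true_log2fc[1],
                .groups = "drop")
    truth_exons <- cov_tbl |>
      mutate(expected_log2fc = log2(.data$cov_tumor / .data$cov_normal),
             is_dee = is.infinite(.data$expected_log2fc) |
               abs(.data$expected_log2fc) > 0.2,
             direction = ifelse(.data$expected_log2fc > 0, "up", "down"))

    truth_junctions <- genes |>
      filter(.data$role == "skip") |>
      transmute(gene_id = .data$gene_id, donor_exon = .data$donor_exon,
                acceptor_exon = .data$acceptor_exon,
                novel_tx = .data$novel_tx,
                tumor_enriched = config$skip_inclusion_tumor >
                  config$skip_inclusion_normal)

    structure(list(design = design, isoforms = iso, molar = molar,
                   mass = mass,
                   truth = list(genes = truth_genes, exons = truth_exons,
                                junctions = truth_junctions)),
              class = "sim_expression")
  })
}

#' Simulate single-end reads for one or more samples
#'
#' Reads are drawn from transcripts (annotated isoforms plus any planted
#' unannotated skip isoforms) with probability proportional to molar
#' abundance times effective length, start positions uniform along the
#' transcript, and independent per-base substitution errors. Read names
#' encode the source sample, transcript and 0-based offset
#' (`sample:transcript:offset:serial`) so that downstream results can be
#' checked against the generating truth.
#'
#' @param sim A `sim_genome`.
#' @param expr A `sim_expression`.
#' @param sample_ids Samples to simulate; default all in the design.
#' @param config Optional override of `sim$config`.
#' @param dir If non-NULL, write one `<sample>.fastq` per sample here.
#' @return Named list of per-sample named character vectors of reads.
#' @export
simulate_reads <- function(sim, expr, sample_ids = NULL,
                           config = sim$config, dir = NULL) {
  stopifnot(inherits(expr, "sim_expression"))
  sample_ids <- sample_ids %||% expr$design$sample_id
  L <- config$read_length

  seqs <- c(transcript_sequences(sim$annotation),
            if (nrow(sim$novel_isoforms) > 0)
              setNames(sim$novel_isoforms$seq,
                       sim$novel_isoforms$transcript_id))
  seqs <- seqs[rownames(expr$mass)]
  too_short <- nchar(seqs) < L
  if (any(too_short))
    warn(sprintf("%d transcript(s) shorter than the read length excluded",
                 sum(too_short)))

  out <- purrr::map(sample_ids, function(s) {
    s_idx <- match(s, expr$design$sample_id)
    withr::with_seed(derive_seed(config$seed, 100 + s_idx), {
      w <- expr$mass[, s]
      w[too_short] <- 0
      if (sum(w) == 0 || config$reads_per_sample == 0)
        return(setNames(character(0), character(0)))
      n <- config$reads_per_sample
      tx <- sample.int(length(w), n, replace = TRUE, prob = w)
      max_start <- nchar(seqs)[tx] - L  # 0-based start in [0, max_start]
      pos <- floor(runif(n) * (max_start + 1))
      reads <- substr(seqs[tx], pos + 1, pos + L)

      n_err <- rbinom(n, L, config$error_rate)
      bases <- c("A", "C", "G", "T")
      # single-error reads vectorized (the vast majority); multi-error
      # reads individually so error positions stay distinct
      one <- which(n_err == 1)
      if (length(one) > 0) {
        p <- sample.int(L, length(one), replace = TRUE)
        old <- substr(reads[one], p, p)
        shift <- sample.int(3, length(one), replace = TRUE)
        new <- bases[(match(old, bases) - 1L + shift) %% 4L + 1L]
        substr(reads[one], p, p) <- new
      }
      multi <- which(n_err > 1)
      for (i in multi) {
        r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        at <- sample.int(L, n_err[i])
        for (p in at) r[p] <- sample(setdiff(bases, r[p]), 1)
        reads[i] <- paste(r, collapse = "")
      }
      setNames(reads,
               sprintf("%s:%s:%d:%d", s, names(seqs)[tx], pos, seq_len(n)))
    })
  })
  names(out) <- sample_ids
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in sample_ids)
      write_fastq(out[[s]], file.path(dir, paste0(s, ".fastq")))
  }
  out
}

#' Write reads to FASTQ (Sanger encoding, constant quality)
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write the simulated genome and annotation to disk
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  Biostrings::writeXStringSet(sim$annotation$genome, fa)
  write_annotation_gtf(sim$annotation, gtf)
  list(genome = fa, gtf = gtf)
}
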