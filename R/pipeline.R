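# Orchestration: end-to-end run on simulated or user-provided reads,
# run summaries, and recovery evaluation against planted truth.

#' Percentage with half-up rounding
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places (half-up rounding, as percentages are
#'   conventionally printed).
#' @return `100 * numerator / denominator`, rounded.
#' @export
pct <- function(numerator, denominator, decimals = 1) {
  assert_that(all(denominator > 0), "denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

wide_counts <- function(per_sample, id_col, all_ids) {
  long <- purrr::imap(per_sample, function(d, s)
    d |> mutate(sample_id = s)) |> bind_rows()
  out <- long |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(id_col),
                       names_from = "sample_id",
                       values_from = "count", values_fill = 0L)
  full <- tibble(!!id_col := all_ids)
  out <- full |> left_join(out, by = id_col)
  out[is.na(out)] <- 0L
  out
}

#' Table-1-style run summary
#'
#' Per-sample sequencing/mapping tallies plus cohort-level detection
#' statistics: union detection of genes/transcripts/exons across all
#' samples with their percentages of the annotation totals, and the
#' counts of genes passing the two expression filters (more than
#' `tags_per_kb` mapped tags per kilobase of transcript on average, and
#' mean RPKM above `rpkm_floor`).
#'
#' @param sample_stats Tibble `sample_id`, `total_reads`,
#'   `aligned_reads`, `n_genes`, `n_transcripts`, `n_exons`.
#' @param gene_counts,tx_counts,exon_counts Wide count tibbles (feature
#'   id + per-sample columns).
#' @param gene_rpkm Wide gene RPKM tibble.
#' @param annotation A `genome_annotation`.
#' @param tags_per_kb Tags-per-kilobase expression filter (default 10).
#' @param rpkm_floor RPKM expression filter (default 3).
#' @return A `run_summary` list: `samples` and `cohort` (tibble with
#'   `metric`, `count`, `denominator`, `pct`).
#' @export
summarize_run <- function(sample_stats, gene_counts, tx_counts,
                          exon_counts, gene_rpkm, annotation,
                          tags_per_kb = 10, rpkm_floor = 3) {
  assert_that(all(sample_stats$aligned_reads <= sample_stats$total_reads),
              "aligned reads exceed total reads")
  union_detect <- function(w) sum(rowSums(as.matrix(w[-1])) > 0)
  n_gene_u <- union_detect(gene_counts)
  n_tx_u <- union_detect(tx_counts)
  n_exon_u <- union_detect(exon_counts)

  tx_len <- annotation$transcripts |>
    group_by(.data$gene_id) |>
    summarise(length = max(.data$length), .groups = "drop")
  mean_count <- rowMeans(as.matrix(gene_counts[-1]))
  len <- setNames(tx_len$length, tx_len$gene_id)[gene_counts$gene_id]
  tags_kb_pass <- sum(mean_count * 1000 / len > tags_per_kb, na.rm = TRUE)
  rpkm_pass <- sum(rowMeans(as.matrix(gene_rpkm[-1])) > rpkm_floor)

  denoms <- annotation_summary(annotation)
  cohort <- tibble(
    metric = c("genes_detected", "transcripts_detected", "exons_detected",
               "genes_tags_per_kb", "genes_rpkm"),
    count = c(n_gene_u, n_tx_u, n_exon_u, tags_kb_pass, rpkm_pass),
    denominator = c(denoms$n_genes, denoms$n_transcripts, denoms$n_exons,
                    denoms$n_genes, denoms$n_genes)) |>
    mutate(pct = pct(.data$count, pmax(.data$denominator, 1), 1))
  structure(list(samples = sample_stats, cohort = cohort),
            class = "run_summary")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates (or reuses) the synthetic cohort, aligns each sample's
#' reads through both hierarchies -- transcriptome for gene-level
#' quantification; genome, then known junctions, then phase-compatible
#' novel junction candidates for exon-level quantification -- counts
#' with the multiread rules, normalizes (RPKM for genes/exons, TPM for
#' junctions), runs the paired tests at every level, classifies
#' gene-versus-exon patterns, and summarises the run.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory; when given, all result
#'   tables are written as TSV together with a content-hash manifest.
#' @param from Optional previous `rnaseq_run` on the same config:
#'   simulation and alignment are skipped and its count matrices are
#'   reused, re-running quantification and all downstream stages.
#' @param quiet Suppress progress messages.
#' @return An `rnaseq_run` list with the annotation, truth, design,
#'   count/expression matrices, per-level `diff_calls`, pattern calls,
#'   Venn decomposition, MA table, correlation summary and run summary.
#' @export
run_pipeline <- function(config, out_dir = NULL, from = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  L <- config$read_length

  if (is.null(from)) {
    say("stage simulate: genome + expression")
    sim <- simulate_genome(config)
    expr <- simulate_expression(sim, config)
    ann <- sim$annotation

    say("stage references: transcriptome, genome, junction databases")
    tx_refs <- transcript_sequences(ann)
    known <- build_known_junctions(ann, read_length = L,
                                   min_overhang = config$min_overhang)
    novel <- build_novel_junctions(ann, known, read_length = L,
                                   min_overhang = config$min_overhang)
    idx_tx <- build_index(tx_refs)
    idx_genome <- build_index(as.character(ann$genome) |>
                                setNames(names(ann$genome)))
    idx_known <- if (nrow(known) > 0) build_index(junction_references(known))
    idx_novel <- if (nrow(novel) > 0) build_index(junction_references(novel))

    tx2gene <- ann$transcripts |> select("transcript_id", "gene_id")
    design <- expr$design
    gene_cnt <- list(); tx_cnt <- list(); exon_cnt <- list()
    jx_cnt <- list(); stats_rows <- list()
    gene_totals <- c(); exon_totals <- c()

    for (s in design$sample_id) {
      say("stage align+count: sample %s", s)
      reads <- simulate_reads(sim, expr, sample_ids = s)[[1]]

      gstages <- list(transcriptome = list(index = idx_tx))
      gres <- align_hierarchical(reads, gstages)
      asg <- assign_reads_gene_level(gres$hits$transcriptome, tx2gene)
      gene_cnt[[s]] <- asg$gene_counts
      tx_cnt[[s]] <- asg$transcript_counts
      gene_totals[s] <- asg$n_assigned

      estages <- list(genome = list(index = idx_genome, both_strands = TRUE))
      if (!is.null(idx_known))
        estages$known_junction <- list(index = idx_known)
      if (!is.null(idx_novel))
        estages$novel_junction <- list(index = idx_novel)
      eres <- align_hierarchical(reads, estages)
      jhits <- bind_rows(eres$hits[["known_junction"]],
                         eres$hits[["novel_junction"]])
      jdb <- bind_rows(known, novel)
      exon_cnt[[s]] <- assign_reads_exon_level(
        eres$hits$genome, jhits, ann, jdb, read_length = L)
      exon_totals[s] <- sum(eres$tally$n_aligned)
      if (!is.null(idx_novel)) {
        jx_cnt[[s]] <- detect_junction_reads(
          eres$hits[["novel_junction"]], novel, read_length = L,
          min_overhang = config$min_overhang)
      }
      stats_rows[[s]] <- tibble(
        sample_id = s, total_reads = length(reads),
        aligned_reads = gres$tally$n_aligned[1],
        n_genes = nrow(asg$gene_counts |> filter(.data$count > 0)),
        n_transcripts = nrow(asg$transcript_counts |>
                               filter(.data$count > 0)),
        n_exons = sum(exon_cnt[[s]]$count > 0))
    }

    gene_counts <- wide_counts(gene_cnt, "gene_id", ann$genes$gene_id)
    tx_counts <- wide_counts(tx_cnt, "transcript_id",
                             ann$transcripts$transcript_id)
    exon_counts <- wide_counts(exon_cnt, "exon_id", ann$exons$exon_id)
    junction_counts <- if (length(jx_cnt) > 0)
      wide_counts(jx_cnt, "junction_id", novel$junction_id) else NULL
    sample_stats <- bind_rows(stats_rows)
  } else {
    say("stage reuse: counts from previous run")
    sim <- from$sim; expr <- from$expr; ann <- sim$annotation
    known <- from$junctions$known; novel <- from$junctions$novel
    gene_counts <- from$counts$gene; tx_counts <- from$counts$transcript
    exon_counts <- from$counts$exon
    junction_counts <- from$counts$junction
    gene_totals <- from$totals$gene; exon_totals <- from$totals$exon
    sample_stats <- from$summary$samples
    design <- expr$design
  }

  say("stage quantify: RPKM / TPM")
  gene_rpkm <- compute_gene_rpkm(gene_counts, tx_counts, ann, gene_totals)
  exon_len <- setNames(ann$exons$length, ann$exons$exon_id)
  exon_rpkm <- compute_rpkm(exon_counts, exon_len, exon_totals)
  junction_tpm <- if (!is.null(junction_counts))
    compute_tpm(junction_counts, exon_totals) else NULL

  say("stage diffexpr: paired tests at gene / exon / junction level")
  de_gene <- call_features(gene_rpkm, gene_counts, design)
  de_exon <- call_features(exon_rpkm, exon_counts, design)
  de_junction <- if (!is.null(junction_tpm))
    call_features(junction_tpm, junction_counts, design) else NULL

  say("stage patterns: gene-versus-exon classification")
  deg_ids <- de_gene$feature_id[de_gene$significant]
  exon_gene <- ann$exons |> select("exon_id", "gene_id")
  patterns <- classify_patterns(de_exon, exon_gene, deg_ids = deg_ids)
  dee_genes <- unique((as_tibble(de_exon) |>
                         filter(.data$significant) |>
                         inner_join(exon_gene,
                                    by = c(feature_id = "exon_id")))$gene_id)
  venn <- venn_gene_exon(deg_ids, dee_genes)

  pooled <- tibble(
    feature_id = gene_counts$gene_id,
    count_tumor = rowSums(as.matrix(
      gene_counts[design$sample_id[design$condition == "tumor"]])),
    count_normal = rowSums(as.matrix(
      gene_counts[design$sample_id[design$condition == "normal"]])))
  ma <- ma_values(pooled,
                  sum(gene_totals[design$sample_id[
                    design$condition == "tumor"]]),
                  sum(gene_totals[design$sample_id[
                    design$condition == "normal"]]))

  log_rpkm <- gene_rpkm
  log_rpkm[-1] <- log2(gene_rpkm[-1] + 1)
  pcc <- sample_correlation_matrix(log_rpkm, design)

  summary <- summarize_run(sample_stats, gene_counts, tx_counts,
                           exon_counts, gene_rpkm, ann)

  run <- structure(list(
    config = config, sim = sim, expr = expr, design = design,
    truth = expr$truth,
    junctions = list(known = known, novel = novel),
    counts = list(gene = gene_counts, transcript = tx_counts,
                  exon = exon_counts, junction = junction_counts),
    totals = list(gene = gene_totals, exon = exon_totals),
    expression = list(gene_rpkm = gene_rpkm, exon_rpkm = exon_rpkm,
                      junction_tpm = junction_tpm),
    de = list(gene = de_gene, exon = de_exon, junction = de_junction),
    patterns = patterns, venn = venn, ma = ma, pcc = pcc,
    summary = summary), class = "rnaseq_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.rnaseq_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0(
    "<rnaseq_run> %d genes x %d samples\n",
    "  DEGs: %d   DEEs: %d (in %d genes)   novel junctions expressed: %d\n"),
    g$n_genes, g$n_samples, g$n_deg, g$n_dee, g$n_dee_genes,
    g$n_novel_junctions_detected))
  invisible(x)
}

#' @export
glance.rnaseq_run <- function(x, ...) {
  exon_gene <- x$sim$annotation$exons |> select("exon_id", "gene_id")
  dee <- as_tibble(x$de$exon) |> filter(.data$significant)
  tibble(
    n_genes = nrow(x$sim$annotation$genes),
    n_samples = nrow(x$design),
    n_deg = sum(x$de$gene$significant),
    n_dee = nrow(dee),
    n_dee_genes = dplyr::n_distinct(
      (dee |> inner_join(exon_gene,
                         by = c(feature_id = "exon_id")))$gene_id),
    n_novel_junctions_detected = if (is.null(x$counts$junction)) 0L else
      sum(rowSums(as.matrix(x$counts$junction[-1])) > 0),
    n_pattern1 = sum(x$patterns$pattern == "1"),
    n_pattern2 = sum(x$patterns$pattern == "2"),
    n_pattern3 = sum(x$patterns$pattern == "3"))
}

#' Write a pipeline run to a directory of TSVs with a manifest
#'
#' @param run An `rnaseq_run`.
#' @param out_dir Output directory.
#' @return Manifest tibble (`file`, `md5`), invisibly.
#' @export
write_run <- function(run, out_dir) {
  dirs <- c("counts", "expression", "diffexpr", "junctions", "patterns",
            "reports")
  for (d in dirs)
    dir.create(file.path(out_dir, d), recursive = TRUE,
               showWarnings = FALSE)
  tsv <- function(x, path) {
    write.table(x, file.path(out_dir, path), sep = "\t", quote = FALSE,
                row.names = FALSE)
    path
  }
  files <- c(
    tsv(run$counts$gene, "counts/gene_counts.tsv"),
    tsv(run$counts$transcript, "counts/transcript_counts.tsv"),
    tsv(run$counts$exon, "counts/exon_counts.tsv"),
    if (!is.null(run$counts$junction))
      tsv(run$counts$junction, "counts/junction_counts.tsv"),
    tsv(run$expression$gene_rpkm, "expression/gene_rpkm.tsv"),
    tsv(run$expression$exon_rpkm, "expression/exon_rpkm.tsv"),
    if (!is.null(run$expression$junction_tpm))
      tsv(run$expression$junction_tpm, "expression/junction_tpm.tsv"),
    tsv(as_tibble(run$de$gene), "diffexpr/de_gene.tsv"),
    tsv(as_tibble(run$de$exon), "diffexpr/de_exon.tsv"),
    if (!is.null(run$de$junction))
      tsv(as_tibble(run$de$junction), "diffexpr/de_junction.tsv"),
    tsv(run$ma, "diffexpr/ma_gene.tsv"),
    tsv(run$junctions$known |> select(-"seq"), "junctions/known.tsv"),
    tsv(run$junctions$novel |> select(-"seq"), "junctions/novel.tsv"),
    tsv(run$patterns, "patterns/pattern_calls.tsv"),
    tsv(run$venn, "patterns/venn.tsv"),
    tsv(run$summary$samples, "reports/sample_summary.tsv"),
    tsv(run$summary$cohort, "reports/cohort_summary.tsv"))
  yaml::write_yaml(run$config[names(run$config)],
                   file.path(out_dir, "reports/config.yaml"))
  files <- c(files, "reports/config.yaml")
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Compare pipeline calls against the planted truth
#'
#' @param run An `rnaseq_run` on a simulated cohort.
#' @return One-row tibble: DEG sensitivity and empirical FDR, pattern
#'   label accuracy over genes with a planted pattern, the fraction of
#'   planted skip junctions present in the novel junction database, the
#'   fraction detected with at least one overhang-satisfying read in
#'   every tumour sample, and the per-(junction, tumour-sample)
#'   detection rate.
#' @export
evaluate_recovery <- function(run) {
  truth <- run$truth
  called <- run$de$gene$feature_id[run$de$gene$significant]
  planted <- truth$genes$gene_id[truth$genes$is_deg]
  unperturbed <- truth$genes$gene_id[truth$genes$role == "null"]
  sens <- if (length(planted) == 0) NA_real_ else
    length(intersect(called, planted)) / length(planted)
  # a call is false only when the gene carries no planted perturbation
  # at all (isoform-switch genes genuinely change at some level)
  fdr <- if (length(called) == 0) 0 else
    length(intersect(called, unperturbed)) / length(called)

  # pattern recovery is judged on the dedicated planted pattern genes
  # (whole-gene DEGs are label-1-consistent but planted for the DEG
  # criterion, at arbitrary expression levels)
  truth_pat <- truth$genes |>
    filter(.data$role %in% c("pattern1", "pattern2", "pattern3", "skip"))
  pred <- setNames(run$patterns$pattern, run$patterns$gene_id)
  pred_vec <- pred[truth_pat$gene_id]  # NA = gene never classified
  acc <- if (nrow(truth_pat) == 0) NA_real_ else
    mean(!is.na(pred_vec) & pred_vec == truth_pat$pattern)

  jx <- truth$junctions
  db_rec <- det_all <- det_rate <- NA_real_
  if (nrow(jx) > 0 && !is.null(run$counts$junction)) {
    novel <- run$junctions$novel
    key <- paste(novel$donor_exon, novel$acceptor_exon)
    jkey <- paste(jx$donor_exon, jx$acceptor_exon)
    db_rec <- mean(jkey %in% key)
    jid <- novel$junction_id[match(jkey, key)]
    tumor_cols <- run$design$sample_id[run$design$condition == "tumor"]
    jc <- run$counts$junction
    counts <- as.matrix(jc[match(jid, jc$junction_id), tumor_cols,
                           drop = FALSE])
    counts[is.na(counts)] <- 0
    det_all <- mean(apply(counts >= 1, 1, all))
    det_rate <- mean(counts >= 1)
  }
  tibble(deg_sensitivity = sens, deg_fdr = fdr,
         pattern_accuracy = acc,
         junction_db_recovery = db_rec,
         junction_all_tumor_detected = det_all,
         junction_detection_rate = det_rate)
}
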