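# Gene-versus-exon regulation patterns and the gene/exon Venn
# decomposition.
#
# Pattern 1: every expressed exon of the gene is differentially
# expressed, all in the same direction (the gene behaves as a unit).
# Pattern 2: a proper subset of exons shifts, all in one direction.
# Pattern 3: exons shift in both directions within the same gene.

#' Classify genes with differentially expressed exons into patterns
#'
#' Operates on exon-level [call_features()] results. A gene is
#' classified only when it has at least one significant expressed exon;
#' "expressed" means mean RPKM above `floor` in at least one condition.
#' Pattern 3 when significant exons include both directions; otherwise
#' pattern 1 when every expressed exon is significant (with
#' `relaxed_fraction < 1`, when at least that fraction is); otherwise
#' pattern 2.
#'
#' @param exon_calls A `diff_calls` tibble from exon-level
#'   [call_features()] (needs `mean_tumor` / `mean_normal` columns).
#' @param exon_gene Tibble `exon_id`, `gene_id` mapping exons to genes.
#' @param floor Expressed-exon floor on mean RPKM (default 1).
#' @param deg_ids Optional character vector of gene-level DEG ids; fills
#'   the `also_deg` column.
#' @param relaxed_fraction Fraction of expressed exons that must be
#'   significant for pattern 1 (default 1 = all; lower for noisy data).
#' @return Tibble `gene_id`, `pattern` ("1"/"2"/"3"), `n_expressed`,
#'   `n_dee`, `n_up`, `n_down`, `also_deg`. Genes without any expressed
#'   exon, or without any significant exon, receive no row.
#' @export
classify_patterns <- function(exon_calls, exon_gene, floor = 1,
                              deg_ids = character(),
                              relaxed_fraction = 1) {
  calls <- as_tibble(exon_calls) |>
    inner_join(exon_gene, by = c(feature_id = "exon_id")) |>
    mutate(expressed = .data$mean_tumor > floor |
             .data$mean_normal > floor)
  calls |>
    filter(.data$expressed) |>
    group_by(.data$gene_id) |>
    summarise(
      n_expressed = dplyr::n(),
      n_dee = sum(.data$significant),
      n_up = sum(.data$significant & .data$direction == "up"),
      n_down = sum(.data$significant & .data$direction == "down"),
      .groups = "drop") |>
    filter(.data$n_dee > 0) |>
    mutate(
      pattern = dplyr::case_when(
        .data$n_up > 0 & .data$n_down > 0 ~ "3",
        .data$n_dee >= relaxed_fraction * .data$n_expressed ~ "1",
        TRUE ~ "2"),
      also_deg = .data$gene_id %in% deg_ids)
}

#' Per-sample expression ratio of two exons, contrasted across conditions
#'
#' Computes `log2(RPKM_a / RPKM_b)` per sample and runs the paired
#' tests on the ratios between tumour and normal. For a pattern-1 gene
#' (both exons scale together) the ratio shows no difference; for
#' pattern-2/3 genes the isoform switch shifts it.
#'
#' @param expression Tibble: exon id column then per-sample RPKM.
#' @param design Design tibble (`sample_id`, `patient_id`, `condition`).
#' @param exon_a,exon_b The exon pair; `exon_b` is the denominator.
#' @return List: `ratios` (tibble `sample_id`, `condition`,
#'   `log2_ratio`), `test` (paired t and Wilcoxon on ratios),
#'   `n_excluded` (pairs dropped for a zero denominator or numerator).
#' @export
exon_ratio_contrast <- function(expression, design, exon_a, exon_b) {
  id_col <- names(expression)[1]
  a <- unlist(expression[expression[[id_col]] == exon_a, -1])
  b <- unlist(expression[expression[[id_col]] == exon_b, -1])
  assert_that(length(a) > 0 && length(b) > 0, "exon not found in matrix")
  design <- design |>
    mutate(condition = ifelse(.data$condition %in%
                                c("non_tumor", "non-tumor", "NT"),
                              "normal", .data$condition))
  ratios <- design |>
    mutate(num = a[.data$sample_id], den = b[.data$sample_id],
           log2_ratio = log2(.data$num / .data$den))
  wide <- ratios |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "condition",
                       values_from = "log2_ratio")
  ok <- is.finite(wide$tumor) & is.finite(wide$normal)
  n_excluded <- sum(!ok)
  tt <- paired_t_test(wide$tumor[ok], wide$normal[ok])
  wt <- wilcoxon_signed_rank(wide$tumor[ok], wide$normal[ok])
  list(
    ratios = ratios |> select("sample_id", "condition", "log2_ratio"),
    test = tibble(t = tt$statistic, t_p = tt$p.value,
                  w = wt$statistic, w_p = wt$p.value,
                  mean_shift = mean(wide$tumor[ok] - wide$normal[ok])),
    n_excluded = n_excluded)
}

#' Venn decomposition of gene-level and exon-level calls
#'
#' @param deg_ids Gene ids significant at the gene level.
#' @param dee_gene_ids Gene ids containing at least one differentially
#'   expressed exon.
#' @return Tibble `deg_only`, `shared`, `dee_only` (three disjoint
#'   counts summing to the union size).
#' @export
venn_gene_exon <- function(deg_ids, dee_gene_ids) {
  deg_ids <- unique(deg_ids)
  dee_gene_ids <- unique(dee_gene_ids)
  tibble(deg_only = length(setdiff(deg_ids, dee_gene_ids)),
         shared = length(intersect(deg_ids, dee_gene_ids)),
         dee_only = length(setdiff(dee_gene_ids, deg_ids)))
}
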