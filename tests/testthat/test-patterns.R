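# Pattern classification, exon-ratio contrasts, Venn decomposition.

fake_exon_calls <- function(df) {
  # df: exon_id, gene_id, significant, direction, expressed level
  out <- tibble::tibble(
    feature_id = df$exon_id,
    mean_tumor = ifelse(df$expressed, 50, 0.1),
    mean_normal = ifelse(df$expressed, 50, 0.1),
    log2fc = ifelse(df$significant,
                    ifelse(df$direction == "up", 2, -2), 0),
    t = 0, t_p = ifelse(df$significant, 0.001, 0.5),
    w = 0, w_p = ifelse(df$significant, 0.001, 0.5),
    q = ifelse(df$significant, 0.01, 0.5),
    significant = df$significant,
    direction = df$direction)
  class(out) <- c("diff_calls", class(out))
  out
}

test_that("the three archetypes classify as patterns 1, 2 and 3", {
  df <- tibble::tribble(
    ~exon_id, ~gene_id, ~significant, ~direction, ~expressed,
    # all expressed exons down-regulated -> pattern 1
    "c1", "CFTRlike", TRUE, "down", TRUE,
    "c2", "CFTRlike", TRUE, "down", TRUE,
    # one exon down, another expressed exon unchanged -> pattern 2
    "d1", "CCDC50like", TRUE, "down", TRUE,
    "d2", "CCDC50like", FALSE, "down", TRUE,
    # one up, one down -> pattern 3
    "s1", "SIGLEC11like", TRUE, "up", TRUE,
    "s2", "SIGLEC11like", TRUE, "down", TRUE,
    "s3", "SIGLEC11like", FALSE, "up", TRUE)
  calls <- fake_exon_calls(df)
  pat <- classify_patterns(calls, df[c("exon_id", "gene_id")],
                           deg_ids = "CFTRlike")
  p <- setNames(pat$pattern, pat$gene_id)
  expect_equal(p[["CFTRlike"]], "1")
  expect_equal(p[["CCDC50like"]], "2")
  expect_equal(p[["SIGLEC11like"]], "3")
  expect_true(pat$also_deg[pat$gene_id == "CFTRlike"])
  # every DEE-containing gene receives exactly one label
  expect_equal(sort(pat$gene_id),
               c("CCDC50like", "CFTRlike", "SIGLEC11like"))
  expect_false(any(duplicated(pat$gene_id)))
})

test_that("unexpressed exons are ignored and DEE-free genes get no call", {
  df <- tibble::tribble(
    ~exon_id, ~gene_id, ~significant, ~direction, ~expressed,
    "a1", "gA", TRUE, "up", TRUE,
    "a2", "gA", FALSE, "up", FALSE,   # below floor: ignored
    "b1", "gB", FALSE, "up", TRUE)    # no DEE: no call
  pat <- classify_patterns(fake_exon_calls(df),
                           df[c("exon_id", "gene_id")])
  expect_equal(pat$gene_id, "gA")
  expect_equal(pat$pattern, "1")  # the only expressed exon is a DEE
})

test_that("exon ratio contrast is flat under joint scaling and shifts under switches", {
  design <- tibble::tibble(
    sample_id = c(sprintf("P%d_T", 1:6), sprintf("P%d_N", 1:6)),
    patient_id = rep(sprintf("P%d", 1:6), 2),
    condition = rep(c("tumor", "normal"), each = 6))
  withr::with_seed(9, {
    scale <- 2^rnorm(12)  # per-sample common factor
    a <- 10 * scale
    b <- 5 * scale
    expr <- tibble::tibble(exon_id = c("ea", "eb")) |>
      dplyr::bind_cols(as.data.frame(rbind(a, b)) |>
                         setNames(design$sample_id))
    res <- exon_ratio_contrast(expr, design, "ea", "eb")
    expect_equal(res$test$t_p, 1)  # identical ratios in every sample
    # a tumour-only switch doubles the ratio in tumour samples
    b2 <- b
    b2[1:6] <- b2[1:6] / 4
    expr2 <- tibble::tibble(exon_id = c("ea", "eb")) |>
      dplyr::bind_cols(as.data.frame(rbind(a, b2)) |>
                         setNames(design$sample_id))
    # the exact constant switch degenerates the t-test (zero variance
    # with nonzero mean), which is flagged
    expect_warning(res2 <- exon_ratio_contrast(expr2, design, "ea", "eb"),
                   "zero variance")
    expect_lt(res2$test$t_p, 0.05)
    expect_equal(res2$test$mean_shift, 2)  # log2(4)
    # zero denominator excludes the pair and reports it
    b3 <- b
    b3[1] <- 0
    expr3 <- tibble::tibble(exon_id = c("ea", "eb")) |>
      dplyr::bind_cols(as.data.frame(rbind(a, b3)) |>
                         setNames(design$sample_id))
    expect_equal(exon_ratio_contrast(expr3, design, "ea", "eb")$n_excluded, 1)
  })
})

test_that("Venn decomposition conserves counts", {
  deg <- sprintf("g%04d", 1:1378)
  dee <- sprintf("g%04d", 105:5392)   # 5288 genes, 1274 shared
  v <- venn_gene_exon(deg, dee)
  expect_equal(v$shared, 1274)
  expect_equal(v$dee_only, 4014)
  expect_equal(v$deg_only + v$shared + v$dee_only,
               length(union(deg, dee)))
  expect_equal(venn_gene_exon(c("a"), c("b"))$shared, 0)
  same <- venn_gene_exon(c("a", "b"), c("a", "b"))
  expect_equal(same$deg_only, 0)
  expect_equal(same$dee_only, 0)
})
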