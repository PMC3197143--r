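# Paired tests, BH correction, the combined calling rule, MA and
# correlation quantities.

test_that("paired t matches the closed form and the reference implementation", {
  x <- c(2, 4, 6, 8)
  y <- c(1, 2, 3, 4)  # d = 1,2,3,4
  res <- paired_t_test(x, y)
  expect_equal(res$statistic, mean(1:4) / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(res$statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_lt(abs(res$p.value - 0.0305), 1e-4)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-12)
  # identical pairs
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # constant nonzero shift degenerates
  expect_warning(deg <- paired_t_test(c(2, 3, 4), c(1, 2, 3)),
                 "zero variance")
  expect_equal(deg$p.value, 0)
})

test_that("paired t on constants-plus-shift equals the one-sample closed form", {
  withr::with_seed(2, {
    y <- rnorm(8)
    x <- y + rnorm(8, mean = 1)
    d <- x - y
    res <- paired_t_test(x, y)
    expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(8)))
  })
})

test_that("exact Wilcoxon equals full 2^n enumeration (property, n <= 12)", {
  withr::with_seed(31, {
    for (i in 1:60) {
      n <- sample(2:12, 1)
      x <- round(rnorm(n), sample(0:2, 1))  # rounding creates ties/zeros
      y <- round(rnorm(n), 1)
      got <- wilcoxon_signed_rank(x, y)
      want <- wilcoxon_enumeration(x, y)
      expect_equal(got$statistic, want$w)
      expect_equal(got$p.value, want$p, tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon handles all-positive, symmetric and zero differences", {
  # n = 5, all positive, distinct -> W+ = 15, p = 2/32
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p.value, 0.0625)
  # mirror-symmetric differences -> p = 1
  expect_equal(wilcoxon_signed_rank(c(1, -1, 2, -2), c(0, 0, 0, 0))$p.value, 1)
  # zero differences are dropped, reducing effective n
  res0 <- wilcoxon_signed_rank(c(1, 2, 3, 5), c(1, 1, 2, 4))
  expect_equal(res0$n_effective, 3L)
  expect_equal(wilcoxon_signed_rank(c(1, 1), c(1, 1))$p.value, 1)
  # agreement with the reference implementation when no ties
  withr::with_seed(4, {
    x <- rnorm(10); y <- rnorm(10)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  })
})

test_that("BH q values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  withr::with_seed(5, {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
    expect_equal(q, p.adjust(p, "BH"))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_design <- function(n) tibble::tibble(
  sample_id = c(sprintf("P%02d_T", 1:n), sprintf("P%02d_N", 1:n)),
  patient_id = rep(sprintf("P%02d", 1:n), 2),
  condition = rep(c("tumor", "normal"), each = n))

test_that("call_features applies the conjunction rule and excludes silent features", {
  withr::with_seed(6, {
    n <- 10
    design <- make_design(n)
    base <- matrix(2^rnorm(200 * 2 * n, 5, 0.3), nrow = 200)
    base[1:20, 1:n] <- base[1:20, 1:n] * 16  # planted 4x up in tumor
    base[200, ] <- 0                          # silent feature
    expr <- tibble::tibble(feature_id = sprintf("f%03d", 1:200)) |>
      dplyr::bind_cols(as.data.frame(base) |>
                         setNames(design$sample_id))
    calls <- call_features(expr, NULL, design)
    expect_false("f200" %in% calls$feature_id)  # all-zero excluded
    expect_true(all(calls$significant[1:20]))
    expect_true(all(calls$direction[1:20] == "up"))
    expect_lt(sum(calls$significant[-(1:20)]), 5)
    # direction is consistent with the sign of log2fc when significant
    sig <- calls[calls$significant, ]
    expect_true(all(sign(sig$log2fc) == ifelse(sig$direction == "up", 1, -1)))
    # permutation equivariance: shuffling features shuffles calls
    perm <- sample(nrow(expr))
    calls_p <- call_features(expr[perm, ], NULL, design)
    expect_equal(calls_p$significant[order(calls_p$feature_id)],
                 calls$significant[order(calls$feature_id)])
    # broom-style accessors
    expect_s3_class(tidy(calls), "tbl_df")
    g <- glance(calls)
    expect_equal(g$n_significant, sum(calls$significant))
    expect_equal(g$n_pairs, n)
  })
})

test_that("an external FDR table replaces the BH column in the conjunction", {
  withr::with_seed(61, {
    design <- make_design(6)
    expr <- tibble::tibble(feature_id = c("a", "b")) |>
      dplyr::bind_cols(as.data.frame(
        rbind(2^c(5, 5, 5, 5, 5, 5, 1, 1, 1, 1, 1, 1),
              2^c(5.1, 4.9, 5, 5.2, 4.8, 5, 5, 5.1, 4.9, 5.2, 5, 4.8))) |>
          setNames(design$sample_id))
    base <- call_features(expr, NULL, design)
    expect_true(base$significant[1])
    ext <- tibble::tibble(feature_id = c("a", "b"), fdr = c(0.9, 0.9))
    noext <- call_features(expr, NULL, design, external_fdr = ext)
    expect_false(any(noext$significant))
  })
})

test_that("MA quantities follow the pooled-count definitions", {
  pooled <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                           count_tumor = c(50, 7, 0),
                           count_normal = c(25, 7, 12))
  ma <- ma_values(pooled, 1e6, 1e6, pseudocount = 0)
  expect_equal(ma$m[1], 1)
  expect_equal(ma$concentration[1], 7.5e-5)
  expect_equal(ma$m[2], 0)
  expect_true(ma$zero_flag[3])
  expect_false(any(ma$zero_flag[1:2]))
})

test_that("sample correlations: duplicates, negations, degenerate columns, group means", {
  expr <- tibble::tibble(feature_id = sprintf("f%d", 1:50),
                         a = 1:50 + 0, b = 1:50 + 0, c = -(1:50) + 0,
                         d = rep(2, 50))
  res <- sample_correlation_matrix(expr)
  expect_equal(res$matrix["a", "b"], 1)
  expect_equal(res$matrix["a", "c"], -1)
  expect_true(all(is.na(res$matrix["d", ])))
  # larger tumour heterogeneity lowers mean tumour-tumour correlation
  withr::with_seed(77, {
    cfg <- small_config(tumor_extra_log2_sd = 1.5, n_pairs = 8)
    sim <- simulate_genome(cfg)
    expr_sim <- simulate_expression(sim, cfg)
    m <- log2(expr_sim$molar + 1e-6)
    tbl <- tibble::tibble(feature_id = rownames(m)) |>
      dplyr::bind_cols(as.data.frame(m))
    cors <- sample_correlation_matrix(tbl, expr_sim$design)
    s <- setNames(cors$summary$mean_pcc, cors$summary$group)
    expect_gt(s[["normal-normal"]], s[["tumor-tumor"]])
  })
})

test_that("platform comparison: identity, affine invariance, attenuation by noise", {
  x <- setNames(rnorm(200, 5, 2), sprintf("g%d", 1:200))
  expect_equal(platform_comparison(x, x)$pcc, 1)
  expect_equal(platform_comparison(x, 2 * x + 3)$pcc, 1)
  withr::with_seed(8, {
    sigma <- 1
    y <- x + rnorm(200, 0, sigma)
    got <- platform_comparison(x, y)$pcc
    want <- sqrt(var(x) / (var(x) + sigma^2))  # attenuation closed form
    expect_equal(got, want, tolerance = 0.1)
  })
  expect_error(platform_comparison(x[1:2], x[1:2]), "fewer than 3")
})
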