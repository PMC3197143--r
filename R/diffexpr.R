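# Paired differential testing: paired t, exact Wilcoxon signed-rank,
# Benjamini-Hochberg correction, the combined significance rule, MA-plot
# quantities and correlation summaries.

#' Paired t-test
#'
#' Classic paired t on the per-pair differences `d = x - y`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, two-sided p from the t
#' distribution with `n - 1` degrees of freedom.
#'
#' Degenerate inputs: when the differences have zero variance, the
#' statistic is 0 with p = 1 if their mean is also zero, otherwise the p
#' value degenerates to 0 (with a warning) since every pair moved by the
#' identical amount.
#'
#' @param x,y Equal-length paired numeric vectors (n >= 2).
#' @return Tibble `statistic`, `df`, `p.value`.
#' @export
paired_t_test <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 2,
              "paired vectors of equal length n >= 2 required")
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(tibble(statistic = 0, df = n - 1, p.value = 1))
    warn("zero variance with nonzero mean difference; p degenerates to 0")
    return(tibble(statistic = sign(mean(d)) * Inf, df = n - 1, p.value = 0))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  tibble(statistic = t_stat, df = n - 1,
         p.value = 2 * pt(-abs(t_stat), df = n - 1))
}

# row-wise paired t over matrices (X, Y columns are paired samples)
paired_t_rows <- function(X, Y) {
  D <- X - Y
  n <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(pmax(rowSums((D - m)^2) / (n - 1), 0))
  t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), df = n - 1))
  p[t_stat == 0 & s == 0] <- 1
  tibble(t = t_stat, t_p = p, mean_diff = m)
}

# exact null distribution of W+ given the (tie-averaged) ranks: the
# distribution of a sum over independent coin flips contributing 0 or
# r_i each -- identical to enumerating all 2^n sign assignments.
signed_rank_distribution <- function(ranks2) {
  # ranks2: ranks doubled to integers (ties give half-integer ranks)
  f <- c(1)
  for (r in ranks2) {
    g <- c(f, rep(0, r))
    g[(r + 1):(r + length(f))] <- g[(r + 1):(r + length(f))] + f
    f <- g
  }
  f / sum(f)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Computes `W+`, the sum of ranks of positive differences (zeros
#' dropped, average ranks for tied magnitudes), and a two-sided p value.
#' For `n <= exact_limit` effective pairs the p value is exact under the
#' sign-flip null -- equal to full enumeration of all `2^n` sign
#' assignments -- via the convolution of the per-pair rank
#' contributions; beyond that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param exact_limit Largest effective n for the exact distribution
#'   (default 25).
#' @return Tibble `statistic` (W+), `p.value`, `n_effective`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  assert_that(length(x) == length(y), "paired vectors must match in length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(tibble(statistic = 0, p.value = 1, n_effective = 0L,
                  exact = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  if (n <= exact_limit) {
    dist <- signed_rank_distribution(as.integer(round(2 * r)))
    # support of 2*W+ is 0..2*total; index i corresponds to 2W = i - 1
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1)])
    p_ge <- sum(dist[(w2 + 1):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(tibble(statistic = w, p.value = p, n_effective = as.integer(n),
                  exact = TRUE))
  }
  mu <- total / 2
  tie_sizes <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_sizes^3 - tie_sizes) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  tibble(statistic = w, p.value = p, n_effective = as.integer(n),
         exact = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q values `q_i = min_{j >= i} (m * p_(j) / j)`, monotone in the
#' p-value ranks (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Numeric vector of q values.
#' @export
bh_fdr <- function(p) {
  assert_that(all(is.na(p) | (p >= 0 & p <= 1)),
              "p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed features between paired samples
#'
#' Applies the combined paired decision rule feature by feature: a
#' feature is significant when the paired t-test p and the exact
#' Wilcoxon signed-rank p are both below `alpha` *and* the BH false
#' discovery rate (computed on the t-test p values) is at most
#' `fdr_ceiling`. Tests run on `log2(RPKM + 1)` by default; the fold
#' change reported is `log2` of the ratio of summed counts across
#' conditions with a pseudocount. An externally computed per-feature FDR
#' (e.g. from a count-model package) can be plugged in via
#' `external_fdr` to replace the built-in BH column in the conjunction.
#'
#' @param expression Tibble: feature id column then one column per
#'   sample (RPKM or TPM).
#' @param counts Tibble of the same shape with raw counts (used for the
#'   fold-change column); may be NULL to compute fold change from
#'   `expression`.
#' @param design Tibble `sample_id`, `patient_id`, `condition` with
#'   condition values `"tumor"` / `"normal"`; at least 3 complete pairs.
#' @param alpha Per-test significance level (default 0.05).
#' @param fdr_ceiling BH FDR ceiling (default 0.05).
#' @param log_transform Test on `log2(value + pseudocount_expr)`
#'   (default TRUE).
#' @param pseudocount_expr Pseudocount for the log transform (default 1).
#' @param pseudocount_fc Pseudocount for the count fold change (default
#'   0.5).
#' @param external_fdr Optional tibble `feature_id`, `fdr` replacing the
#'   BH column in the significance conjunction.
#' @return A `diff_calls` tibble: `feature_id`, mean expression per
#'   condition, `log2fc`, `t`, `t_p`, `w`, `w_p`, `q`, `significant`,
#'   `direction`. Features expressed in no sample are excluded before
#'   testing.
#' @export
call_features <- function(expression, counts = NULL, design,
                          alpha = 0.05, fdr_ceiling = 0.05,
                          log_transform = TRUE, pseudocount_expr = 1,
                          pseudocount_fc = 0.5, external_fdr = NULL) {
  id_col <- names(expression)[1]
  design <- design |>
    mutate(condition = ifelse(.data$condition %in%
                                c("non_tumor", "non-tumor", "NT"),
                              "normal", .data$condition))
  patients <- design |>
    tidyr::pivot_wider(id_cols = "patient_id", names_from = "condition",
                       values_from = "sample_id")
  assert_that(all(c("tumor", "normal") %in% names(patients)) &&
                nrow(patients) >= 3,
              "a paired design with at least 3 complete pairs is required")
  t_cols <- patients$tumor
  n_cols <- patients$normal

  feats <- expression[[id_col]]
  Xt <- as.matrix(expression[t_cols])
  Xn <- as.matrix(expression[n_cols])
  keep <- rowMeans(Xt) > 0 | rowMeans(Xn) > 0
  feats <- feats[keep]
  Xt <- Xt[keep, , drop = FALSE]
  Xn <- Xn[keep, , drop = FALSE]

  Vt <- if (log_transform) log2(Xt + pseudocount_expr) else Xt
  Vn <- if (log_transform) log2(Xn + pseudocount_expr) else Xn

  t_res <- paired_t_rows(Vt, Vn)
  w_res <- purrr::map(seq_len(nrow(Vt)), function(i)
    wilcoxon_signed_rank(Vt[i, ], Vn[i, ])) |> bind_rows()

  if (!is.null(counts)) {
    cm <- counts[match(feats, counts[[1]]), , drop = FALSE]
    ct <- rowSums(as.matrix(cm[t_cols]))
    cn <- rowSums(as.matrix(cm[n_cols]))
  } else {
    ct <- rowSums(Xt)
    cn <- rowSums(Xn)
  }
  log2fc <- log2((ct + pseudocount_fc) / (cn + pseudocount_fc))

  q <- bh_fdr(t_res$t_p)
  if (!is.null(external_fdr))
    q <- external_fdr$fdr[match(feats, external_fdr$feature_id)]

  out <- tibble(
    feature_id = feats,
    mean_tumor = rowMeans(Xt), mean_normal = rowMeans(Xn),
    log2fc = log2fc,
    t = t_res$t, t_p = t_res$t_p,
    w = w_res$statistic, w_p = w_res$p.value,
    q = q,
    significant = t_res$t_p < alpha & w_res$p.value < alpha &
      !is.na(q) & q <= fdr_ceiling,
    direction = ifelse(t_res$mean_diff >= 0, "up", "down"))
  attr(out, "alpha") <- alpha
  attr(out, "fdr_ceiling") <- fdr_ceiling
  attr(out, "n_pairs") <- nrow(patients)
  class(out) <- c("diff_calls", class(out))
  out
}

#' @export
tidy.diff_calls <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @export
glance.diff_calls <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_significant = sum(x$significant),
         n_up = sum(x$significant & x$direction == "up"),
         n_down = sum(x$significant & x$direction == "down"),
         alpha = attr(x, "alpha"),
         fdr_ceiling = attr(x, "fdr_ceiling"),
         n_pairs = attr(x, "n_pairs"))
}

#' MA-plot quantities from pooled condition counts
#'
#' `M` is the log2 fold change of pooled tumour over pooled normal
#' counts with a pseudocount; the abundance coordinate ("concentration")
#' is the sum of the two count fractions,
#' `count_T / total_T + count_N / total_N`, on raw counts. Features with
#' a zero raw count in either condition are flagged (plotted as their
#' own class on an MA plot).
#'
#' @param pooled Tibble `feature_id`, `count_tumor`, `count_normal`.
#' @param total_tumor,total_normal Pooled total read counts.
#' @param pseudocount Pseudocount for `M` only (default 0.5).
#' @return Tibble `feature_id`, `m`, `concentration`, `zero_flag`.
#' @export
ma_values <- function(pooled, total_tumor, total_normal,
                      pseudocount = 0.5) {
  pooled |>
    transmute(
      feature_id = .data$feature_id,
      m = log2((.data$count_tumor + pseudocount) /
                 (.data$count_normal + pseudocount)),
      concentration = .data$count_tumor / total_tumor +
        .data$count_normal / total_normal,
      zero_flag = .data$count_tumor == 0 | .data$count_normal == 0)
}

#' Pairwise Pearson correlations between samples
#'
#' @param expression Tibble: feature id column then per-sample columns
#'   (typically log2-transformed).
#' @param design Optional design tibble; when given, mean correlations
#'   are summarised for normal-normal, tumour-tumour and tumour-normal
#'   sample pairs.
#' @return List with `matrix` (symmetric PCC matrix; samples with
#'   constant expression give `NA` rows) and `summary` (tibble of group
#'   mean PCCs, or NULL).
#' @export
sample_correlation_matrix <- function(expression, design = NULL) {
  M <- as.matrix(expression[-1])
  sds <- apply(M, 2, sd)
  cc <- suppressWarnings(cor(M, method = "pearson"))
  cc[sds == 0, ] <- NA
  cc[, sds == 0] <- NA
  diag(cc) <- ifelse(sds == 0, NA, 1)
  summary <- NULL
  if (!is.null(design)) {
    design <- design |>
      mutate(condition = ifelse(.data$condition %in%
                                  c("non_tumor", "non-tumor", "NT"),
                                "normal", .data$condition))
    cond <- setNames(design$condition, design$sample_id)[colnames(cc)]
    pairs <- which(upper.tri(cc), arr.ind = TRUE)
    ptbl <- tibble(
      a = cond[pairs[, 1]], b = cond[pairs[, 2]],
      pcc = cc[pairs]) |>
      mutate(group = dplyr::case_when(
        .data$a == "normal" & .data$b == "normal" ~ "normal-normal",
        .data$a == "tumor" & .data$b == "tumor" ~ "tumor-tumor",
        TRUE ~ "tumor-normal"))
    summary <- ptbl |>
      group_by(.data$group) |>
      summarise(mean_pcc = mean(.data$pcc, na.rm = TRUE),
                n_pairs = dplyr::n(), .groups = "drop")
  }
  list(matrix = cc, summary = summary)
}

#' Cross-platform expression comparison
#'
#' Pearson correlation of mean log2 expression between two platforms on
#' their shared features, plus each platform's dynamic range.
#'
#' @param x,y Named numeric vectors of mean log2 expression (names are
#'   feature ids), or tibbles `feature_id`, `value`.
#' @param mapping Optional tibble `feature_x`, `feature_y` mapping ids
#'   between platforms; default matches on identical names.
#' @return Tibble `pcc`, `n_common`, `range_x_min`, `range_x_max`,
#'   `range_y_min`, `range_y_max`.
#' @export
platform_comparison <- function(x, y, mapping = NULL) {
  as_named <- function(v) {
    if (is.data.frame(v)) setNames(v[[2]], v[[1]]) else v
  }
  x <- as_named(x)
  y <- as_named(y)
  if (is.null(mapping)) {
    common <- intersect(names(x), names(y))
    xv <- x[common]
    yv <- y[common]
  } else {
    keep <- mapping$feature_x %in% names(x) & mapping$feature_y %in% names(y)
    xv <- x[mapping$feature_x[keep]]
    yv <- y[mapping$feature_y[keep]]
  }
  assert_that(length(xv) >= 3,
              "fewer than 3 common features between platforms")
  tibble(pcc = cor(xv, yv), n_common = length(xv),
         range_x_min = min(xv), range_x_max = max(xv),
         range_y_min = min(yv), range_y_max = max(yv))
}
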