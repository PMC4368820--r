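#' Pooled two-sample t-test per feature
#'
#' The classical baseline: per feature, the pooled (common) sample
#' variance
#'
#'   S_c^2 = ((n1 - 1) S1^2 + (n2 - 1) S2^2) / (n1 + n2 - 2)
#'
#' and t = (xbar_t - xbar_c) / (S_c * sqrt(1/n1 + 1/n2)) with
#' n1 + n2 - 2 degrees of freedom, two-sided p-values and BH FDR.  The
#' per-feature variance estimate is exactly what molecular heterogeneity
#' corrupts: subtype-driven spread is mistaken for error and the feature
#' is deprioritized.
#'
#' Degenerate features with S_c = 0 and zero mean difference are
#' reported with t = 0, p = 1 and the `degenerate` flag; S_c = 0 with a
#' nonzero difference yields an infinite t (p floored at the smallest
#' positive double), also flagged.
#'
#' @param x expression matrix of log2 intensities.
#' @param design a `cohort_design` with >= 2 samples per cohort.
#' @return data.frame with columns `feature`, `mean_diff` (log2),
#'   `s_c` (common sample SD), `t`, `df`, `p`, `q`, `degenerate`.
#' @export
pooled_t_test <- function(x, design) {
  x <- expression_matrix(x)
  check_design(design, x)
  xt <- x[, design$test, drop = FALSE]
  xc <- x[, design$control, drop = FALSE]
  n1 <- ncol(xt)
  n2 <- ncol(xc)
  m1 <- rowMeans(xt)
  m2 <- rowMeans(xc)
  s1sq <- rowSums((xt - m1)^2) / (n1 - 1)
  s2sq <- rowSums((xc - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2L
  scsq <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
  se <- sqrt(scsq * (1 / n1 + 1 / n2))
  diff <- m1 - m2
  tstat <- diff / se
  degenerate <- scsq == 0
  zero_both <- degenerate & diff == 0
  tstat[zero_both] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero_both] <- 1
  p <- pmax(p, .Machine$double.xmin)
  data.frame(feature = rownames(x), mean_diff = diff, s_c = sqrt(scsq),
             t = tstat, df = df, p = p, q = bh_fdr(p),
             degenerate = degenerate, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Hybrid p-value plus fold-change selection
#'
#' The widely adopted hybrid method: keep features whose significance
#' p-value is below `p_cut` AND whose absolute log2 fold-change exceeds
#' `fc_cut`, both inequalities strict.  Defaults reproduce the common
#' HM(p < 0.05, |FC| > 1) recipe.  The significance test feeding the
#' selection is the pooled t-test.
#'
#' @param tt result of [pooled_t_test()] (any data.frame with `feature`
#'   and `p` columns works).
#' @param fc per-feature log2 mean difference; defaults to
#'   `tt$mean_diff`.
#' @param p_cut p-value cutoff in (0, 1).
#' @param fc_cut absolute log2 fold-change cutoff, >= 0.
#' @return character vector of selected feature identifiers.
#' @export
hybrid_select <- function(tt, fc = NULL, p_cut = 0.05, fc_cut = 1) {
  if (!is.data.frame(tt) || !all(c("feature", "p") %in% names(tt)))
    stop("'tt' must be a result table with 'feature' and 'p' columns",
         call. = FALSE)
  if (is.null(fc)) {
    if (!"mean_diff" %in% names(tt))
      stop("supply 'fc' or a table with a 'mean_diff' column", call. = FALSE)
    fc <- tt$mean_diff
  }
  if (length(fc) != nrow(tt))
    stop("'fc' must have one value per feature", call. = FALSE)
  if (!is.numeric(p_cut) || length(p_cut) != 1L || p_cut <= 0 || p_cut >= 1)
    stop("'p_cut' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(fc_cut) || length(fc_cut) != 1L || fc_cut < 0)
    stop("'fc_cut' must be >= 0", call. = FALSE)
  tt$feature[tt$p < p_cut & abs(fc) > fc_cut]
}
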