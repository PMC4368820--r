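#' Variance of per-feature log2 differences between two arrays
#'
#' For arrays r_i and r_j of one cohort, the per-feature difference
#' d_f = x(f, i) - x(f, j) removes the biological signal shared by the
#' cohort, so under normally distributed technical error the variance of
#' d across features estimates the sum of the two arrays' error
#' variances, Var(d) = sigma2_i + sigma2_j.  Most features are assumed
#' non-differential, so all features enter the estimate.
#'
#' @param x expression matrix.
#' @param sample_i,sample_j distinct sample (column) identifiers.
#' @param robust if `TRUE`, use the squared scaled median absolute
#'   deviation of the differences instead of their variance; a guard for
#'   heavy-tailed contamination, off by default.
#' @return the difference variance (log2 units squared).
#' @export
pairwise_difference_variance <- function(x, sample_i, sample_j,
                                         robust = FALSE) {
  x <- expression_matrix(x)
  sample_i <- as.character(sample_i)
  sample_j <- as.character(sample_j)
  if (identical(sample_i, sample_j))
    stop("sample_i and sample_j must be distinct arrays", call. = FALSE)
  missing <- setdiff(c(sample_i, sample_j), colnames(x))
  if (length(missing))
    stop("sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- x[, sample_i] - x[, sample_j]
  if (robust) stats::mad(d)^2 else stats::var(d)
}

#' Estimate samplewise error variances from pairwise array comparisons
#'
#' Technical error is taken as homogeneous across features but
#' heterogeneous across arrays.  For each unordered pair (r_i, r_j)
#' within the cohort the difference variance sigma2_ij is computed with
#' [pairwise_difference_variance()]; since sigma2_ij = sigma2_i +
#' sigma2_j, sigma2_ij / 2 estimates sigma2_i, and averaging over the
#' n - 1 partners gives
#'
#'   sigma2_i = (1/2) * (1/(n-1)) * sum_{j != i} sigma2_ij.
#'
#' The estimate is invariant under scaling normalization because
#' per-array additive shifts cancel in the differences.
#'
#' @param x expression matrix (need not be normalized).
#' @param cohort character vector of >= 2 sample identifiers.
#' @param robust passed to [pairwise_difference_variance()].
#' @return an object of class `sample_error_model`: list with `sigma2`
#'   (named per-sample error variances), `pairwise` (named difference
#'   variances, names `"i|j"`), `cohort`, `robust`, and the flooring
#'   state (`floored`, `floor`).
#' @export
estimate_sample_error_variances <- function(x, cohort, robust = FALSE) {
  x <- expression_matrix(x)
  cohort <- as.character(cohort)
  n <- length(cohort)
  if (n < 2L)
    stop("error-variance estimation needs a cohort of at least 2 arrays",
         call. = FALSE)
  if (anyDuplicated(cohort))
    stop("duplicated sample identifiers in cohort", call. = FALSE)
  missing <- setdiff(cohort, colnames(x))
  if (length(missing))
    stop("cohort sample(s) absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pairs <- utils::combn(cohort, 2L)
  pairwise <- apply(pairs, 2L, function(pr)
    pairwise_difference_variance(x, pr[1L], pr[2L], robust = robust))
  names(pairwise) <- paste(pairs[1L, ], pairs[2L, ], sep = "|")
  sigma2 <- vapply(cohort, function(s) {
    involve <- pairs[1L, ] == s | pairs[2L, ] == s
    0.5 * mean(pairwise[involve])
  }, numeric(1L))
  structure(list(sigma2 = sigma2, pairwise = pairwise, cohort = cohort,
                 robust = robust, floored = FALSE, floor = NA_real_),
            class = "sample_error_model")
}

#' @export
print.sample_error_model <- function(x, ...) {
  cat("Samplewise error model (", length(x$cohort), " arrays",
      if (x$robust) ", robust", ")\n", sep = "")
  cat("Estimated error SDs (log2):\n")
  print(round(sqrt(x$sigma2), 5))
  if (isTRUE(x$floored))
    cat("Variance floor", format(x$floor), "was applied\n")
  invisible(x)
}

#' Floor degenerate error variances
#'
#' Replaces every samplewise error variance below `floor` by `floor`,
#' preventing infinite precision weights on degenerate inputs (e.g.
#' duplicated arrays in synthetic data).  The model records whether any
#' replacement occurred.
#'
#' @param model a `sample_error_model`.
#' @param floor strictly positive variance (log2 units squared).
#' @return the model with floored `sigma2` and updated flags.
#' @export
apply_variance_floor <- function(model, floor = 1e-12) {
  if (!inherits(model, "sample_error_model"))
    stop("'model' must be a sample_error_model", call. = FALSE)
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor) ||
      floor <= 0)
    stop("'floor' must be a single variance > 0", call. = FALSE)
  hit <- model$sigma2 < floor
  model$sigma2[hit] <- floor
  model$floored <- any(hit)
  model$floor <- floor
  model
}

#' Posterior of a cohort's true mean for one feature
#'
#' Each measurement carries a Gaussian density centred on its observed
#' log2 value with its array's error variance.  Multiplying the cohort's
#' Gaussians (flat prior) yields a Gaussian posterior for the cohort's
#' true mean with the standard precision-weighted form:
#'
#'   var = 1 / sum_i (1 / sigma2_i),   mu = var * sum_i (x_i / sigma2_i).
#'
#' @param values numeric vector of one feature's log2 values across the
#'   cohort's arrays.
#' @param sigma2 matching vector of (floored) positive error variances.
#' @return list with elements `mu` and `var`.
#' @examples
#' cohort_posterior(c(0, 1), c(1, 4))  # mu 0.2, var 0.8
#' @export
cohort_posterior <- function(values, sigma2) {
  if (length(values) != length(sigma2))
    stop("'values' and 'sigma2' must have the same length", call. = FALSE)
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("all error variances must be finite and > 0 (apply a variance floor)",
         call. = FALSE)
  w <- 1 / sigma2
  v <- 1 / sum(w)
  list(mu = v * sum(values * w), var = v)
}

#' Heterogeneity-aware z-test for differential expression
#'
#' The full pipeline for one two-cohort contrast:
#' \enumerate{
#'   \item estimate samplewise error variances within each cohort from
#'     pairwise array comparisons (on the matrix as given; the estimate
#'     is invariant under scaling normalization);
#'   \item apply scaling normalization (unless `normalize = FALSE`, for
#'     matrices already on a common level);
#'   \item combine each cohort's per-measurement Gaussians into the
#'     precision-weighted posterior of the cohort's true mean;
#'   \item test each feature with z = (mu_t - mu_c) / sqrt(var_t + var_c),
#'     two-sided standard-normal p-values, and Benjamini-Hochberg FDR
#'     over all features.
#' }
#'
#' Because the error variance is shared across features, equal sample
#' quality makes the |z| ranking identical to the |fold-change| ranking;
#' uneven quality downweights noisy arrays instead of inflating
#' per-feature variance estimates the way a t-test does.
#'
#' @param x expression matrix of log2 intensities.
#' @param design a `cohort_design`; every sample must be a column of `x`.
#' @param variance_floor lower bound applied to the samplewise error
#'   variances (log2 units squared).
#' @param robust use robust pairwise difference variances.
#' @param normalize apply scaling normalization before combining cohort
#'   means (default `TRUE`).
#' @return data.frame with one row per feature and columns `feature`,
#'   `fc_hat` (log2 fold-change estimate mu_t - mu_c), `var_fc`
#'   (var_t + var_c), `z`, `p`, `q`.  The two fitted
#'   `sample_error_model`s and the normalization report are attached as
#'   attributes `error_models` and `normalization`.
#' @export
hta_test <- function(x, design, variance_floor = 1e-12, robust = FALSE,
                     normalize = TRUE) {
  x <- expression_matrix(x)
  check_design(design, x)
  model_t <- apply_variance_floor(
    estimate_sample_error_variances(x, design$test, robust = robust),
    variance_floor)
  model_c <- apply_variance_floor(
    estimate_sample_error_variances(x, design$control, robust = robust),
    variance_floor)
  norm_report <- NULL
  if (normalize) {
    norm <- scaling_normalize(x)
    x <- norm$matrix
    norm_report <- norm$report
  }
  w_t <- 1 / model_t$sigma2
  w_c <- 1 / model_c$sigma2
  var_t <- 1 / sum(w_t)
  var_c <- 1 / sum(w_c)
  mu_t <- as.vector(x[, design$test, drop = FALSE] %*% w_t) * var_t
  mu_c <- as.vector(x[, design$control, drop = FALSE] %*% w_c) * var_c
  fc_hat <- mu_t - mu_c
  var_fc <- var_t + var_c
  z <- fc_hat / sqrt(var_fc)
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  res <- data.frame(feature = rownames(x), fc_hat = fc_hat,
                    var_fc = var_fc, z = z, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "error_models") <- list(test = model_t, control = model_c)
  attr(res, "normalization") <- norm_report
  res
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values q_(i) = min_(k >= i) m p_(k) / k, capped at
#' 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0L)
    stop("'pvalues' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}
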