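# Small matrices and designs built in code for the unit tests.

tiny_matrix <- function(values, features = NULL, samples = NULL) {
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (!is.matrix(values)) values <- matrix(values, nrow = n)
  if (is.null(features)) features <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  values
}

# Template + iid Gaussian error arrays, one call site for many tests.
noisy_cohort <- function(n_features, n_arrays, sd, seed,
                         prefix = "r") {
  set.seed(seed)
  template <- rnorm(n_features, 7, 2)
  x <- template + matrix(rnorm(n_features * n_arrays, 0, sd),
                         n_features, n_arrays)
  dimnames(x) <- list(sprintf("f%05d", seq_len(n_features)),
                      paste0(prefix, seq_len(n_arrays)))
  x
}

# Independent oracle: multiply Gaussian densities on a fine grid and
# read mean/variance off the normalized product.
grid_posterior <- function(values, sigma2) {
  sd_all <- sqrt(sigma2)
  lo <- min(values - 10 * sd_all)
  hi <- max(values + 10 * sd_all)
  y <- seq(lo, hi, length.out = 400001L)
  logd <- rep(0, length(y))
  for (i in seq_along(values))
    logd <- logd + dnorm(y, values[i], sd_all[i], log = TRUE)
  d <- exp(logd - max(logd))
  d <- d / sum(d)
  mu <- sum(y * d)
  list(mu = mu, var = sum((y - mu)^2 * d))
}

# Independent oracle: BH step-up by direct enumeration of
# q_(i) = min_{k >= i} m p_(k) / k.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(k) m * p[ord[k]] / k, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# Independent oracle: exhaustive hypergeometric upper tail by
# enumerating all C(N, n) selections.
enumerated_upper_tail <- function(N, K, n, k) {
  sels <- combn(N, n)
  inset <- seq_len(K)
  overlaps <- apply(sels, 2, function(s) sum(s %in% inset))
  mean(overlaps >= k)
}
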