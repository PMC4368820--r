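test_that("generation is a deterministic function of config and seed", {
  cfg <- synthetic_config(n_features = 300, deg_fraction = 0.1,
                          n_sets = 10, seed = 42)
  a <- simulate_type1(cfg)
  b <- simulate_type1(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$collection$sets, b$collection$sets)
  c2 <- simulate_type1(synthetic_config(n_features = 300,
                                        deg_fraction = 0.1, n_sets = 10,
                                        seed = 43))
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(error_sd = 0), "> 0")
  expect_error(synthetic_config(deg_fraction = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(n_test = 1), "at least 2")
  expect_error(synthetic_config(n_subtypes = 5, n_test = 3),
               "more subtypes")
  expect_error(simulate_type1(synthetic_config(n_subtypes = 2)),
               "no latent subtypes")
  expect_error(simulate_type2(synthetic_config()), "at least one")
})

test_that("ground truth is consistent with the generated matrix", {
  cfg <- synthetic_config(n_features = 2000, n_test = 5, n_control = 5,
                          deg_fraction = 0.1, error_sd = 0.05,
                          seed = 50)
  ds <- simulate_type1(cfg)
  tr <- ds$truth$features
  expect_true(all(tr$true_fc[!tr$is_deg] == 0))
  expect_true(all(abs(tr$true_fc[tr$is_deg]) >= 0.3 &
                    abs(tr$true_fc[tr$is_deg]) <= 2))
  # empirical fold-changes track the planted shifts
  fc_emp <- rowMeans(ds$matrix[, ds$design$test]) -
    rowMeans(ds$matrix[, ds$design$control])
  expect_gt(cor(fc_emp[tr$is_deg], tr$true_fc[tr$is_deg]), 0.95)
})

test_that("type I data show no variance-fold-change dependence, type II do", {
  ds1 <- simulate_type1(synthetic_config(
    n_features = 4000, n_test = 6, n_control = 6, deg_fraction = 0.05,
    seed = 60))
  tt1 <- pooled_t_test(ds1$matrix, ds1$design)
  rho1 <- suppressWarnings(cor.test(tt1$s_c, abs(tt1$mean_diff),
                                    method = "spearman"))
  expect_lt(abs(rho1$estimate), 0.05)

  ds2 <- simulate_type2(synthetic_config(
    n_features = 4000, n_test = 6, n_control = 6, deg_fraction = 0.05,
    n_subtypes = 2, subtype_block_size = 150, seed = 60))
  tt2 <- pooled_t_test(ds2$matrix, ds2$design)
  rho2 <- suppressWarnings(cor.test(tt2$s_c, abs(tt2$mean_diff),
                                    method = "spearman", exact = FALSE))
  expect_gt(rho2$estimate, 0)
  expect_lt(rho2$p.value, 0.01)
})

test_that("type II with zero subtype shift collapses to type I bit for bit", {
  cfg2 <- synthetic_config(n_features = 800, n_subtypes = 2,
                           subtype_block_size = 40, subtype_shift = 0,
                           seed = 71)
  cfg1 <- synthetic_config(n_features = 800, seed = 71)
  expect_identical(simulate_type2(cfg2)$matrix,
                   simulate_type1(cfg1)$matrix)
})

test_that("per-feature pooled SDs on null type I data match the chi-square form", {
  sd0 <- 0.25
  ds <- simulate_type1(synthetic_config(n_features = 5000,
                                        error_sd = sd0, seed = 81))
  tt <- pooled_t_test(ds$matrix, ds$design)
  df <- tt$df[1]
  ks <- suppressWarnings(ks.test(df * tt$s_c^2 / sd0^2, "pchisq",
                                 df = df))
  expect_gt(ks$p.value, 0.01)
})

test_that("signal sets are enriched in true differential features by construction", {
  ds <- simulate_type2(synthetic_config(
    n_features = 3000, n_test = 6, n_control = 6, deg_fraction = 0.05,
    n_subtypes = 2, subtype_block_size = 100, n_sets = 20, seed = 90))
  tr <- ds$truth
  deg <- tr$features$feature[tr$features$is_deg]
  expect_gt(sum(tr$functions$is_signal_set), 0)
  for (fn in tr$functions$function_id[tr$functions$is_signal_set]) {
    p <- bias_toward_functions(ds$collection$sets[[fn]], deg,
                               ds$collection$universe)
    expect_lt(p, 0.001)
  }
})

test_that("uneven per-sample error SDs shrink toward the cohort mean as derived", {
  # splitting each pairwise variance in half attributes
  # sigma2_i_hat = (sigma2_i + mean_{j != i} sigma2_j) / 2: the average
  # variance is recovered exactly and the quality ordering is kept, but
  # individual values shrink toward the cohort mean.
  sds <- c(0.1, 0.3, 0.5, 0.2, 0.2, 0.2, 0.2, 0.2)
  ds <- simulate_type1(synthetic_config(n_features = 20000, n_test = 4,
                                        n_control = 4, error_sd = sds,
                                        seed = 95))
  m <- estimate_sample_error_variances(ds$matrix, ds$design$test)
  v <- sds[1:4]^2
  expected <- vapply(1:4, function(i)
    (v[i] + mean(v[-i])) / 2, numeric(1))
  expect_equal(unname(m$sigma2), expected, tolerance = 0.05)
  expect_equal(mean(m$sigma2), mean(v), tolerance = 0.05)
  expect_identical(order(m$sigma2), order(v))
})

test_that("study collections share biology and differ only in noise", {
  cfg <- synthetic_config(n_features = 800, n_test = 4, n_control = 4,
                          deg_fraction = 0.1, n_subtypes = 2,
                          subtype_block_size = 40, n_sets = 15,
                          seed = 97)
  sc <- simulate_study_collection(cfg, n_datasets = 3)
  expect_length(sc$datasets, 3L)
  expect_identical(sc$datasets$d1$matrix, simulate_type2(cfg)$matrix)
  # shared signal, distinct noise
  expect_identical(sc$datasets$d1$signal, sc$datasets$d2$signal)
  expect_false(identical(sc$datasets$d1$matrix, sc$datasets$d2$matrix))
  # deterministic regeneration
  sc2 <- simulate_study_collection(cfg, n_datasets = 3)
  expect_identical(sc$datasets$d3$matrix, sc2$datasets$d3$matrix)
  expect_error(simulate_study_collection(cfg, 1), "at least 2")
})

test_that("the fixture suite regenerates identically and passes its readers", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_fixture_suite(dir1, seed = 3, n_features = 300)
  make_fixture_suite(dir2, seed = 3, n_features = 300)
  man <- read.delim(file.path(dir1, "manifest.tsv"),
                    colClasses = "character")
  expect_setequal(man$dataset, c("null_type1", "deg_type1", "type2",
                                 "paired_type2"))
  for (i in seq_len(nrow(man))) {
    expect_identical(readLines(file.path(dir1, man$matrix[i])),
                     readLines(file.path(dir2, man$matrix[i])))
    x <- read_expression_matrix(file.path(dir1, man$matrix[i]))
    d <- read_cohort_design(file.path(dir1, man$design[i]))
    expect_true(all(c(d$test, d$control) %in% colnames(x)))
    if (nzchar(man$gmt[i])) {
      col <- read_gene_sets(file.path(dir1, man$gmt[i]), rownames(x))
      expect_gt(length(col$sets), 0)
    }
  }
  # the null fixture is calibrated under the z-test
  null_x <- read_expression_matrix(file.path(dir1, "null_type1_matrix.tsv"))
  null_d <- read_cohort_design(file.path(dir1, "null_type1_design.tsv"))
  de <- hta_test(null_x, null_d)
  expect_lt(abs(mean(de$p < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / nrow(de)) + 0.01)
})
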