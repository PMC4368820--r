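# Handmade method outputs let the ratio operations be checked by
# arithmetic without running any pipeline.
fake_output <- function(method, dataset, detected, n_fdr,
                        scores = NULL) {
  structure(list(method = method, dataset = dataset,
                 selected_p = character(), selected_q = character(),
                 n_selected_fdr = n_fdr, functions_detected = detected,
                 function_p = scores),
            class = "method_output")
}

test_that("relative specificity and sensitivity follow their definitions", {
  ref <- fake_output("ref", "d1", sprintf("F%d", 1:12), 400)
  m <- fake_output("m", "d1", sprintf("F%d", 1:3), 100)
  expect_equal(relative_specificity(m, ref), 0.25)
  expect_equal(relative_specificity(ref, ref), 1)
  # RSE = RSP * Gq_m / Gq_ref = 0.25 * 100 / 400
  expect_equal(relative_sensitivity(m, ref), 0.0625)
  expect_equal(relative_sensitivity(ref, ref), 1)

  # zero FDR selection zeroes sensitivity regardless of specificity
  m0 <- fake_output("m0", "d1", sprintf("F%d", 1:6), 0)
  expect_equal(relative_sensitivity(m0, ref), 0)

  # reference with no detected functions: flagged undefined, no error
  empty_ref <- fake_output("ref", "d1", character(), 10)
  rsp <- relative_specificity(m, empty_ref)
  expect_true(is.na(rsp))
  expect_true(attr(rsp, "undefined"))

  # different data sets must not be compared
  other <- fake_output("m", "d2", "F1", 5)
  expect_error(relative_specificity(other, ref), "different data sets")
})

test_that("relative reproducibility averages occurrence over instances", {
  # datasets {A: {f1, f2}, B: {f1}}: occurrences f1 = 2, f2 = 1;
  # instances (f1@A, f2@A, f1@B) -> mean (2 + 1 + 2) / 3 = 5/3
  m <- list(fake_output("m", "A", c("f1", "f2"), 1),
            fake_output("m", "B", "f1", 1))
  ref <- list(fake_output("ref", "A", "f9", 1),
              fake_output("ref", "B", "f9", 1))  # raw statistic 2
  expect_equal(relative_reproducibility(m, ref), (5 / 3) / 2)
  # the per-unique-function alternative: mean(2, 1) / 2
  expect_equal(relative_reproducibility(m, ref, per = "function"),
               1.5 / 2)
  # one function in all D data sets, identical reference -> ratio 1
  solo <- list(fake_output("m", "A", "f1", 1),
               fake_output("m", "B", "f1", 1))
  expect_equal(relative_reproducibility(solo, solo), 1)
  # nothing detected -> flagged undefined
  none <- list(fake_output("m", "A", character(), 0),
               fake_output("m", "B", character(), 0))
  rr <- relative_reproducibility(none, ref)
  expect_true(is.na(rr) && attr(rr, "undefined"))
  expect_error(relative_reproducibility(m[1], ref[1]), "at least 2")
})

test_that("detection rate averages per-data-set fractions", {
  universe <- sprintf("g%02d", 1:30)
  col <- gene_set_collection(
    setNames(lapply(1:5, function(i) universe[(3 * i - 2):(3 * i)]),
             sprintf("DF%d", 1:5)), universe)
  outs <- list(fake_output("m", "A", sprintf("DF%d", 1:3), 1),
               fake_output("m", "B", "DF1", 1))
  # 3/5 in A, 1/5 in B -> 0.4
  expect_equal(detection_rate(outs, sprintf("DF%d", 1:5), col), 0.4)
  expect_equal(detection_rate(outs, sprintf("DF%d", 1:5), col,
                              per_dataset = FALSE), 0.6)
  all_out <- list(fake_output("m", "A", sprintf("DF%d", 1:5), 1))
  expect_equal(detection_rate(all_out, sprintf("DF%d", 1:5), col), 1)
  expect_error(detection_rate(outs, "DF9", col), "unknown")
})

test_that("AUC against a reference set honours ranks, ties and symmetry", {
  fns <- sprintf("F%02d", 1:20)
  ref <- fns[1:5]
  perfect <- setNames(seq(1e-9, 1e-4, length.out = 20), fns)
  expect_equal(as.numeric(auc_vs_reference(perfect, ref, fns)), 1)
  reversed <- setNames(rev(unname(perfect)), fns)
  expect_equal(as.numeric(auc_vs_reference(reversed, ref, fns)), 0)
  expect_true(attr(auc_vs_reference(reversed, ref, fns), "misanalyzed"))

  # invariant under strictly monotone transformation of the scores
  set.seed(12)
  sc <- setNames(runif(20), fns)
  a1 <- as.numeric(auc_vs_reference(sc, ref, fns))
  a2 <- as.numeric(auc_vs_reference(sc^3, ref, fns))
  expect_equal(a1, a2)

  # unevaluated functions rank last
  partial <- sc[1:10]
  a3 <- as.numeric(auc_vs_reference(partial, ref, fns))
  manual <- {
    full <- rep(Inf, 20); names(full) <- fns; full[names(partial)] <- partial
    r <- rank(-full); (sum(r[fns %in% ref]) - 5 * 6 / 2) / (5 * 15)
  }
  expect_equal(a3, manual)

  expect_error(auc_vs_reference(sc, character(), fns), "non-empty")
  expect_error(auc_vs_reference(sc, fns, fns), "full function universe")
})

test_that("random rankings centre the AUC at one half", {
  fns <- sprintf("F%02d", 1:40)
  ref <- fns[1:8]
  set.seed(66)
  aucs <- replicate(10000, {
    as.numeric(auc_vs_reference(setNames(runif(40), sample(fns)), ref,
                                fns))
  })
  mc_se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * mc_se)
})

test_that("progressive degradation permutes pairs cumulatively and reproducibly", {
  ds <- simulate_type2(synthetic_config(
    n_features = 500, n_test = 4, n_control = 4, deg_fraction = 0.1,
    n_subtypes = 2, subtype_block_size = 30, seed = 14))
  reps <- progressive_degradation(ds$matrix, ds$design, seed = 5)
  expect_length(reps, 5L)
  expect_identical(reps$rep0, ds$matrix)
  # same seed, same series
  reps2 <- progressive_degradation(ds$matrix, ds$design, seed = 5)
  expect_identical(reps, reps2)
  # each replicate only rearranges values within arrays
  for (r in reps)
    expect_equal(apply(r, 2, sort), apply(ds$matrix, 2, sort))
  # fully degraded replicate: arrays of pair 1 differ, column sets same
  expect_false(identical(reps$rep4[, "t1"], ds$matrix[, "t1"]))

  unpaired <- cohort_design(c("t1", "t2", "t3"), c("c1", "c2"))
  expect_error(progressive_degradation(ds$matrix, unpaired, seed = 1),
               "paired")
})

test_that("detected-function counts decline along the degradation series", {
  ds <- simulate_type2(synthetic_config(
    n_features = 3000, n_test = 8, n_control = 8, deg_fraction = 0.06,
    n_subtypes = 2, subtype_block_size = 100, n_sets = 25, seed = 44))
  reps <- progressive_degradation(ds$matrix, ds$design, seed = 44)
  curve <- degradation_curve(reps, ds$design, ds$collection,
                             method = "ttest")
  psel <- curve[curve$selection == "p<0.05", ]
  ct <- suppressWarnings(cor.test(psel$replicate, psel$n_functions,
                                  method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
  expect_gte(psel$n_functions[1], psel$n_functions[nrow(psel)])
  # top-fraction curves exist for the three standard fractions
  expect_setequal(unique(curve$selection),
                  c("p<0.05", "top5%", "top10%", "top15%"))
})

test_that("self-normalization pins every relative measure of the reference at 1", {
  sc <- simulate_study_collection(synthetic_config(
    n_features = 1500, n_test = 4, n_control = 4, deg_fraction = 0.08,
    n_subtypes = 2, subtype_block_size = 60, n_sets = 20, seed = 200),
    n_datasets = 2)
  datasets <- lapply(sc$datasets, function(d)
    list(matrix = d$matrix, design = d$design))
  rep <- bmorr_report(datasets, sc$collection, methods = "hta")
  hta_rows <- rep$per_dataset[rep$per_dataset$method == "hta", ]
  expect_equal(hta_rows$rsp, rep(1, 2))
  expect_equal(hta_rows$rse, rep(1, 2))
  expect_equal(rep$per_method$rr[rep$per_method$method == "hta"], 1)
})

test_that("on heterogeneous data the reference method outranks the t-test in sensitivity", {
  wins <- 0L
  n_runs <- 5L
  for (i in seq_len(n_runs)) {
    ds <- simulate_type2(synthetic_config(
      n_features = 2000, n_test = 6, n_control = 6, deg_fraction = 0.05,
      n_subtypes = 2, subtype_block_size = 120, n_sets = 20,
      seed = 500 + i))
    datasets <- list(d1 = list(matrix = ds$matrix, design = ds$design))
    rep <- bmorr_report(datasets, ds$collection,
                        methods = c("hta", "ttest"))
    rse_t <- rep$per_dataset$rse[rep$per_dataset$method == "ttest"]
    if (is.na(rse_t) || rse_t <= 1) wins <- wins + 1L
  }
  expect_gt(wins, n_runs / 2)
})
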